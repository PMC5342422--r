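#' Load a gene-by-sample matrix from TSV
#'
#' Reads a tab-separated matrix with sample identifiers in the header row and
#' gene symbols in the first column (genes in rows, samples in columns).
#' Mutation matrices must be binary (0 = wild type, 1 = mutated); expression
#' matrices hold finite continuous values. Values other than 0/1 in a
#' mutation matrix are rejected rather than interpreted: binarize upstream.
#'
#' @param path path to a TSV file.
#' @param kind `"mutation"` for a binary incidence matrix, `"expression"`
#'   for a continuous matrix.
#' @return a numeric matrix (integer for mutation) with gene rownames and
#'   sample colnames, in file order.
#' @seealso [write_matrix()], [align_samples()]
#' @export
load_matrix <- function(path, kind = c("mutation", "expression")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file needs a gene column plus >=1 sample column: ", path)
  genes <- trimws(df[[1L]])
  samples <- trimws(colnames(df)[-1L])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene label: ", dup[1L])
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop("duplicate sample label: ", dup[1L])

  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- trimws(df[[j + 1L]])
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   col[bad[1L]], genes[bad[1L]], samples[j]))
    }
    vals[, j] <- num
  }
  if (kind == "mutation") {
    bad <- which(!(vals %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1L] - 1L) %% nrow(vals)) + 1L
      j <- ((bad[1L] - 1L) %/% nrow(vals)) + 1L
      stop(sprintf("mutation value not in {0,1}: %g at gene '%s', sample '%s'",
                   vals[bad[1L]], genes[i], samples[j]))
    }
    if (nrow(vals) < 1L || ncol(vals) < 2L)
      stop("mutation matrix needs >=1 gene and >=2 samples")
    storage.mode(vals) <- "integer"
  } else {
    if (any(!is.finite(vals))) stop("expression matrix contains non-finite values")
  }
  vals
}

#' Write a gene-by-sample matrix to TSV
#'
#' Inverse of [load_matrix()]: values are printed with full double precision
#' so that a load/write/load round trip reproduces the matrix exactly.
#'
#' @param m matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Restrict mutation and expression matrices to their shared samples
#'
#' Driver scoring relates mutations to expression changes sample-by-sample,
#' so both matrices must cover the same cohort slice in the same order.
#'
#' @param mut binary mutation matrix (genes x samples).
#' @param expr expression matrix (genes x samples).
#' @return list with elements `mutation`, `expression` (both restricted to
#'   the sample intersection, identical column order) and `n_shared`.
#' @export
align_samples <- function(mut, expr) {
  shared <- intersect(colnames(mut), colnames(expr))
  if (length(shared) == 0L) stop("no overlapping samples between mutation and expression data")
  list(mutation = mut[, shared, drop = FALSE],
       expression = expr[, shared, drop = FALSE],
       n_shared = length(shared))
}

#' Load a two-column gene-pair list
#'
#' Pairs are unordered: each row is canonicalized (lexicographically smaller
#' symbol first) and duplicates, including `(B,A)` repeats of `(A,B)`, are
#' collapsed. Self-pairs are dropped with a warning. A first line whose two
#' fields both start with "gene" (case-insensitive) is treated as a header.
#'
#' @param path two-column TSV file.
#' @return data.frame with character columns `gene_a`, `gene_b`.
#' @export
load_pair_list <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("line %d has %d fields (expected 2)", lineno[bad], nf[bad]))
  }
  a <- trimws(vapply(fields, `[[`, character(1L), 1L))
  b <- trimws(vapply(fields, `[[`, character(1L), 2L))
  if (length(a) && grepl("^gene", a[1L], ignore.case = TRUE) &&
      grepl("^gene", b[1L], ignore.case = TRUE)) {
    a <- a[-1L]; b <- b[-1L]
  }
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    a <- a[!self]; b <- b[!self]
  }
  pairs <- .canonical_pairs(a, b)
  pairs[!duplicated(.pair_id(pairs$gene_a, pairs$gene_b)), , drop = FALSE]
}

#' Write a gene-pair list to TSV
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_list <- function(pairs, path) {
  writeLines(c("gene_a\tgene_b", paste(pairs$gene_a, pairs$gene_b, sep = "\t")), path)
  invisible(path)
}

#' Load a one-symbol-per-line gene list
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @return character vector of unique symbols.
#' @export
load_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}

#' Load an interaction edge list (two-column TSV or SIF)
#'
#' Accepts either a plain two-column TSV of interacting symbols or the SIF
#' format `node <relation> node`; the relation column is ignored. Edges are
#' canonicalized and deduplicated; self-loops are kept here and removed by
#' [build_cancer_network()].
#'
#' @param path edge-list file.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
load_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(!nf %in% c(2L, 3L))) {
    bad <- which(!nf %in% c(2L, 3L))[1L]
    stop(sprintf("line %d has %d fields (expected 2, or 3 for SIF)", lineno[bad], nf[bad]))
  }
  a <- trimws(vapply(fields, `[[`, character(1L), 1L))
  b <- trimws(mapply(function(f, n) f[[n]], fields, nf))
  if (length(a) && grepl("^gene", a[1L], ignore.case = TRUE) &&
      grepl("^gene", b[1L], ignore.case = TRUE)) {
    a <- a[-1L]; b <- b[-1L]
  }
  edges <- .canonical_pairs(a, b)
  edges[!duplicated(.pair_id(edges$gene_a, edges$gene_b)), , drop = FALSE]
}

#' Write a ranked pair table to TSV
#'
#' Rows are written in rank order with a fixed numeric format, so the output
#' is byte-identical for identical input. Every record must carry a rank.
#'
#' @param records data.frame as returned by [rank_candidates()] (candidate
#'   rows of a feature table with `score` and `rank` filled in).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_pairs <- function(records, path) {
  cols <- c("gene_a", "gene_b", "label", "coverage", "driver_score",
            "centrality", "coverage_norm", "driver_norm", "centrality_norm",
            "chi2_p", "exclusivity", "score", "rank")
  missing <- setdiff(cols, colnames(records))
  if (length(missing)) stop("records lack columns: ", paste(missing, collapse = ", "))
  if (any(is.na(records$rank))) stop("unranked record (rank is NA); rank before writing")
  records <- records[order(records$rank), , drop = FALSE]
  fmt <- function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "NA", sprintf("%.10g", x)) else as.character(x)
  }
  body <- do.call(paste, c(lapply(records[cols], fmt), sep = "\t"))
  writeLines(c(paste(cols, collapse = "\t"), body), path)
  invisible(path)
}
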