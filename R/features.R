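#' Pair mutation coverage
#'
#' Fraction of cohort samples mutated in at least one member of the pair.
#' For a gene mutated in samples s1, s3, s6 paired with a gene mutated in
#' s3, s8, s9 over n samples, coverage is 5/n.
#'
#' @param mut binary mutation matrix.
#' @param gene_a,gene_b equal-length gene symbol vectors, all rows of `mut`.
#' @return coverage fractions in `[0, 1]`.
#' @export
pair_coverage <- function(mut, gene_a, gene_b) {
  missing <- setdiff(unique(c(gene_a, gene_b)), rownames(mut))
  if (length(missing)) stop("gene absent from mutation matrix: ", missing[1L])
  A <- mut[gene_a, , drop = FALSE]
  B <- mut[gene_b, , drop = FALSE]
  unname(rowSums(A == 1L | B == 1L) / ncol(mut))
}

#' Expression outlier events
#'
#' Flags (gene, sample) events where a sample's expression deviates from the
#' gene's cohort mean by at least `z_cutoff` standard deviations (per-gene
#' mean and SD across samples, SD with denominator n-1; the comparison is
#' inclusive). Genes with zero variance yield no events.
#'
#' @param expr expression matrix (genes x samples, >= 3 samples).
#' @param z_cutoff absolute z-score threshold (default 2).
#' @return data.frame with columns `gene`, `sample`, `z`.
#' @export
expression_outliers <- function(expr, z_cutoff = 2) {
  stopifnot(ncol(expr) >= 3L)
  ev <- .outlier_matrix(expr, z_cutoff)
  idx <- which(ev$events, arr.ind = TRUE)
  data.frame(gene = rownames(expr)[idx[, 1L]],
             sample = colnames(expr)[idx[, 2L]],
             z = ev$z[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

# internal: logical event matrix + z matrix
.outlier_matrix <- function(expr, z_cutoff) {
  mu <- rowMeans(expr)
  n <- ncol(expr)
  s <- sqrt(rowSums((expr - mu)^2) / (n - 1L))
  z <- (expr - mu) / ifelse(s > 0, s, NA_real_)
  events <- !is.na(z) & abs(z) >= z_cutoff
  list(events = events, z = z)
}

#' Per-gene driver-mutation p-values from a greedy event cover
#'
#' Scores how strongly each gene's mutations explain expression-outlier
#' events in the gene itself or its network neighbors, in the spirit of
#' mutation-to-expression driver analysis. An outlier event (g, s) is
#' *coverable* by a mutated gene m in sample s when g equals m or is one of
#' m's neighbors in the cancer network. Genes are selected greedily: the
#' mutated gene covering the most still-uncovered events is picked (ties go
#' to lexicographic gene order), its covered events are removed, and the
#' process repeats until no event is coverable. Each selected gene then
#' receives a permutation p-value: gene labels of the mutation-matrix rows
#' are permuted `n_perm` times and
#' `p = (1 + #permutations with coverage >= observed) / (1 + n_perm)`,
#' where coverage (observed and null) is the gene's event coverage against
#' the full event set. Unselected genes get p = 1.
#'
#' Alternatively, a precomputed per-gene p-value table (e.g. from a
#' dedicated driver-discovery package) can be supplied via `external` and is
#' returned as-is, aligned to the gene universe.
#'
#' @param mut binary mutation matrix, sample-aligned with `expr`.
#' @param expr expression matrix (same samples, same order).
#' @param net `cancer_network` used as the influence graph.
#' @param z_cutoff outlier threshold passed to the event layer.
#' @param n_perm number of label permutations (default 100).
#' @param seed integer seed for the permutation generator.
#' @param external optional data.frame with columns `gene`, `p`; when given,
#'   the greedy scorer is skipped.
#' @return named numeric vector of p-values in `(0, 1]` over the union of
#'   mutation and expression genes; the attribute `"selected"` records the
#'   greedily selected genes in selection order (absent for external input).
#' @export
driver_pvalues <- function(mut, expr, net, z_cutoff = 2, n_perm = 100L,
                           seed = 1L, external = NULL) {
  genes_u <- sort(unique(c(rownames(mut), rownames(expr))))
  if (!is.null(external)) {
    p <- rep(1, length(genes_u))
    names(p) <- genes_u
    hit <- intersect(external$gene, genes_u)
    p[hit] <- external$p[match(hit, external$gene)]
    if (any(p <= 0 | p > 1)) stop("external p-values must be in (0, 1]")
    return(p)
  }
  if (!identical(colnames(mut), colnames(expr)))
    stop("mutation and expression matrices must be sample-aligned (see align_samples)")

  nu <- length(genes_u)
  S <- ncol(mut)
  MutU <- matrix(0, nu, S, dimnames = list(genes_u, colnames(mut)))
  MutU[rownames(mut), ] <- mut
  EvU <- matrix(0, nu, S, dimnames = list(genes_u, colnames(mut)))
  EvU[rownames(expr), ] <- .outlier_matrix(expr, z_cutoff)$events

  p <- rep(1, nu)
  names(p) <- genes_u
  attr(p, "selected") <- character(0)
  if (sum(EvU) == 0) {
    warning("no expression-outlier events; all driver p-values are 1")
    return(p)
  }

  # closed-neighborhood incidence over the gene universe
  Nb <- diag(nu)
  el <- igraph::as_edgelist(net$graph)
  el <- el[el[, 1L] %in% genes_u & el[, 2L] %in% genes_u, , drop = FALSE]
  if (nrow(el)) {
    i <- match(el[, 1L], genes_u); j <- match(el[, 2L], genes_u)
    Nb[cbind(i, j)] <- 1
    Nb[cbind(j, i)] <- 1
  }

  PreN <- Nb %*% EvU                       # events reachable per (gene, sample)
  cov_full <- rowSums(MutU * PreN)         # full-event-set coverage per gene

  # greedy cover decides which genes are scored
  EvCur <- EvU
  PreCur <- PreN
  selected <- integer(0)
  repeat {
    cnt <- rowSums(MutU * PreCur)
    cnt[selected] <- 0
    best <- max(cnt)
    if (best <= 0) break
    pick <- which(cnt == best)[1L]         # genes_u sorted => lexicographic tie-break
    selected <- c(selected, pick)
    nbr <- which(Nb[pick, ] > 0)
    scols <- which(MutU[pick, ] == 1)
    if (length(scols)) {
      EvCur[nbr, scols] <- 0
      PreCur[, scols] <- Nb %*% EvCur[, scols, drop = FALSE]
    }
  }
  attr(p, "selected") <- genes_u[selected]
  if (length(selected) == 0L) return(p)

  set.seed(seed)
  obs <- cov_full[selected]
  PreSel <- PreN[selected, , drop = FALSE]
  exceed <- integer(length(selected))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nu)
    covb <- rowSums(MutU[perm[selected], , drop = FALSE] * PreSel)
    exceed <- exceed + (covb >= obs)
  }
  p[selected] <- (1 + exceed) / (1 + n_perm)
  p
}

#' Driver score of a gene pair
#'
#' The smaller of the two genes' driver p-values, transformed to
#' `-log10(p)`; p is floored at 1e-16, capping the score at 16. Genes
#' without a p-value are treated as p = 1 (score contribution 0).
#'
#' @param gene_a,gene_b equal-length gene symbol vectors.
#' @param pvals named p-value vector from [driver_pvalues()].
#' @return non-negative scores.
#' @export
pair_driver_score <- function(gene_a, gene_b, pvals) {
  get_p <- function(g) {
    p <- unname(pvals[g])
    p[is.na(p)] <- 1
    p
  }
  p <- pmin(get_p(gene_a), get_p(gene_b))
  -log10(pmax(p, 1e-16))
}

#' Min-max normalization to \[0, 1\]
#'
#' `(x - min(x)) / (max(x) - min(x))`; a constant vector maps to all zeros.
#'
#' @param x numeric vector.
#' @return normalized vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  stopifnot(length(x) >= 1L, all(is.finite(x)))
  rng <- range(x)
  if (rng[1L] == rng[2L]) return(rep(0, length(x)))
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

#' Build the feature table for positives and candidates
#'
#' Computes the three raw features (coverage, driver score, information
#' centrality) for every screened candidate pair and every positive SL pair,
#' then min-max normalizes each feature over the union of both sets, so that
#' positives and candidates share one scale (they are compared by the
#' ranker). Positive pairs lacking either gene in the mutation matrix are
#' dropped with a message; positives outside the network get centrality by
#' the no-op-removal rule (0 when neither gene is present). Candidate rows
#' that duplicate a positive pair are re-labeled `"positive"`, so no pair is
#' both labeled and unlabeled (disable with `cfg$relabel_positives = FALSE`
#' to keep such pairs in the ranked candidate set instead).
#'
#' @param candidates screened candidate table from [screen_candidates()].
#' @param positives data.frame of positive pairs (`gene_a`, `gene_b`).
#' @param mut,expr sample-aligned mutation and expression matrices.
#' @param net `cancer_network`.
#' @param cfg run configuration ([sl_config()]); fields used: `outlier_z`,
#'   `permutations`, `rng_seed`, `continuity`, `driver_external`.
#' @param driver optional precomputed named p-value vector; when `NULL`,
#'   [driver_pvalues()] is run with seed `cfg$rng_seed`.
#' @return data.frame with screening statistics, raw and normalized feature
#'   columns, `label`, and unset `score`/`rank`.
#' @export
build_feature_table <- function(candidates, positives, mut, expr, net,
                                cfg = sl_config(), driver = NULL) {
  positives <- .canonical_pairs(positives$gene_a, positives$gene_b)
  positives <- positives[!duplicated(.pair_id(positives$gene_a, positives$gene_b)), ,
                         drop = FALSE]
  in_mut <- positives$gene_a %in% rownames(mut) & positives$gene_b %in% rownames(mut)
  if (any(!in_mut))
    message(sum(!in_mut), " positive pair(s) dropped (gene absent from mutation matrix)")
  positives <- positives[in_mut, , drop = FALSE]
  if (nrow(positives) == 0L) stop("no positive pair has both genes in the mutation matrix")

  pos_id <- .pair_id(positives$gene_a, positives$gene_b)
  records <- candidates
  if (isTRUE(cfg$relabel_positives %||% TRUE))
    records$label[records$pair_id %in% pos_id] <- "positive"

  new_pos <- positives[!pos_id %in% records$pair_id, , drop = FALSE]
  if (nrow(new_pos)) {
    ct <- pair_contingency(mut, new_pos$gene_a, new_pos$gene_b)
    add <- data.frame(gene_a = new_pos$gene_a, gene_b = new_pos$gene_b,
                      pair_id = .pair_id(new_pos$gene_a, new_pos$gene_b),
                      ct,
                      chi2_p = chi_square_p(ct$M, ct$N, ct$X, ct$Y,
                                            correct = cfg$continuity),
                      exclusivity = exclusivity(ct$M, ct$N, ct$X),
                      label = "positive",
                      stringsAsFactors = FALSE)
    records <- rbind(records, add)
  }
  if (nrow(records) == 0L) stop("empty feature table (no candidates and no positives)")

  if (is.null(driver)) {
    driver <- driver_pvalues(mut, expr, net,
                             z_cutoff = cfg$outlier_z,
                             n_perm = cfg$permutations,
                             seed = cfg$rng_seed,
                             external = cfg$driver_external)
  }

  records$coverage <- pair_coverage(mut, records$gene_a, records$gene_b)
  records$driver_score <- pair_driver_score(records$gene_a, records$gene_b, driver)
  records$centrality <- .pair_centralities(net, records$gene_a, records$gene_b)
  records$coverage_norm <- minmax_normalize(records$coverage)
  records$driver_norm <- minmax_normalize(records$driver_score)
  records$centrality_norm <- minmax_normalize(records$centrality)
  records$score <- NA_real_
  records$rank <- NA_integer_
  records <- records[order(records$label != "positive", records$pair_id), , drop = FALSE]
  rownames(records) <- NULL
  records
}
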