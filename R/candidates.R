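#' Per-gene mutation rates
#'
#' Fraction of cohort samples in which each gene is mutated.
#'
#' @param mut binary mutation matrix (genes x samples).
#' @return named numeric vector of rates in `[0, 1]`.
#' @export
mutation_rates <- function(mut) {
  rowMeans(mut)
}

#' Select candidate genes by mutation-rate cutoff
#'
#' @param rates named rates from [mutation_rates()].
#' @param cutoff minimum rate, in `(0, 1]`; the comparison is inclusive
#'   (a gene mutated in exactly `cutoff` of samples is kept).
#' @return character vector of candidate gene symbols (possibly empty, with
#'   a warning).
#' @export
select_candidate_genes <- function(rates, cutoff = 0.01) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0, cutoff <= 1)
  genes <- names(rates)[rates >= cutoff]
  if (length(genes) == 0L) warning("no gene reaches the mutation-rate cutoff")
  genes
}

#' Enumerate raw candidate pairs
#'
#' A raw candidate pair combines a candidate gene (mutation rate above the
#' cutoff) with a gene of the cancer network. Both genes must be present in
#' the mutation matrix, since the downstream contingency test needs mutation
#' profiles for both. Pairs are unordered and deduplicated.
#'
#' @param cand_genes candidate gene symbols.
#' @param net a `cancer_network`.
#' @param mut binary mutation matrix.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
enumerate_raw_pairs <- function(cand_genes, net, mut) {
  cand <- intersect(cand_genes, rownames(mut))
  netg <- intersect(net$nodes, rownames(mut))
  if (length(cand) == 0L || length(netg) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE))
  grid <- expand.grid(c = cand, g = netg, stringsAsFactors = FALSE)
  grid <- grid[grid$c != grid$g, , drop = FALSE]
  pairs <- .canonical_pairs(grid$c, grid$g)
  pairs[!duplicated(.pair_id(pairs$gene_a, pairs$gene_b)), , drop = FALSE]
}

#' 2x2 mutation contingency counts for gene pairs
#'
#' For each pair, counts samples by joint mutation status: `M` both genes
#' mutated, `N` only the first, `X` only the second, `Y` neither. The four
#' cells always sum to the number of samples.
#'
#' @param mut binary mutation matrix.
#' @param gene_a,gene_b equal-length vectors of gene symbols; all must be
#'   rows of `mut`.
#' @return data.frame with columns `M`, `N`, `X`, `Y` (one row per pair).
#' @export
pair_contingency <- function(mut, gene_a, gene_b) {
  missing <- setdiff(unique(c(gene_a, gene_b)), rownames(mut))
  if (length(missing)) stop("gene absent from mutation matrix: ", missing[1L])
  A <- mut[gene_a, , drop = FALSE]
  B <- mut[gene_b, , drop = FALSE]
  M <- rowSums(A == 1L & B == 1L)
  N <- rowSums(A == 1L & B == 0L)
  X <- rowSums(A == 0L & B == 1L)
  Y <- rowSums(A == 0L & B == 0L)
  data.frame(M = as.integer(M), N = as.integer(N),
             X = as.integer(X), Y = as.integer(Y), row.names = NULL)
}

#' Pearson chi-square p-value for 2x2 mutation contingency tables
#'
#' Tests the null hypothesis that the two genes' mutations occur
#' independently across samples. Vectorized over tables; with
#' `correct = TRUE` (default) the Yates continuity correction
#' `max(0, |O - E| - 1/2)` is applied, matching the standard corrected 2x2
#' test. Tables with a zero row or column marginal have no defined test and
#' return `NA`.
#'
#' @param M,N,X,Y cell counts (both mutated / first only / second only /
#'   neither), vectorized.
#' @param correct apply the continuity correction.
#' @return p-values in `[0, 1]`, `NA` where a marginal is zero.
#' @export
chi_square_p <- function(M, N, X, Y, correct = TRUE) {
  M <- as.numeric(M); N <- as.numeric(N); X <- as.numeric(X); Y <- as.numeric(Y)
  total <- M + N + X + Y
  r1 <- M + N; r2 <- X + Y; c1 <- M + X; c2 <- N + Y
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  e11 <- r1 * c1 / total; e12 <- r1 * c2 / total
  e21 <- r2 * c1 / total; e22 <- r2 * c2 / total
  dev <- abs(M - e11)                       # identical for all 4 cells of a 2x2
  if (correct) dev <- pmax(0, dev - 0.5)
  stat <- dev^2 * (1 / e11 + 1 / e12 + 1 / e21 + 1 / e22)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  p[!ok] <- NA_real_
  p
}

#' Mutation exclusivity of a gene pair
#'
#' Fraction of mutated samples that carry exactly one of the pair's
#' mutations, `(X + N) / (M + N + X)`. A value of 1 means fully mutually
#' exclusive mutations, 0 fully co-occurring. Undefined (`NA`) when neither
#' gene is ever mutated.
#'
#' @param M,N,X contingency cells as in [pair_contingency()], vectorized.
#' @return exclusivity in `[0, 1]`, `NA` when `M + N + X = 0`.
#' @export
exclusivity <- function(M, N, X) {
  tot <- M + N + X
  out <- (X + N) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Screen raw pairs by independence test and mutation exclusivity
#'
#' Computes the contingency table, chi-square p-value and exclusivity for
#' every raw pair and keeps those with defined statistics,
#' `chi2_p <= chi2_p_max` and `exclusivity >= exclusivity_min` (both
#' thresholds inclusive). Pairs with undefined statistics (zero marginal, or
#' no mutated sample) are excluded, not imputed; their count is reported.
#'
#' @param pairs data.frame of raw pairs (`gene_a`, `gene_b`).
#' @param mut binary mutation matrix.
#' @param cfg run configuration from [sl_config()]; fields used:
#'   `chi2_p_max`, `exclusivity_min`, `continuity`.
#' @return data.frame of surviving candidate pairs with columns `gene_a`,
#'   `gene_b`, `pair_id`, `M`, `N`, `X`, `Y`, `chi2_p`, `exclusivity`,
#'   `label` (all `"candidate"`).
#' @export
screen_candidates <- function(pairs, mut, cfg = sl_config()) {
  if (nrow(pairs) == 0L) {
    warning("no raw pairs to screen")
    return(.empty_candidates())
  }
  ct <- pair_contingency(mut, pairs$gene_a, pairs$gene_b)
  p <- chi_square_p(ct$M, ct$N, ct$X, ct$Y, correct = cfg$continuity)
  ex <- exclusivity(ct$M, ct$N, ct$X)
  undefined <- is.na(p) | is.na(ex)
  if (any(undefined))
    message(sum(undefined), " pair(s) with undefined statistics excluded")
  keep <- !undefined & p <= cfg$chi2_p_max & ex >= cfg$exclusivity_min
  if (!any(keep)) {
    warning("no pair survives screening")
    return(.empty_candidates())
  }
  out <- data.frame(gene_a = pairs$gene_a[keep], gene_b = pairs$gene_b[keep],
                    pair_id = .pair_id(pairs$gene_a[keep], pairs$gene_b[keep]),
                    ct[keep, , drop = FALSE],
                    chi2_p = p[keep], exclusivity = ex[keep],
                    label = "candidate",
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

.empty_candidates <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             pair_id = character(0),
             M = integer(0), N = integer(0), X = integer(0), Y = integer(0),
             chi2_p = numeric(0), exclusivity = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}
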