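#' Normalized discounted cumulative gain at position p
#'
#' `DCG@p = sum_{i=1}^{p} (2^{rel_i} - 1) / log2(i + 1)` over the ranked
#' binary relevance list, normalized by the ideal DCG obtained by placing
#' `min(total_relevant, p)` relevant items at the top ranks. Returns a value
#' in `[0, 1]`; 1 for a perfect ranking, 0 when no relevant item appears in
#' the top p.
#'
#' @param ranked_relevances binary (0/1 or logical) relevance by rank.
#' @param p evaluation depth (>= 1).
#' @param total_relevant number of relevant items in the whole list (>= 1);
#'   defaults to `sum(ranked_relevances)`.
#' @return NDCG in `[0, 1]`.
#' @export
ndcg_at_p <- function(ranked_relevances, p, total_relevant = sum(ranked_relevances)) {
  stopifnot(p >= 1L, total_relevant >= 1L)
  rel <- as.numeric(ranked_relevances)
  i <- seq_len(min(p, length(rel)))
  dcg <- sum((2^rel[i] - 1) / log2(i + 1))
  ideal_i <- seq_len(min(total_relevant, p))
  ideal <- sum(1 / log2(ideal_i + 1))
  if (ideal == 0) return(0)
  dcg / ideal
}

#' Hypergeometric enrichment of positives in a top-n list
#'
#' Probability of the observed count of positives in the top n of a ranking
#' under random draws without replacement:
#' `p = 1 - sum_{x=0}^{k} C(M, x) C(N-M, n-x) / C(N, n)`
#' with `N` ranked pairs in total, `M` of them positive, and `k` positives
#' observed in the top `n`. As printed, this is the strictly-greater tail
#' `P(K > k)`; `tail = "geq"` switches to the conventional `P(K >= k)`.
#'
#' @param N total number of ranked pairs.
#' @param M number of positives among them.
#' @param n top-list size.
#' @param k positives observed in the top n; `0 <= k <= min(M, n)`.
#' @param tail `"greater"` (as printed, default) or `"geq"`.
#' @return probability in `[0, 1]`.
#' @export
enrichment_p <- function(N, M, n, k, tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  if (!(M <= N && n <= N && k >= 0 && k <= min(M, n)))
    stop("invalid combinatorial bounds: need k <= min(M, n) <= N and M <= N")
  if (tail == "greater") {
    1 - stats::phyper(k, M, N - M, n)
  } else {
    stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
  }
}

# internal: shared state for CV runs (affinity spectrum + fold assignments)
.cv_prepare <- function(records, cfg, permute_labels = FALSE) {
  X <- as.matrix(records[, c("coverage_norm", "driver_norm", "centrality_norm")])
  W <- affinity_matrix(X, cfg$affinity)
  L <- normalized_affinity(W)
  spectrum <- .ranking_spectrum(L)
  pos <- which(records$label == "positive")
  if (permute_labels) {
    set.seed(cfg$rng_seed + 104729L)       # fixed offset stream for the null
    pos <- sort(sample.int(nrow(records), length(pos)))
  }
  q <- length(pos)
  if (q < cfg$cv_folds)
    stop("need at least cv_folds (", cfg$cv_folds, ") positive pairs, got ", q)
  set.seed(cfg$rng_seed)
  folds <- lapply(seq_len(cfg$cv_shuffles), function(s)
    sample(rep_len(seq_len(cfg$cv_folds), q)))
  list(spectrum = spectrum, pos = pos, folds = folds,
       pair_id = records$pair_id, n = nrow(records), cfg = cfg)
}

# internal: one CV pass at a fixed alpha
.cv_run <- function(prep, alpha) {
  cfg <- prep$cfg
  rows <- vector("list", cfg$cv_shuffles * cfg$cv_folds)
  r <- 0L
  for (s in seq_len(cfg$cv_shuffles)) {
    assign <- prep$folds[[s]]
    for (fold in seq_len(cfg$cv_folds)) {
      held <- prep$pos[assign == fold]
      train <- setdiff(prep$pos, held)
      y <- numeric(prep$n)
      y[train] <- 1
      f <- .manifold_rank_spectrum(prep$spectrum, y, alpha)
      unl <- which(y == 0)
      ord <- unl[order(-f[unl], prep$pair_id[unl])]
      rel <- ord %in% held
      p <- cfg$top_k %||% length(held)
      k <- sum(rel[seq_len(min(p, length(rel)))])
      r <- r + 1L
      rows[[r]] <- data.frame(
        shuffle = s, fold = fold, alpha = alpha,
        held_out = length(held),
        ndcg = ndcg_at_p(rel, p, length(held)),
        enrichment_p = enrichment_p(length(unl), length(held), min(p, length(unl)), k,
                                    tail = cfg$enrichment_tail))
    }
  }
  do.call(rbind, rows)
}

#' Repeated k-fold cross-validation of the ranking
#'
#' The positive pairs are split into `cv_folds` segments; in turn each
#' segment is held out, its pairs are merged into the unlabeled set (label
#' score 0), the remaining positives train the diffusion, and the held-out
#' positives' placement in the resulting candidate ranking is scored by
#' NDCG@p and hypergeometric enrichment (top-list size n = p). The
#' evaluation depth p defaults to the held-out positive count (override
#' with `cfg$top_k`). The split is reshuffled `cv_shuffles` times and all
#' shuffle-by-fold results are averaged.
#'
#' @param records feature table ([build_feature_table()]).
#' @param cfg run configuration; fields used: `cv_folds`, `cv_shuffles`,
#'   `top_k`, `rng_seed`, `affinity`, `enrichment_tail`.
#' @param alpha diffusion parameter; defaults to `cfg$alpha`.
#' @param permute_labels when `TRUE`, the positive labels are reassigned to
#'   a random record subset of the same size (a permutation baseline for
#'   the real labels' performance).
#' @return object of class `sl_cv`: list with `results` (one row per
#'   shuffle-by-fold evaluation), `mean_ndcg`, `mean_enrichment_p`, `alpha`.
#' @export
cross_validate <- function(records, cfg = sl_config(), alpha = cfg$alpha,
                           permute_labels = FALSE) {
  prep <- .cv_prepare(records, cfg, permute_labels = permute_labels)
  res <- .cv_run(prep, alpha)
  structure(list(results = res,
                 mean_ndcg = mean(res$ndcg),
                 mean_enrichment_p = mean(res$enrichment_p),
                 alpha = alpha),
            class = "sl_cv")
}

#' @export
print.sl_cv <- function(x, ...) {
  cat(sprintf("sl_cv: alpha %.3f over %d evaluations; mean NDCG %.4f, mean enrichment p %.3g\n",
              x$alpha, nrow(x$results), x$mean_ndcg, x$mean_enrichment_p))
  invisible(x)
}

#' Optimize the diffusion parameter alpha on a grid
#'
#' Runs [cross_validate()] at every alpha of `cfg$alpha_grid` (the affinity
#' spectrum and the CV fold assignments are shared across the grid) and
#' returns the alpha maximizing the mean NDCG; ties go to the smallest
#' alpha.
#'
#' @param records feature table.
#' @param cfg run configuration (`alpha_grid` plus the CV fields).
#' @return list with `alpha` (the optimum), `grid` (data.frame of alpha,
#'   mean_ndcg, mean_enrichment_p) and `best` (the `sl_cv` at the optimum).
#' @export
optimize_alpha <- function(records, cfg = sl_config()) {
  stopifnot(length(cfg$alpha_grid) >= 1L)
  prep <- .cv_prepare(records, cfg)
  runs <- lapply(cfg$alpha_grid, function(a) .cv_run(prep, a))
  grid <- data.frame(alpha = cfg$alpha_grid,
                     mean_ndcg = vapply(runs, function(r) mean(r$ndcg), numeric(1L)),
                     mean_enrichment_p = vapply(runs, function(r) mean(r$enrichment_p),
                                                numeric(1L)))
  at_max <- which(grid$mean_ndcg == max(grid$mean_ndcg))
  best_i <- at_max[which.min(grid$alpha[at_max])]
  res <- runs[[best_i]]
  list(alpha = grid$alpha[best_i],
       grid = grid,
       best = structure(list(results = res, mean_ndcg = mean(res$ndcg),
                             mean_enrichment_p = mean(res$enrichment_p),
                             alpha = grid$alpha[best_i]), class = "sl_cv"))
}

#' One-sided comparison of drug sensitivity between cell-line groups
#'
#' Welch two-sample t test of whether cell lines carrying the partner-gene
#' mutation are *more* sensitive to the drug than wild-type lines. For
#' readouts where larger means more sensitive (e.g. PIC50 = -log10 IC50)
#' use `higher_is_sensitive = TRUE`; for readouts where smaller means more
#' sensitive (e.g. z-scored GI50) use `FALSE`. When both groups are
#' constant, the p-value is 0.5 at equal means, otherwise 0 or 1 by
#' direction.
#'
#' @param values_mut sensitivities of mutation-carrying lines (length >= 2).
#' @param values_wt sensitivities of wild-type lines (length >= 2).
#' @param higher_is_sensitive orientation of the readout.
#' @return one-sided p-value.
#' @export
compare_drug_sensitivity <- function(values_mut, values_wt, higher_is_sensitive = TRUE) {
  stopifnot(length(values_mut) >= 2L, length(values_wt) >= 2L)
  alt <- if (higher_is_sensitive) "greater" else "less"
  out <- tryCatch(
    stats::t.test(values_mut, values_wt, alternative = alt)$p.value,
    error = function(e) {
      d <- mean(values_mut) - mean(values_wt)
      if (d == 0) return(0.5)
      favourable <- if (higher_is_sensitive) d > 0 else d < 0
      if (favourable) 0 else 1
    })
  out
}

#' Relative cell growth under treatment
#'
#' Ratio of cell growth under siRNA (or drug) treatment to growth under
#' placebo.
#'
#' @param treated growth under treatment.
#' @param placebo growth under placebo; must be positive.
#' @return `treated / placebo`, vectorized.
#' @export
relative_growth <- function(treated, placebo) {
  if (any(placebo <= 0)) stop("placebo growth must be positive")
  treated / placebo
}
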