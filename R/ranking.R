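#' Cosine affinity matrix of feature points
#'
#' Builds the pairwise affinity `W` used by manifold ranking. With the
#' default `measure = "cosine_similarity"`, `W_ij` is the cosine of the
#' angle between the feature triples of pairs i and j — the "relevance"
#' between points, in `[0, 1]` for the non-negative normalized features.
#' The alternative reading `measure = "cosine_distance"` sets
#' `W_ij = 1 - cos(i, j)` instead. The diagonal is always 0, and a point
#' with zero norm has similarity 0 to everything.
#'
#' @param points numeric matrix, one row per pair (normalized features in
#'   `[0, 1]`).
#' @param measure `"cosine_similarity"` (default) or `"cosine_distance"`.
#' @return symmetric non-negative matrix with zero diagonal.
#' @export
affinity_matrix <- function(points, measure = c("cosine_similarity", "cosine_distance")) {
  measure <- match.arg(measure)
  points <- as.matrix(points)
  norms <- sqrt(rowSums(points^2))
  unit <- points / ifelse(norms > 0, norms, 1)
  unit[norms == 0, ] <- 0
  W <- tcrossprod(unit)
  if (measure == "cosine_distance") W <- 1 - W
  W[W < 0] <- 0
  diag(W) <- 0
  W
}

#' Symmetrically normalized affinity
#'
#' `L = D^{-1/2} W D^{-1/2}` with `D` the diagonal matrix of row sums of
#' `W`. Rows with zero degree stay zero, so isolated points do not receive
#' diffused mass.
#'
#' @param W affinity matrix from [affinity_matrix()].
#' @return symmetric matrix with spectral radius at most 1.
#' @export
normalized_affinity <- function(W) {
  d <- rowSums(W)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- W * tcrossprod(s)
  (L + t(L)) / 2                           # enforce exact symmetry
}

#' Manifold ranking scores
#'
#' Diffuses the initial labels `y` (1 for known positives, 0 for unlabeled
#' points) over the normalized affinity graph. The closed form is
#' `f* = (1 - alpha) (I - alpha L)^{-1} y`; the equivalent iteration is
#' `f_{t+1} = alpha L f_t + (1 - alpha) y` from `f_0 = y`, run until the
#' maximum absolute change drops below `tol`. `alpha` in `[0, 1)` trades
#' off diffusion against fidelity to the initial labels; `alpha = 0`
#' returns `y` unchanged. Points with zero degree end up with
#' `(1 - alpha) y_i`.
#'
#' @param L normalized affinity from [normalized_affinity()].
#' @param y numeric 0/1 label vector.
#' @param alpha diffusion parameter in `[0, 1)`.
#' @param method `"closed_form"` (default) or `"iterative"`.
#' @param tol convergence tolerance for the iterative solver.
#' @param max_iter iteration cap for the iterative solver.
#' @return numeric score vector `f*` (non-negative).
#' @export
manifold_rank <- function(L, y, alpha, method = c("closed_form", "iterative"),
                          tol = 1e-9, max_iter = 10000L) {
  method <- match.arg(method)
  stopifnot(alpha >= 0, alpha < 1, length(y) == nrow(L))
  if (method == "closed_form") {
    f <- solve(diag(nrow(L)) - alpha * L, y) * (1 - alpha)
    return(as.numeric(f))
  }
  f <- y
  for (it in seq_len(max_iter)) {
    f_new <- alpha * as.numeric(L %*% f) + (1 - alpha) * y
    if (max(abs(f_new - f)) < tol) return(f_new)
    f <- f_new
  }
  warning("iterative manifold ranking did not reach tol within max_iter")
  f
}

# internal: eigendecomposition of L, reused across alphas and CV folds
.ranking_spectrum <- function(L) {
  eigen(L, symmetric = TRUE)
}

# internal: f* via the spectrum; (I - alpha L)^{-1} = V diag(1/(1-alpha*lambda)) V'
.manifold_rank_spectrum <- function(spectrum, y, alpha) {
  coef <- crossprod(spectrum$vectors, y)
  as.numeric(spectrum$vectors %*% (coef * ((1 - alpha) / (1 - alpha * spectrum$values))))
}

#' Rank unlabeled candidate pairs by their diffusion scores
#'
#' Only unlabeled points (label != "positive") are ranked, in decreasing
#' order of `f*`; ties are broken by the canonical pair identifier, so the
#' ranking is independent of input order.
#'
#' @param records feature table ([build_feature_table()]).
#' @param f_star score vector aligned with `records` rows.
#' @return `records` with `score` filled for all rows and `rank` (1-based,
#'   dense over candidates) for unlabeled rows; positives keep `NA` rank.
#' @export
rank_candidates <- function(records, f_star) {
  stopifnot(length(f_star) == nrow(records))
  records$score <- as.numeric(f_star)
  cand <- which(records$label != "positive")
  ord <- cand[order(-records$score[cand], records$pair_id[cand])]
  records$rank <- NA_integer_
  records$rank[ord] <- seq_along(ord)
  records
}
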