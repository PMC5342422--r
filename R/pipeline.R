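#' Run configuration
#'
#' Collects the tunable parameters of the ranking pipeline with the
#' reference defaults: candidate genes must be mutated in at least 1% of
#' samples; candidate pairs must pass the 2x2 chi-square test at p <= 0.05
#' with mutation exclusivity >= 0.8; the diffusion parameter alpha is
#' optimized on a 0 to 0.99 grid (step 0.01) by 10-times-5-fold
#' cross-validation.
#'
#' @param mutation_rate_cutoff minimum per-gene mutation rate, `(0, 1]`.
#' @param chi2_p_max maximum chi-square p-value (inclusive).
#' @param exclusivity_min minimum mutation exclusivity (inclusive).
#' @param continuity apply the Yates continuity correction in screening.
#' @param alpha single diffusion parameter used when no grid search is run.
#' @param alpha_grid grid for [optimize_alpha()], values in `[0, 1)`.
#' @param cv_folds number of cross-validation folds.
#' @param cv_shuffles number of reshuffled CV repetitions.
#' @param top_k evaluation depth for NDCG/enrichment; `NULL` (default) uses
#'   the held-out positive count of each fold.
#' @param rng_seed integer seed driving folds, permutations and any other
#'   randomness.
#' @param outlier_z z-score threshold of the expression-outlier layer.
#' @param permutations label permutations for driver p-values.
#' @param driver_external optional data.frame (`gene`, `p`) of externally
#'   computed driver p-values, bypassing the built-in greedy scorer.
#' @param affinity affinity reading: `"cosine_similarity"` (default) or
#'   `"cosine_distance"`.
#' @param enrichment_tail `"greater"` (the printed strictly-greater tail)
#'   or `"geq"`.
#' @param relabel_positives when `TRUE` (default), screened candidate pairs
#'   that duplicate a known positive are re-labeled positive, so no pair is
#'   both labeled and unlabeled; when `FALSE`, such pairs stay unlabeled
#'   candidates (and are ranked), and only positives absent from the
#'   candidate set form the labeled block.
#' @return object of class `sl_config` (a validated list).
#' @export
sl_config <- function(mutation_rate_cutoff = 0.01,
                      chi2_p_max = 0.05,
                      exclusivity_min = 0.8,
                      continuity = TRUE,
                      alpha = 0.84,
                      alpha_grid = seq(0, 0.99, by = 0.01),
                      cv_folds = 5L,
                      cv_shuffles = 10L,
                      top_k = NULL,
                      rng_seed = 1L,
                      outlier_z = 2,
                      permutations = 100L,
                      driver_external = NULL,
                      affinity = c("cosine_similarity", "cosine_distance"),
                      enrichment_tail = c("greater", "geq"),
                      relabel_positives = TRUE) {
  affinity <- match.arg(affinity)
  enrichment_tail <- match.arg(enrichment_tail)
  stopifnot(mutation_rate_cutoff > 0, mutation_rate_cutoff <= 1,
            chi2_p_max > 0, chi2_p_max <= 1,
            exclusivity_min >= 0, exclusivity_min <= 1,
            alpha >= 0, alpha < 1,
            all(alpha_grid >= 0), all(alpha_grid < 1),
            cv_folds >= 2L, cv_shuffles >= 1L,
            is.null(top_k) || top_k >= 1L,
            rng_seed == as.integer(rng_seed),
            outlier_z >= 0, permutations >= 1L)
  structure(list(mutation_rate_cutoff = mutation_rate_cutoff,
                 chi2_p_max = chi2_p_max,
                 exclusivity_min = exclusivity_min,
                 continuity = continuity,
                 alpha = alpha,
                 alpha_grid = alpha_grid,
                 cv_folds = as.integer(cv_folds),
                 cv_shuffles = as.integer(cv_shuffles),
                 top_k = top_k,
                 rng_seed = as.integer(rng_seed),
                 outlier_z = outlier_z,
                 permutations = as.integer(permutations),
                 driver_external = driver_external,
                 affinity = affinity,
                 enrichment_tail = enrichment_tail,
                 relabel_positives = isTRUE(relabel_positives)),
            class = "sl_config")
}

.load_if_path <- function(x, loader) {
  if (is.character(x) && length(x) == 1L) loader(x) else x
}

#' Run the full ranking pipeline
#'
#' Executes the workflow end to end: sample alignment, biomarker-filtered
#' network construction, mutation-rate / chi-square / exclusivity candidate
#' screening, feature computation and normalization, alpha optimization by
#' repeated cross-validation, and a final ranking trained on *all* positive
#' pairs at the optimized alpha. Inputs may be in-memory objects or file
#' paths (TSV, loaded with the package readers).
#'
#' @param mutation binary mutation matrix or TSV path.
#' @param expression expression matrix or TSV path.
#' @param edges interaction edge list (data.frame or TSV/SIF path).
#' @param biomarkers biomarker symbols (character vector or path).
#' @param positives positive SL pairs (data.frame or two-column TSV path).
#' @param cfg run configuration ([sl_config()]).
#' @param out_dir optional directory; when given, the ranked candidate
#'   table (`ranked_pairs.tsv`), the full feature table
#'   (`feature_table.tsv`), the alpha diagnostics (`alpha_grid.tsv`) and
#'   the run manifest (`manifest.json`) are written there with a
#'   deterministic byte layout.
#' @param top_n size of the reported head slice (default 10).
#' @return list with `records` (scored and ranked feature table),
#'   `alpha` (optimized value), `cv` (the `sl_cv` at the optimum), `grid`
#'   (alpha diagnostics), `top` (head slice of the ranking) and `manifest`.
#' @export
run_pipeline <- function(mutation, expression, edges, biomarkers, positives,
                         cfg = sl_config(), out_dir = NULL, top_n = 10L) {
  mutation <- .load_if_path(mutation, function(p) load_matrix(p, "mutation"))
  expression <- .load_if_path(expression, function(p) load_matrix(p, "expression"))
  edges <- .load_if_path(edges, load_edge_list)
  biomarkers <- .load_if_path(biomarkers, load_gene_list)
  positives <- .load_if_path(positives, load_pair_list)

  aligned <- align_samples(mutation, expression)
  mut <- aligned$mutation
  expr <- aligned$expression

  net <- build_cancer_network(edges, biomarkers)

  rates <- mutation_rates(mut)
  cand_genes <- select_candidate_genes(rates, cfg$mutation_rate_cutoff)
  raw_pairs <- enumerate_raw_pairs(cand_genes, net, mut)
  candidates <- screen_candidates(raw_pairs, mut, cfg)
  if (nrow(candidates) == 0L) stop("screening left no candidate pair")

  records <- build_feature_table(candidates, positives, mut, expr, net, cfg)
  if (!any(records$label != "positive"))
    stop("no unlabeled candidate pair left to rank")

  opt <- optimize_alpha(records, cfg)

  y <- as.numeric(records$label == "positive")
  L <- normalized_affinity(affinity_matrix(
    as.matrix(records[, c("coverage_norm", "driver_norm", "centrality_norm")]),
    cfg$affinity))
  f <- manifold_rank(L, y, opt$alpha)
  records <- rank_candidates(records, f)

  ranked <- records[records$label != "positive", , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  top <- utils::head(ranked, top_n)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "driver_external")],
    seed = cfg$rng_seed,
    n_samples_shared = aligned$n_shared,
    n_network_nodes = length(net$nodes),
    n_network_edges = net$n_edges,
    network_diameter = net$diameter,
    network_efficiency = net$efficiency,
    n_candidate_genes = length(cand_genes),
    n_raw_pairs = nrow(raw_pairs),
    n_screened_pairs = nrow(candidates),
    n_positive_records = sum(records$label == "positive"),
    n_ranked_candidates = nrow(ranked),
    optimized_alpha = opt$alpha,
    cv_mean_ndcg = opt$best$mean_ndcg,
    cv_mean_enrichment_p = opt$best$mean_enrichment_p,
    top_pairs = top$pair_id)

  out <- list(records = records, alpha = opt$alpha, cv = opt$best,
              grid = opt$grid, top = top, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ranked_pairs(ranked, file.path(out_dir, "ranked_pairs.tsv"))
    .write_table_tsv(records, file.path(out_dir, "feature_table.tsv"))
    report_diagnostics(opt, file.path(out_dir, "alpha_grid.tsv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(out_dir, "manifest.json"))
  }
  out
}

# internal: deterministic TSV writer for data.frames
.write_table_tsv <- function(df, path) {
  fmt <- function(x) {
    if (is.double(x)) ifelse(is.na(x), "NA", sprintf("%.10g", x)) else {
      y <- as.character(x); y[is.na(y)] <- "NA"; y
    }
  }
  body <- do.call(paste, c(lapply(df, fmt), sep = "\t"))
  writeLines(c(paste(colnames(df), collapse = "\t"), body), path)
  invisible(path)
}

#' Write alpha-grid ranking diagnostics
#'
#' One row per grid alpha with the CV mean NDCG and mean enrichment
#' p-value — the numbers behind an alpha-vs-performance curve.
#'
#' @param opt result of [optimize_alpha()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
report_diagnostics <- function(opt, path) {
  .write_table_tsv(opt$grid, path)
}
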