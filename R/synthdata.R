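#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with independent background mutations, a set of planted
#' mutually exclusive gene pairs whose members double as expression drivers,
#' and a preferential-attachment interaction network partially covered by a
#' biomarker list. Defaults describe the reference study conditions used
#' throughout the package's tests: a mid-sized cohort (200 samples, 300
#' genes) with sparse background mutations (2%), ten planted pairs at
#' exclusivity 0.9 whose member genes are mutated at driver-gene-like rates
#' (45% of samples; high marginal rates are what give the 2x2 independence
#' test power to call exclusivity at this cohort size), and a 3-SD
#' expression shift on network neighbors of mutated planted genes.
#'
#' @param n_samples cohort size (>= 2).
#' @param n_genes number of genes (>= 10).
#' @param background_rate i.i.d. per-gene, per-sample mutation probability.
#' @param n_planted_pairs number of planted SL pairs.
#' @param exclusivity_level probability that a planted-pair mutation event
#'   hits exactly one member (the remainder hits both); in `[0.8, 1]` so
#'   planted pairs pass the default screen.
#' @param planted_rate per-gene mutation rate of planted-pair members; must
#'   satisfy `planted_rate <= 1 - exclusivity_level / 2` so the implied
#'   per-sample event rate stays below 1.
#' @param driver_effect expression shift, in SD units, applied to network
#'   neighbors of a mutated planted gene in its mutated samples.
#' @param n_net_genes number of genes carrying the interaction network.
#' @param pa_edges edges added per node in the preferential-attachment
#'   model (network density knob).
#' @param biomarker_fraction fraction of network genes on the biomarker
#'   list (so biomarker filtering prunes some edges).
#' @param rng_seed integer seed; mandatory, every draw derives from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200L, n_genes = 300L,
                       background_rate = 0.02, n_planted_pairs = 10L,
                       exclusivity_level = 0.9, planted_rate = 0.45,
                       driver_effect = 3, n_net_genes = 100L, pa_edges = 2L,
                       biomarker_fraction = 0.8, rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  stopifnot(n_samples >= 2L, n_genes >= 10L,
            background_rate > 0, background_rate < 1,
            n_planted_pairs >= 0L,
            exclusivity_level >= 0, exclusivity_level <= 1,
            planted_rate > 0, planted_rate <= 1 - exclusivity_level / 2,
            driver_effect >= 0,
            n_net_genes >= 10L, n_net_genes <= n_genes,
            biomarker_fraction >= 0, biomarker_fraction <= 1,
            rng_seed == as.integer(rng_seed))
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 background_rate = background_rate,
                 n_planted_pairs = as.integer(n_planted_pairs),
                 exclusivity_level = exclusivity_level,
                 planted_rate = planted_rate,
                 driver_effect = driver_effect,
                 n_net_genes = as.integer(n_net_genes),
                 pa_edges = as.integer(pa_edges),
                 biomarker_fraction = biomarker_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

.sim_genes <- function(cfg) {
  sprintf("g%04d", seq_len(cfg$n_genes))
}

#' Simulate an interaction network and biomarker list
#'
#' Draws a connected preferential-attachment graph over a random subset of
#' the gene universe and marks a configured fraction of its nodes as
#' biomarkers, so that [build_cancer_network()] prunes some edges — the
#' same shape as a protein-interaction database filtered by a curated
#' cancer-gene list.
#'
#' @param cfg a [sim_config()].
#' @return list with `edges` (data.frame `gene_a`/`gene_b`), `biomarkers`
#'   (character), `net_genes` (nodes of the raw graph) and `genes` (the full
#'   gene universe).
#' @export
simulate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  genes <- .sim_genes(cfg)
  net_genes <- sort(sample(genes, cfg$n_net_genes))
  g <- igraph::sample_pa(cfg$n_net_genes, power = 1, m = cfg$pa_edges,
                         directed = FALSE)
  igraph::V(g)$name <- net_genes
  el <- igraph::as_edgelist(g)
  edges <- .canonical_pairs(el[, 1L], el[, 2L])
  edges <- edges[!duplicated(.pair_id(edges$gene_a, edges$gene_b)), , drop = FALSE]
  n_bio <- round(cfg$biomarker_fraction * cfg$n_net_genes)
  biomarkers <- sort(sample(net_genes, n_bio))
  list(edges = edges, biomarkers = biomarkers,
       net_genes = net_genes, genes = genes)
}

#' Simulate a tumor cohort with planted synthetic-lethal pairs
#'
#' Background mutations are i.i.d. Bernoulli at `background_rate`. Each
#' planted pair replaces its members' background rows with an explicit
#' exclusivity scheme: per sample, a pair-level mutation event occurs with
#' the rate implied by `planted_rate`, and the event hits exactly one
#' member (chosen 50/50) with probability `exclusivity_level`, both members
#' otherwise — so the pair's empirical exclusivity concentrates on
#' `exclusivity_level` while its co-mutation count falls far below the
#' independence expectation. Expression is standard normal noise; for each
#' planted gene, the expression of its cancer-network neighbors is shifted
#' by `driver_effect` SDs in the samples where that gene is mutated
#' (driver-linked outliers). Planted genes are drawn from the
#' biomarker-filtered network so planted pairs are reachable by the
#' candidate screen. All draws derive from `cfg$rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @param network output of [simulate_network()] for the same config.
#' @return list with `mutation` (binary matrix), `expression` (numeric
#'   matrix), `positives` (data.frame of planted pairs) and `planted_genes`.
#' @export
simulate_cohort <- function(cfg, network) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed + 1L)
  genes <- network$genes
  samples <- sprintf("s%04d", seq_len(cfg$n_samples))

  mut <- matrix(stats::rbinom(length(genes) * cfg$n_samples, 1L, cfg$background_rate),
                nrow = length(genes), dimnames = list(genes, samples))

  cancer_net <- build_cancer_network(network$edges, network$biomarkers)
  if (2L * cfg$n_planted_pairs > length(cancer_net$nodes))
    stop("not enough biomarker-network genes for the requested planted pairs")
  planted <- if (cfg$n_planted_pairs > 0L)
    sample(cancer_net$nodes, 2L * cfg$n_planted_pairs) else character(0)
  positives <- .canonical_pairs(planted[seq_len(cfg$n_planted_pairs) * 2L - 1L],
                                planted[seq_len(cfg$n_planted_pairs) * 2L])

  eps <- cfg$exclusivity_level
  hit_rate <- cfg$planted_rate / (1 - eps / 2)
  for (i in seq_len(cfg$n_planted_pairs)) {
    a <- positives$gene_a[i]; b <- positives$gene_b[i]
    hit <- stats::runif(cfg$n_samples) < hit_rate
    u <- stats::runif(cfg$n_samples)
    both <- hit & u >= eps
    a_only <- hit & u < eps / 2
    b_only <- hit & u >= eps / 2 & u < eps
    mut[a, ] <- as.integer(both | a_only)
    mut[b, ] <- as.integer(both | b_only)
  }

  expr <- matrix(stats::rnorm(length(genes) * cfg$n_samples),
                 nrow = length(genes), dimnames = list(genes, samples))
  for (g in planted) {
    nbrs <- names(igraph::neighbors(cancer_net$graph, g))
    mutated <- mut[g, ] == 1L
    if (length(nbrs) && any(mutated))
      expr[nbrs, mutated] <- expr[nbrs, mutated] + cfg$driver_effect
  }
  storage.mode(mut) <- "integer"
  list(mutation = mut, expression = expr,
       positives = positives, planted_genes = planted)
}

#' Simulate a complete ranking dataset
#'
#' Convenience wrapper: [simulate_network()] followed by
#' [simulate_cohort()].
#'
#' @param cfg a [sim_config()].
#' @return list with `mutation`, `expression`, `edges`, `biomarkers`,
#'   `positives`, `planted_genes`.
#' @export
simulate_sl_dataset <- function(cfg) {
  network <- simulate_network(cfg)
  cohort <- simulate_cohort(cfg, network)
  c(cohort[c("mutation", "expression", "positives", "planted_genes")],
    network[c("edges", "biomarkers")])
}
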