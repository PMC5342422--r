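test_that("pair coverage counts the mutated-sample union", {
  samples <- sprintf("s%d", 1:10)
  mut <- make_mut(list(A = c("s1", "s3", "s6"), B = c("s3", "s8", "s9"),
                       C = character(0)), samples)
  expect_equal(pair_coverage(mut, "A", "B"), 0.5)
  expect_equal(pair_coverage(mut, "C", "C"), 0)

  two <- make_mut(list(A = "s1", B = "s2"), c("s1", "s2"))
  expect_equal(pair_coverage(two, "A", "B"), 1)

  expect_error(pair_coverage(mut, "A", "NOPE"), "NOPE")

  # union monotonicity: coverage is at least either member's mutation rate
  set.seed(5)
  m <- matrix(rbinom(80, 1, 0.3), 8, 10,
              dimnames = list(letters[1:8], samples))
  r <- mutation_rates(m)
  for (i in 1:10) {
    gg <- sample(letters[1:8], 2)
    expect_gte(pair_coverage(m, gg[1], gg[2]), max(r[gg]))
  }
})

test_that("expression outliers use per-gene z-scores with an inclusive cutoff", {
  samples <- sprintf("s%d", 1:4)
  expr <- matrix(c(0, 0, 0, 10,
                   5, 5, 5, 5), 2, 4, byrow = TRUE,
                 dimnames = list(c("A", "B"), samples))
  ev <- expression_outliers(expr, z_cutoff = 1.5)   # z of the 10 is exactly 1.5
  expect_equal(nrow(ev), 1)
  expect_equal(ev$gene, "A")
  expect_equal(ev$sample, "s4")

  # constant genes never produce events, even at cutoff 0
  ev0 <- expression_outliers(expr, z_cutoff = 0)
  expect_false("B" %in% ev0$gene)
  expect_equal(sum(ev0$gene == "A"), 4)             # every defined z passes at 0
})

test_that("the greedy driver scorer selects covering genes and scores them", {
  samples <- c("s1", "s2", "s3", "s4")
  # A is mutated where its neighbor B has an outlier; C is mutated elsewhere
  mut <- make_mut(list(A = "s4", B = character(0), C = "s1"), samples)
  expr <- matrix(c(0, 0, 0, 0,
                   0, 0, 0, 10,
                   0, 0, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("A", "B", "C"), samples))
  net <- net_from_edges(edges_df("A", "B", "B", "C"))
  p <- driver_pvalues(mut, expr, net, z_cutoff = 1.5, n_perm = 50, seed = 9)
  expect_identical(attr(p, "selected"), "A")
  expect_lt(p[["A"]], 1)
  expect_equal(p[["B"]], 1)
  expect_equal(p[["C"]], 1)
  expect_true(all(p > 0 & p <= 1))

  # determinism under a fixed seed
  p2 <- driver_pvalues(mut, expr, net, z_cutoff = 1.5, n_perm = 50, seed = 9)
  expect_identical(p, p2)
})

test_that("greedy selection is by decreasing uncovered-event coverage", {
  samples <- sprintf("s%02d", 1:12)
  # D covers 3 outlier events via its neighbor, A covers 1, disjoint samples
  mut <- make_mut(list(A = "s01", D = c("s03", "s04", "s05"),
                       N1 = character(0), N2 = character(0)), samples)
  expr <- matrix(0, 4, 12, dimnames = list(c("A", "D", "N1", "N2"), samples))
  expr["N1", "s01"] <- 10
  expr["N2", c("s03", "s04", "s05")] <- 10
  net <- net_from_edges(edges_df("A", "N1", "D", "N2"))
  p <- driver_pvalues(mut, expr, net, z_cutoff = 1.2, n_perm = 20, seed = 1)
  expect_identical(attr(p, "selected"), c("D", "A"))
})

test_that("a planted driver scores below the bystander genes", {
  set.seed(77)
  n_s <- 50; n_g <- 30
  genes <- sprintf("g%02d", 1:n_g)
  samples <- sprintf("s%02d", 1:n_s)
  mut <- matrix(rbinom(n_g * n_s, 1, 0.04), n_g, n_s,
                dimnames = list(genes, samples))
  # driver g01: mutated in 5 samples, shifts its 4 neighbors by 3 SD there
  mut["g01", ] <- 0L
  mut["g01", samples[1:5]] <- 1L
  expr <- matrix(rnorm(n_g * n_s), n_g, n_s, dimnames = list(genes, samples))
  nbrs <- c("g02", "g03", "g04", "g05")
  expr[nbrs, samples[1:5]] <- expr[nbrs, samples[1:5]] + 3
  edges <- data.frame(gene_a = "g01", gene_b = nbrs, stringsAsFactors = FALSE)
  # a background scaffold so permutations have somewhere to go
  edges <- rbind(edges, edges_df("g10", "g11", "g12", "g13", "g14", "g15"))
  net <- build_cancer_network(edges, genes)
  p <- driver_pvalues(mut, expr, net, z_cutoff = 2, n_perm = 100, seed = 3)
  expect_lt(p[["g01"]], median(p[setdiff(genes, "g01")]))
  expect_lte(p[["g01"]], 0.05)
})

test_that("driver p-values are calibrated without a mutation-expression link", {
  set.seed(12)
  genes <- sprintf("g%02d", 1:20)
  samples <- sprintf("s%02d", 1:40)
  mut <- matrix(rbinom(800, 1, 0.1), 20, 40, dimnames = list(genes, samples))
  expr <- matrix(rnorm(800), 20, 40, dimnames = list(genes, samples))
  net <- build_cancer_network(complete_edges(genes[1:10]), genes)
  p <- driver_pvalues(mut, expr, net, z_cutoff = 2, n_perm = 100, seed = 5)
  # null data: small p-values must stay near their nominal share
  expect_lte(mean(p <= 0.1), 0.3)
})

test_that("pair driver score takes the smaller p on a -log10 scale, capped", {
  pv <- c(A = 0.01, B = 0.5, C = 1)
  expect_equal(pair_driver_score("A", "B", pv), 2)
  expect_equal(pair_driver_score("C", "C", pv), 0)
  expect_equal(pair_driver_score("A", "MISSING", pv), 2)   # absent gene = p 1
  expect_equal(pair_driver_score("Z", "W", c(Z = 1e-20, W = 1)), 16)
})

test_that("min-max normalization maps to [0,1] and preserves order", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(5, 5, 5)), c(0, 0, 0))
  set.seed(2)
  x <- rnorm(30)
  nx <- minmax_normalize(x)
  expect_equal(nx[which.min(x)], 0)
  expect_equal(nx[which.max(x)], 1)
  expect_identical(order(x), order(nx))            # monotone transform
})

test_that("the feature table shares one normalization scale across labels", {
  samples <- sprintf("s%02d", 1:20)
  mut <- make_mut(list(A = samples[1:8], B = samples[9:16],
                       C = samples[1:2], D = samples[3:4],
                       E = samples[5:6], F = samples[7:8]), samples)
  expr <- matrix(rnorm(120), 6, 20, dimnames = list(rownames(mut), samples))
  net <- net_from_edges(edges_df("A", "B", "B", "C", "C", "D"))
  cfg <- sl_config(rng_seed = 4)
  candidates <- suppressMessages(screen_candidates(
    data.frame(gene_a = c("C", "E"), gene_b = c("D", "F")), mut,
    sl_config(chi2_p_max = 1, exclusivity_min = 0)))
  positives <- data.frame(gene_a = "A", gene_b = "B")
  recs <- suppressWarnings(build_feature_table(candidates, positives, mut, expr, net, cfg))

  expect_equal(nrow(recs), 3)
  expect_equal(sum(recs$label == "positive"), 1)
  for (f in c("coverage_norm", "driver_norm", "centrality_norm")) {
    expect_gte(min(recs[[f]]), 0)
    expect_lte(max(recs[[f]]), 1)
    if (max(recs[[f]]) > 0) expect_equal(max(recs[[f]]), 1)
  }
  # positives come first (the labeled block leads the point set)
  expect_equal(recs$label[1], "positive")

  # pair with both genes outside the network: centrality by the no-op rule
  expect_equal(recs$centrality[recs$pair_id == "E|F"], 0)

  # recomputation with the same seed is identical
  recs2 <- suppressWarnings(build_feature_table(candidates, positives, mut, expr, net, cfg))
  expect_identical(recs, recs2)

  # positives lacking a matrix gene are dropped with a message
  pos_bad <- data.frame(gene_a = c("A", "A"), gene_b = c("B", "ZZ"))
  expect_message(suppressWarnings(
    build_feature_table(candidates, pos_bad, mut, expr, net, cfg)), "dropped")
})

test_that("known positives can optionally stay in the ranked candidate set", {
  samples <- sprintf("s%02d", 1:20)
  mut <- make_mut(list(A = samples[1:8], B = samples[9:16],
                       C = samples[1:2], D = samples[3:4]), samples)
  expr <- matrix(rnorm(80), 4, 20, dimnames = list(rownames(mut), samples))
  net <- net_from_edges(edges_df("A", "B", "B", "C"))
  cand <- suppressMessages(screen_candidates(
    data.frame(gene_a = c("A", "C"), gene_b = c("B", "D")), mut,
    sl_config(chi2_p_max = 1, exclusivity_min = 0)))
  positives <- data.frame(gene_a = "A", gene_b = "B")

  relabeled <- suppressWarnings(build_feature_table(
    cand, positives, mut, expr, net, sl_config(rng_seed = 1)))
  expect_equal(relabeled$label[relabeled$pair_id == "A|B"], "positive")

  kept <- suppressWarnings(build_feature_table(
    cand, positives, mut, expr, net,
    sl_config(rng_seed = 1, relabel_positives = FALSE)))
  expect_equal(kept$label[kept$pair_id == "A|B"], "candidate")
  expect_equal(sum(kept$pair_id == "A|B"), 1)   # never duplicated
})
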