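# Shared fixture builders and independent oracles.

# genes-x-samples binary matrix from a list of mutated-sample names
make_mut <- function(profiles, samples) {
  m <- matrix(0L, nrow = length(profiles), ncol = length(samples),
              dimnames = list(names(profiles), samples))
  for (g in names(profiles)) m[g, profiles[[g]]] <- 1L
  m
}

edges_df <- function(...) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(gene_a = e[, 1], gene_b = e[, 2], stringsAsFactors = FALSE)
}

# path a-b-c-... as an edge list
path_edges <- function(nodes) {
  data.frame(gene_a = nodes[-length(nodes)], gene_b = nodes[-1],
             stringsAsFactors = FALSE)
}

complete_edges <- function(nodes) {
  idx <- t(combn(nodes, 2))
  data.frame(gene_a = idx[, 1], gene_b = idx[, 2], stringsAsFactors = FALSE)
}

net_from_edges <- function(edges) {
  build_cancer_network(edges, unique(c(edges$gene_a, edges$gene_b)))
}

# ---- independent graph oracle: hand-written BFS over an adjacency list ----

bfs_dist_oracle <- function(adj, start) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# efficiency by explicit BFS over all ordered pairs
efficiency_oracle <- function(edges, nodes, d_unreachable) {
  n <- length(nodes)
  if (n < 2) return(0)
  adj <- setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$gene_a[i], nodes); b <- match(edges$gene_b[i], nodes)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  total <- 0
  for (i in seq_len(n)) {
    d <- bfs_dist_oracle(adj, i)
    d[!is.finite(d)] <- d_unreachable
    total <- total + sum(1 / d[-i])
  }
  total / (n * (n - 1))
}

diameter_oracle <- function(edges, nodes) {
  n <- length(nodes)
  adj <- setNames(vector("list", n), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$gene_a[i], nodes); b <- match(edges$gene_b[i], nodes)
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  dmax <- 0
  for (i in seq_len(n)) {
    d <- bfs_dist_oracle(adj, i)
    finite <- d[is.finite(d) & d > 0]
    if (length(finite)) dmax <- max(dmax, max(finite))
  }
  dmax
}

# connected-ish random graph fixture: random edges, dedup, no self-loops
random_graph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  a <- sample(nodes, n_edges, replace = TRUE)
  b <- sample(nodes, n_edges, replace = TRUE)
  keep <- a != b
  e <- data.frame(gene_a = pmin(a[keep], b[keep]),
                  gene_b = pmax(a[keep], b[keep]), stringsAsFactors = FALSE)
  e <- e[!duplicated(paste(e$gene_a, e$gene_b)), , drop = FALSE]
  e
}

# naive NDCG oracle written directly from the definition
ndcg_oracle <- function(rel, p, total_relevant) {
  dcg <- 0
  for (i in seq_len(min(p, length(rel)))) dcg <- dcg + (2^rel[i] - 1) / log2(i + 1)
  ideal <- 0
  for (i in seq_len(min(total_relevant, p))) ideal <- ideal + 1 / log2(i + 1)
  if (ideal == 0) 0 else dcg / ideal
}

# hypergeometric tail oracle by exhaustive enumeration of all top-n draws
enrichment_oracle <- function(N, M, n, k) {
  draws <- combn(N, n)                 # items 1..M are the positives
  overlap <- colSums(draws <= M)
  mean(overlap > k)
}
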