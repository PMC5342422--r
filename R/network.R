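#' Build the biomarker-filtered cancer network
#'
#' Keeps an interaction edge only when both endpoints are cancer biomarkers,
#' removes self-loops and duplicate edges, and caches the quantities needed
#' for information-centrality calculations: the network diameter `D` and the
#' efficiency `E` evaluated with unreachable pairs penalized at `D + 1`.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` (undirected).
#' @param biomarkers character vector of biomarker gene symbols.
#' @return an object of class `cancer_network`: a list with `graph` (igraph),
#'   `nodes`, `n_edges`, `diameter`, `d_unreachable` (= diameter + 1) and
#'   `efficiency`.
#' @export
build_cancer_network <- function(edges, biomarkers) {
  if (is.null(edges) || nrow(edges) == 0L) stop("empty edge list")
  edges <- .canonical_pairs(edges$gene_a, edges$gene_b)
  keep <- edges$gene_a %in% biomarkers & edges$gene_b %in% biomarkers &
    edges$gene_a != edges$gene_b
  edges <- edges[keep, , drop = FALSE]
  edges <- edges[!duplicated(.pair_id(edges$gene_a, edges$gene_b)), , drop = FALSE]
  if (nrow(edges) == 0L) stop("no interaction edge has both endpoints in the biomarker list")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  D <- graph_diameter(g)
  net <- structure(list(graph = g,
                        nodes = igraph::V(g)$name,
                        n_edges = igraph::ecount(g),
                        diameter = D,
                        d_unreachable = D + 1L,
                        efficiency = NA_real_),
                   class = "cancer_network")
  net$efficiency <- network_efficiency(g, net$d_unreachable)
  net
}

#' @export
print.cancer_network <- function(x, ...) {
  cat(sprintf("cancer_network: %d nodes, %d edges, diameter %d, efficiency %.4f\n",
              length(x$nodes), x$n_edges, x$diameter, x$efficiency))
  invisible(x)
}

.as_graph <- function(net) {
  if (inherits(net, "cancer_network")) net$graph else net
}

#' Network diameter (maximum finite shortest-path length)
#'
#' On a disconnected graph the diameter is the maximum over connected
#' components, i.e. unreachable pairs are ignored; this keeps the diameter
#' finite so it can serve as the base of the unreachable penalty used by
#' [network_efficiency()].
#'
#' @param net a `cancer_network` or an igraph graph with >= 2 nodes.
#' @return positive integer.
#' @export
graph_diameter <- function(net) {
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) stop("diameter needs >= 2 nodes")
  d <- igraph::distances(g)
  finite <- d[is.finite(d) & d > 0]
  if (length(finite) == 0L) stop("graph has no finite path (no edges)")
  as.integer(max(finite))
}

#' Network efficiency
#'
#' The efficiency of a graph G with N nodes is the mean reciprocal shortest
#' path length over ordered node pairs,
#' `E(G) = 1/(N(N-1)) * sum_{i != j} 1/d_ij`,
#' where `d_ij` is the shortest-path length when j is reachable from i and
#' `d_unreachable` otherwise. By convention the penalty is `D + 1` with `D`
#' the diameter of the reference network, so efficiency stays comparable
#' when nodes are deleted. Graphs with fewer than 2 nodes have efficiency 0.
#'
#' @param net a `cancer_network` or igraph graph.
#' @param d_unreachable penalty distance for unreachable pairs; defaults to
#'   the cached `d_unreachable` when `net` is a `cancer_network`.
#' @return efficiency in `[0, 1]` (1 exactly for a complete graph).
#' @export
network_efficiency <- function(net, d_unreachable = NULL) {
  if (is.null(d_unreachable)) {
    if (!inherits(net, "cancer_network"))
      stop("d_unreachable must be given when net is a bare graph")
    d_unreachable <- net$d_unreachable
  }
  g <- .as_graph(net)
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  d <- igraph::distances(g)
  d[!is.finite(d)] <- d_unreachable
  diag(d) <- Inf               # exclude i == j from the sum
  sum(1 / d) / (n * (n - 1))
}

#' Information centrality of a gene pair
#'
#' Quantifies how much deleting both genes of a pair degrades network
#' communication: `C = |(E(G) - E(G')) / E(G)|`, where `G'` is the network
#' after removing whichever of the two genes are present (removing an absent
#' gene is a no-op, and a pair with neither gene in the network scores 0).
#' `E(G')` is evaluated with the unreachable penalty of the *original*
#' network (`diameter(G) + 1`), so disconnection caused by the deletion is
#' penalized on a fixed scale. If deletion leaves fewer than two nodes,
#' `E(G') = 0` and `C = 1`.
#'
#' @param net a `cancer_network` (from [build_cancer_network()]).
#' @param gene_a,gene_b gene symbols of the pair.
#' @param recompute_diameter evaluate `E(G')` with a penalty based on the
#'   diameter of `G'` itself instead of the reference network's; `FALSE`
#'   (the default) keeps the penalty on the original network's fixed scale,
#'   which is stable when deletion disconnects the graph.
#' @return non-negative centrality; 0 for a no-op removal.
#' @export
pair_information_centrality <- function(net, gene_a, gene_b,
                                        recompute_diameter = FALSE) {
  stopifnot(inherits(net, "cancer_network"))
  if (!is.finite(net$efficiency) || net$efficiency <= 0)
    stop("reference network has zero efficiency")
  present <- intersect(unique(c(gene_a, gene_b)), net$nodes)
  if (length(present) == 0L) return(0)
  g2 <- igraph::delete_vertices(net$graph, present)
  pen <- net$d_unreachable
  if (recompute_diameter) {
    pen <- tryCatch(graph_diameter(g2) + 1L, error = function(e) net$d_unreachable)
  }
  e2 <- network_efficiency(g2, pen)
  abs((net$efficiency - e2) / net$efficiency)
}

# internal: centrality for many pairs with caching on the deleted node set
.pair_centralities <- function(net, gene_a, gene_b) {
  keys <- vapply(seq_along(gene_a), function(i) {
    paste(sort(intersect(c(gene_a[i], gene_b[i]), net$nodes)), collapse = "|")
  }, character(1L))
  out <- numeric(length(keys))
  for (key in unique(keys)) {
    idx <- which(keys == key)
    if (key == "") {
      out[idx] <- 0
    } else {
      i <- idx[1L]
      out[idx] <- pair_information_centrality(net, gene_a[i], gene_b[i])
    }
  }
  out
}
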