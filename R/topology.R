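# Topological characterization. All distance-based indices are computed on
# the unweighted, unsigned skeleton of the network: link signs and weights
# carry correlation information, not path lengths.

.skeleton <- function(net) {
  g <- igraph::simplify(net$graph, edge.attr.comb = "first")
  for (a in intersect(c("weight", "sign"), igraph::edge_attr_names(g)))
    g <- igraph::delete_edge_attr(g, a)
  g
}

.pair_count <- function(n) n * (n - 1) / 2

#' Krackhardt connectedness
#'
#' Fraction of unordered node pairs joined by some path:
#' `Con = 1 - (#unreachable pairs) / (n(n-1)/2)`.
#'
#' @param net an `eco_network`.
#' @return A fraction in `[0, 1]`.
#' @export
connectedness <- function(net) {
  g <- .skeleton(net)
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  d <- igraph::distances(g)
  unreach <- sum(is.infinite(d[upper.tri(d)]))
  1 - unreach / .pair_count(n)
}

#' Geodesic efficiency and harmonic geodesic distance
#'
#' Efficiency is the mean over unordered node pairs of the inverse shortest
#' path length (disconnected pairs contribute 0); a higher value means nodes
#' sit closer together. The harmonic geodesic distance is its reciprocal
#' (`Inf` for an edgeless network).
#'
#' @param net an `eco_network`.
#' @return A single number.
#' @export
geodesic_efficiency <- function(net) {
  g <- .skeleton(net)
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  d <- igraph::distances(g)
  mean(1 / d[upper.tri(d)])
}

#' @rdname geodesic_efficiency
#' @export
harmonic_geodesic_distance <- function(net) {
  e <- geodesic_efficiency(net)
  if (e == 0) Inf else 1 / e
}

#' Stress centrality and its centralization
#'
#' `stress_centrality` counts, for each node v, the shortest paths between
#' all pairs (s, t) with s != t != v that pass through v (raw, unnormalized
#' counts). `centralization_stress` is
#' `sum(max - stress) / ((n - 1) * max)`, 0 when every node has zero stress;
#' values near 0 mean all nodes carry the same load.
#'
#' @param net an `eco_network` with at least 3 nodes.
#' @return Named numeric vector (per node) / single number.
#' @export
stress_centrality <- function(net) {
  g <- .skeleton(net)
  n <- igraph::vcount(g)
  stopifnot(n >= 3)
  d <- igraph::distances(g)
  # nsp[s, v]: number of shortest s->v paths, by BFS layering per source
  nsp <- matrix(0, n, n)
  # plain integer neighbour lists (igraph.vs indexing has its own DSL)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  for (s in seq_len(n)) {
    ds <- d[s, ]
    ord <- order(ds)
    nsp[s, s] <- 1
    for (v in ord) {
      if (v == s || is.infinite(ds[v])) next
      pred <- adj[[v]][ds[adj[[v]]] == ds[v] - 1]
      nsp[s, v] <- sum(nsp[s, pred])
    }
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    w <- nsp[, v]                       # = nsp[v, ] by symmetry
    on_geo <- outer(d[, v], d[v, ], "+") == d & is.finite(d)
    contrib <- outer(w, w) * on_geo
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    stress[v] <- sum(contrib) / 2
  }
  stats::setNames(stress, igraph::V(g)$name)
}

#' @rdname stress_centrality
#' @export
centralization_stress <- function(net) {
  s <- stress_centrality(net)
  mx <- max(s)
  if (mx == 0) return(0)
  sum(mx - s) / ((length(s) - 1) * mx)
}

#' Module detection by greedy modularity maximization
#'
#' Fast-greedy (CNM-style) agglomerative modularity optimization on the
#' unsigned, unweighted skeleton, the convention of the molecular ecological
#' network literature. The algorithm is deterministic for a given graph;
#' `seed` is accepted for interface stability.
#'
#' @param net an `eco_network`.
#' @param seed integer, set before clustering.
#' @return A `module_partition`: list with `membership` (named integer
#'   vector), `sizes`, and Newman-Girvan `modularity_q`.
#' @export
detect_modules <- function(net, seed = 1L) {
  g <- .skeleton(net)
  stopifnot(igraph::vcount(g) > 0)
  set.seed(as.integer(seed))
  cl <- igraph::cluster_fast_greedy(g)
  # cut the merge dendrogram at the step with maximal modularity ourselves:
  # igraph's default cut can return a worse partition on degenerate graphs
  memb <- igraph::membership(cl)
  if (length(cl$modularity) > 0 && igraph::ecount(g) > 0 &&
      igraph::vcount(g) > 1) {
    best_step <- which.max(round(cl$modularity, 12))
    for (steps in unique(pmax(0L, c(best_step - 1L, best_step)))) {
      memb2 <- tryCatch(suppressWarnings(igraph::cut_at(cl, steps = steps)),
                        error = function(e) NULL)
      if (is.null(memb2)) next
      names(memb2) <- igraph::V(g)$name
      if (igraph::modularity(g, memb2) > igraph::modularity(g, memb))
        memb <- memb2
    }
  }
  structure(list(membership = stats::setNames(as.integer(memb),
                                              names(memb)),
                 sizes = as.integer(table(as.integer(memb))),
                 modularity_q = igraph::modularity(g, memb)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, Q = %.3f\n",
              length(x$sizes), length(x$membership), x$modularity_q))
  invisible(x)
}

#' Large modules of a partition
#'
#' @param part a [detect_modules()] partition.
#' @param min_size minimum node count (default 5, the usual cutoff for
#'   "large" modules; 2 selects everything beyond singletons).
#' @return `data.frame` with `label` (M1, M2, ... by decreasing size),
#'   `module` (original id) and `size`.
#' @export
large_modules <- function(part, min_size = 5L) {
  tab <- table(part$membership)
  big <- tab[tab >= min_size]
  if (length(big) == 0)
    return(data.frame(label = character(0), module = integer(0),
                      size = integer(0)))
  ord <- order(-as.integer(big), as.integer(names(big)))
  data.frame(label = paste0("M", seq_along(big)),
             module = as.integer(names(big))[ord],
             size = as.integer(big)[ord], row.names = NULL)
}

#' Betweenness and eigenvector centrality
#'
#' Betweenness is the standard shortest-path betweenness normalized by
#' `(n-1)(n-2)/2`. Eigenvector centrality is computed on the largest
#' connected component (nonnegative principal eigenvector, scaled to a
#' maximum of 1); nodes outside it get 0.
#'
#' @param net an `eco_network`.
#' @return Named numeric vector per node.
#' @export
betweenness_centrality <- function(net) {
  g <- .skeleton(net)
  igraph::betweenness(g, normalized = TRUE)
}

#' @rdname betweenness_centrality
#' @export
eigenvector_centrality <- function(net) {
  g <- .skeleton(net)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  out <- stats::setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  ec <- igraph::eigen_centrality(sub)$vector
  out[names(ec)] <- abs(ec)
  out
}

#' Negative-link fraction of a network
#'
#' @param net an `eco_network` with at least one link.
#' @return Fraction of links with negative sign.
#' @export
negative_link_ratio <- function(net) {
  L <- n_links(net)
  if (L == 0) stop("network has no links")
  sum(igraph::E(net$graph)$sign < 0) / L
}

#' Topology summary of a network
#'
#' One row of the usual network-characterization table: node and link
#' counts, average degree (`avgK = 2L/n`), connectedness, geodesic
#' efficiency and harmonic geodesic distance, modularity, centralization of
#' stress centrality, power-law R^2 of the degree distribution (NA when
#' fewer than 3 distinct degrees), and the negative-link fraction.
#'
#' @param net an `eco_network` (nonempty).
#' @param part optional [detect_modules()] partition (computed if missing).
#' @return `data.frame` with one row.
#' @export
summarize_topology <- function(net, part = NULL) {
  stopifnot(n_nodes(net) > 0)
  if (is.null(part)) part <- detect_modules(net)
  pl <- tryCatch(powerlaw_fit(igraph::degree(net$graph)),
                 error = function(e) list(r_squared = NA_real_,
                                          exponent = NA_real_))
  data.frame(
    n_nodes = n_nodes(net),
    n_links = n_links(net),
    avg_degree = 2 * n_links(net) / n_nodes(net),
    connectedness = connectedness(net),
    geodesic_efficiency = geodesic_efficiency(net),
    harmonic_geodesic_distance = harmonic_geodesic_distance(net),
    modularity = part$modularity_q,
    n_modules = length(part$sizes),
    centralization_stress = if (n_nodes(net) >= 3)
      centralization_stress(net) else NA_real_,
    powerlaw_r2 = pl$r_squared,
    powerlaw_exponent = pl$exponent,
    negative_link_fraction = if (n_links(net) > 0)
      negative_link_ratio(net) else NA_real_)
}

#' Key nodes per centrality metric
#'
#' Reports the argmax node for degree, betweenness, stress and eigenvector
#' centrality -- the "key network nodes" of a co-occurrence network.
#'
#' @param net an `eco_network` with >= 3 nodes.
#' @return `data.frame` with `metric`, `otu_id`, `value`.
#' @export
key_nodes <- function(net) {
  metrics <- list(degree = igraph::degree(net$graph),
                  betweenness = betweenness_centrality(net),
                  stress = stress_centrality(net),
                  eigenvector = eigenvector_centrality(net))
  data.frame(metric = names(metrics),
             otu_id = vapply(metrics, function(v) names(v)[which.max(v)],
                             character(1)),
             value = vapply(metrics, max, numeric(1)), row.names = NULL)
}

#' Normalized mutual information between two partitions
#'
#' Convenience wrapper (igraph's NMI) used to compare detected modules with
#' a planted ground truth over a common node set.
#'
#' @param memb1,memb2 named membership vectors; only shared names are used.
#' @return NMI in `[0, 1]` (1 when either partition is trivial and equal).
#' @export
partition_nmi <- function(memb1, memb2) {
  common <- intersect(names(memb1), names(memb2))
  stopifnot(length(common) >= 2)
  a <- as.integer(factor(memb1[common]))
  b <- as.integer(factor(memb2[common]))
  igraph::compare(a, b, method = "nmi")
}
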