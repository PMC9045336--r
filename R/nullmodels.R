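# Degree-preserving randomization and significance of empirical topology.

#' Degree-preserving rewiring
#'
#' Maslov-Sneppen double-edge swaps on the network skeleton: the node set
#' and degree sequence are preserved exactly and no self-loops or
#' multi-edges are created. Link weights (and hence signs) are then
#' reassigned by a random permutation of the original weight multiset, since
#' a rewired graph has no natural correlation values of its own.
#'
#' @param net an `eco_network` with >= 2 links.
#' @param n_swaps number of attempted swaps; default `10 * n_links(net)`.
#' @param seed integer seed; output is deterministic given `seed`.
#' @return A rewired `eco_network` with the same `st` and `provenance`.
#' @export
rewire_network <- function(net, n_swaps = NULL, seed = 1L) {
  L <- n_links(net)
  if (L < 2) {
    warning("fewer than 2 links; returning network unchanged")
    return(net)
  }
  if (is.null(n_swaps)) n_swaps <- 10L * L
  g <- net$graph
  w <- igraph::E(g)$weight
  set.seed(as.integer(seed))
  r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                niter = n_swaps))
  wp <- sample(w)
  igraph::E(r)$weight <- wp
  igraph::E(r)$sign <- ifelse(wp >= 0, 1L, -1L)
  structure(list(graph = r, st = net$st, provenance = net$provenance),
            class = "eco_network")
}

#' Null-model significance of topology metrics
#'
#' Generates `reps` degree-preserving randomizations of the network
#' (default 100, the conventional ensemble size), evaluates each metric on
#' every randomization, and reports empirical value, null mean and sd,
#' z-score and a two-sided normal p-value per metric. A degenerate null
#' (sd = 0) is flagged with `p = NA`.
#'
#' @param net an `eco_network`.
#' @param metrics named list of functions `eco_network -> number`; the
#'   default covers modularity, average degree, connectedness, geodesic
#'   efficiency and centralization of stress centrality.
#' @param reps ensemble size (default 100).
#' @param seed integer seed for the ensemble.
#' @return A `data.frame` with one row per metric and attribute `reps`.
#' @export
null_ensemble <- function(net, metrics = default_null_metrics(), reps = 100L,
                          seed = 1L) {
  stopifnot(reps >= 2)
  emp <- vapply(metrics, function(f) f(net), numeric(1))
  nulls <- matrix(NA_real_, nrow = reps, ncol = length(metrics),
                  dimnames = list(NULL, names(metrics)))
  for (i in seq_len(reps)) {
    r <- rewire_network(net, seed = seed + i - 1L)
    nulls[i, ] <- vapply(metrics, function(f) f(r), numeric(1))
  }
  mu <- colMeans(nulls)
  sdev <- apply(nulls, 2L, stats::sd)
  z <- ifelse(sdev > 0, (emp - mu) / sdev, NA_real_)
  out <- data.frame(metric = names(metrics), empirical = unname(emp),
                    null_mean = unname(mu), null_sd = unname(sdev),
                    z = unname(z),
                    p = unname(2 * stats::pnorm(-abs(z))),
                    degenerate = unname(sdev == 0), row.names = NULL)
  attr(out, "reps") <- reps
  out
}

#' @rdname null_ensemble
#' @export
default_null_metrics <- function() {
  list(
    modularity = function(net) detect_modules(net)$modularity_q,
    avg_degree = function(net) 2 * n_links(net) / n_nodes(net),
    connectedness = connectedness,
    geodesic_efficiency = geodesic_efficiency,
    centralization_stress = function(net)
      if (n_nodes(net) >= 3) centralization_stress(net) else NA_real_
  )
}
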