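# Shared builders and independent oracles. Oracles deliberately avoid the
# code paths they check: graph quantities are recomputed from the adjacency
# matrix with plain R.

make_ct <- function(m, ...) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  count_table(m, ...)
}

# eco_network from an explicit edge list (weights give signs)
make_net <- function(from, to, weight = rep(1, length(from)), st = 0.5) {
  nodes <- sort(unique(c(from, to)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = weight,
               sign = ifelse(weight >= 0, 1L, -1L)),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, st = st, provenance = NA_character_),
            class = "eco_network")
}

# eco_network from an igraph graph, weights +1 unless given
wrap_net <- function(g, weights = NULL, st = 0.5) {
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  if (is.null(weights)) weights <- rep(1, igraph::ecount(g))
  igraph::E(g)$weight <- weights
  igraph::E(g)$sign <- ifelse(weights >= 0, 1L, -1L)
  structure(list(graph = g, st = st, provenance = NA_character_),
            class = "eco_network")
}

# all-pairs shortest path lengths by BFS on an adjacency matrix (no igraph)
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0)
      nxt <- nxt[d[s, nxt] == Inf]
      if (length(nxt) == 0) break
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

oracle_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bfs_distances(adj)
  mean(1 / d[upper.tri(d)])
}

# node-removal vulnerability straight from the definition
oracle_vulnerability <- function(adj) {
  E <- oracle_efficiency(adj)
  n <- nrow(adj)
  vi <- vapply(seq_len(n), function(i) {
    (E - oracle_efficiency(adj[-i, -i, drop = FALSE])) / E
  }, numeric(1))
  list(global_efficiency = E, v = vi, network_vulnerability = max(vi))
}

# brute-force Zi/Pi by explicit link counting over an edge list
oracle_zi_pi <- function(edges, membership) {
  nodes <- names(membership)
  ki <- setNames(numeric(length(nodes)), nodes)
  kic <- list()
  for (v in nodes) kic[[v]] <- numeric(0)
  for (r in seq_len(nrow(edges))) {
    a <- edges$from[r]; b <- edges$to[r]
    ki[a] <- ki[a] + 1; ki[b] <- ki[b] + 1
    ma <- as.character(membership[b]); mb <- as.character(membership[a])
    kic[[a]][ma] <- sum(kic[[a]][ma], 1, na.rm = TRUE)
    kic[[b]][mb] <- sum(kic[[b]][mb], 1, na.rm = TRUE)
  }
  kib <- vapply(nodes, function(v) {
    own <- as.character(membership[v])
    if (own %in% names(kic[[v]])) kic[[v]][[own]] else 0
  }, numeric(1))
  zi <- setNames(numeric(length(nodes)), nodes)
  for (b in unique(membership)) {
    mem <- nodes[membership[nodes] == b]
    mu <- mean(kib[mem]); sdev <- stats::sd(kib[mem])
    zi[mem] <- if (is.na(sdev) || sdev == 0) 0 else (kib[mem] - mu) / sdev
  }
  pi_v <- vapply(nodes, function(v) {
    if (ki[v] == 0) return(NA_real_)
    1 - sum((kic[[v]] / ki[v])^2)
  }, numeric(1))
  data.frame(otu_id = nodes, zi = unname(zi), pi = unname(pi_v),
             row.names = NULL)
}

# all set partitions of a small vector (Bell-number enumeration)
set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(x[1]), p)
  }
  out
}

# Newman-Girvan modularity of a partition from the definition
oracle_modularity <- function(adj, membership) {
  L <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (b in unique(membership)) {
    idx <- which(membership == b)
    lb <- sum(adj[idx, idx]) / 2
    db <- sum(deg[idx])
    q <- q + lb / L - (db / (2 * L))^2
  }
  q
}

# random connected-ish test graph wrapped as eco_network (no isolated nodes)
random_net <- function(n, p, seed, neg_frac = 0.3) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::vcount(g) < 2 || igraph::ecount(g) < 1) return(NULL)
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  w <- runif(igraph::ecount(g), 0.5, 1) *
    ifelse(runif(igraph::ecount(g)) < neg_frac, -1, 1)
  wrap_net(g, weights = w)
}

# independent lognormal relative-abundance table (pure-noise community)
noise_abundance <- function(n_taxa, n_samples, seed, sdlog = 1) {
  set.seed(seed)
  m <- matrix(stats::rlnorm(n_taxa * n_samples, sdlog = sdlog), n_taxa,
              n_samples,
              dimnames = list(paste0("OTU", seq_len(n_taxa)),
                              paste0("s", seq_len(n_samples))))
  abundance_table(sweep(m, 2, colSums(m), "/"))
}
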