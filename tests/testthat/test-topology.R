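# Closed forms come from hand enumeration over tiny graphs; the modularity
# check uses an exhaustive partition oracle.

test_that("summary indices match closed forms on tiny graphs", {
  tri <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  ts <- summarize_topology(tri)
  expect_equal(ts$n_nodes, 3L)
  expect_equal(ts$n_links, 3L)
  expect_equal(ts$avg_degree, 2)
  expect_equal(ts$connectedness, 1)
  expect_equal(ts$geodesic_efficiency, 1)
  expect_equal(ts$harmonic_geodesic_distance, 1)

  # two disjoint edges: 2 reachable pairs of 6
  disj <- make_net(c("a", "c"), c("b", "d"))
  expect_equal(connectedness(disj), 1 / 3)

  # path a-b-c plus isolated d: 3 unreachable pairs of 6
  p3i <- wrap_net(igraph::make_graph(~ a - b, b - c, d))
  expect_equal(connectedness(p3i), 0.5)

  k5 <- wrap_net(igraph::make_full_graph(5))
  expect_equal(geodesic_efficiency(k5), 1)
})

test_that("geodesic efficiency enumerates inverse path lengths", {
  p3 <- make_net(c("a", "b"), c("b", "c"))
  expect_equal(geodesic_efficiency(p3), (1 + 1 + 0.5) / 3)
  expect_equal(harmonic_geodesic_distance(p3), 1 / (5 / 6))
  # star with center + 3 leaves: 3 pairs at distance 1, 3 at distance 2
  s4 <- wrap_net(igraph::make_star(4, mode = "undirected"))
  expect_equal(geodesic_efficiency(s4), (3 * 1 + 3 * 0.5) / 6)
  # edgeless pair
  empty2 <- wrap_net(igraph::make_empty_graph(2, directed = FALSE))
  expect_equal(geodesic_efficiency(empty2), 0)
  expect_equal(harmonic_geodesic_distance(empty2), Inf)
})

test_that("stress centrality counts geodesics through each node", {
  k4 <- wrap_net(igraph::make_full_graph(4))
  expect_equal(unname(stress_centrality(k4)), rep(0, 4))
  expect_equal(centralization_stress(k4), 0)

  p3 <- make_net(c("a", "b"), c("b", "c"))
  expect_equal(stress_centrality(p3), c(a = 0, b = 1, c = 0))
  expect_equal(centralization_stress(p3), (1 + 1) / (2 * 1))

  # star S5: center lies on all C(4,2) = 6 leaf geodesics
  s5 <- wrap_net(igraph::make_star(5, mode = "undirected", center = 1))
  st <- stress_centrality(s5)
  expect_equal(unname(st[1]), 6)
  expect_equal(unname(st[-1]), rep(0, 4))

  # diamond: two shortest paths between the far corners
  dia <- make_net(c("a", "a", "b", "c"), c("b", "c", "d", "d"))
  st2 <- stress_centrality(dia)
  expect_equal(st2[["b"]], 1)
  expect_equal(st2[["c"]], 1)
})

test_that("module detection matches the exhaustive modularity oracle", {
  # two disjoint triangles: Q = 0.5 exactly, 2 modules
  tt <- make_net(c("a", "b", "c", "x", "y", "z"),
                 c("b", "c", "a", "y", "z", "x"))
  part <- detect_modules(tt)
  expect_equal(length(part$sizes), 2L)
  expect_equal(part$modularity_q, 0.5)

  k4 <- wrap_net(igraph::make_full_graph(4))
  expect_equal(length(detect_modules(k4)$sizes), 1L)

  # greedy Q within 0.05 of the best partition (exhaustive, n <= 8)
  for (seed in 1:4) {
    net <- random_net(7, 0.45, seed = seed)
    if (is.null(net)) next
    part <- detect_modules(net)
    adj <- as.matrix(igraph::as_adjacency_matrix(net$graph))
    nodes <- rownames(adj)
    best <- -Inf
    for (p in set_partitions(nodes)) {
      memb <- setNames(rep(seq_along(p), lengths(p)), unlist(p))
      best <- max(best, oracle_modularity(adj, memb[nodes]))
    }
    expect_gte(part$modularity_q, best - 0.05)
    # and the reported Q is a true modularity of the reported partition
    expect_equal(part$modularity_q,
                 oracle_modularity(adj, part$membership[nodes]),
                 tolerance = 1e-12)
  }
})

test_that("large modules are selected and labelled by size", {
  part <- structure(list(membership = setNames(
    rep(c(1L, 2L, 3L), c(7, 4, 2)), paste0("n", 1:13)),
    sizes = c(7L, 4L, 2L), modularity_q = 0.3),
    class = "module_partition")
  lm5 <- large_modules(part)
  expect_equal(nrow(lm5), 1L)
  expect_equal(lm5$label, "M1")
  expect_equal(lm5$size, 7L)
  lm2 <- large_modules(part, min_size = 2)
  expect_equal(lm2$size, c(7L, 4L, 2L))
  empty <- structure(list(membership = setNames(integer(0), character(0)),
                          sizes = integer(0), modularity_q = NA_real_),
                     class = "module_partition")
  expect_equal(nrow(large_modules(empty)), 0L)
})

test_that("betweenness and eigenvector centralities behave canonically", {
  s5 <- wrap_net(igraph::make_star(5, mode = "undirected", center = 1))
  bt <- betweenness_centrality(s5)
  expect_equal(unname(which.max(bt)), 1L)
  expect_equal(unname(bt[-1]), rep(0, 4))

  cyc <- wrap_net(igraph::make_ring(6))
  expect_equal(length(unique(round(betweenness_centrality(cyc), 12))), 1L)

  k2 <- wrap_net(igraph::make_full_graph(2))
  ec <- eigenvector_centrality(k2)
  expect_equal(unname(ec[1]), unname(ec[2]))

  # disconnected: only the largest component gets nonzero centrality
  two <- wrap_net(igraph::make_graph(~ a - b, b - c, x - y))
  ec2 <- eigenvector_centrality(two)
  expect_true(all(ec2[c("x", "y")] == 0))
  expect_true(all(ec2[c("a", "b", "c")] > 0))
})

test_that("distance metrics ignore edge signs and weights", {
  pos <- make_net(c("a", "b", "c"), c("b", "c", "d"), c(0.9, 0.8, 0.95))
  neg <- make_net(c("a", "b", "c"), c("b", "c", "d"), c(-0.9, -0.8, -0.95))
  expect_equal(geodesic_efficiency(pos), geodesic_efficiency(neg))
  expect_equal(connectedness(pos), connectedness(neg))
  expect_equal(stress_centrality(pos), stress_centrality(neg))
  expect_equal(detect_modules(pos)$modularity_q,
               detect_modules(neg)$modularity_q)
})

test_that("key nodes report the argmax per metric", {
  s5 <- wrap_net(igraph::make_star(5, mode = "undirected", center = 1))
  kn <- key_nodes(s5)
  expect_setequal(kn$metric, c("degree", "betweenness", "stress",
                               "eigenvector"))
  expect_true(all(kn$otu_id == igraph::V(s5$graph)$name[1]))
})

test_that("avgK = 2L/n on generated networks", {
  for (seed in 1:5) {
    net <- random_net(25, 0.15, seed = seed)
    if (is.null(net)) next
    ts <- summarize_topology(net)
    expect_equal(ts$avg_degree, 2 * ts$n_links / ts$n_nodes)
    expect_true(ts$connectedness >= 0 && ts$connectedness <= 1)
    expect_true(ts$geodesic_efficiency >= 0 && ts$geodesic_efficiency <= 1)
    if (ts$n_links > 0) expect_gte(ts$harmonic_geodesic_distance, 1)
  }
})
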