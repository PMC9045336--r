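test_that("zi/pi match hand-computed cases", {
  # node "x" with 2 links in module 1 and 2 in module 2 -> pi = 0.5
  net <- make_net(c("x", "x", "x", "x", "a", "c"),
                  c("a", "b", "c", "d", "b", "d"))
  part <- structure(list(membership = c(a = 1L, b = 1L, c = 2L, d = 2L,
                                        x = 1L),
                         sizes = c(3L, 2L), modularity_q = 0),
                    class = "module_partition")
  zp <- zi_pi(net, part)
  x <- zp[zp$otu_id == "x", ]
  expect_equal(x$pi, 0.5)
  expect_equal(x$ki, 4L)
  expect_equal(x$kib, 2L)

  # all links inside the own module -> pi = 0
  tri <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  p1 <- structure(list(membership = c(a = 1L, b = 1L, c = 1L), sizes = 3L,
                       modularity_q = 0), class = "module_partition")
  zp1 <- zi_pi(tri, p1)
  expect_true(all(zp1$pi == 0))
  # identical within-module degree -> sd = 0 -> zi = 0, flagged
  expect_true(all(zp1$zi == 0))
  expect_true(all(zp1$sigma_zero))

  # link bookkeeping: sum_c k_ic = k_i is implied by pi <= 1 - 1/N_M
  expect_true(all(zp$pi <= 1 - 1 / length(unique(part$membership)) + 1e-12))
})

test_that("zi/pi agree with the brute-force oracle on random graphs", {
  for (seed in 1:30) {
    net <- random_net(sample(8:30, 1), runif(1, 0.15, 0.4), seed = seed)
    if (is.null(net)) next
    nodes <- igraph::V(net$graph)$name
    memb <- setNames(sample(1:4, length(nodes), replace = TRUE), nodes)
    part <- structure(list(membership = memb,
                           sizes = as.integer(table(memb)),
                           modularity_q = 0), class = "module_partition")
    zp <- zi_pi(net, part)
    edges <- igraph::as_data_frame(net$graph, what = "edges")
    oracle <- oracle_zi_pi(edges, memb)
    idx <- match(zp$otu_id, oracle$otu_id)
    expect_lt(max(abs(zp$zi - oracle$zi[idx])), 1e-12)
    expect_lt(max(abs(zp$pi - oracle$pi[idx])), 1e-12)
  }
})

test_that("roles partition the plane with strict printed inequalities", {
  expect_identical(classify_role(3.0, 0.70), "network_hub")
  expect_identical(classify_role(3.0, 0.50), "module_hub")
  expect_identical(classify_role(1.0, 0.70), "connector")
  expect_identical(classify_role(0, 0), "peripheral")
  # the boundary point itself is peripheral: both inequalities are strict
  expect_identical(classify_role(2.5, 0.62), "peripheral")
  # vectorized and exhaustive on a grid: exactly one role each
  zi <- rep(c(2.4, 2.5, 2.6), each = 3)
  pi <- rep(c(0.61, 0.62, 0.63), times = 3)
  roles <- classify_role(zi, pi)
  expect_equal(length(roles), 9L)
  expect_true(all(roles %in% c("network_hub", "module_hub", "connector",
                               "peripheral")))
})

test_that("pi is invariant to module relabeling", {
  net <- random_net(20, 0.25, seed = 8)
  nodes <- igraph::V(net$graph)$name
  memb <- setNames(sample(1:3, length(nodes), replace = TRUE), nodes)
  relab <- setNames(c(7L, 5L, 9L)[memb], nodes)
  mk <- function(m) structure(list(membership = m,
                                   sizes = as.integer(table(m)),
                                   modularity_q = 0),
                              class = "module_partition")
  expect_equal(zi_pi(net, mk(memb))$pi, zi_pi(net, mk(relab))$pi)
  expect_equal(zi_pi(net, mk(memb))$zi, zi_pi(net, mk(relab))$zi)
})

test_that("keystone tables join abundance classes and count shares", {
  roles <- data.frame(
    otu_id = paste0("o", 1:25),
    zi = c(rep(3, 4), rep(0, 21)),
    pi = c(rep(0.7, 4), rep(0.7, 21)),
    role = c(rep("network_hub", 4), rep("connector", 21)),
    abundance_class = c(rep("rare", 4), rep("rare", 20), "abundant"),
    mean_abundance = runif(25, 1e-5, 1e-4))
  kt <- keystone_table(roles)
  expect_equal(nrow(kt$keystones), 25L)
  s <- kt$summary
  conn_rare <- s[s$role == "connector" & s$class == "rare", ]
  expect_equal(conn_rare$count, 20L)
  expect_equal(conn_rare$percent, 100 * 20 / 21, tolerance = 1e-12)
  hub_rare <- s[s$role == "network_hub" & s$class == "rare", ]
  expect_equal(hub_rare$count, 4L)

  empty <- keystone_table(roles[roles$role == "peripheral", ])
  expect_equal(nrow(empty$keystones), 0L)
  expect_equal(nrow(empty$summary), 0L)
})

test_that("keystone-diversity screening detects monotone association", {
  set.seed(31)
  n <- 30
  counts <- matrix(rpois(50 * n, 2), 50,
                   dimnames = list(paste0("OTU", 1:50), paste0("s", 1:n)))
  ct <- count_table(counts)
  div <- alpha_diversity(ct)
  # plant an OTU tracking richness rank-for-rank; spread the remainder
  # evenly so columns sum to 1 without disturbing OTU1's ranks
  x <- rank(div$richness) / (2 * n)
  v <- rbind(OTU1 = x,
             matrix(rep((1 - x) / 49, each = 49), 49, n,
                    dimnames = list(paste0("OTU", 2:50), NULL)))
  colnames(v) <- div$sample_id
  a <- abundance_table(v)
  keystones <- data.frame(otu_id = c("OTU1", "OTU2"),
                          role = c("connector", "module_hub"))
  res <- keystone_diversity_association(a, div, keystones)
  r1 <- res[res$otu_id == "OTU1", ]
  expect_equal(r1$r_richness, 1, tolerance = 1e-9)
  expect_lt(r1$p_richness, 1e-6)
  expect_true(all(c("r_shannon", "p_shannon") %in% colnames(res)))
  expect_true(is.logical(res$passes_all))

  # constant OTU is flagged and excluded
  a$values["OTU2", ] <- mean(a$values["OTU2", ])
  a$values <- sweep(a$values, 2, colSums(a$values), "/")
  # renormalization breaks exact constancy; force it
  a2 <- a
  a2$values["OTU2", ] <- 0.001
  expect_warning(res2 <- keystone_diversity_association(a2, div, keystones),
                 "constant")
  expect_false("OTU2" %in% res2$otu_id)
})
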