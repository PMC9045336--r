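test_that("TSV count tables round-trip and reject malformed input", {
  m <- matrix(c(5L, 0L, 3L, 2L, 1L, 4L), nrow = 3,
              dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
  ct <- make_ct(m)
  expect_equal(dim(ct), c(3L, 2L))

  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, p)
  back <- read_count_table(p)
  expect_identical(back$counts, ct$counts)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(back, p2)
  expect_identical(readLines(p), readLines(p2))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t1,204\t3", "OTU2\t1\t2"), bad)
  expect_error(read_count_table(bad), "non-numeric.*1,204")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1", "OTU1\t1", "OTU1\t2"), dup)
  expect_error(read_count_table(dup), "duplicate")
})

test_that("count_table validates its invariants", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(count_table(m), "count_table")
  expect_error(count_table(matrix(c(-1, 1, 1, 1), 2,
                                  dimnames = dimnames(m))), "nonnegative")
  expect_error(count_table(matrix(c(0.5, 1, 1, 1), 2,
                                  dimnames = dimnames(m))), "integer")
  meta <- data.frame(sample_id = "s1", dph = 12)
  expect_error(count_table(m, metadata = meta), "missing from metadata")
})

test_that("rarefy hits the target depth exactly and is seed-deterministic", {
  set.seed(42)
  m <- matrix(rpois(60, 40), 6,
              dimnames = list(paste0("OTU", 1:6), paste0("s", 1:10)))
  ct <- make_ct(m)
  r <- rarefy(ct, depth = 100, seed = 7)
  expect_true(all(colSums(r$counts) == 100))
  expect_identical(r$counts, rarefy(ct, depth = 100, seed = 7)$counts)
  # idempotent at the same depth: already-exact samples pass through
  expect_identical(rarefy(r, depth = 100, seed = 7)$counts, r$counts)

  # a sample whose total equals the depth is returned unchanged
  col <- c(60L, 30L, 10L)
  one <- make_ct(matrix(col, 3))
  expect_identical(rarefy(one, depth = 100, seed = 1)$counts[, 1],
                   setNames(col, paste0("OTU", 1:3)))

  expect_identical(formals(rarefy)$depth, 14666L)
  expect_error(rarefy(make_ct(matrix(c(3L, 2L), 2)), depth = 10),
               "fewer than")
  big <- make_ct(matrix(c(1000L, 1000L, 30L, 20L), 2))
  expect_warning(rarefy(big, depth = 100, seed = 1), "dropped")
})

test_that("rarefied counts match the hypergeometric mean", {
  # OTU at proportion p in a large sample: mean rarefied count ~ p * depth
  col <- c(2000L, 6000L, 2000L)
  ct <- make_ct(matrix(col, 3))
  depth <- 500
  draws <- vapply(1:300, function(s)
    rarefy(ct, depth = depth, seed = s)$counts[2, 1], numeric(1))
  p <- 0.6
  se <- sqrt(depth * p * (1 - p) * (1 - (depth - 1) / (sum(col) - 1))) /
    sqrt(300)
  expect_lt(abs(mean(draws) - p * depth), 3 * se)
})

test_that("to_relative normalizes and rejects empty samples", {
  two <- to_relative(make_ct(matrix(c(2L, 2L), 2)))
  expect_equal(unname(two$values[, 1]), c(0.5, 0.5))
  a <- to_relative(make_ct(matrix(c(1L, 0L, 3L), 3)))
  expect_equal(unname(a$values[, 1]), c(0.25, 0, 0.75))
  expect_equal(unname(colSums(a$values)), 1)
  z <- make_ct(matrix(c(1L, 0L, 0L, 0L), 2))
  expect_error(to_relative(z), "all-zero sample.*s2")
})

test_that("prevalence filter uses an inclusive boundary and is idempotent", {
  # OTU in 1 of 5 samples at min_fraction 0.2 -> retained (boundary)
  m <- matrix(0L, 2, 5, dimnames = list(c("keep", "drop"), paste0("s", 1:5)))
  m["keep", 1] <- 5L  # prevalence exactly 1/5
  f <- suppressWarnings(prevalence_filter(make_ct(m), 0.2))
  expect_identical(rownames(f$counts), "keep")

  # 10 samples, OTU in 1 sample -> 0.1 < 0.2 -> removed
  m10 <- matrix(0L, 2, 10)
  m10[1, ] <- 1L
  m10[2, 3] <- 1L
  f10 <- prevalence_filter(make_ct(m10), 0.2)
  expect_identical(rownames(f10$counts), "OTU1")

  expect_identical(prevalence_filter(f10, 0.2)$counts, f10$counts)
  expect_warning(prevalence_filter(make_ct(matrix(0L, 1, 4)), 0.5),
                 "removed every OTU")
})

test_that("log transform applies the pseudocount policy monotonically", {
  a <- to_relative(make_ct(matrix(c(1L, 3L, 0L, 4L, 2L, 2L), 3)))
  lg <- log_transform(a)
  p <- attr(lg, "pseudocount")
  expect_equal(p, min(a$values[a$values > 0]) / 2)
  expect_equal(lg, log(a$values + p), ignore_attr = TRUE)
  # monotone: ordering of abundances preserved within and across samples
  expect_identical(order(a$values), order(lg))
  # abundance 1 with zero pseudocount maps to 0
  one <- abundance_table(matrix(1, 1, 1, dimnames = list("x", "s")))
  expect_equal(unname(log_transform(one, pseudocount = 0)[1, 1]), 0)
})

test_that("abundance classes follow the 0.01% / 0.1% / 1% rules", {
  v <- rbind(
    abund_mean  = c(2e-3, 2e-3, 2e-3),   # mean 0.2% > 0.1%
    rare        = c(5e-5, 1.5e-3, 1e-4),  # < 0.01% once, never >= 1%
    intermediate = c(5e-4, 5e-4, 5e-4),  # constant 0.05%: fails all rules
    local_abund = c(1.5e-2, 2e-4, 1e-4)) # >= 0.01% always, >= 1% once
  v <- rbind(v, filler = 1 - colSums(v))
  colnames(v) <- paste0("s", 1:3)
  a <- abundance_table(v)
  cls <- classify_abundance(a)
  got <- setNames(cls$class, cls$otu_id)
  expect_identical(got[["abund_mean"]], "abundant")
  expect_identical(got[["rare"]], "rare")
  expect_identical(got[["intermediate"]], "intermediate")
  expect_identical(got[["local_abund"]], "abundant")
  # classes partition the OTU set
  expect_identical(nrow(cls), nrow(v))
  expect_true(all(cls$class %in% c("abundant", "rare", "intermediate")))
  # scope restricts the regional community
  expect_error(classify_abundance(a, scope = "nope"))
})

test_that("alpha diversity matches closed forms", {
  u <- make_ct(matrix(rep(10L, 5), 5))
  expect_equal(alpha_diversity(u)$shannon, log(5))
  expect_equal(alpha_diversity(u)$richness, 5L)
  one <- make_ct(matrix(c(7L, 0L), 2))
  expect_equal(alpha_diversity(one)$shannon, 0)
  expect_equal(alpha_diversity(one)$richness, 1L)
  h <- alpha_diversity(make_ct(matrix(c(1L, 1L, 2L), 3)))$shannon
  expect_equal(h, log(4) - (2 / 4) * log(2), tolerance = 1e-12)
  expect_error(alpha_diversity(make_ct(matrix(0L, 2, 1))), "all-zero")
})

test_that("BIOM v1 JSON tables are read when biomformat is present", {
  skip_if_not_installed("biomformat")
  p <- withr::local_tempfile(fileext = ".biom")
  biom <- list(
    id = "t", format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org", type = "OTU table",
    generated_by = "miconet-test", date = "2026-01-01T00:00:00",
    matrix_type = "dense", matrix_element_type = "int", shape = c(2L, 3L),
    rows = list(list(id = "OTU1", metadata = NULL),
                list(id = "OTU2", metadata = NULL)),
    columns = list(list(id = "s1", metadata = NULL),
                   list(id = "s2", metadata = NULL),
                   list(id = "s3", metadata = NULL)),
    data = list(c(5L, 0L, 2L), c(1L, 3L, 0L)))
  jsonlite::write_json(biom, p, auto_unbox = TRUE, null = "null")
  ct <- read_biom_table(p)
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct), c(2L, 3L))
  expect_equal(unname(ct$counts["OTU1", "s1"]), 5L)
})
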