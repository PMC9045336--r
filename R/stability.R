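# Community-stability layer: cohesion (positive/negative), N:P ratio,
# node-removal vulnerability, negative-link ratio (the last lives with the
# topology helpers).

#' Community cohesion
#'
#' Quantifies per-sample microbial connectivity following the
#' null-model-corrected correlation protocol:
#' 1. observed pairwise Pearson correlations between taxa across samples, on
#'    relative abundances;
#' 2. a "taxa shuffle" null: each taxon's abundances are independently
#'    permuted across samples, correlations recomputed, repeated `null_reps`
#'    times and averaged, giving a per-pair null expectation;
#' 3. corrected correlation = observed - null mean;
#' 4. per-taxon connectedness: the positive (resp. negative) corrected
#'    correlations of taxon j, summed and divided by the number of partner
#'    taxa, so a taxon weakly connected to many partners is not inflated
#'    (0 when a taxon has no partner of that sign);
#' 5. per-sample cohesion: abundance-weighted sums
#'    `cohesion_pos(s) = sum_j a_sj * connectedness_pos(j)` (>= 0) and the
#'    analogous `cohesion_neg(s)` (<= 0).
#'
#' Taxa below the persistence cutoff (present in fewer than `persistence`
#' of samples, default the 20% network prevalence rule) are excluded before
#' the correlation step but their abundances still count in the relative
#' abundances used as weights.
#'
#' @param a an [abundance_table()] (>= 3 samples; a warning below 10).
#' @param null_reps taxa-shuffle repetitions (default 200).
#' @param seed integer seed; deterministic given `seed`.
#' @param persistence minimum presence fraction for a taxon to enter the
#'   correlation matrix (default 0.2).
#' @param method correlation type, `"pearson"` (protocol default) or
#'   `"spearman"`.
#' @return A `cohesion_result`: list with `connectedness` (per-taxon
#'   data.frame), `samples` (per-sample data.frame with `cohesion_pos`,
#'   `cohesion_neg`, `np_ratio`), `corrected` (taxon x taxon corrected
#'   correlation matrix), `null_reps`, `seed`.
#' @export
cohesion <- function(a, null_reps = 200L, seed = 1L, persistence = 0.2,
                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "abundance_table"), null_reps >= 1)
  v <- a$values
  ns <- ncol(v)
  if (ns < 3) stop("cohesion needs at least 3 samples")
  if (ns < 10) warning("fewer than 10 samples; cohesion will be noisy")
  keep <- rowMeans(v > 0) >= persistence
  m <- t(v[keep, , drop = FALSE])          # samples x taxa
  nt <- ncol(m)
  if (nt < 2) stop("fewer than 2 taxa pass the persistence cutoff")
  obs <- stats::cor(m, method = method)
  set.seed(as.integer(seed))
  null_sum <- matrix(0, nt, nt)
  for (r in seq_len(null_reps)) {
    perm <- apply(m, 2L, sample)
    null_sum <- null_sum + stats::cor(perm, method = method)
  }
  corrected <- obs - null_sum / null_reps
  diag(corrected) <- 0
  conn_pos <- colSums(corrected * (corrected > 0)) / (nt - 1)
  conn_neg <- colSums(corrected * (corrected < 0)) / (nt - 1)
  cp <- as.numeric(m %*% conn_pos)
  cn <- as.numeric(m %*% conn_neg)
  np <- ifelse(cp > 0, abs(cn) / cp, NA_real_)
  if (any(cp == 0)) warning("cohesion_pos = 0 in some sample(s); ",
                            "np_ratio undefined there")
  structure(list(
    connectedness = data.frame(otu_id = colnames(m),
                               connectedness_pos = unname(conn_pos),
                               connectedness_neg = unname(conn_neg),
                               row.names = NULL),
    samples = data.frame(sample_id = rownames(m), cohesion_pos = cp,
                         cohesion_neg = cn, np_ratio = np, row.names = NULL),
    corrected = corrected, null_reps = null_reps, seed = as.integer(seed),
    method = method), class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf(
    "cohesion_result: %d taxa, %d samples (%s, %d null reps)\n",
    nrow(x$connectedness), nrow(x$samples), x$method, x$null_reps))
  cat(sprintf("  mean cohesion_pos %.4f, mean cohesion_neg %.4f\n",
              mean(x$samples$cohesion_pos), mean(x$samples$cohesion_neg)))
  invisible(x)
}

#' Group summaries of cohesion and N:P
#'
#' Per-group mean and standard error of positive/negative cohesion and the
#' N:P ratio (N:P is computed per sample, then averaged). Groups with fewer
#' than 2 samples are excluded with a warning. ANOVA with LSD letters across
#' groups is available through [anova_lsd()].
#'
#' @param c a [cohesion()] result.
#' @param groups named character/factor vector, names are sample ids.
#' @return `data.frame`, one row per group x statistic with `mean` and `se`.
#' @export
np_ratio_summary <- function(c, groups) {
  stopifnot(inherits(c, "cohesion_result"))
  s <- c$samples
  g <- groups[s$sample_id]
  if (anyNA(g)) stop("groups missing for some samples")
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with < 2 samples excluded: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    s <- s[keep, , drop = FALSE]
    g <- g[keep]
  }
  stat_cols <- c("cohesion_pos", "cohesion_neg", "np_ratio")
  out <- do.call(rbind, lapply(stat_cols, function(colname) {
    vals <- split(s[[colname]], g)
    data.frame(group = names(vals), statistic = colname,
               mean = vapply(vals, function(x) mean(x, na.rm = TRUE),
                             numeric(1)),
               se = vapply(vals, function(x) {
                 x <- x[!is.na(x)]
                 stats::sd(x) / sqrt(length(x))
               }, numeric(1)),
               n = vapply(vals, function(x) sum(!is.na(x)), integer(1)),
               row.names = NULL)
  }))
  out
}

#' Network vulnerability
#'
#' Global efficiency `E` is the mean inverse geodesic distance over
#' unordered node pairs (disconnected pairs contribute 0). Each node's
#' vulnerability is its relative contribution to global efficiency,
#' `v_i = (E - E_i) / E`, where `E_i` is the efficiency of the network with
#' node i removed (computed over the remaining n - 1 nodes, so the
#' denominator shrinks with the node set). The network's vulnerability is
#' `max_i v_i`; a lower value reads as a more stable community.
#'
#' @param net an `eco_network` with >= 3 nodes and at least one link.
#' @return A list with `global_efficiency`, `node` (per-node data.frame of
#'   `otu_id`, `vulnerability`) and `network_vulnerability`.
#' @export
vulnerability <- function(net) {
  g <- .skeleton(net)
  n <- igraph::vcount(g)
  stopifnot(n >= 3)
  eff <- function(gr) {
    k <- igraph::vcount(gr)
    if (k < 2) return(0)
    d <- igraph::distances(gr)
    mean(1 / d[upper.tri(d)])
  }
  E <- eff(g)
  if (E == 0) stop("edgeless network: global efficiency is 0")
  vi <- vapply(seq_len(n), function(i) {
    (E - eff(igraph::delete_vertices(g, i))) / E
  }, numeric(1))
  list(global_efficiency = E,
       node = data.frame(otu_id = igraph::V(g)$name, vulnerability = vi,
                         row.names = NULL),
       network_vulnerability = max(vi))
}
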