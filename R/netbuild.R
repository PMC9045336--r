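#' Spearman similarity matrix
#'
#' Pairwise Spearman rank correlations between OTUs across samples, computed
#' on a (log-transformed) abundance matrix with OTUs in rows. Ties get
#' average ranks. OTUs with zero variance across samples have undefined rank
#' correlations; they are recorded as 0 with a warning so downstream
#' thresholding simply never links them.
#'
#' @param x numeric matrix, OTUs in rows, samples in columns (>= 3 samples).
#' @return Symmetric matrix of class `similarity_matrix` with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 3) stop("need at least 3 samples for rank correlation")
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sum(flat), " zero-variance OTU(s) get similarity 0: ",
            paste(utils::head(rownames(x)[flat], 5L), collapse = ", "))
  s <- suppressWarnings(stats::cor(t(x), method = "spearman"))
  s[is.na(s)] <- 0
  diag(s) <- 1
  class(s) <- c("similarity_matrix", class(s))
  s
}

#' Build a signed co-occurrence network at a similarity threshold
#'
#' Links every unordered OTU pair whose absolute correlation is at least
#' `st` (inclusive); the link weight is the signed correlation coefficient.
#' OTUs with no link are excluded from the network.
#'
#' @param s a [spearman_matrix()] (any symmetric correlation matrix works).
#' @param st similarity threshold in (0, 1); 0.802 is the RMT-derived value
#'   used for the reference gut-microbiota analyses.
#' @param provenance optional group label (a dph or stage tag) stored on the
#'   network.
#' @return An `eco_network`: a list with an igraph `graph` (edge attributes
#'   `weight` = correlation, `sign` = +1/-1), `st` and `provenance`.
#' @export
build_network <- function(s, st = 0.802, provenance = NA_character_) {
  stopifnot(st > 0, st < 1)
  m <- unclass(s)
  diag(m) <- 0
  idx <- which(abs(m) >= st & upper.tri(m), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("empty network at st = ", st)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    w <- m[idx]
    nodes <- sort(unique(c(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]])))
    g <- igraph::graph_from_data_frame(
      data.frame(from = rownames(m)[idx[, 1]],
                 to = colnames(m)[idx[, 2]],
                 weight = w, sign = ifelse(w >= 0, 1L, -1L)),
      directed = FALSE, vertices = nodes)
  }
  structure(list(graph = g, st = st, provenance = provenance),
            class = "eco_network")
}

#' @export
print.eco_network <- function(x, ...) {
  g <- x$graph
  L <- igraph::ecount(g)
  neg <- if (L > 0) sum(igraph::E(g)$sign < 0) else 0L
  cat(sprintf(
    "eco_network (st = %.3f%s): %d nodes, %d links (%.1f%% negative)\n",
    x$st,
    if (is.na(x$provenance)) "" else paste0(", group ", x$provenance),
    igraph::vcount(g), L, if (L > 0) 100 * neg / L else 0))
  invisible(x)
}

#' Node and link counts of a network
#'
#' @param net an `eco_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname n_nodes
#' @export
n_links <- function(net) igraph::ecount(net$graph)

#' RMT threshold scan
#'
#' Scans candidate similarity thresholds and, at each, tests whether the
#' nearest-neighbour spacing distribution (NNSD) of the unfolded eigenvalues
#' of the thresholded correlation matrix follows Poisson statistics (as
#' expected once noise links are gone) rather than the Gaussian orthogonal
#' ensemble (GOE, Wigner surmise) characteristic of a noise-dominated matrix.
#' The chosen threshold is the smallest grid value at which the chi-squared
#' goodness-of-fit accepts Poisson (p > `alpha_poisson`) and rejects GOE
#' (p < `alpha_goe`).
#'
#' Rows/columns left with no off-diagonal entry at a candidate threshold are
#' dropped before the eigendecomposition; eigenvalues are unfolded with a
#' smoothing spline fitted to the empirical cumulative spectral function, and
#' the NNSD is binned on [0, 3] with width 0.1 (one overflow bin).
#'
#' @param s a [spearman_matrix()].
#' @param grid numeric vector of candidate thresholds, default
#'   `seq(0.30, 0.95, by = 0.01)`.
#' @param alpha_poisson,alpha_goe decision levels (defaults 0.05).
#' @param min_dim minimum matrix dimension for a meaningful spacing test
#'   (default 20); smaller candidate matrices are skipped.
#' @return A `threshold_scan` data-frame-backed object with per-threshold
#'   statistics and attribute `chosen_st` (NA if no grid point qualifies).
#' @export
rmt_threshold_scan <- function(s, grid = seq(0.30, 0.95, by = 0.01),
                               alpha_poisson = 0.05, alpha_goe = 0.05,
                               min_dim = 20L) {
  stopifnot(all(grid > 0), all(grid < 1))
  if (nrow(s) < min_dim)
    stop("similarity matrix smaller than min_dim = ", min_dim)
  m0 <- unclass(s)
  res <- lapply(grid, function(th) {
    m <- m0
    m[abs(m) < th] <- 0
    diag(m) <- 1
    off <- rowSums(m != 0) - 1L
    m <- m[off > 0, off > 0, drop = FALSE]
    if (nrow(m) < min_dim)
      return(data.frame(st = th, dim = nrow(m), p_poisson = NA_real_,
                        p_goe = NA_real_, chisq_poisson = NA_real_,
                        chisq_goe = NA_real_))
    sp <- .nnsd_spacings(m)
    if (length(sp) < min_dim - 1L)
      return(data.frame(st = th, dim = nrow(m), p_poisson = NA_real_,
                        p_goe = NA_real_, chisq_poisson = NA_real_,
                        chisq_goe = NA_real_))
    gp <- .chisq_gof(sp, law = "poisson")
    gg <- .chisq_gof(sp, law = "goe")
    data.frame(st = th, dim = nrow(m), p_poisson = gp$p, p_goe = gg$p,
               chisq_poisson = gp$stat, chisq_goe = gg$stat)
  })
  tab <- do.call(rbind, res)
  ok <- !is.na(tab$p_poisson) & tab$p_poisson > alpha_poisson &
    !is.na(tab$p_goe) & tab$p_goe < alpha_goe
  chosen <- if (any(ok)) tab$st[which(ok)[1L]] else NA_real_
  attr(tab, "chosen_st") <- chosen
  class(tab) <- c("threshold_scan", class(tab))
  tab
}

#' @export
print.threshold_scan <- function(x, ...) {
  chosen <- attr(x, "chosen_st")
  cat(sprintf("threshold_scan over %d candidates; chosen St = %s\n",
              nrow(x), if (is.na(chosen)) "none" else format(chosen)))
  invisible(x)
}

# Unfolded nearest-neighbour eigenvalue spacings of a symmetric matrix.
# Unfolding: fit a smoothing spline to the empirical cumulative spectral
# function G(lambda) and take spacings of n * G_hat(lambda_i), which have
# unit mean by construction.
.nnsd_spacings <- function(m) {
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  ev <- unique(round(ev, 8))
  n <- length(ev)
  if (n < 5) return(numeric(0))
  G <- (seq_len(n) - 0.5) / n
  df <- max(4, min(15, n / 4))
  fit <- stats::smooth.spline(ev, G, df = df)
  unfolded <- n * stats::predict(fit, ev)$y
  sp <- diff(sort(unfolded))
  sp[sp >= 0]
}

# Chi-squared goodness of fit of spacings against Poisson exp(-s) or the
# GOE Wigner surmise (pi*s/2) exp(-pi s^2 / 4); histogram on [0,3] by 0.1
# plus one overflow bin.
.chisq_gof <- function(sp, law = c("poisson", "goe"), binwidth = 0.1,
                       upper = 3) {
  law <- match.arg(law)
  breaks <- seq(0, upper, by = binwidth)
  obs <- c(graphics::hist(sp[sp <= upper], breaks = breaks,
                          plot = FALSE)$counts,
           sum(sp > upper))
  cdf <- switch(law,
    poisson = function(s) 1 - exp(-s),
    goe = function(s) 1 - exp(-pi * s^2 / 4))
  p <- diff(c(cdf(breaks), 1))
  expd <- length(sp) * p
  # pool sparse expected cells to keep the chi-squared approximation honest
  keep <- expd >= 1
  obs2 <- c(obs[keep], sum(obs[!keep]))
  exp2 <- c(expd[keep], sum(expd[!keep]))
  nz <- exp2 > 0
  stat <- sum((obs2[nz] - exp2[nz])^2 / exp2[nz])
  df <- max(1L, sum(nz) - 1L)
  list(stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Power-law fit of a degree distribution
#'
#' Ordinary least squares of log frequency on log degree over degrees with
#' nonzero frequency; an R^2 above ~0.8 is conventionally read as scale-free
#' behaviour.
#'
#' @param degrees integer degree sequence (>= 3 distinct positive values).
#' @return list with `r_squared` and `exponent` (the OLS slope).
#' @export
powerlaw_fit <- function(degrees) {
  degrees <- degrees[degrees > 0]
  tab <- table(degrees)
  if (length(tab) < 3)
    stop("need at least 3 distinct positive degrees for a power-law fit")
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  fit <- stats::lm(log(f) ~ log(k))
  list(r_squared = summary(fit)$r.squared,
       exponent = unname(stats::coef(fit)[2L]))
}

#' Export network edge and node tables
#'
#' @param net an `eco_network`.
#' @param edge_path,node_path,graphml_path output paths (NULL skips).
#' @param modules optional [detect_modules()] partition used to fill the
#'   node table's `module` column.
#' @return Invisibly, a list of the paths written.
#' @export
export_network <- function(net, edge_path = NULL, node_path = NULL,
                           graphml_path = NULL, modules = NULL) {
  g <- net$graph
  written <- list()
  if (!is.null(edge_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    colnames(el)[1:2] <- c("source", "target")
    utils::write.table(el, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$edges <- edge_path
  }
  if (!is.null(node_path)) {
    nd <- data.frame(otu_id = igraph::V(g)$name,
                     degree = igraph::degree(g),
                     module = if (!is.null(modules))
                       modules$membership[igraph::V(g)$name] else NA_integer_,
                     row.names = NULL)
    utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written$nodes <- node_path
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
    written$graphml <- graphml_path
  }
  invisible(written)
}
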