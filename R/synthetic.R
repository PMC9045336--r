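# Synthetic rarefied-count generator with planted ground truth.
#
# World model: per sample, correlated standard-normal module factors; each
# taxon's latent log-abundance is a loading on its module factor(s) plus
# independent noise, standardized and scaled by a global log-sd; counts are
# multinomial at fixed depth on the softmax of latent log-abundances.
# Negative associations come from negative loadings; planted hubs are
# low-noise members (they correlate with everything in their module);
# planted connectors load evenly on three module factors.

#' Synthetic community specification
#'
#' Defaults describe the generator's reference single-stage world: 4 modules
#' of 15 taxa (each containing one planted low-noise hub), 2 planted
#' connectors loading on all four module factors, independent background
#' and rare taxa, 100 samples rarefied to 14,666 reads. Member noise
#' variances are evenly spaced over `member_noise_range`, giving weak
#' member-member correlations (around 0.25-0.30) under a strong hub-member
#' correlation (around 0.5): at the recommended similarity threshold
#' (`st_recommended`, default 0.36) each module is a hub-anchored, sparsely
#' interlinked star, so the hub's within-module degree stands out
#' (Zi > 2.5) while ordinary members stay peripheral. See
#' [strong_module_spec()] for the homogeneous strong-coupling variant used
#' to benchmark module recovery.
#'
#' @param n_samples samples to draw (default 100).
#' @param n_modules number of planted modules (default 4).
#' @param module_size taxa per module, hub included (default 15).
#' @param n_connectors planted connector taxa, each loading on up to four
#'   modules (default 2; requires `n_modules >= 3` when > 0).
#' @param n_background independent non-rare taxa (default 33).
#' @param n_rare independent taxa with expected relative abundance below
#'   0.01% (default 25).
#' @param depth reads per sample (default 14666).
#' @param coupling global multiplier on all factor loadings (default 1;
#'   0 gives a fully independent community).
#' @param neg_fraction fraction of each module's non-hub members with a
#'   negative loading (default 0.25).
#' @param neg_strength magnitude of negative loadings relative to positive
#'   ones, in (0, 1] (default 1).
#' @param member_noise_range range of member noise variances (default
#'   c(2.1, 2.7)).
#' @param hub_noise,connector_noise noise variances of planted hubs and
#'   connectors (defaults 0.02 and 0.05).
#' @param factor_rho pairwise correlation of module factors (default 0.3;
#'   needed so connectors can correlate with three modules at once).
#' @param module_share expected relative-abundance share of module plus
#'   connector taxa (default 0.5).
#' @param rare_abundance expected relative abundance of each rare taxon
#'   (default 3e-5, safely below the 0.01% rare threshold).
#' @param sigma_log log-scale abundance sd after standardization
#'   (default 0.8).
#' @param st_recommended similarity threshold matched to the generator's
#'   correlation strengths (default 0.36).
#' @param stage,dph_pool,tanks metadata: stage label, dph values sampled
#'   per sample, tank labels.
#' @param seed integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 100L, n_modules = 4L,
                           module_size = 15L, n_connectors = 2L,
                           n_background = 33L, n_rare = 25L,
                           depth = 14666L, coupling = 1,
                           neg_fraction = 0.25, neg_strength = 1,
                           member_noise_range = c(2.1, 2.7),
                           hub_noise = 0.02, connector_noise = 0.05,
                           factor_rho = 0.3, module_share = 0.5,
                           rare_abundance = 3e-5, sigma_log = 0.8,
                           st_recommended = 0.36,
                           stage = "stage1",
                           dph_pool = c(12L, 20L, 27L, 42L),
                           tanks = paste0("T", 1:3), seed = 1L) {
  stopifnot(depth >= 100, n_modules >= 1, module_size >= 2,
            neg_fraction >= 0, neg_fraction <= 1,
            neg_strength > 0, neg_strength <= 1,
            module_share > 0, module_share < 1)
  if (n_connectors > 0 && n_modules < 3)
    stop("planted connectors need at least 3 modules (Pi > 0.62 is ",
         "unreachable with links split over fewer)")
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  spec
}

#' Strong-module preset
#'
#' A homogeneous strong-coupling variant of [synthetic_spec()]: 3 modules of
#' 15 taxa with within-module latent correlations near 0.9 and no planted
#' connectors, the benchmark world for module recovery (at any threshold
#' between the noise floor and 0.9 the modules are near-cliques and
#' separate components). The recommended threshold is 0.7.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
strong_module_spec <- function(...) {
  args <- list(n_modules = 3L, module_size = 15L, n_connectors = 0L,
               n_background = 48L, member_noise_range = c(0.10, 0.13),
               st_recommended = 0.7)
  override <- list(...)
  args[names(override)] <- override
  do.call(synthetic_spec, args)
}

#' Generate one synthetic stage
#'
#' Draws a rarefied-style count table plus its ground truth from a
#' [synthetic_spec()]. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` (a [count_table()] with metadata) and `truth`
#'   (`data.frame`: `otu_id`, `type` in member/hub/connector/background/rare,
#'   `module` (NA for unassigned types), `loading_sign`), plus the spec's
#'   `st_recommended` as an attribute on `truth`.
#' @export
generate_stage <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(as.integer(spec$seed))
  nm <- spec$n_modules
  msz <- spec$module_size
  n_members <- nm * msz
  n_neg_per_module <- round(spec$neg_fraction * (msz - 1L))
  if (spec$neg_fraction > 0 && n_neg_per_module == 0L)
    stop("neg_fraction ", spec$neg_fraction, " infeasible for module size ",
         msz, " (no member would carry a negative loading)")

  ids <- c(sprintf("OTU%04d", seq_len(n_members)),
           if (spec$n_connectors > 0)
             sprintf("CON%02d", seq_len(spec$n_connectors)),
           if (spec$n_background > 0)
             sprintf("BG%03d", seq_len(spec$n_background)),
           if (spec$n_rare > 0) sprintf("RARE%03d", seq_len(spec$n_rare)))
  type <- c(rep("member", n_members),
            rep("connector", spec$n_connectors),
            rep("background", spec$n_background),
            rep("rare", spec$n_rare))
  module <- c(rep(seq_len(nm), each = msz),
              rep(NA_integer_, length(ids) - n_members))
  # one hub per module: the first member of each block
  hub_idx <- (seq_len(nm) - 1L) * msz + 1L
  type[hub_idx] <- "hub"

  # loadings and noise
  loading_sign <- rep(1L, length(ids))
  noise_var <- numeric(length(ids))
  lambda <- numeric(length(ids))          # loading magnitude on own factor
  for (m in seq_len(nm)) {
    block <- which(module == m)
    members <- setdiff(block, hub_idx)
    neg <- if (n_neg_per_module > 0) sample(members, n_neg_per_module)
           else integer(0)
    loading_sign[neg] <- -1L
    # evenly spaced noise variances: heterogeneous degrees (so hubs can
    # stand out in Zi) without seed-to-seed density swings
    noise_var[members] <- seq(spec$member_noise_range[1],
                              spec$member_noise_range[2],
                              length.out = length(members))
    lambda[members] <- 1
    # negative members: weaker loading, noise topped up so total variance
    # matches a positive member's
    lambda[neg] <- spec$neg_strength
    noise_var[neg] <- noise_var[neg] + (1 - spec$neg_strength^2)
  }
  noise_var[hub_idx] <- spec$hub_noise
  lambda[hub_idx] <- 1
  conn_idx <- which(type == "connector")
  noise_var[conn_idx] <- spec$connector_noise
  other <- type %in% c("background", "rare")
  noise_var[other] <- 1
  lambda[other] <- 0
  lambda <- lambda * spec$coupling

  # connectors load on up to four modules (at least three, so that an even
  # spread of links can exceed the Pi > 0.62 connector threshold)
  n_load <- min(4L, nm)
  conn_modules <- lapply(conn_idx, function(i) sort(sample(nm, n_load)))

  # latent factors: pairwise correlation factor_rho via a shared component
  ns <- spec$n_samples
  rho <- spec$factor_rho
  shared <- stats::rnorm(ns)
  fac <- sqrt(rho) * matrix(shared, ns, nm) +
    sqrt(1 - rho) * matrix(stats::rnorm(ns * nm), ns, nm)

  z <- matrix(stats::rnorm(ns * length(ids)), ns, length(ids))
  z <- sweep(z, 2L, sqrt(noise_var), "*")
  for (j in seq_along(ids)) {
    if (type[j] %in% c("member", "hub")) {
      z[, j] <- z[, j] + loading_sign[j] * lambda[j] * fac[, module[j]]
    } else if (type[j] == "connector") {
      mods <- conn_modules[[match(j, conn_idx)]]
      k <- length(mods)
      denom <- sqrt(k + k * (k - 1) * rho)
      z[, j] <- z[, j] + spec$coupling * rowSums(fac[, mods, drop = FALSE]) /
        denom
    }
  }
  # standardize each taxon's latent scale, then apply the global log-sd
  zsd <- sqrt(lambda^2 + noise_var)
  zsd[conn_idx] <- sqrt(spec$coupling^2 + spec$connector_noise)
  z <- sweep(z, 2L, zsd, "/") * spec$sigma_log

  # baseline offsets from target abundance shares
  rare_total <- spec$n_rare * spec$rare_abundance
  n_coupled <- n_members + spec$n_connectors
  base <- numeric(length(ids))
  base[!other] <- log(spec$module_share / n_coupled)
  base[type == "background"] <- log((1 - spec$module_share - rare_total) /
                                      max(spec$n_background, 1L))
  base[type == "rare"] <- log(spec$rare_abundance)
  x <- sweep(z, 2L, base, "+")

  counts <- apply(x, 1L, function(row) {
    p <- exp(row - max(row))
    stats::rmultinom(1L, spec$depth, p / sum(p))[, 1L]
  })
  rownames(counts) <- ids

  sample_names <- sprintf("%s_s%03d", spec$stage, seq_len(ns))
  colnames(counts) <- sample_names
  meta <- data.frame(sample_id = sample_names,
                     dph = sample(spec$dph_pool, ns, replace = TRUE),
                     stage = spec$stage,
                     tank = sample(spec$tanks, ns, replace = TRUE),
                     stringsAsFactors = FALSE)
  truth <- data.frame(otu_id = ids, type = type, module = module,
                      loading_sign = ifelse(lambda == 0, NA_integer_,
                                            loading_sign),
                      stringsAsFactors = FALSE)
  attr(truth, "st_recommended") <- spec$st_recommended
  attr(truth, "connector_modules") <- conn_modules
  list(table = count_table(counts, metadata = meta), truth = truth)
}

#' Generate a developmental series of synthetic stages
#'
#' A three-stage schedule emulating a host-development succession: later
#' stages have more coupled taxa, a larger fraction and strength of
#' negative couplings, a smaller abundance share on the (more numerous)
#' coupled taxa, and stronger dominance swings (`sigma_log`), the
#' compositional expression of competitive exclusion under fixed
#' sequencing depth. Under this schedule node and link counts, average
#' degree, the negative-link ratio and the cohesion N:P ratio are expected
#' to increase with stage while positive cohesion decreases.
#'
#' @param seed integer master seed.
#' @param n_stages number of stages (default 3; the defaults below are
#'   defined for 3 and recycled beyond).
#' @param n_samples,n_modules,module_size,neg_fraction,neg_strength,module_share,sigma_log
#'   per-stage vectors (recycled).
#' @param member_noise_range list of per-stage noise-variance ranges; the
#'   series couples modules more tightly than the single-stage default so
#'   that stage contrasts in cohesion stand clear of the correlation noise
#'   floor.
#' @param n_background,n_rare uncoupled taxa per stage (smaller than the
#'   single-stage default, so that coupled taxa dominate the persistent
#'   community).
#' @param ... further arguments passed to every stage's [synthetic_spec()].
#' @return list of per-stage `list(table, truth)` as from
#'   [generate_stage()], named by stage label.
#' @export
generate_series <- function(seed = 1L, n_stages = 3L,
                            n_samples = c(80L, 100L, 120L),
                            n_modules = c(3L, 3L, 4L),
                            module_size = c(10L, 15L, 15L),
                            neg_fraction = c(0.10, 0.30, 0.50),
                            neg_strength = c(0.40, 0.75, 1.00),
                            module_share = c(0.55, 0.45, 0.35),
                            sigma_log = c(0.35, 0.70, 1.05),
                            member_noise_range = list(c(0.5, 0.9),
                                                      c(0.8, 1.3),
                                                      c(1.0, 1.6)),
                            n_background = 12L, n_rare = 10L,
                            ...) {
  stopifnot(n_stages >= 2)
  stages <- c("stage1_12to26dph", "stage2_27to42dph", "stage3_56to98dph")
  dph_pools <- list(c(12L, 15L, 20L, 26L), c(27L, 35L, 42L),
                    c(56L, 70L, 98L))
  if (!is.list(member_noise_range))
    member_noise_range <- list(member_noise_range)
  rec <- function(v, i) v[(i - 1L) %% length(v) + 1L]
  out <- lapply(seq_len(n_stages), function(i) {
    spec <- synthetic_spec(
      n_samples = rec(n_samples, i), n_modules = rec(n_modules, i),
      module_size = rec(module_size, i),
      neg_fraction = rec(neg_fraction, i),
      neg_strength = rec(neg_strength, i),
      module_share = rec(module_share, i),
      sigma_log = rec(sigma_log, i),
      member_noise_range = member_noise_range[[(i - 1L) %%
                                                 length(member_noise_range) +
                                                 1L]],
      n_background = n_background, n_rare = n_rare,
      stage = rec(stages, i), dph_pool = dph_pools[[(i - 1L) %% 3L + 1L]],
      seed = as.integer(seed) * 131L + i, ...)
    generate_stage(spec)
  })
  names(out) <- vapply(out, function(s) s$table$metadata$stage[1L],
                       character(1))
  out
}

#' Serialize / read back ground truth
#'
#' @param truth a ground-truth `data.frame` from [generate_stage()].
#' @param path JSON output path.
#' @return `path` / the ground-truth `data.frame`.
#' @export
write_ground_truth <- function(truth, path) {
  payload <- list(st_recommended = attr(truth, "st_recommended"),
                  connector_modules = attr(truth, "connector_modules"),
                  taxa = truth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(payload$taxa, stringsAsFactors = FALSE)
  truth$module <- as.integer(truth$module)
  truth$loading_sign <- as.integer(truth$loading_sign)
  attr(truth, "st_recommended") <- payload$st_recommended
  cm <- payload$connector_modules
  # simplifyVector collapses equal-length triples into a matrix
  attr(truth, "connector_modules") <- if (is.matrix(cm)) {
    lapply(seq_len(nrow(cm)), function(i) as.integer(cm[i, ]))
  } else {
    lapply(cm, as.integer)
  }
  truth
}
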