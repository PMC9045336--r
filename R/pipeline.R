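# Cross-group orchestration: per-group network builds, trend regressions,
# ANOVA + LSD letters, networked-community overlaps, manifest.

#' Analysis configuration
#'
#' @param grouping `"by_stage"` (default) or `"by_dph"`.
#' @param min_replicates groups with fewer samples are excluded from network
#'   construction but kept in the diversity report (default 27, the usual
#'   minimum replication for a reliable correlation network).
#' @param st similarity threshold policy: a number (default 0.802) for a
#'   fixed threshold, or `"scan"` for RMT selection with fallback to
#'   `st_fallback`.
#' @param st_fallback threshold used when a scan selects nothing
#'   (default 0.802).
#' @param prevalence detection fraction for the OTU filter (default 0.2).
#' @param depth rarefaction depth; `NA` (default) skips rarefaction.
#' @param null_reps randomized networks per empirical network (default 100).
#' @param cohesion_reps taxa-shuffle repetitions for cohesion (default 200).
#' @param seed master seed.
#' @param out_dir output directory (`NA` disables file output).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(grouping = c("by_stage", "by_dph"),
                            min_replicates = 27L, st = 0.802,
                            st_fallback = 0.802, prevalence = 0.2,
                            depth = NA, null_reps = 100L,
                            cohesion_reps = 200L, seed = 1L,
                            out_dir = NA_character_) {
  grouping <- match.arg(grouping)
  cfg <- as.list(environment())
  class(cfg) <- "analysis_config"
  cfg
}

#' Run the full per-group analysis pipeline
#'
#' For each sample group (developmental stage or dph) with enough
#' replicates: prevalence filter, relative abundance, log transform,
#' Spearman matrix, threshold (fixed or RMT scan), network build, module
#' detection, topology summary, null ensemble, Zi/Pi roles with abundance
#' classes, keystone table, cohesion, vulnerability. Cross-group:
#' alpha-diversity for every group, metric-vs-dph regressions (dph
#' grouping), ANOVA + LSD letters on cohesion statistics, and
#' networked-community overlap counts. A manifest records every seed and
#' policy; when `cfg$out_dir` is set all tables are written beneath it.
#'
#' @param t a [count_table()] with metadata (`dph`, `stage`).
#' @param cfg an [analysis_config()].
#' @return A `pipeline_result` list: `groups` (per-group results),
#'   `diversity`, `trends`, `anova`, `overlap`, `manifest`.
#' @export
run_pipeline <- function(t, cfg = analysis_config()) {
  stopifnot(inherits(t, "count_table"), inherits(cfg, "analysis_config"))
  if (is.null(t$metadata)) stop("pipeline needs sample metadata")
  if (!is.na(cfg$depth)) t <- rarefy(t, cfg$depth, seed = cfg$seed)
  meta <- t$metadata
  key <- if (cfg$grouping == "by_stage") "stage" else "dph"
  if (!key %in% colnames(meta)) stop("metadata lacks column ", key)
  groups <- split(rownames(meta), meta[[key]])

  diversity <- alpha_diversity(t)
  diversity$group <- as.character(meta[diversity$sample_id, key])

  group_res <- list()
  for (gname in names(groups)) {
    ids <- groups[[gname]]
    if (length(ids) < cfg$min_replicates) {
      group_res[[gname]] <- list(skipped = TRUE, n = length(ids))
      next
    }
    sub <- count_table(t$counts[, ids, drop = FALSE],
                       metadata = meta[ids, , drop = FALSE],
                       taxonomy = t$taxonomy)
    filt <- prevalence_filter(sub, cfg$prevalence)
    rel_full <- to_relative(sub)
    rel <- to_relative(filt)
    lg <- log_transform(rel)
    s <- spearman_matrix(lg)
    st_used <- if (identical(cfg$st, "scan")) {
      sc <- rmt_threshold_scan(s)
      ch <- attr(sc, "chosen_st")
      if (is.na(ch)) cfg$st_fallback else ch
    } else as.numeric(cfg$st)
    net <- withCallingHandlers(
      build_network(s, st_used, provenance = gname),
      warning = function(w) invokeRestart("muffleWarning"))
    res <- list(skipped = FALSE, n = length(ids), st = st_used, net = net)
    if (n_links(net) > 0) {
      part <- detect_modules(net, seed = cfg$seed)
      res$modules <- part
      res$topology <- summarize_topology(net, part)
      res$null <- null_ensemble(net, reps = cfg$null_reps, seed = cfg$seed)
      classes <- classify_abundance(rel_full)
      res$roles <- node_roles(net, part, classes = classes)
      res$keystones <- keystone_table(res$roles)
      if (n_nodes(net) >= 3)
        res$vulnerability <- vulnerability(net)
    }
    res$cohesion <- cohesion(rel_full, null_reps = cfg$cohesion_reps,
                             seed = cfg$seed,
                             persistence = cfg$prevalence)
    group_res[[gname]] <- res
  }

  built <- Filter(function(r) !isTRUE(r$skipped) && !is.null(r$topology),
                  group_res)
  trends <- NULL
  if (cfg$grouping == "by_dph" && length(built) >= 3) {
    times <- as.numeric(names(built))
    trends <- do.call(rbind, lapply(
      c("n_nodes", "n_links", "avg_degree", "connectedness"),
      function(mname) {
        vals <- vapply(built, function(r) r$topology[[mname]], numeric(1))
        tr <- regress_vs_time(vals, times)
        cbind(data.frame(metric = mname), tr)
      }))
  }

  anova_tab <- NULL
  cdat <- do.call(rbind, lapply(names(group_res), function(g) {
    r <- group_res[[g]]
    if (isTRUE(r$skipped)) return(NULL)
    cbind(r$cohesion$samples, group = g)
  }))
  if (!is.null(cdat) && length(unique(cdat$group)) >= 2) {
    anova_tab <- lapply(c("cohesion_pos", "cohesion_neg", "np_ratio"),
                        function(colname) {
      ok <- !is.na(cdat[[colname]])
      anova_lsd(cdat[[colname]][ok], cdat$group[ok])
    })
    names(anova_tab) <- c("cohesion_pos", "cohesion_neg", "np_ratio")
  }

  overlap <- if (length(built) >= 2) {
    networked_community_overlap(lapply(built, function(r) r$net))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("miconet")),
    grouping = cfg$grouping, min_replicates = cfg$min_replicates,
    st_policy = cfg$st, st_fallback = cfg$st_fallback,
    st_used = lapply(built, function(r) r$st),
    prevalence = cfg$prevalence, depth = cfg$depth,
    null_reps = cfg$null_reps, cohesion_reps = cfg$cohesion_reps,
    seed = cfg$seed,
    groups = lapply(group_res, function(r)
      list(n = r$n, skipped = isTRUE(r$skipped))))

  out <- structure(list(groups = group_res, diversity = diversity,
                        trends = trends, anova = anova_tab,
                        overlap = overlap, manifest = manifest),
                   class = "pipeline_result")
  if (!is.na(cfg$out_dir)) .write_pipeline_outputs(out, cfg$out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  built <- sum(vapply(x$groups, function(r) !isTRUE(r$skipped), logical(1)))
  cat(sprintf("pipeline_result: %d group(s), %d analysed\n",
              length(x$groups), built))
  invisible(x)
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(res$diversity, "alpha_diversity.tsv")
  for (g in names(res$groups)) {
    r <- res$groups[[g]]
    if (isTRUE(r$skipped) || is.null(r$topology)) next
    pre <- gsub("[^A-Za-z0-9_.-]", "_", g)
    export_network(r$net,
                   edge_path = file.path(out_dir,
                                         paste0(pre, "_edges.tsv")),
                   node_path = file.path(out_dir,
                                         paste0(pre, "_nodes.tsv")),
                   graphml_path = file.path(out_dir,
                                            paste0(pre, ".graphml")),
                   modules = r$modules)
    wt(r$topology, paste0(pre, "_topology.tsv"))
    wt(r$null, paste0(pre, "_null.tsv"))
    wt(r$roles, paste0(pre, "_roles.tsv"))
    wt(r$cohesion$samples, paste0(pre, "_cohesion.tsv"))
  }
  if (!is.null(res$trends)) wt(res$trends, "trends.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Metric-versus-time regression
#'
#' Ordinary least squares of a per-group metric on days post-hatching.
#' Point-dropping (for example restricting to a contiguous run of time
#' points) is always explicit through `subset`, never automatic.
#'
#' @param values numeric metric per group.
#' @param times numeric dph per group (same length, >= 3 points).
#' @param subset optional logical/integer subset applied to both vectors.
#' @return `data.frame` with `slope`, `adjusted_r2`, `p` (of the slope) and
#'   `n_points`.
#' @export
regress_vs_time <- function(values, times, subset = NULL) {
  if (!is.null(subset)) {
    values <- values[subset]
    times <- times[subset]
  }
  stopifnot(length(values) == length(times))
  if (length(values) < 3) stop("need at least 3 points for a regression")
  if (stats::var(values) == 0) {
    # an exactly constant response carries no evidence of a trend
    return(data.frame(slope = 0, adjusted_r2 = 0, p = 1,
                      n_points = length(values)))
  }
  fit <- stats::lm(values ~ times)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  p <- if (nrow(sm$coefficients) < 2 || is.na(stats::coef(fit)[2L])) {
    NA_real_
  } else sm$coefficients[2L, 4L]
  data.frame(slope = unname(stats::coef(fit)[2L]),
             adjusted_r2 = sm$adj.r.squared, p = p,
             n_points = length(values))
}

#' One-way ANOVA with LSD letters
#'
#' One-way ANOVA followed by unadjusted pairwise least-significant-
#' difference t-tests (pooled within-group variance, residual df), the
#' classical Fisher LSD protocol, plus a compact letter display in which
#' groups sharing a letter are not significantly different at `alpha`. An
#' optional Holm adjustment of the pairwise p-values is off by default.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups with >= 2 samples each).
#' @param alpha significance level for the letters (default 0.05).
#' @param adjust `"none"` (default, LSD as classically printed) or
#'   `"holm"`.
#' @return list with `F`, `p`, `df`, `pairwise` (data.frame of group pairs
#'   and p-values) and `letters` (named character vector, groups ordered by
#'   decreasing mean).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05,
                      adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  pvals <- apply(pairs, 2L, function(pr) {
    if (mse <= 0) return(if (means[pr[1]] == means[pr[2]]) 1 else 0)
    se <- sqrt(mse * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    tval <- (means[pr[1]] - means[pr[2]]) / se
    2 * stats::pt(-abs(tval), dfres)
  })
  if (adjust == "holm") pvals <- stats::p.adjust(pvals, "holm")
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         p = pvals, row.names = NULL)
  letters <- .compact_letters(lv[order(-means)], pairwise, alpha)
  list(F = an["groups", "F value"], p = an["groups", "Pr(>F)"],
       df = c(an["groups", "Df"], dfres), pairwise = pairwise,
       letters = letters[lv])
}

# Insert-and-absorb compact letter display. `ordered_groups` are sorted by
# decreasing mean so the first letter attaches to the largest mean.
.compact_letters <- function(ordered_groups, pairwise, alpha) {
  absorb <- function(sets) {
    drop <- rep(FALSE, length(sets))
    for (k in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j == k || drop[j]) next
        if (all(sets[[k]] %in% sets[[j]]) &&
            (length(sets[[k]]) < length(sets[[j]]) || j < k)) {
          drop[k] <- TRUE
          break
        }
      }
    }
    sets[!drop]
  }
  sig <- pairwise[pairwise$p < alpha, , drop = FALSE]
  sets <- list(ordered_groups)
  for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    for (k in rev(seq_along(sets))) {
      s <- sets[[k]]
      if (a %in% s && b %in% s) {
        sets[[k]] <- setdiff(s, a)
        sets[[length(sets) + 1L]] <- setdiff(s, b)
      }
    }
    sets <- absorb(sets[vapply(sets, length, integer(1)) > 0])
  }
  # order letter sets by the position of their best-ranked member
  rank1 <- vapply(sets, function(s) min(match(s, ordered_groups)),
                  numeric(1))
  sets <- sets[order(rank1)]
  out <- stats::setNames(rep("", length(ordered_groups)), ordered_groups)
  for (k in seq_along(sets)) {
    for (gname in sets[[k]]) out[gname] <- paste0(out[gname], letters[k])
  }
  out
}

#' Overlap of networked communities
#'
#' Counts OTUs by exact network membership pattern (the numbers behind a
#' Venn diagram of "networked" OTUs) plus the list shared by all networks.
#'
#' @param nets list of >= 2 `eco_network`s (named, or names are invented).
#' @return list with `counts` (`data.frame`: membership `pattern`, member
#'   networks, `count`) and `shared_all` (character vector).
#' @export
networked_community_overlap <- function(nets) {
  stopifnot(length(nets) >= 2)
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    names(nets) <- paste0("net", seq_along(nets))
  sets <- lapply(nets, function(n) igraph::V(n$graph)$name)
  all_otus <- unique(unlist(sets))
  memb <- vapply(sets, function(s) all_otus %in% s,
                 logical(length(all_otus)))
  if (length(all_otus) == 1L) memb <- matrix(memb, nrow = 1L,
                                             dimnames = list(NULL,
                                                             names(nets)))
  pattern <- apply(memb, 1L, function(row)
    paste(names(nets)[row], collapse = "&"))
  counts <- as.data.frame(table(pattern = pattern),
                          stringsAsFactors = FALSE)
  colnames(counts)[2L] <- "count"
  shared_all <- all_otus[rowSums(memb) == length(nets)]
  list(counts = counts, shared_all = sort(shared_all),
       n_total = length(all_otus))
}
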