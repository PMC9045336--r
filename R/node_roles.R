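# Zi/Pi node roles, keystone identification, keystone-diversity screening.

#' Within-module (Zi) and among-module (Pi) connectivity
#'
#' For node i in module b,
#' `Zi = (k_ib - mean(k_b)) / sd(k_b)` standardizes the node's number of
#' links into its own module against that module's within-module degree
#' distribution, and `Pi = 1 - sum_c (k_ic / k_i)^2` measures how evenly the
#' node's `k_i` links spread over modules c (0 when all links stay in one
#' module). Modules where every member has the same within-module degree
#' (`sd = 0`) give `Zi = 0` by convention, flagged in the output.
#'
#' @param net an `eco_network`.
#' @param part a [detect_modules()] partition covering all network nodes.
#' @return `data.frame` with `otu_id`, `module`, `ki`, `kib`, `zi`, `pi`,
#'   `sigma_zero` (TRUE where the sd-zero convention applied).
#' @export
zi_pi <- function(net, part) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  memb <- part$membership[nodes]
  if (anyNA(memb)) stop("partition does not cover all network nodes")
  deg <- igraph::degree(g)
  if (any(deg < 1)) stop("network contains degree-0 nodes")
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  n <- length(nodes)
  kib <- numeric(n)
  pi_v <- numeric(n)
  for (i in seq_len(n)) {
    nb_mod <- memb[as.integer(adj[[i]])]
    kic <- table(nb_mod)
    kib[i] <- sum(nb_mod == memb[i])
    pi_v[i] <- 1 - sum((as.numeric(kic) / deg[i])^2)
  }
  # per-module mean/sd of within-module degree, over module members
  zi <- numeric(n)
  sigma_zero <- logical(n)
  for (b in unique(memb)) {
    in_b <- memb == b
    mu <- mean(kib[in_b])
    sdev <- stats::sd(kib[in_b])
    if (is.na(sdev) || sdev == 0) {
      zi[in_b] <- 0
      sigma_zero[in_b] <- TRUE
    } else {
      zi[in_b] <- (kib[in_b] - mu) / sdev
    }
  }
  data.frame(otu_id = nodes, module = as.integer(memb),
             ki = as.integer(deg), kib = as.integer(kib),
             zi = zi, pi = pi_v, sigma_zero = sigma_zero, row.names = NULL)
}

#' Classify a node role from (Zi, Pi)
#'
#' Role thresholds: network hubs have `Zi > 2.5` and `Pi > 0.62`; module
#' hubs `Zi > 2.5` and `Pi <= 0.62`; connectors `Zi <= 2.5` and
#' `Pi > 0.62`; everything else is peripheral. Hubs and connectors together
#' form the potential keystone set. Both inequalities are strict exactly as
#' printed, so (2.5, 0.62) is peripheral.
#'
#' @param zi,pi numeric vectors (recycled to common length).
#' @param zi_threshold,pi_threshold the role boundaries (defaults 2.5, 0.62).
#' @return Character vector in
#'   `c("network_hub", "module_hub", "connector", "peripheral")`.
#' @export
classify_role <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  hub <- zi > zi_threshold
  conn <- pi > pi_threshold
  ifelse(hub & conn, "network_hub",
         ifelse(hub, "module_hub",
                ifelse(conn, "connector", "peripheral")))
}

#' Node role table for a network
#'
#' Convenience wrapper: [zi_pi()] plus [classify_role()], optionally joined
#' with abundance classes.
#'
#' @param net an `eco_network`.
#' @param part a [detect_modules()] partition.
#' @param classes optional [classify_abundance()] output to join.
#' @inheritParams classify_role
#' @return `data.frame`: the [zi_pi()] columns plus `role` (and
#'   `abundance_class`, `mean_abundance` when `classes` is given).
#' @export
node_roles <- function(net, part, classes = NULL, zi_threshold = 2.5,
                       pi_threshold = 0.62) {
  zp <- zi_pi(net, part)
  zp$role <- classify_role(zp$zi, zp$pi, zi_threshold, pi_threshold)
  if (!is.null(classes)) {
    idx <- match(zp$otu_id, classes$otu_id)
    if (anyNA(idx))
      stop("abundance class missing for: ",
           paste(utils::head(zp$otu_id[is.na(idx)], 5L), collapse = ", "))
    zp$abundance_class <- classes$class[idx]
    zp$mean_abundance <- classes$mean_abundance[idx]
  }
  zp
}

#' Keystone table and role-by-class summary
#'
#' Restricts a [node_roles()] table to the potential keystone set (network
#' hubs, module hubs, connectors) and tabulates abundance classes per role.
#'
#' @param roles a [node_roles()] table including `abundance_class`.
#' @return list with `keystones` (rows of `roles`) and `summary`
#'   (`data.frame` of role, class, count, share within role as a
#'   percentage).
#' @export
keystone_table <- function(roles) {
  stopifnot("abundance_class" %in% colnames(roles))
  ks <- roles[roles$role != "peripheral", , drop = FALSE]
  ks <- ks[order(ks$role, ks$otu_id), , drop = FALSE]
  if (nrow(ks) == 0) {
    return(list(keystones = ks,
                summary = data.frame(role = character(0),
                                     class = character(0),
                                     count = integer(0),
                                     percent = numeric(0))))
  }
  tab <- as.data.frame(table(role = ks$role, class = ks$abundance_class),
                       stringsAsFactors = FALSE)
  colnames(tab)[3L] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  per_role <- tapply(tab$count, tab$role, sum)
  tab$percent <- 100 * tab$count / as.numeric(per_role[tab$role])
  rownames(tab) <- NULL
  list(keystones = ks, summary = tab)
}

#' Keystone-diversity association screening
#'
#' Correlates each keystone OTU's relative abundance with per-sample alpha
#' diversity indices across samples; a keystone "passes" when every
#' configured index is significantly associated (p < `alpha`). Spearman is
#' the default correlation (robust to abundance skew); Pearson is available.
#' OTUs with constant abundance are flagged and excluded.
#'
#' @param a an [abundance_table()].
#' @param div an [alpha_diversity()] table aligned to the same samples.
#' @param keystones a [node_roles()]-style table with `otu_id` and `role`.
#' @param indices columns of `div` to screen (default richness and shannon).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha per-index significance level (default 0.05).
#' @return `data.frame` sorted by role then otu_id with one `r_<index>` and
#'   `p_<index>` column pair per index and a `passes_all` flag.
#' @export
keystone_diversity_association <- function(a, div, keystones,
                                           indices = c("richness", "shannon"),
                                           method = c("spearman", "pearson"),
                                           alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(a, "abundance_table"), all(indices %in% colnames(div)))
  v <- a$values[, div$sample_id, drop = FALSE]
  otus <- intersect(keystones$otu_id, rownames(v))
  out <- list()
  for (otu in otus) {
    x <- v[otu, ]
    if (stats::sd(x) == 0) {
      warning("constant abundance for ", otu, "; excluded from screening")
      next
    }
    row <- list(otu_id = otu,
                role = keystones$role[match(otu, keystones$otu_id)],
                mean_abundance = mean(x))
    ps <- numeric(0)
    for (ix in indices) {
      ct <- suppressWarnings(
        stats::cor.test(x, div[[ix]], method = method, exact = FALSE))
      row[[paste0("r_", ix)]] <- unname(ct$estimate)
      row[[paste0("p_", ix)]] <- ct$p.value
      ps <- c(ps, ct$p.value)
    }
    row$passes_all <- all(ps < alpha)
    out[[otu]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(otu_id = character(0), role = character(0),
                      passes_all = logical(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$role, res$otu_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
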