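#' Construct an OTU count table
#'
#' A `count_table` holds a nonnegative integer OTU-by-sample matrix together
#' with optional per-sample metadata (days post-hatching `dph`, developmental
#' `stage`, rearing `tank`) and an optional per-OTU taxonomy lineage.
#'
#' @param counts integer matrix, OTUs in rows, samples in columns; must have
#'   unique, non-empty dimnames.
#' @param metadata optional `data.frame` with one row per sample and a
#'   `sample_id` column (or row names) matching `colnames(counts)`; typical
#'   columns are `dph`, `stage`, `tank`.
#' @param taxonomy optional named character vector of lineage strings, names
#'   are OTU ids.
#' @return An object of class `count_table` with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L, 1L, 0L), nrow = 3,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' ct <- count_table(m)
#' dim(ct)
#' @export
count_table <- function(counts, metadata = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!is.null(metadata$sample_id)) {
      rownames(metadata) <- as.character(metadata$sample_id)
    }
    missing <- setdiff(colnames(counts), rownames(metadata))
    if (length(missing))
      stop("samples missing from metadata: ", paste(missing, collapse = ", "))
    metadata <- metadata[colnames(counts), , drop = FALSE]
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[intersect(names(taxonomy), rownames(counts))]
  }
  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "count_table")
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d OTUs x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  cat(sprintf("  total reads: %s; median depth: %s\n",
              format(sum(as.numeric(x$counts)), big.mark = ","),
              format(stats::median(colSums(x$counts)), big.mark = ",")))
  if (!is.null(x$metadata))
    cat("  metadata columns:", paste(colnames(x$metadata), collapse = ", "),
        "\n")
  invisible(x)
}

otu_ids <- function(t) rownames(t$counts)
sample_ids <- function(t) colnames(t$counts)

#' Relative-abundance table
#'
#' Same axes as [count_table()] but holding per-sample relative abundances
#' (columns sum to 1).
#'
#' @param values numeric matrix with dimnames, columns summing to 1.
#' @param metadata,taxonomy as in [count_table()].
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, metadata = NULL, taxonomy = NULL) {
  values <- as.matrix(values)
  cs <- colSums(values)
  if (any(abs(cs - 1) > 1e-9))
    stop("abundance columns must sum to 1 (worst sample: ",
         colnames(values)[which.max(abs(cs - 1))], ")")
  structure(list(values = values, metadata = metadata, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d OTUs x %d samples\n", nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

.values <- function(t) if (inherits(t, "count_table")) t$counts else t$values

#' Read an OTU count table from TSV
#'
#' Accepts the common tab-separated layout with taxa ids in the first column
#' (header cell optionally `#OTU ID`, as written by QIIME-style exporters).
#'
#' @param path file path of a TSV count table.
#' @param orientation `"otus_as_rows"` (default) or `"samples_as_rows"`; the
#'   returned table is always OTU x sample.
#' @param metadata_path optional TSV with columns `sample_id`, `dph`, `stage`,
#'   `tank`.
#' @param taxonomy_path optional TSV with columns `otu_id`, `lineage`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("otus_as_rows", "samples_as_rows"),
                             metadata_path = NULL, taxonomy_path = NULL) {
  orientation <- match.arg(orientation)
  header <- readLines(path, n = 1L)
  # the leading '#' of "#OTU ID" must not be treated as a comment char
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          comment.char = "", quote = "",
                          stringsAsFactors = FALSE, colClasses = "character")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ids in first column of ", path)
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, function(col) as.numeric(col), numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]], path))
  }
  rownames(num) <- ids
  if (orientation == "samples_as_rows") num <- t(num)
  metadata <- if (!is.null(metadata_path)) {
    utils::read.table(metadata_path, sep = "\t", header = TRUE,
                      comment.char = "", quote = "",
                      stringsAsFactors = FALSE)
  }
  taxonomy <- if (!is.null(taxonomy_path)) {
    tx <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                            comment.char = "", quote = "",
                            stringsAsFactors = FALSE)
    stats::setNames(as.character(tx[[2L]]), as.character(tx[[1L]]))
  }
  count_table(num, metadata = metadata, taxonomy = taxonomy)
}

#' Write a count table as TSV
#'
#' @param t a [count_table()].
#' @param path output file path.
#' @param otu_header header cell for the id column, default `"#OTU ID"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(t, path, otu_header = "#OTU ID") {
  df <- data.frame(id = otu_ids(t), t$counts, check.names = FALSE)
  colnames(df)[1L] <- otu_header
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BIOM v1 (JSON) table
#'
#' Thin wrapper over the biomformat package (must be installed); dense or
#' sparse JSON BIOM files are supported.
#'
#' @param path path to a BIOM v1 JSON file.
#' @return A [count_table()].
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  count_table(m)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples whose total is below `depth` are
#' dropped with a warning. The default depth of 14,666 reads per sample
#' matches the even depth used throughout this pipeline's reference analyses.
#'
#' @param t a [count_table()].
#' @param depth target reads per sample (default 14666).
#' @param seed integer seed; the result is deterministic given `seed`.
#' @return A rarefied [count_table()] (possibly with fewer samples).
#' @export
rarefy <- function(t, depth = 14666L, seed = 1L) {
  stopifnot(inherits(t, "count_table"), depth >= 1)
  totals <- colSums(t$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples have fewer than ", depth, " reads")
  if (any(!keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(sample_ids(t)[!keep], collapse = ", "))
  counts <- t$counts[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  out <- apply(counts, 2L, function(col) {
    tot <- sum(col)
    if (tot == depth) return(col)
    picked <- sample.int(tot, depth)
    # map sampled read indices back onto OTUs via cumulative counts
    tabulate(findInterval(picked, cumsum(col), left.open = TRUE) + 1L,
             nbins = length(col))
  })
  rownames(out) <- otu_ids(t)
  meta <- if (!is.null(t$metadata)) t$metadata[colnames(out), , drop = FALSE]
  count_table(out, metadata = meta, taxonomy = t$taxonomy)
}

#' Convert counts to relative abundances
#'
#' @param t a [count_table()].
#' @return An [abundance_table()]; errors on an all-zero sample.
#' @export
to_relative <- function(t) {
  stopifnot(inherits(t, "count_table"))
  cs <- colSums(t$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ",
         paste(sample_ids(t)[cs == 0], collapse = ", "))
  abundance_table(sweep(t$counts, 2L, cs, "/"), metadata = t$metadata,
                  taxonomy = t$taxonomy)
}

#' Prevalence filter
#'
#' Retains OTUs detected (value > 0) in at least `min_fraction` of the
#' samples. The default of 0.2 follows the common rule of keeping OTUs
#' detected in 20% of replicate samples before network construction; the
#' boundary is inclusive (detected in exactly 20% is retained).
#'
#' @param t a [count_table()] or [abundance_table()].
#' @param min_fraction minimum detection fraction in (0, 1].
#' @return Filtered table of the same class; warns if nothing survives.
#' @export
prevalence_filter <- function(t, min_fraction = 0.2) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  v <- .values(t)
  prev <- rowMeans(v > 0)
  keep <- prev >= min_fraction
  if (!any(keep)) warning("prevalence filter removed every OTU")
  if (inherits(t, "count_table")) {
    count_table(t$counts[keep, , drop = FALSE], metadata = t$metadata,
                taxonomy = t$taxonomy)
  } else {
    out <- t
    out$values <- t$values[keep, , drop = FALSE]
    out
  }
}

#' Log-transform relative abundances
#'
#' Natural log of abundance plus a pseudocount. The default pseudocount is
#' half the smallest nonzero abundance in the table, a standard zero policy
#' when the upstream protocol does not state one.
#'
#' @param a an [abundance_table()].
#' @param pseudocount `"half_min_nonzero"` (default) or a nonnegative number.
#' @return A numeric matrix of log abundances with an attribute
#'   `pseudocount` recording the value used.
#' @export
log_transform <- function(a, pseudocount = "half_min_nonzero") {
  stopifnot(inherits(a, "abundance_table"))
  v <- a$values
  p <- if (identical(pseudocount, "half_min_nonzero")) {
    nz <- v[v > 0]
    if (length(nz) == 0) stop("table has no nonzero abundance")
    min(nz) / 2
  } else {
    stopifnot(is.numeric(pseudocount), pseudocount >= 0)
    pseudocount
  }
  out <- log(v + p)
  attr(out, "pseudocount") <- p
  out
}

#' Classify OTUs as abundant, rare or intermediate
#'
#' Abundance classes over a regional community (a sample scope, typically all
#' samples of one developmental stage):
#' * abundant: mean relative abundance > 0.1%, or >= 0.01% in all samples and
#'   >= 1% in at least one sample (locally abundant);
#' * rare: < 0.01% in at least one sample and never >= 1% in any sample;
#' * intermediate: everything else (neither rare nor abundant).
#'
#' Abundant takes precedence over rare so every OTU gets exactly one class.
#'
#' @param a an [abundance_table()].
#' @param scope optional character vector of sample ids restricting the
#'   regional community (default: all samples).
#' @return `data.frame` with `otu_id`, `class`, `mean_abundance`.
#' @export
classify_abundance <- function(a, scope = NULL) {
  stopifnot(inherits(a, "abundance_table"))
  v <- a$values
  if (!is.null(scope)) {
    stopifnot(length(scope) > 0, all(scope %in% colnames(v)))
    v <- v[, scope, drop = FALSE]
  }
  mean_ab <- rowMeans(v)
  ge_1pct_some <- apply(v >= 0.01, 1L, any)
  ge_001pct_all <- apply(v >= 1e-4, 1L, all)
  lt_001pct_some <- apply(v < 1e-4, 1L, any)
  abundant <- mean_ab > 1e-3 | (ge_001pct_all & ge_1pct_some)
  rare <- !abundant & lt_001pct_some & !ge_1pct_some
  cls <- ifelse(abundant, "abundant", ifelse(rare, "rare", "intermediate"))
  data.frame(otu_id = rownames(v), class = cls, mean_abundance = mean_ab,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample alpha diversity
#'
#' @param t a [count_table()].
#' @return `data.frame` with `sample_id`, `richness` (OTUs with count > 0)
#'   and `shannon` (natural-log units).
#' @export
alpha_diversity <- function(t) {
  stopifnot(inherits(t, "count_table"))
  cs <- colSums(t$counts)
  if (any(cs == 0))
    stop("all-zero sample(s): ", paste(sample_ids(t)[cs == 0], collapse = ", "))
  rich <- colSums(t$counts > 0)
  shan <- apply(t$counts, 2L, function(col) {
    p <- col[col > 0] / sum(col)
    -sum(p * log(p))
  })
  data.frame(sample_id = sample_ids(t), richness = as.integer(rich),
             shannon = shan, row.names = NULL, stringsAsFactors = FALSE)
}
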