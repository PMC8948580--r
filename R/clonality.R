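checkSizes <- function(sizes) {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L || all(is.na(sizes)))
    stop("clone-size vector is empty")
  if (anyNA(sizes) || any(sizes < 0))
    stop("clone sizes must be non-negative numbers")
  if (sum(sizes) <= 0)
    stop("clone sizes are all zero")
  sizes
}

#' @rdname expansionRatio
#' @export
setMethod("expansionRatio", "numeric", function(x) {
  sizes <- checkSizes(x)
  sum(sizes[sizes >= 2]) / sum(sizes)
})

#' @rdname expansionRatio
#' @export
setMethod("expansionRatio", "Repertoire",
  function(x) expansionRatio(clonotypeSizes(x)))

#' @rdname giniCoefficient
#' @export
setMethod("giniCoefficient", "numeric", function(x) {
  sizes <- checkSizes(x)
  n <- length(sizes)
  if (n == 1L) return(0)
  s <- sort(sizes)
  # rank form of the pairwise-difference Gini:
  # G = 2 * sum(i * x_(i)) / (n * sum(x)) - (n + 1) / n
  2 * sum(seq_len(n) * s) / (n * sum(s)) - (n + 1) / n
})

#' @rdname giniCoefficient
#' @export
setMethod("giniCoefficient", "Repertoire",
  function(x) giniCoefficient(clonotypeSizes(x)))

#' @rdname lorenzCurve
#' @export
setMethod("lorenzCurve", "numeric", function(x) {
  sizes <- checkSizes(x)
  s <- sort(sizes)
  n <- length(s)
  data.frame(p = c(0, seq_len(n) / n), L = c(0, cumsum(s) / sum(s)))
})

#' @rdname lorenzCurve
#' @export
setMethod("lorenzCurve", "Repertoire", function(x) {
  ct <- clonotypeTable(x)
  # ties in the ascending size sort broken by key string for reproducibility
  o <- order(ct$size, ct$key, method = "radix")
  s <- as.numeric(ct$size[o])
  n <- length(s)
  data.frame(p = c(0, seq_len(n) / n), L = c(0, cumsum(s) / sum(s)))
})

#' Gini coefficient from a Lorenz curve
#'
#' Area-based Gini: one minus twice the trapezoid area under the curve.
#' Agrees with [giniCoefficient()] to numerical precision; used as an
#' internal cross-check.
#'
#' @param curve a data.frame from [lorenzCurve()].
#' @return the Gini coefficient.
#' @export
giniFromLorenz <- function(curve) {
  stopifnot(all(c("p", "L") %in% names(curve)))
  p <- curve$p; L <- curve$L
  auc <- sum(diff(p) * (utils::head(L, -1) + utils::tail(L, -1)) / 2)
  1 - 2 * auc
}

#' Overlap of two repertoires
#'
#' Set algebra over the distinct clonotype keys of two repertoires, the
#' quantity shown in TCR-sharing Venn diagrams. Both repertoires must use the
#' same clonotype-key configuration; cross-sample identity is by key
#' equality, never by barcode.
#'
#' @param a,b \linkS4class{Repertoire} objects.
#' @return a list with \code{a_only}, \code{b_only}, \code{shared} counts and
#'   \code{shared_keys} (sorted character vector).
#' @export
repertoireOverlap <- function(a, b) {
  stopifnot(is(a, "Repertoire"), is(b, "Repertoire"))
  if (!identical(keyConfig(a), keyConfig(b)))
    stop("repertoires use different clonotype-key configurations")
  ka <- unique(clonotypeKeys(a))
  kb <- unique(clonotypeKeys(b))
  shared <- sort(intersect(ka, kb))
  list(a_only = length(setdiff(ka, kb)),
       b_only = length(setdiff(kb, ka)),
       shared = length(shared),
       shared_keys = shared)
}

#' Clonotypes shared across samples
#'
#' Lists clonotype keys observed in at least \code{min_samples} distinct
#' samples -- the "same TCR in different mice" readout. Rows are ordered by
#' descending total size, ties by key.
#'
#' @param repertoires list of \linkS4class{Repertoire} objects (>= 2) with a
#'   uniform key configuration.
#' @param min_samples minimum number of distinct samples (default 2).
#' @return data.frame with columns \code{key}, \code{n_samples},
#'   \code{sample_ids} (comma-separated), \code{sizes} (comma-separated,
#'   parallel to sample_ids) and \code{total_size}.
#' @export
sharedClonotypes <- function(repertoires, min_samples = 2) {
  if (length(repertoires) < 2L)
    stop("need at least 2 repertoires to look for shared clonotypes")
  if (min_samples < 2L) stop("min_samples must be >= 2")
  cfgs <- unique(lapply(repertoires, keyConfig))
  if (length(cfgs) != 1L)
    stop("repertoires use different clonotype-key configurations")

  long <- do.call(rbind, lapply(repertoires, function(r)
    data.frame(key = clonotypeKeys(r), sample_id = sampleID(r),
      size = clonotypeSizes(r), stringsAsFactors = FALSE)))
  long <- long[order(long$key, long$sample_id, method = "radix"), ,
               drop = FALSE]
  spl <- split(long, long$key)
  keep <- vapply(spl, function(d) length(unique(d$sample_id)),
    integer(1)) >= min_samples
  spl <- spl[keep]
  out <- data.frame(
    key = names(spl),
    n_samples = vapply(spl, function(d) length(unique(d$sample_id)),
      integer(1)),
    sample_ids = vapply(spl, function(d) paste(d$sample_id, collapse = ","),
      character(1)),
    sizes = vapply(spl, function(d)
      paste(as.integer(d$size), collapse = ","), character(1)),
    total_size = vapply(spl, function(d) sum(d$size), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$total_size, out$key, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample clonality summary
#'
#' One row per repertoire with the headline clonality statistics: number of
#' cells and clonotypes, clonal expansion ratio, Gini coefficient, and the
#' fraction of cells in the largest clone.
#'
#' @param repertoires a \linkS4class{Repertoire} or list of them.
#' @return data.frame with one row per sample.
#' @seealso [aggregateClonality()] for the cross-sample mean +/- SEM.
#' @export
clonalitySummary <- function(repertoires) {
  if (is(repertoires, "Repertoire")) repertoires <- list(repertoires)
  rows <- lapply(repertoires, function(r) {
    sz <- clonotypeSizes(r)
    data.frame(sample_id = sampleID(r), tissue = tissueLabel(r),
      n_cells = sum(sz), n_clonotypes = length(sz),
      expansion_ratio = expansionRatio(sz),
      gini = giniCoefficient(sz),
      largest_clone_fraction = max(sz) / sum(sz),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate clonality statistics across samples
#'
#' Mean and standard error of the mean of each clonality statistic across
#' samples (each mouse/sample contributing one value), optionally grouped by
#' tissue.
#'
#' @param summary data.frame from [clonalitySummary()].
#' @param by optional grouping column name (e.g. \code{"tissue"}).
#' @return data.frame with one row per (group x statistic): \code{statistic},
#'   \code{n_samples}, \code{mean}, \code{sem}.
#' @export
aggregateClonality <- function(summary, by = NULL) {
  stats <- c("expansion_ratio", "gini", "largest_clone_fraction")
  groups <- if (is.null(by)) list(all = summary)
    else split(summary, summary[[by]])
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    do.call(rbind, lapply(stats, function(s) {
      v <- d[[s]]
      data.frame(group = g, statistic = s, n_samples = length(v),
        mean = mean(v),
        sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
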