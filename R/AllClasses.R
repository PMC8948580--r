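#' @import methods
NULL

#' PairedCellSet: cells resolved to one productive alpha/beta chain pair
#'
#' Container for the output of [filterPairedProductive()]. Each row of the
#' cell table is one cell carrying exactly one productive TCR-alpha and one
#' productive TCR-beta chain descriptor (V gene, J gene, CDR3 nucleotide and
#' amino-acid sequence per chain). The filter report records how the input
#' contigs were reduced to this set.
#'
#' @slot cells data.frame with columns \code{cell_barcode}, \code{sample_id},
#'   \code{tissue}, \code{alpha_v}, \code{alpha_j}, \code{alpha_cdr3_nt},
#'   \code{alpha_cdr3_aa}, \code{beta_v}, \code{beta_j}, \code{beta_cdr3_nt},
#'   \code{beta_cdr3_aa}.
#' @slot report list with counters \code{n_input_cells}, \code{n_retained},
#'   \code{n_dropped_unpaired}, \code{n_dropped_multi},
#'   \code{n_multi_chain_resolved}.
#'
#' @export
setClass("PairedCellSet",
  representation(cells = "data.frame", report = "list"))

.PAIRED_COLS <- c("cell_barcode", "sample_id", "tissue",
  "alpha_v", "alpha_j", "alpha_cdr3_nt", "alpha_cdr3_aa",
  "beta_v", "beta_j", "beta_cdr3_nt", "beta_cdr3_aa")

setValidity("PairedCellSet", function(object) {
  msg <- character()
  if (!all(.PAIRED_COLS %in% names(object@cells)))
    msg <- c(msg, paste("cells must contain columns:",
      paste(setdiff(.PAIRED_COLS, names(object@cells)), collapse = ", ")))
  else {
    key <- paste(object@cells$sample_id, object@cells$cell_barcode)
    if (anyDuplicated(key))
      msg <- c(msg, "each (sample_id, cell_barcode) may appear only once")
    if (nrow(object@cells) > 0 &&
        (any(!nzchar(object@cells$alpha_cdr3_nt)) ||
         any(!nzchar(object@cells$beta_cdr3_nt))))
      msg <- c(msg, "every retained cell needs non-empty alpha and beta CDR3")
  }
  need <- c("n_input_cells", "n_retained", "n_dropped_unpaired")
  if (!all(need %in% names(object@report)))
    msg <- c(msg, "report must contain the standard filter counters")
  if (length(msg)) msg else TRUE
})

#' Repertoire: one sample's cells collapsed into paired-chain clonotypes
#'
#' A clonotype is the set of cells sharing one alpha/beta receptor, where
#' receptor identity is defined by the clonotype key configuration: CDR3 at
#' nucleotide or amino-acid level, with or without V/J gene calls, always for
#' both chains jointly. Cells partition into clonotypes, so the clone sizes
#' sum to the number of cells.
#'
#' @slot sampleID single sample identifier.
#' @slot tissue tissue label (e.g. \code{"aorta"}, \code{"spleen"}).
#' @slot clonotypes data.frame, one row per clonotype: \code{clonotype_id},
#'   \code{key}, \code{size}, and the chain descriptors
#'   (\code{alpha_v}, \code{alpha_j}, \code{alpha_cdr3_nt},
#'   \code{alpha_cdr3_aa}, \code{beta_*}) of a representative cell.
#' @slot members list of character vectors of cell barcodes, parallel to the
#'   rows of \code{clonotypes}.
#' @slot keyLevel \code{"nt"} or \code{"aa"}: the sequence level used in the
#'   clonotype key.
#' @slot includeVJ logical: whether V and J gene calls are part of the key.
#'
#' @export
setClass("Repertoire",
  representation(sampleID = "character", tissue = "character",
    clonotypes = "data.frame", members = "list",
    keyLevel = "character", includeVJ = "logical"))

setValidity("Repertoire", function(object) {
  msg <- character()
  if (length(object@sampleID) != 1L)
    msg <- c(msg, "sampleID must be a single string")
  if (!object@keyLevel %in% c("nt", "aa"))
    msg <- c(msg, "keyLevel must be 'nt' or 'aa'")
  ct <- object@clonotypes
  if (!all(c("clonotype_id", "key", "size") %in% names(ct)))
    msg <- c(msg, "clonotypes needs columns clonotype_id, key, size")
  else {
    if (nrow(ct) == 0L)
      msg <- c(msg, "a Repertoire must contain at least one clonotype")
    if (nrow(ct) != length(object@members))
      msg <- c(msg, "members must parallel the clonotype table")
    else if (nrow(ct) > 0L) {
      if (!identical(as.integer(ct$size), lengths(object@members)))
        msg <- c(msg, "clonotype size must equal the number of member cells")
      if (any(ct$size < 1L))
        msg <- c(msg, "clonotype sizes must be >= 1")
      bcs <- unlist(object@members, use.names = FALSE)
      if (anyDuplicated(bcs))
        msg <- c(msg, "member cells must be disjoint across clonotypes")
      if (anyDuplicated(ct$key))
        msg <- c(msg, "clonotype keys must be unique")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RecruitmentEstimate: the parabiosis recruitment calculation
#'
#' Holds every intermediate of the recruitment chain: per-mouse aorta-to-blood
#' normalized chimerism, their unweighted mean, the Treg counts before and
#' after injury, the accumulated count (post minus steady state), the
#' recruited count (mean recruitment applied to the accumulation, rounded to
#' the nearest cell) and the recruited fraction of the total post-injury pool.
#' All slots carry full precision; display rounding to one decimal happens
#' only in \code{show()} and [displayValues()].
#'
#' @slot perMouseRecruitmentPct per-mouse normalized recruitment percentages.
#' @slot meanRecruitmentPct unweighted mean of the per-mouse values.
#' @slot steadyStateCount,postInjuryCount Treg counts (cells).
#' @slot accumulatedCount post-injury minus steady-state count.
#' @slot recruitedCount round(mean/100 x accumulated).
#' @slot recruitedFractionOfTotalPct 100 x recruited / post-injury.
#' @slot ci bootstrap percentile CI of the mean recruitment (length 2, or
#'   \code{NA} when no bootstrap was requested).
#'
#' @export
setClass("RecruitmentEstimate",
  representation(perMouseRecruitmentPct = "numeric",
    meanRecruitmentPct = "numeric",
    steadyStateCount = "numeric", postInjuryCount = "numeric",
    accumulatedCount = "numeric", recruitedCount = "numeric",
    recruitedFractionOfTotalPct = "numeric", ci = "numeric"))

setValidity("RecruitmentEstimate", function(object) {
  msg <- character()
  acc <- object@postInjuryCount - object@steadyStateCount
  if (acc < 0)
    msg <- c(msg, "post-injury count must be >= steady-state count")
  if (!isTRUE(all.equal(object@accumulatedCount, acc)))
    msg <- c(msg, "accumulatedCount must equal post - steady")
  rec <- roundHalfUp(object@meanRecruitmentPct / 100 * acc, 0)
  if (!isTRUE(all.equal(object@recruitedCount, rec)))
    msg <- c(msg, "recruitedCount must equal round(mean/100 x accumulated)")
  if (object@postInjuryCount > 0) {
    frac <- 100 * object@recruitedCount / object@postInjuryCount
    if (!isTRUE(all.equal(object@recruitedFractionOfTotalPct, frac)))
      msg <- c(msg, "recruitedFractionOfTotalPct must equal 100 x recruited / post")
  }
  if (length(msg)) msg else TRUE
})

#' ConcordanceResult: signature agreement of a differential-expression table
#'
#' Fraction of signature genes whose fold change goes in the anticipated
#' direction (up-signature genes up, down-signature genes down) beyond a
#' minimum fold threshold, together with the per-gene verdicts.
#'
#' @slot nSignaturePresent number of signature genes in the denominator.
#' @slot nConcordant number of concordant signature genes.
#' @slot fractionPct 100 x nConcordant / nSignaturePresent.
#' @slot verdicts per-gene data.frame: \code{gene}, \code{direction},
#'   \code{present}, \code{expressed}, \code{log2fc}, \code{concordant}.
#' @slot minFold linear fold threshold used.
#' @slot denominator \code{"present"} or \code{"all"}.
#'
#' @export
setClass("ConcordanceResult",
  representation(nSignaturePresent = "numeric", nConcordant = "numeric",
    fractionPct = "numeric", verdicts = "data.frame",
    minFold = "numeric", denominator = "character"))

setValidity("ConcordanceResult", function(object) {
  msg <- character()
  if (object@nConcordant > object@nSignaturePresent)
    msg <- c(msg, "nConcordant cannot exceed nSignaturePresent")
  if (object@nSignaturePresent > 0 &&
      !isTRUE(all.equal(object@fractionPct,
        100 * object@nConcordant / object@nSignaturePresent)))
    msg <- c(msg, "fractionPct must equal 100 x nConcordant / nSignaturePresent")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PairedCellSet", function(object) {
  r <- object@report
  cat("PairedCellSet with", nrow(object@cells), "cells",
    sprintf("(%d samples)\n", length(unique(object@cells$sample_id))))
  cat(sprintf("  input cells: %d | retained: %d | dropped unpaired: %d\n",
    r$n_input_cells, r$n_retained, r$n_dropped_unpaired))
  if (!is.null(r$n_multi_chain_resolved) && r$n_multi_chain_resolved > 0)
    cat("  multi-chain cells resolved:", r$n_multi_chain_resolved, "\n")
  if (!is.null(r$n_dropped_multi) && r$n_dropped_multi > 0)
    cat("  multi-chain cells dropped:", r$n_dropped_multi, "\n")
})

setMethod("show", "Repertoire", function(object) {
  cat("Repertoire of sample", object@sampleID,
    if (nzchar(object@tissue)) paste0("(", object@tissue, ")"), "\n")
  cat(sprintf("  %d cells in %d clonotypes (key: CDR3 %s%s)\n",
    nCells(object), nClonotypes(object), object@keyLevel,
    if (object@includeVJ) " + V/J" else ""))
  sz <- sort(clonotypeSizes(object), decreasing = TRUE)
  cat("  clone sizes:", paste(utils::head(sz, 8), collapse = " "),
    if (length(sz) > 8) "...", "\n")
})

setMethod("show", "RecruitmentEstimate", function(object) {
  d <- displayValues(object)
  cat("RecruitmentEstimate over", length(object@perMouseRecruitmentPct),
    "mice\n")
  cat(sprintf("  mean recruitment: %.1f%%\n", d$mean_recruitment_pct))
  cat(sprintf("  Tregs: steady %d -> post-injury %d (accumulated %d)\n",
    as.integer(object@steadyStateCount), as.integer(object@postInjuryCount),
    as.integer(object@accumulatedCount)))
  cat(sprintf("  recruited: %d cells = %.1f%% of the post-injury pool\n",
    as.integer(object@recruitedCount), d$recruited_fraction_of_total_pct))
  if (!anyNA(object@ci))
    cat(sprintf("  bootstrap 95%% CI of mean recruitment: [%.1f, %.1f]\n",
      object@ci[1], object@ci[2]))
})

setMethod("show", "ConcordanceResult", function(object) {
  cat("ConcordanceResult:", object@nConcordant, "of",
    object@nSignaturePresent, "signature genes concordant",
    sprintf("(%.1f%%)\n", object@fractionPct))
  cat(sprintf("  min fold: %g, denominator: %s\n",
    object@minFold, object@denominator))
})
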