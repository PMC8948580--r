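#' Normalize tissue chimerism to blood chimerism
#'
#' Parabiosis recruitment normalization: the partner-derived fraction in a
#' tissue divided by the partner-derived fraction in blood, as a percentage.
#' A mouse whose aorta chimerism equals its blood chimerism has 100%
#' recruitment. Values above 100% (tissue chimerism exceeding blood) are
#' returned unclipped with a warning -- truncating them would bias a cohort
#' mean.
#'
#' @param blood_pct blood chimerism percentage(s), > 0.
#' @param tissue_pct tissue chimerism percentage(s), >= 0.
#' @return recruitment percentage(s): \code{100 * tissue_pct / blood_pct},
#'   full precision (display rounding is the caller's concern).
#' @examples
#' normalizeRecruitment(35.7, 30.9)  # 86.55...; reported as 86.6
#' @export
normalizeRecruitment <- function(blood_pct, tissue_pct) {
  if (any(is.na(blood_pct)) || any(blood_pct <= 0))
    stop("blood chimerism must be > 0 (it is the denominator)")
  if (any(is.na(tissue_pct)) || any(tissue_pct < 0))
    stop("tissue chimerism must be >= 0")
  out <- 100 * tissue_pct / blood_pct
  if (any(out > 100))
    warning(sum(out > 100),
      " value(s) exceed 100% (tissue chimerism above blood); ",
      "returned unclipped")
  out
}

#' Estimate the recruited contribution to a tissue Treg increase
#'
#' The full parabiosis recruitment chain: per-mouse aorta-to-blood
#' normalization, unweighted mean across mice, and the projection onto cell
#' counts -- the accumulated Tregs (post-injury minus steady state), the
#' recruited Tregs (mean recruitment applied to the accumulation, rounded to
#' the nearest cell) and the recruited fraction of the total post-injury
#' pool. Intermediates are kept at full precision; only display output is
#' rounded (half-up, one decimal).
#'
#' @param cohort data.frame with columns \code{mouse_id},
#'   \code{blood_chimerism_pct}, \code{tissue_chimerism_pct}; or \code{NULL}
#'   when \code{mean_recruitment_pct} is supplied directly (e.g. reanalyzing
#'   a published mean).
#' @param steady_state_count Treg count in the uninjured tissue.
#' @param post_injury_count Treg count after injury; must be >= steady state.
#' @param mean_recruitment_pct optional: skip the cohort and use this mean.
#' @param weights \code{"equal"} (default; unweighted arithmetic mean across
#'   mice) or \code{"cells"} (blood-chimerism-weighted mean).
#' @param boot if TRUE, attach a percentile bootstrap CI (resampling mice).
#' @param n_boot bootstrap draws (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed for the bootstrap.
#' @return a \linkS4class{RecruitmentEstimate}.
#' @examples
#' estimateRecruitment(mean_recruitment_pct = 78.6,
#'   steady_state_count = 20, post_injury_count = 5375)
#' @export
estimateRecruitment <- function(cohort = NULL, steady_state_count,
                                post_injury_count,
                                mean_recruitment_pct = NULL,
                                weights = c("equal", "cells"),
                                boot = FALSE, n_boot = 2000, conf = 0.95,
                                seed = 1) {
  weights <- match.arg(weights)
  if (post_injury_count < steady_state_count)
    stop("post-injury count must be >= steady-state count")
  if (steady_state_count < 0) stop("counts must be non-negative")

  if (is.null(mean_recruitment_pct)) {
    if (is.null(cohort) || nrow(cohort) == 0L)
      stop("need a non-empty cohort or an explicit mean_recruitment_pct")
    need <- c("blood_chimerism_pct", "tissue_chimerism_pct")
    if (!all(need %in% names(cohort)))
      stop("cohort is missing column(s): ",
        paste(setdiff(need, names(cohort)), collapse = ", "))
    per_mouse <- normalizeRecruitment(cohort$blood_chimerism_pct,
      cohort$tissue_chimerism_pct)
    if (!is.null(cohort$mouse_id)) names(per_mouse) <- cohort$mouse_id
    mean_pct <- if (weights == "equal") mean(per_mouse)
      else stats::weighted.mean(per_mouse, cohort$blood_chimerism_pct)
  } else {
    per_mouse <- mean_recruitment_pct
    mean_pct <- mean_recruitment_pct
  }

  ci <- NA_real_
  if (boot && length(per_mouse) > 1L) {
    ci <- withSeed(seed, {
      means <- vapply(seq_len(n_boot), function(i)
        mean(sample(per_mouse, replace = TRUE)), numeric(1))
      stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
        names = FALSE)
    })
  }

  accumulated <- post_injury_count - steady_state_count
  recruited <- roundHalfUp(mean_pct / 100 * accumulated, 0)
  frac_total <- if (post_injury_count > 0)
    100 * recruited / post_injury_count else 0
  new("RecruitmentEstimate",
    perMouseRecruitmentPct = per_mouse,
    meanRecruitmentPct = mean_pct,
    steadyStateCount = as.numeric(steady_state_count),
    postInjuryCount = as.numeric(post_injury_count),
    accumulatedCount = as.numeric(accumulated),
    recruitedCount = recruited,
    recruitedFractionOfTotalPct = frac_total,
    ci = ci)
}

#' @rdname RecruitmentEstimate-accessors
#' @export
setMethod("meanRecruitmentPct", "RecruitmentEstimate",
  function(x) x@meanRecruitmentPct)

#' @rdname RecruitmentEstimate-accessors
#' @export
setMethod("perMouseRecruitmentPct", "RecruitmentEstimate",
  function(x) x@perMouseRecruitmentPct)

#' @rdname RecruitmentEstimate-accessors
#' @export
setMethod("accumulatedCount", "RecruitmentEstimate",
  function(x) x@accumulatedCount)

#' @rdname RecruitmentEstimate-accessors
#' @export
setMethod("recruitedCount", "RecruitmentEstimate",
  function(x) x@recruitedCount)

#' @rdname RecruitmentEstimate-accessors
#' @export
setMethod("recruitedFractionPct", "RecruitmentEstimate",
  function(x) x@recruitedFractionOfTotalPct)

#' @rdname displayValues
#' @export
setMethod("displayValues", "RecruitmentEstimate", function(x) {
  list(
    per_mouse_recruitment_pct = roundHalfUp(x@perMouseRecruitmentPct, 1),
    mean_recruitment_pct = roundHalfUp(x@meanRecruitmentPct, 1),
    steady_state_count = as.integer(x@steadyStateCount),
    post_injury_count = as.integer(x@postInjuryCount),
    accumulated_count = as.integer(x@accumulatedCount),
    recruited_count = as.integer(x@recruitedCount),
    recruited_fraction_of_total_pct =
      roundHalfUp(x@recruitedFractionOfTotalPct, 1))
})

#' Photoconversion migration ratio
#'
#' Fraction of photoconverted (e.g. Kikume-red) cells in each organ,
#' normalized to the fraction in the nondraining lymph node, which measures
#' systemic circulation. A ratio of 1 means an organ receives tagged cells at
#' the systemic rate; > 1 means enrichment (directed migration).
#'
#' @param samples data.frame with columns \code{organ}, \code{phc_fraction}
#'   (fraction of photoconverted cells, in [0,1]) and
#'   \code{is_nondraining_reference} (logical; exactly one TRUE row).
#' @return data.frame with columns \code{organ}, \code{phc_fraction},
#'   \code{ratio} (the reference organ's own ratio is 1).
#' @export
migrationRatio <- function(samples) {
  need <- c("organ", "phc_fraction", "is_nondraining_reference")
  if (!all(need %in% names(samples)))
    stop("samples table is missing column(s): ",
      paste(setdiff(need, names(samples)), collapse = ", "))
  ref <- samples$is_nondraining_reference
  if (is.character(ref)) ref <- parseProductive(ref)
  ref <- as.logical(ref)
  if (sum(ref) != 1L)
    stop("exactly one organ must be flagged as the nondraining reference")
  ref_frac <- samples$phc_fraction[ref]
  if (is.na(ref_frac) || ref_frac <= 0)
    stop("the reference organ's photoconverted fraction must be > 0")
  if (any(samples$phc_fraction < 0 | samples$phc_fraction > 1))
    stop("photoconverted fractions must lie in [0, 1]")
  data.frame(organ = samples$organ,
    phc_fraction = samples$phc_fraction,
    ratio = samples$phc_fraction / ref_frac,
    stringsAsFactors = FALSE)
}
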