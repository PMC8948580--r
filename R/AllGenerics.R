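#' @rdname Repertoire-class
#' @param x,object a \linkS4class{Repertoire} (or, for the statistics
#'   generics, a numeric vector of clone sizes).
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname Repertoire-class
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))

#' @rdname Repertoire-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname Repertoire-class
#' @export
setGeneric("nClonotypes", function(x) standardGeneric("nClonotypes"))

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypeSizes", function(x) standardGeneric("clonotypeSizes"))

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypeKeys", function(x) standardGeneric("clonotypeKeys"))

#' @rdname Repertoire-class
#' @export
setGeneric("clonotypeTable", function(x) standardGeneric("clonotypeTable"))

#' Clonal expansion ratio
#'
#' Proportion of cells that belong to clonotypes of two or more cells, among
#' all cells analyzed. 0 when every clonotype is a singleton; 1 when every
#' cell shares its receptor with at least one other cell.
#'
#' @param x a \linkS4class{Repertoire}, or a numeric vector of clone sizes.
#' @return a fraction in [0, 1].
#' @examples
#' expansionRatio(c(3, 2, 1, 1, 1))  # 5/8
#' @export
setGeneric("expansionRatio", function(x) standardGeneric("expansionRatio"))

#' Gini inequality coefficient of clone sizes
#'
#' Population (uncorrected) Gini coefficient
#' \eqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)}: 0 for a repertoire
#' where every clonotype has equal abundance, approaching 1 for a repertoire
#' dominated by a single clone (the exact upper bound for n clonotypes is
#' (n-1)/n).
#'
#' @param x a \linkS4class{Repertoire}, or a numeric vector of non-negative
#'   clone sizes (at least one positive).
#' @return a value in [0, (n-1)/n].
#' @examples
#' giniCoefficient(c(5, 5, 5, 5))  # 0
#' giniCoefficient(c(3, 1))        # 0.25
#' @export
setGeneric("giniCoefficient", function(x) standardGeneric("giniCoefficient"))

#' Lorenz curve of clone sizes
#'
#' Cumulative proportion of cells (y) against cumulative proportion of
#' clonotypes (x), clonotypes sorted ascending by size. Starts at (0,0),
#' ends at (1,1), and lies on or below the diagonal.
#'
#' @param x a \linkS4class{Repertoire}, or a numeric vector of clone sizes.
#' @return a data.frame with columns \code{p} (cumulative clonotype
#'   proportion) and \code{L} (cumulative cell proportion).
#' @seealso [giniFromLorenz()]
#' @export
setGeneric("lorenzCurve", function(x) standardGeneric("lorenzCurve"))

#' Accessors for RecruitmentEstimate
#'
#' @param x a \linkS4class{RecruitmentEstimate}.
#' @name RecruitmentEstimate-accessors
#' @export
setGeneric("meanRecruitmentPct",
  function(x) standardGeneric("meanRecruitmentPct"))

#' @rdname RecruitmentEstimate-accessors
#' @export
setGeneric("perMouseRecruitmentPct",
  function(x) standardGeneric("perMouseRecruitmentPct"))

#' @rdname RecruitmentEstimate-accessors
#' @export
setGeneric("accumulatedCount", function(x) standardGeneric("accumulatedCount"))

#' @rdname RecruitmentEstimate-accessors
#' @export
setGeneric("recruitedCount", function(x) standardGeneric("recruitedCount"))

#' @rdname RecruitmentEstimate-accessors
#' @export
setGeneric("recruitedFractionPct",
  function(x) standardGeneric("recruitedFractionPct"))

#' Display-rounded values of an estimate
#'
#' Returns the human-readable (half-up, one-decimal) renderings of an
#' object's headline numbers; the slots themselves always keep full
#' precision.
#'
#' @param x an object with display rounding (currently
#'   \linkS4class{RecruitmentEstimate}).
#' @return a named list of rounded numbers.
#' @export
setGeneric("displayValues", function(x) standardGeneric("displayValues"))

#' Filter/parse report accessor
#'
#' @param x a \linkS4class{PairedCellSet} or a contig data.frame returned by
#'   [readContigTable()].
#' @return the report list attached to the object.
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname ConcordanceResult-class
#' @param x a \linkS4class{ConcordanceResult}.
#' @export
setGeneric("concordanceFractionPct",
  function(x) standardGeneric("concordanceFractionPct"))

#' @rdname ConcordanceResult-class
#' @export
setGeneric("geneVerdicts", function(x) standardGeneric("geneVerdicts"))
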