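#' Read a differential-expression table
#'
#' TSV with columns \code{gene}, \code{log2fc} and optionally
#' \code{expressed} (default TRUE). Gene symbols must be unique after
#' case-normalization.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{expressed}.
#' @export
readDETable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE)
  need <- c("gene", "log2fc")
  if (!all(need %in% names(df)))
    stop("DE table is missing column(s): ",
      paste(setdiff(need, names(df)), collapse = ", "))
  if (is.null(df$expressed)) df$expressed <- TRUE
  if (is.character(df$expressed)) df$expressed <- parseProductive(df$expressed)
  validateDETable(df)
  df[, c("gene", "log2fc", "expressed")]
}

validateDETable <- function(table) {
  if (!all(c("gene", "log2fc") %in% names(table)))
    stop("DE table needs columns gene and log2fc")
  if (anyDuplicated(toupper(table$gene)))
    stop("gene symbols must be unique after case-normalization")
  invisible(table)
}

#' Read an up/down gene signature
#'
#' Two-column TSV: \code{gene}, \code{direction} (\code{up} for genes
#' induced in the population of interest, \code{down} for repressed).
#'
#' @param path TSV path.
#' @return list with character vectors \code{up} and \code{down}.
#' @export
readSignature <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% names(df)))
    stop("signature file needs columns gene and direction")
  if (!all(df$direction %in% c("up", "down")))
    stop("signature direction must be 'up' or 'down'")
  sig <- list(up = df$gene[df$direction == "up"],
              down = df$gene[df$direction == "down"])
  validateSignature(sig)
  sig
}

validateSignature <- function(signature) {
  if (!is.list(signature) || !all(c("up", "down") %in% names(signature)))
    stop("signature must be a list with elements 'up' and 'down'")
  if (length(signature$up) + length(signature$down) == 0L)
    stop("signature is empty")
  if (length(intersect(toupper(signature$up), toupper(signature$down))))
    stop("up and down signature sets must be disjoint")
  invisible(signature)
}

#' Count genes beyond a fold-change threshold
#'
#' Number of expressed genes whose absolute fold change exceeds a linear
#' threshold (strictly), in the requested direction -- the "genes whose
#' expression differed by more than k-fold" count printed on volcano plots.
#'
#' @param table DE table (columns \code{gene}, \code{log2fc}, optionally
#'   \code{expressed}).
#' @param fold_threshold linear fold threshold, > 1 (default 2).
#' @param direction \code{"both"}, \code{"up"} or \code{"down"}.
#' @return integer count.
#' @examples
#' de <- data.frame(gene = c("A", "B", "C"), log2fc = c(2, -1.5, 0.5))
#' countFoldChangeGenes(de, 2, "both")  # 2
#' @export
countFoldChangeGenes <- function(table, fold_threshold = 2,
                                 direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  validateDETable(table)
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stop("fold_threshold must be a linear fold > 1")
  expressed <- if (is.null(table$expressed)) rep(TRUE, nrow(table))
    else table$expressed
  lfc <- table$log2fc[expressed]
  th <- log2(fold_threshold)
  switch(direction,
    both = sum(abs(lfc) > th),
    up = sum(lfc > th),
    down = sum(lfc < -th))
}

#' Score a DE table against an up/down signature
#'
#' A signature gene is concordant iff it is present and expressed in the
#' table AND its fold change goes in the anticipated direction beyond the
#' minimum fold: \code{log2fc > log2(min_fold)} for up-signature genes,
#' \code{log2fc < -log2(min_fold)} for down-signature genes. With the default
#' \code{min_fold = 1} any strictly correct-direction change counts. Gene
#' matching is case-insensitive. The denominator is, by default, the
#' signature genes present in the table (\code{denominator = "present"});
#' with \code{"all"} absent genes count against the score.
#'
#' @param table DE table (columns \code{gene}, \code{log2fc}, optionally
#'   \code{expressed}); positive log2fc = higher in the population of
#'   interest.
#' @param signature list with character vectors \code{up} and \code{down}.
#' @param min_fold minimum linear fold in the anticipated direction,
#'   >= 1 (default 1).
#' @param denominator \code{"present"} (default) or \code{"all"}.
#' @return a \linkS4class{ConcordanceResult}.
#' @export
signatureConcordance <- function(table, signature, min_fold = 1,
                                 denominator = c("present", "all")) {
  denominator <- match.arg(denominator)
  validateDETable(table)
  validateSignature(signature)
  if (!is.numeric(min_fold) || min_fold < 1)
    stop("min_fold must be a linear fold >= 1")
  if (is.null(table$expressed)) table$expressed <- TRUE

  genes_uc <- toupper(table$gene)
  th <- log2(min_fold)
  verdict_one <- function(gs, dir) {
    if (!length(gs)) return(NULL)
    i <- match(toupper(gs), genes_uc)
    present <- !is.na(i)
    expressed <- ifelse(present, table$expressed[i], FALSE)
    lfc <- ifelse(present, table$log2fc[i], NA_real_)
    conc <- present & expressed &
      (if (dir == "up") lfc > th else lfc < -th)
    conc[is.na(conc)] <- FALSE
    data.frame(gene = gs, direction = dir, present = present,
      expressed = expressed, log2fc = lfc, concordant = conc,
      stringsAsFactors = FALSE)
  }
  verdicts <- rbind(verdict_one(signature$up, "up"),
                    verdict_one(signature$down, "down"))
  rownames(verdicts) <- NULL

  n_present <- if (denominator == "present") sum(verdicts$present)
    else nrow(verdicts)
  n_conc <- sum(verdicts$concordant)
  if (n_present == 0L)
    stop("no signature genes present in the table")
  new("ConcordanceResult",
    nSignaturePresent = as.numeric(n_present),
    nConcordant = as.numeric(n_conc),
    fractionPct = 100 * n_conc / n_present,
    verdicts = verdicts, minFold = min_fold, denominator = denominator)
}

#' @rdname ConcordanceResult-class
#' @export
setMethod("concordanceFractionPct", "ConcordanceResult",
  function(x) x@fractionPct)

#' @rdname ConcordanceResult-class
#' @export
setMethod("geneVerdicts", "ConcordanceResult", function(x) x@verdicts)
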