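#' Collapse paired cells into clonotypes
#'
#' Cells are partitioned by equality of their paired-chain clonotype key: two
#' cells belong to the same clonotype iff their alpha components are equal
#' AND their beta components are equal. The key is built from the CDR3 at the
#' chosen sequence level, optionally together with the V and J gene calls of
#' both chains (the default, the strictest interpretation and the 10x
#' convention).
#'
#' @param cells a \linkS4class{PairedCellSet}, or its cell data.frame. All
#'   cells must share one \code{sample_id}; use [callClonotypesBySample()]
#'   for multi-sample input.
#' @param key_level \code{"nt"} (CDR3 nucleotide, default) or \code{"aa"}
#'   (CDR3 amino acid).
#' @param include_vj include V/J gene calls in the key (default TRUE).
#' @return a \linkS4class{Repertoire}, or \code{NULL} (the explicit empty
#'   marker) when \code{cells} is empty.
#' @export
callClonotypes <- function(cells, key_level = c("nt", "aa"),
                           include_vj = TRUE) {
  key_level <- match.arg(key_level)
  df <- if (is(cells, "PairedCellSet")) pairedCells(cells) else cells
  stopifnot(is.data.frame(df))
  if (nrow(df) == 0L) return(NULL)
  sid <- unique(df$sample_id)
  if (length(sid) != 1L)
    stop("cells span ", length(sid),
      " samples; callClonotypes expects one (see callClonotypesBySample)")

  key <- clonotypeKey(df, key_level, include_vj)
  o <- order(key, df$cell_barcode, method = "radix")
  df <- df[o, , drop = FALSE]
  key <- key[o]
  first <- !duplicated(key)
  rep_rows <- df[first, , drop = FALSE]
  sizes <- as.integer(table(key)[key[first]])
  members <- split(df$cell_barcode, factor(key, levels = key[first]))

  # deterministic clonotype ids: by descending size, ties by key string
  ord <- order(-sizes, key[first], method = "radix")
  rep_rows <- rep_rows[ord, , drop = FALSE]
  sizes <- sizes[ord]
  members <- unname(members[ord])
  ct <- data.frame(
    clonotype_id = sprintf("clonotype%03d", seq_along(sizes)),
    key = key[first][ord], size = sizes,
    alpha_v = rep_rows$alpha_v, alpha_j = rep_rows$alpha_j,
    alpha_cdr3_nt = rep_rows$alpha_cdr3_nt,
    alpha_cdr3_aa = rep_rows$alpha_cdr3_aa,
    beta_v = rep_rows$beta_v, beta_j = rep_rows$beta_j,
    beta_cdr3_nt = rep_rows$beta_cdr3_nt,
    beta_cdr3_aa = rep_rows$beta_cdr3_aa,
    stringsAsFactors = FALSE)
  rownames(ct) <- NULL
  new("Repertoire", sampleID = sid,
    tissue = as.character(df$tissue[1]),
    clonotypes = ct, members = members,
    keyLevel = key_level, includeVJ = include_vj)
}

#' @rdname callClonotypes
#' @return for \code{callClonotypesBySample}: a named list of
#'   \linkS4class{Repertoire} objects, one per sample (empty samples are
#'   omitted).
#' @export
callClonotypesBySample <- function(cells, key_level = c("nt", "aa"),
                                   include_vj = TRUE) {
  key_level <- match.arg(key_level)
  df <- if (is(cells, "PairedCellSet")) pairedCells(cells) else cells
  sids <- sort(unique(df$sample_id))
  reps <- lapply(sids, function(s)
    callClonotypes(df[df$sample_id == s, , drop = FALSE],
      key_level, include_vj))
  names(reps) <- sids
  reps[!vapply(reps, is.null, logical(1))]
}

# Build the paired clonotype key for each cell. Alpha and beta components
# are kept separable so equal keys mean equal alpha AND equal beta.
clonotypeKey <- function(df, key_level, include_vj) {
  seq_a <- if (key_level == "nt") df$alpha_cdr3_nt else df$alpha_cdr3_aa
  seq_b <- if (key_level == "nt") df$beta_cdr3_nt else df$beta_cdr3_aa
  a <- if (include_vj) paste(df$alpha_v, df$alpha_j, seq_a, sep = ".")
       else seq_a
  b <- if (include_vj) paste(df$beta_v, df$beta_j, seq_b, sep = ".")
       else seq_b
  paste0("a:", a, "|b:", b)
}

#' @rdname Repertoire-class
#' @export
setMethod("sampleID", "Repertoire", function(x) x@sampleID)

#' @rdname Repertoire-class
#' @export
setMethod("tissueLabel", "Repertoire", function(x) x@tissue)

#' @rdname Repertoire-class
#' @export
setMethod("nCells", "Repertoire", function(x) sum(x@clonotypes$size))

#' @rdname Repertoire-class
#' @export
setMethod("nClonotypes", "Repertoire", function(x) nrow(x@clonotypes))

#' @rdname Repertoire-class
#' @export
setMethod("clonotypeSizes", "Repertoire",
  function(x) as.numeric(x@clonotypes$size))

#' @rdname Repertoire-class
#' @export
setMethod("clonotypeKeys", "Repertoire", function(x) x@clonotypes$key)

#' @rdname Repertoire-class
#' @export
setMethod("clonotypeTable", "Repertoire", function(x) x@clonotypes)

#' @rdname Repertoire-class
#' @export
keyConfig <- function(x) {
  stopifnot(is(x, "Repertoire"))
  list(key_level = x@keyLevel, include_vj = x@includeVJ)
}

#' @rdname Repertoire-class
#' @export
clonotypeMembers <- function(x) {
  stopifnot(is(x, "Repertoire"))
  x@members
}
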