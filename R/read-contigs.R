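.TENX_COLS <- c("barcode", "chain", "cdr3", "cdr3_nt", "v_gene", "j_gene",
  "productive", "umis", "reads")
.AIRR_COLS <- c("cell_id", "locus", "junction", "junction_aa", "v_call",
  "j_call", "productive", "duplicate_count")

.CONTIG_COLS <- c("cell_barcode", "sample_id", "tissue", "locus", "cdr3_nt",
  "cdr3_aa", "v_gene", "j_gene", "productive", "umi_count", "read_count")

#' Read a single-cell V(D)J contig table
#'
#' Reads assembled contig annotations in either the 10x Genomics
#' \code{filtered_contig_annotations.csv} dialect or the AIRR Rearrangement
#' TSV dialect, returning one record per TRA/TRB contig. Rows from other loci
#' (IGH, IGK, TRG, ...) and rows with a missing cell barcode are dropped and
#' counted in the parse report attached to the result. Barcode suffixes such
#' as \code{"-1"} are stripped. Sample identity comes from a \code{sample_id}
#' column if present or from the \code{sample_id} argument, never from the
#' barcode.
#'
#' @param path path to the contig table.
#' @param dialect \code{"tenx"} (CSV; columns barcode, chain, cdr3, cdr3_nt,
#'   v_gene, j_gene, productive, umis, reads) or \code{"airr"} (TSV; columns
#'   cell_id, locus, junction, junction_aa, v_call, j_call, productive,
#'   duplicate_count).
#' @param sample_id sample label applied when the file has no
#'   \code{sample_id} column (default \code{"sample1"}); overrides the file's
#'   column when given explicitly.
#' @param tissue tissue label, same precedence rules as \code{sample_id}.
#' @return a data.frame of contig records (columns \code{cell_barcode},
#'   \code{sample_id}, \code{tissue}, \code{locus}, \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{v_gene}, \code{j_gene}, \code{productive},
#'   \code{umi_count}, \code{read_count}) with a \code{parse_report}
#'   attribute (see [filterReport()]).
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' df <- data.frame(barcode = c("AAA-1", "AAA-1"), chain = c("TRA", "TRB"),
#'   cdr3 = c("CAVF", "CASF"), cdr3_nt = c("TGTGCCGTGTTT", "TGTGCCAGCTTT"),
#'   v_gene = c("TRAV1", "TRBV1"), j_gene = c("TRAJ1", "TRBJ1"),
#'   productive = "True", umis = 5, reads = 100)
#' write.csv(df, tf, row.names = FALSE, quote = FALSE)
#' contigs <- readContigTable(tf, "tenx")
#' filterReport(contigs)$n_records
#' @export
readContigTable <- function(path, dialect = c("tenx", "airr"),
                            sample_id = NULL, tissue = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE,
    sep = if (dialect == "tenx") "," else "\t",
    colClasses = "character", check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (nrow(raw) == 0L) stop("empty contig table: ", path)

  need <- if (dialect == "tenx") .TENX_COLS else .AIRR_COLS
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("contig table is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "))

  if (dialect == "tenx") {
    df <- data.frame(
      cell_barcode = raw$barcode, locus = raw$chain,
      cdr3_nt = raw$cdr3_nt, cdr3_aa = raw$cdr3,
      v_gene = raw$v_gene, j_gene = raw$j_gene,
      productive_raw = raw$productive,
      umi_count = suppressWarnings(as.integer(raw$umis)),
      read_count = suppressWarnings(as.integer(raw$reads)),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      cell_barcode = raw$cell_id, locus = raw$locus,
      cdr3_nt = raw$junction, cdr3_aa = raw$junction_aa,
      v_gene = raw$v_call, j_gene = raw$j_call,
      productive_raw = raw$productive,
      umi_count = suppressWarnings(as.integer(raw$duplicate_count)),
      read_count = if ("consensus_count" %in% names(raw))
        suppressWarnings(as.integer(raw$consensus_count)) else 0L,
      stringsAsFactors = FALSE)
  }
  df$sample_id <- if (!is.null(sample_id)) sample_id
    else if ("sample_id" %in% names(raw)) raw$sample_id else "sample1"
  df$tissue <- if (!is.null(tissue)) tissue
    else if ("tissue" %in% names(raw)) raw$tissue else ""

  n_rows <- nrow(df)
  no_bc <- is.na(df$cell_barcode) | !nzchar(trimws(df$cell_barcode))
  bad_locus <- !df$locus %in% c("TRA", "TRB")
  keep <- !no_bc & !bad_locus
  df <- df[keep, , drop = FALSE]

  df$cell_barcode <- stripBarcodeSuffix(df$cell_barcode)
  df$productive <- parseProductive(df$productive_raw)
  df$productive_raw <- NULL
  df$umi_count[is.na(df$umi_count)] <- 0L
  df$read_count[is.na(df$read_count)] <- 0L
  if (any(df$productive & !nzchar(df$cdr3_nt)))
    stop("productive contig with empty CDR3 nucleotide sequence")

  df <- df[, .CONTIG_COLS]
  rownames(df) <- NULL
  report <- list(n_rows = n_rows, n_records = nrow(df),
    n_dropped_locus = sum(bad_locus & !no_bc),
    n_dropped_missing_barcode = sum(no_bc))
  if (report$n_dropped_locus > 0)
    message("readContigTable: dropped ", report$n_dropped_locus,
      " non-TRA/TRB contig(s)")
  attr(df, "parse_report") <- report
  df
}

#' Write contig records
#'
#' Serializes contig records (as returned by [readContigTable()] or
#' [simulateRepertoire()]) back to disk in either dialect, with fixed column
#' order and LF line endings so identical records give byte-identical files.
#'
#' @param contigs contig record data.frame.
#' @param path output path.
#' @param dialect \code{"tenx"} or \code{"airr"}.
#' @return the path, invisibly.
#' @export
writeContigTable <- function(contigs, path, dialect = c("tenx", "airr")) {
  dialect <- match.arg(dialect)
  if (dialect == "tenx") {
    out <- data.frame(
      barcode = paste0(contigs$cell_barcode, "-1"),
      chain = contigs$locus, cdr3 = contigs$cdr3_aa,
      cdr3_nt = contigs$cdr3_nt, v_gene = contigs$v_gene,
      j_gene = contigs$j_gene,
      productive = ifelse(contigs$productive, "True", "False"),
      umis = contigs$umi_count, reads = contigs$read_count,
      sample_id = contigs$sample_id, tissue = contigs$tissue,
      stringsAsFactors = FALSE)
    writeFlatTable(out, path, sep = ",")
  } else {
    out <- data.frame(
      cell_id = contigs$cell_barcode, locus = contigs$locus,
      junction = contigs$cdr3_nt, junction_aa = contigs$cdr3_aa,
      v_call = contigs$v_gene, j_call = contigs$j_gene,
      productive = ifelse(contigs$productive, "T", "F"),
      duplicate_count = contigs$umi_count,
      consensus_count = contigs$read_count,
      sample_id = contigs$sample_id, tissue = contigs$tissue,
      stringsAsFactors = FALSE)
    writeFlatTable(out, path, sep = "\t")
  }
  invisible(path)
}

#' Write a clonotype table
#'
#' One row per clonotype with sample, size and both chain descriptors --
#' the interchange format consumed by the clonality statistics stage.
#'
#' @param repertoires a \linkS4class{Repertoire} or list of them.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeClonotypeTable <- function(repertoires, path) {
  if (is(repertoires, "Repertoire")) repertoires <- list(repertoires)
  rows <- lapply(repertoires, function(r) {
    ct <- clonotypeTable(r)
    cbind(data.frame(sample_id = sampleID(r), tissue = tissueLabel(r),
      stringsAsFactors = FALSE), ct)
  })
  writeFlatTable(do.call(rbind, rows), path)
}

#' @rdname filterReport
#' @export
setMethod("filterReport", "PairedCellSet", function(x) x@report)

#' @rdname filterReport
#' @export
setMethod("filterReport", "data.frame", function(x) {
  rep <- attr(x, "parse_report")
  if (is.null(rep)) stop("no parse report attached to this data.frame")
  rep
})
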