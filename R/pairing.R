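#' Resolve cells to one productive alpha/beta chain pair
#'
#' Only cells carrying both a productive TCR-alpha and a productive TCR-beta
#' chain are retained; all other cells are dropped and counted. Cells with
#' more than one productive contig for a locus are resolved per
#' \code{policy}:
#' \describe{
#'   \item{\code{"dominant"} (default)}{keep the contig with the highest UMI
#'     count, ties broken by read count, then lexicographically by CDR3
#'     nucleotide sequence; the cell is counted once in
#'     \code{n_multi_chain_resolved}.}
#'   \item{\code{"drop-multi"}}{drop the cell entirely, counted in
#'     \code{n_dropped_multi}.}
#' }
#'
#' @param contigs contig record data.frame from [readContigTable()] or
#'   [simulateRepertoire()].
#' @param policy multi-chain resolution policy.
#' @return a \linkS4class{PairedCellSet}; its [filterReport()] carries
#'   \code{n_input_cells}, \code{n_retained}, \code{n_dropped_unpaired},
#'   \code{n_dropped_multi} and \code{n_multi_chain_resolved}.
#' @export
filterPairedProductive <- function(contigs,
                                   policy = c("dominant", "drop-multi")) {
  policy <- match.arg(policy)
  stopifnot(is.data.frame(contigs))
  if (nrow(contigs) == 0L) {
    return(new("PairedCellSet",
      cells = emptyPairedCells(),
      report = list(n_input_cells = 0L, n_retained = 0L,
        n_dropped_unpaired = 0L, n_dropped_multi = 0L,
        n_multi_chain_resolved = 0L)))
  }

  prod <- contigs[contigs$productive & contigs$locus %in% c("TRA", "TRB"), ,
                  drop = FALSE]
  cell_key_all <- unique(paste(contigs$sample_id, contigs$cell_barcode,
    sep = "\r"))
  n_input <- length(cell_key_all)

  # deterministic dominant-chain ordering: UMIs desc, reads desc, cdr3_nt asc
  ord <- order(prod$sample_id, prod$cell_barcode, prod$locus,
    -prod$umi_count, -prod$read_count, prod$cdr3_nt, method = "radix")
  prod <- prod[ord, , drop = FALSE]
  grp <- paste(prod$sample_id, prod$cell_barcode, prod$locus, sep = "\r")
  is_first <- !duplicated(grp)
  multi_cells <- unique(paste(prod$sample_id, prod$cell_barcode,
    sep = "\r")[duplicated(grp)])
  top <- prod[is_first, , drop = FALSE]

  cell_of <- paste(top$sample_id, top$cell_barcode, sep = "\r")
  a <- top[top$locus == "TRA", , drop = FALSE]
  b <- top[top$locus == "TRB", , drop = FALSE]
  a_cell <- cell_of[top$locus == "TRA"]
  b_cell <- cell_of[top$locus == "TRB"]
  paired_cells <- intersect(a_cell, b_cell)

  if (policy == "drop-multi") {
    n_dropped_multi <- sum(paired_cells %in% multi_cells)
    paired_cells <- setdiff(paired_cells, multi_cells)
    n_resolved <- 0L
  } else {
    n_dropped_multi <- 0L
    n_resolved <- sum(paired_cells %in% multi_cells)
  }

  ai <- match(paired_cells, a_cell)
  bi <- match(paired_cells, b_cell)
  cells <- data.frame(
    cell_barcode = a$cell_barcode[ai], sample_id = a$sample_id[ai],
    tissue = a$tissue[ai],
    alpha_v = a$v_gene[ai], alpha_j = a$j_gene[ai],
    alpha_cdr3_nt = a$cdr3_nt[ai], alpha_cdr3_aa = a$cdr3_aa[ai],
    beta_v = b$v_gene[bi], beta_j = b$j_gene[bi],
    beta_cdr3_nt = b$cdr3_nt[bi], beta_cdr3_aa = b$cdr3_aa[bi],
    stringsAsFactors = FALSE)
  cells <- cells[order(cells$sample_id, cells$cell_barcode,
    method = "radix"), , drop = FALSE]
  rownames(cells) <- NULL

  report <- list(
    n_input_cells = n_input,
    n_retained = nrow(cells),
    n_dropped_unpaired = n_input - nrow(cells) - n_dropped_multi,
    n_dropped_multi = n_dropped_multi,
    n_multi_chain_resolved = n_resolved)
  new("PairedCellSet", cells = cells, report = report)
}

emptyPairedCells <- function() {
  df <- as.data.frame(setNames(rep(list(character()), length(.PAIRED_COLS)),
    .PAIRED_COLS), stringsAsFactors = FALSE)
  df
}

#' @describeIn PairedCellSet-class the per-cell chain table.
#' @param x,object a \code{PairedCellSet}.
#' @export
pairedCells <- function(x) {
  stopifnot(is(x, "PairedCellSet"))
  x@cells
}
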