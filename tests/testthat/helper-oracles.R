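# Independent brute-force oracles, kept deliberately naive.

# Gini by the literal double loop over all pairs.
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# Expansion ratio by pair enumeration: a cell is "expanded" iff some other
# cell shares its clonotype key.
expansion_bruteforce <- function(cell_keys) {
  expanded <- vapply(seq_along(cell_keys), function(i)
    any(cell_keys[-i] == cell_keys[i]), logical(1))
  mean(expanded)
}

# Minimal in-memory contig row constructor for hand-built fixtures.
contig_row <- function(barcode, locus, cdr3_nt, v = paste0(substr(locus, 1, 3), "V1"),
                       j = paste0(substr(locus, 1, 3), "J1"),
                       productive = TRUE, umis = 5L, reads = 100L,
                       sample_id = "s1", tissue = "aorta") {
  data.frame(cell_barcode = barcode, sample_id = sample_id, tissue = tissue,
    locus = locus, cdr3_nt = cdr3_nt,
    cdr3_aa = paste0("C", substr(cdr3_nt, 1, 3), "F"),
    v_gene = v, j_gene = j, productive = productive,
    umi_count = as.integer(umis), read_count = as.integer(reads),
    stringsAsFactors = FALSE)
}

# A paired cell (one TRA + one TRB contig) with chosen CDR3s.
paired_contigs <- function(barcode, a_nt, b_nt, sample_id = "s1", ...) {
  rbind(
    contig_row(barcode, "TRA", a_nt, sample_id = sample_id, ...),
    contig_row(barcode, "TRB", b_nt, sample_id = sample_id, ...))
}
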