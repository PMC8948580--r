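## Synthetic-data generators. Each generator draws from its own seeded RNG
## stream (withSeed), writes plain-text files with fixed column order and LF
## endings, and returns a ground-truth record from which every downstream
## statistic can be computed in closed form.

.TRAV <- paste0("TRAV", c(1, 3, 4, 6, 7, 9, 12, 14, 16, 19))
.TRAJ <- paste0("TRAJ", c(2, 9, 15, 21, 23, 26, 31, 33, 37, 40))
.TRBV <- paste0("TRBV", c(1, 2, 3, 4, 5, 12, 13, 16, 19, 20))
.TRBJ <- paste0("TRBJ", c("1-1", "1-2", "1-4", "2-1", "2-3", "2-5", "2-7"))

# the 61 sense codons (no stops), so productive CDR3s never translate to "*"
.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- apply(expand.grid(b, b, b), 1, paste0, collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

# CDR3 nucleotide string: fixed TGT...TTT boundary (Cys...Phe), random sense
# codons in between, total length a multiple of 3 within len_range
randomCDR3nt <- function(len_range) {
  lens <- seq(len_range[1], len_range[2], by = 3)
  L <- if (length(lens) == 1L) lens else sample(lens, 1)
  mid <- paste0(sample(.SENSE_CODONS, L / 3 - 2, replace = TRUE),
    collapse = "")
  paste0("TGT", mid, "TTT")
}

translateCDR3 <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nt)))
}

# one clonotype's paired-chain descriptors
randomClonotypeChains <- function(len_range) {
  a_nt <- randomCDR3nt(len_range)
  b_nt <- randomCDR3nt(len_range)
  data.frame(
    alpha_v = sample(.TRAV, 1), alpha_j = sample(.TRAJ, 1),
    alpha_cdr3_nt = a_nt, alpha_cdr3_aa = translateCDR3(a_nt),
    beta_v = sample(.TRBV, 1), beta_j = sample(.TRBJ, 1),
    beta_cdr3_nt = b_nt, beta_cdr3_aa = translateCDR3(b_nt),
    stringsAsFactors = FALSE)
}

#' Simulate a single-cell paired-chain TCR repertoire
#'
#' Generates a contig table (one productive TRA and one productive TRB contig
#' per cell) whose clone-size distribution follows the chosen abundance
#' model, plus a ground-truth record of the planted clone sizes and keys.
#' Optional decoy cells exercise the pairing filter: unpaired cells carry
#' only one chain, multi-chain cells carry an extra lower-UMI beta contig.
#' Clonotype uniqueness is guaranteed by rejection sampling at the amino-acid
#' CDR3-pair level, which implies uniqueness under every key configuration.
#' Fully deterministic given \code{seed}.
#'
#' @param n_cells number of paired cells (default 200).
#' @param abundance clone-size model: \code{"dirichlet"} (symmetric Dirichlet
#'   clone frequencies, then multinomial sampling of cells),
#'   \code{"powerlaw"} (frequencies proportional to rank^-exponent), or
#'   \code{"explicit"} (use \code{sizes} as given).
#' @param n_clonotypes number of candidate clonotypes for the dirichlet /
#'   powerlaw models (default \code{ceiling(n_cells / 2)}).
#' @param concentration symmetric Dirichlet concentration (large = even
#'   repertoire, Gini near 0; small = skewed).
#' @param exponent power-law exponent (default 2).
#' @param sizes explicit clone sizes; must sum to \code{n_cells}.
#' @param planted_keys optional data.frame of chain descriptors (columns
#'   \code{alpha_v} ... \code{beta_cdr3_aa}, e.g. rows of another truth
#'   record's \code{clonotypes}) forced to appear as this sample's first
#'   clonotypes -- used to plant shared clonotypes across samples.
#' @param fraction_unpaired fraction (of \code{n_cells}) of extra decoy cells
#'   carrying only one productive chain.
#' @param fraction_multichain fraction of paired cells that also carry a
#'   second, lower-UMI productive beta contig.
#' @param cdr3_length_range CDR3 nucleotide length bounds, multiples of 3
#'   (default 30--48 nt).
#' @param sample_id,tissue sample labels.
#' @param seed RNG seed (required for reproducibility; default 1).
#' @param dir if given, writes \code{<sample_id>_tenx.csv},
#'   \code{<sample_id>_airr.tsv} and \code{<sample_id>_truth.json} there.
#' @return list with \code{contigs} (contig record data.frame), \code{truth}
#'   (list: \code{sizes} sorted descending, \code{clonotypes} with keys and
#'   chain descriptors, \code{n_cells}, \code{n_unpaired},
#'   \code{n_multichain}, \code{expansion_ratio}, \code{gini}) and
#'   \code{paths} (when \code{dir} is given).
#' @export
simulateRepertoire <- function(n_cells = 200,
                               abundance = c("dirichlet", "powerlaw",
                                             "explicit"),
                               n_clonotypes = NULL, concentration = 1,
                               exponent = 2, sizes = NULL,
                               planted_keys = NULL,
                               fraction_unpaired = 0,
                               fraction_multichain = 0,
                               cdr3_length_range = c(30, 48),
                               sample_id = "S1", tissue = "aorta",
                               seed = 1, dir = NULL) {
  abundance <- match.arg(abundance)
  if (abundance == "explicit") {
    if (is.null(sizes)) stop("abundance = 'explicit' requires sizes")
    if (any(sizes < 1) || any(sizes != round(sizes)))
      stop("explicit sizes must be positive integers")
    if (sum(sizes) != n_cells)
      stop("explicit sizes must sum to n_cells (", sum(sizes), " != ",
        n_cells, ")")
  }
  if (any(cdr3_length_range %% 3 != 0) || cdr3_length_range[1] < 9)
    stop("cdr3_length_range must be multiples of 3, >= 9 nt")

  withSeed(seed, {
    clone_sizes <- switch(abundance,
      explicit = as.integer(sizes),
      dirichlet = {
        K <- if (is.null(n_clonotypes)) max(2L, ceiling(n_cells / 2))
          else n_clonotypes
        w <- stats::rgamma(K, shape = concentration, rate = 1)
        cnt <- as.integer(stats::rmultinom(1, n_cells, w / sum(w)))
        cnt[cnt > 0]
      },
      powerlaw = {
        K <- if (is.null(n_clonotypes)) max(2L, ceiling(n_cells / 2))
          else n_clonotypes
        p <- seq_len(K)^(-exponent)
        cnt <- as.integer(stats::rmultinom(1, n_cells, p / sum(p)))
        cnt[cnt > 0]
      })
    clone_sizes <- sort(clone_sizes, decreasing = TRUE)
    K <- length(clone_sizes)

    n_planted <- if (is.null(planted_keys)) 0L else nrow(planted_keys)
    if (n_planted > K)
      stop("more planted keys (", n_planted, ") than clonotypes (", K, ")")

    chain_cols <- c("alpha_v", "alpha_j", "alpha_cdr3_nt", "alpha_cdr3_aa",
      "beta_v", "beta_j", "beta_cdr3_nt", "beta_cdr3_aa")
    chains <- if (n_planted > 0)
      planted_keys[, chain_cols, drop = FALSE] else NULL
    seen_aa <- if (n_planted > 0)
      paste(chains$alpha_cdr3_aa, chains$beta_cdr3_aa) else character()
    while (nrow(chains %||% data.frame()) < K) {
      cand <- randomClonotypeChains(cdr3_length_range)
      aa <- paste(cand$alpha_cdr3_aa, cand$beta_cdr3_aa)
      if (aa %in% seen_aa) next
      seen_aa <- c(seen_aa, aa)
      chains <- rbind(chains, cand)
    }
    rownames(chains) <- NULL

    clone_of_cell <- rep(seq_len(K), clone_sizes)
    n <- length(clone_of_cell)
    barcodes <- sprintf("BC%06d", seq_len(n))
    umi_a <- sample(5:60, n, replace = TRUE)
    umi_b <- sample(5:60, n, replace = TRUE)

    contig_row <- function(bc, locus, v, j, nt, aa, umi) data.frame(
      cell_barcode = bc, sample_id = sample_id, tissue = tissue,
      locus = locus, cdr3_nt = nt, cdr3_aa = aa, v_gene = v, j_gene = j,
      productive = TRUE, umi_count = umi, read_count = umi * 23L,
      stringsAsFactors = FALSE)

    ci <- chains[clone_of_cell, , drop = FALSE]
    contigs <- rbind(
      contig_row(barcodes, "TRA", ci$alpha_v, ci$alpha_j,
        ci$alpha_cdr3_nt, ci$alpha_cdr3_aa, umi_a),
      contig_row(barcodes, "TRB", ci$beta_v, ci$beta_j,
        ci$beta_cdr3_nt, ci$beta_cdr3_aa, umi_b))

    # decoy: extra productive beta contig with strictly lower UMI, so the
    # dominant-chain policy keeps the intended chain
    n_multi <- as.integer(round(fraction_multichain * n))
    multi_bcs <- character()
    if (n_multi > 0) {
      pick <- sort(sample(n, n_multi))
      multi_bcs <- barcodes[pick]
      extra <- do.call(rbind, lapply(pick, function(i) {
        ch <- randomClonotypeChains(cdr3_length_range)
        contig_row(barcodes[i], "TRB", ch$beta_v, ch$beta_j,
          ch$beta_cdr3_nt, ch$beta_cdr3_aa, sample(1:4, 1))
      }))
      contigs <- rbind(contigs, extra)
    }

    # decoy: cells with a single productive chain (alternating TRA / TRB)
    n_unpaired <- as.integer(round(fraction_unpaired * n))
    if (n_unpaired > 0) {
      up <- do.call(rbind, lapply(seq_len(n_unpaired), function(i) {
        ch <- randomClonotypeChains(cdr3_length_range)
        bc <- sprintf("UP%06d", i)
        if (i %% 2 == 1)
          contig_row(bc, "TRA", ch$alpha_v, ch$alpha_j,
            ch$alpha_cdr3_nt, ch$alpha_cdr3_aa, sample(5:60, 1))
        else
          contig_row(bc, "TRB", ch$beta_v, ch$beta_j,
            ch$beta_cdr3_nt, ch$beta_cdr3_aa, sample(5:60, 1))
      }))
      contigs <- rbind(contigs, up)
    }
    contigs <- contigs[order(contigs$cell_barcode, contigs$locus,
      -contigs$umi_count, method = "radix"), , drop = FALSE]
    rownames(contigs) <- NULL

    ct_truth <- cbind(
      data.frame(key = clonotypeKey(chains, "nt", TRUE),
        size = clone_sizes, stringsAsFactors = FALSE),
      chains)
    truth <- list(sample_id = sample_id, tissue = tissue,
      abundance = abundance, n_cells = n, sizes = clone_sizes,
      n_clonotypes = K, clonotypes = ct_truth,
      n_planted = n_planted,
      planted_keys = if (n_planted > 0) ct_truth$key[seq_len(n_planted)]
        else character(),
      n_unpaired = n_unpaired, n_multichain = n_multi,
      multichain_barcodes = multi_bcs,
      expansion_ratio = expansionRatio(clone_sizes),
      gini = giniCoefficient(clone_sizes), seed = seed)

    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(
        tenx = file.path(dir, paste0(sample_id, "_tenx.csv")),
        airr = file.path(dir, paste0(sample_id, "_airr.tsv")),
        truth = file.path(dir, paste0(sample_id, "_truth.json")))
      writeContigTable(contigs, paths$tenx, "tenx")
      writeContigTable(contigs, paths$airr, "airr")
      writeJSONReport(truth, paths$truth)
    }
    list(contigs = contigs, truth = truth, paths = paths)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a parabiosis cohort with known true recruitment
#'
#' Per mouse, blood chimerism is drawn from a Gaussian truncated to (0, 100];
#' tissue chimerism is blood times the true recruitment fraction plus
#' Gaussian noise (in percentage points), floored at 0. Defaults mirror the
#' worked experimental conditions: blood chimerism around 35.7%, steady-state
#' count 20, post-injury count 5375.
#'
#' @param n_mice cohort size (default 5).
#' @param true_recruitment_fraction planted recruitment fraction in [0, 1]
#'   (default 0.786).
#' @param blood_chimerism_mean,blood_chimerism_sd blood chimerism Gaussian
#'   parameters, percent (defaults 35.7 and 5).
#' @param tissue_noise_sd sd of the tissue-chimerism measurement noise, in
#'   percentage points (default 5).
#' @param steady_state_count,post_injury_count Treg counts (defaults 20 and
#'   5375).
#' @param seed RNG seed.
#' @param dir if given, writes \code{cohort.csv} and \code{truth.json}.
#' @return list with \code{cohort} (data.frame: mouse_id,
#'   blood_chimerism_pct, tissue_chimerism_pct), the two counts, \code{truth}
#'   and \code{paths}.
#' @export
simulateParabiosis <- function(n_mice = 5,
                               true_recruitment_fraction = 0.786,
                               blood_chimerism_mean = 35.7,
                               blood_chimerism_sd = 5,
                               tissue_noise_sd = 5,
                               steady_state_count = 20,
                               post_injury_count = 5375,
                               seed = 1, dir = NULL) {
  stopifnot(n_mice >= 1,
    true_recruitment_fraction >= 0, true_recruitment_fraction <= 1)
  withSeed(seed, {
    blood <- numeric(0)
    while (length(blood) < n_mice) {
      cand <- stats::rnorm(n_mice, blood_chimerism_mean, blood_chimerism_sd)
      blood <- c(blood, cand[cand > 0 & cand <= 100])
    }
    blood <- blood[seq_len(n_mice)]
    tissue <- pmax(0, blood * true_recruitment_fraction +
      stats::rnorm(n_mice, 0, tissue_noise_sd))
    cohort <- data.frame(mouse_id = sprintf("m%02d", seq_len(n_mice)),
      blood_chimerism_pct = blood, tissue_chimerism_pct = tissue,
      stringsAsFactors = FALSE)
    truth <- list(true_recruitment_fraction = true_recruitment_fraction,
      true_recruitment_pct = 100 * true_recruitment_fraction,
      n_mice = n_mice, tissue_noise_sd = tissue_noise_sd,
      blood_chimerism_mean = blood_chimerism_mean,
      blood_chimerism_sd = blood_chimerism_sd,
      steady_state_count = steady_state_count,
      post_injury_count = post_injury_count, seed = seed)
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(cohort = file.path(dir, "cohort.csv"),
        truth = file.path(dir, "truth.json"))
      writeFlatTable(cohort, paths$cohort, sep = ",")
      writeJSONReport(truth, paths$truth)
    }
    list(cohort = cohort, steady_state_count = steady_state_count,
      post_injury_count = post_injury_count, truth = truth, paths = paths)
  })
}

#' Simulate photoconverted-cell fractions across organs
#'
#' Organ fractions are the nondraining-reference fraction times an
#' organ-specific enrichment factor, plus optional Gaussian noise (floored at
#' 0). In noise-free mode the migration ratios recover the planted
#' enrichments exactly.
#'
#' @param reference_fraction photoconverted fraction in the nondraining
#'   reference lymph node, > 0 (default 0.01).
#' @param enrichments named positive factors, one per non-reference organ
#'   (default \code{c(PaLN = 3, aorta = 5)}).
#' @param noise_sd Gaussian noise sd on the organ fractions (default 0).
#' @param reference_organ name of the reference organ (default "ALN").
#' @param seed RNG seed.
#' @param dir if given, writes \code{photoconversion.csv} and
#'   \code{truth.json}.
#' @return list with \code{samples} (data.frame: organ, phc_fraction,
#'   is_nondraining_reference), \code{truth} and \code{paths}.
#' @export
simulatePhotoconversion <- function(reference_fraction = 0.01,
                                    enrichments = c(PaLN = 3, aorta = 5),
                                    noise_sd = 0, reference_organ = "ALN",
                                    seed = 1, dir = NULL) {
  if (reference_fraction <= 0) stop("reference_fraction must be > 0")
  if (any(enrichments <= 0)) stop("enrichment factors must be positive")
  if (is.null(names(enrichments)) || any(!nzchar(names(enrichments))))
    names(enrichments) <- paste0("organ", seq_along(enrichments))
  withSeed(seed, {
    frac <- pmax(0, reference_fraction * enrichments +
      stats::rnorm(length(enrichments), 0, noise_sd))
    samples <- data.frame(
      organ = c(reference_organ, names(enrichments)),
      phc_fraction = c(reference_fraction, unname(frac)),
      is_nondraining_reference = c(TRUE, rep(FALSE, length(enrichments))),
      stringsAsFactors = FALSE)
    truth <- list(reference_fraction = reference_fraction,
      enrichments = as.list(enrichments), noise_sd = noise_sd, seed = seed)
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(samples = file.path(dir, "photoconversion.csv"),
        truth = file.path(dir, "truth.json"))
      writeFlatTable(samples, paths$samples, sep = ",")
      writeJSONReport(truth, paths$truth)
    }
    list(samples = samples, truth = truth, paths = paths)
  })
}

#' Simulate a differential-expression table with a planted signature
#'
#' Draws a DE table of background genes (log2 fold changes centered at 0)
#' and signature genes planted concordant with a chosen probability:
#' concordant genes get a correct-direction effect, discordant genes the
#' flipped sign. In noise-free mode the concordant fraction is recovered
#' exactly.
#'
#' @param n_genes total genes (default 2000).
#' @param n_signature signature genes, <= n_genes (default 100).
#' @param planted_concordant_fraction probability a signature gene is
#'   concordant (default 0.74); the planted count is
#'   \code{round(fraction * n_signature)}.
#' @param effect_size_log2 magnitude of true signature fold changes, log2
#'   units (default 3).
#' @param noise_sd_log2 Gaussian sd added to every log2 fold change
#'   (default 0).
#' @param seed RNG seed.
#' @param dir if given, writes \code{de.tsv}, \code{signature.tsv} and
#'   \code{truth.json}.
#' @return list with \code{de} (data.frame: gene, log2fc, expressed),
#'   \code{signature} (list up/down), \code{truth} (per-gene labels and the
#'   planted concordant count) and \code{paths}.
#' @export
simulateDETable <- function(n_genes = 2000, n_signature = 100,
                            planted_concordant_fraction = 0.74,
                            effect_size_log2 = 3, noise_sd_log2 = 0,
                            seed = 1, dir = NULL) {
  if (n_signature > n_genes) stop("n_signature cannot exceed n_genes")
  if (planted_concordant_fraction < 0 || planted_concordant_fraction > 1)
    stop("planted_concordant_fraction must lie in [0, 1]")
  withSeed(seed, {
    genes <- sprintf("Gene%05d", seq_len(n_genes))
    sig_idx <- sort(sample(n_genes, n_signature))
    direction <- sample(c("up", "down"), n_signature, replace = TRUE)
    n_conc <- round(planted_concordant_fraction * n_signature)
    concordant <- rep(FALSE, n_signature)
    concordant[sample(n_signature, n_conc)] <- TRUE

    lfc <- stats::rnorm(n_genes, 0, noise_sd_log2)
    sgn <- ifelse(direction == "up", 1, -1) * ifelse(concordant, 1, -1)
    lfc[sig_idx] <- sgn * effect_size_log2 +
      stats::rnorm(n_signature, 0, noise_sd_log2)

    de <- data.frame(gene = genes, log2fc = lfc, expressed = TRUE,
      stringsAsFactors = FALSE)
    signature <- list(up = genes[sig_idx][direction == "up"],
      down = genes[sig_idx][direction == "down"])
    truth <- list(n_genes = n_genes, n_signature = n_signature,
      planted_concordant_fraction = planted_concordant_fraction,
      n_concordant = n_conc,
      labels = data.frame(gene = genes[sig_idx], direction = direction,
        concordant = concordant, stringsAsFactors = FALSE),
      effect_size_log2 = effect_size_log2,
      noise_sd_log2 = noise_sd_log2, seed = seed)
    paths <- NULL
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(de = file.path(dir, "de.tsv"),
        signature = file.path(dir, "signature.tsv"),
        truth = file.path(dir, "truth.json"))
      writeFlatTable(de, paths$de)
      sig_df <- data.frame(
        gene = c(signature$up, signature$down),
        direction = c(rep("up", length(signature$up)),
          rep("down", length(signature$down))),
        stringsAsFactors = FALSE)
      writeFlatTable(sig_df, paths$signature)
      writeJSONReport(truth, paths$truth)
    }
    list(de = de, signature = signature, truth = truth, paths = paths)
  })
}
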