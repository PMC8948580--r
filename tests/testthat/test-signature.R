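de_fixture <- function() data.frame(
  gene = c("Foxp3", "Il2ra", "Ctla4", "Sell", "Tff1"),
  log2fc = c(2.0, -1.5, 0.5, -3.0, 4.0),
  expressed = TRUE, stringsAsFactors = FALSE)

test_that("fold-change counting uses a strict linear threshold on expressed genes", {
  de <- data.frame(gene = c("A", "B", "C"), log2fc = c(2.0, -1.5, 0.5))
  expect_equal(countFoldChangeGenes(de, 2, "both"), 2L)
  expect_equal(countFoldChangeGenes(de, 2, "up"), 1L)
  expect_equal(countFoldChangeGenes(de, 2, "down"), 1L)
  # up + down partition both
  de2 <- de_fixture()
  expect_equal(countFoldChangeGenes(de2, 2, "up") +
    countFoldChangeGenes(de2, 2, "down"),
    countFoldChangeGenes(de2, 2, "both"))
  # unexpressed genes never count
  de3 <- de_fixture(); de3$expressed[de3$gene == "Tff1"] <- FALSE
  expect_equal(countFoldChangeGenes(de3, 2, "up"),
    countFoldChangeGenes(de2, 2, "up") - 1L)
  expect_error(countFoldChangeGenes(de, 1), "> 1")
})

test_that("planted up/down counts are recovered from a constructed table", {
  lfc <- c(runif(62, 1.5, 5), runif(85, -5, -1.5), runif(200, -0.9, 0.9))
  de <- data.frame(gene = sprintf("g%03d", seq_along(lfc)), log2fc = lfc)
  expect_equal(countFoldChangeGenes(de, 2, "up"), 62L)
  expect_equal(countFoldChangeGenes(de, 2, "down"), 85L)
})

test_that("concordance follows direction, threshold and presence rules", {
  sig <- list(up = c("Foxp3", "Ctla4", "Tff1"), down = c("Sell", "Il2ra"))
  res <- signatureConcordance(de_fixture(), sig, min_fold = 1)
  # all five present; all concordant (every gene moves the anticipated way)
  expect_equal(res@nSignaturePresent, 5)
  expect_equal(concordanceFractionPct(res), 100)

  # direction flip counts as discordant
  sig_flip <- list(up = c("Foxp3", "Sell"), down = character())
  res2 <- signatureConcordance(de_fixture(), sig_flip)
  v <- geneVerdicts(res2)
  expect_false(v$concordant[v$gene == "Sell"])
  expect_equal(concordanceFractionPct(res2), 50)

  # raising min_fold is monotone non-increasing in concordant count
  sig_all <- list(up = c("Foxp3", "Ctla4", "Tff1"), down = c("Sell", "Il2ra"))
  n_prev <- Inf
  for (f in c(1, 1.5, 2, 4, 16)) {
    n <- signatureConcordance(de_fixture(), sig_all, min_fold = f)@nConcordant
    expect_lte(n, n_prev)
    n_prev <- n
  }

  # matching is case-insensitive; absent genes only count under "all"
  sig_case <- list(up = c("FOXP3", "NotInTable"), down = character())
  r_present <- signatureConcordance(de_fixture(), sig_case)
  expect_equal(r_present@nSignaturePresent, 1)
  expect_equal(concordanceFractionPct(r_present), 100)
  r_all <- signatureConcordance(de_fixture(), sig_case, denominator = "all")
  expect_equal(r_all@nSignaturePresent, 2)
  expect_equal(concordanceFractionPct(r_all), 50)

  expect_error(signatureConcordance(de_fixture(),
    list(up = character(), down = character())), "empty")
})

test_that("concordance is invariant to row order and non-signature genes", {
  sim <- simulateDETable(n_genes = 300, n_signature = 60,
    planted_concordant_fraction = 0.7, noise_sd_log2 = 0.4, seed = 71)
  base <- concordanceFractionPct(
    signatureConcordance(sim$de, sim$signature))
  shuffled <- sim$de[sample(nrow(sim$de)), ]
  expect_equal(concordanceFractionPct(
    signatureConcordance(shuffled, sim$signature)), base)
  extra <- rbind(sim$de, data.frame(gene = "ZzzDecoy", log2fc = 9,
    expressed = TRUE))
  expect_equal(concordanceFractionPct(
    signatureConcordance(extra, sim$signature)), base)
})

test_that("a table labelled by its own fold-change signs is 100% concordant", {
  set.seed(72)
  lfc <- round(rnorm(50, 0, 2), 3)
  lfc <- lfc[lfc != 0]
  de <- data.frame(gene = sprintf("g%02d", seq_along(lfc)), log2fc = lfc)
  sig <- list(up = de$gene[de$log2fc > 0], down = de$gene[de$log2fc < 0])
  expect_equal(concordanceFractionPct(
    signatureConcordance(de, sig, min_fold = 1)), 100)
})

test_that("planted concordance is recovered exactly in noise-free mode", {
  sim <- simulateDETable(n_genes = 1000, n_signature = 100,
    planted_concordant_fraction = 0.74, noise_sd_log2 = 0, seed = 73)
  res <- signatureConcordance(sim$de, sim$signature, min_fold = 1)
  expect_equal(concordanceFractionPct(res), 74)
  # full concordance when everything is planted concordant
  sim1 <- simulateDETable(n_genes = 200, n_signature = 40,
    planted_concordant_fraction = 1, noise_sd_log2 = 0, seed = 74)
  expect_equal(concordanceFractionPct(
    signatureConcordance(sim1$de, sim1$signature)), 100)
  # per-gene verdicts match the generator's labels
  v <- geneVerdicts(res)
  truth <- sim$truth$labels
  m <- match(truth$gene, v$gene)
  expect_equal(v$concordant[m], truth$concordant)
})

test_that("signature files round-trip through the readers", {
  sim <- simulateDETable(n_genes = 150, n_signature = 30,
    planted_concordant_fraction = 0.8, noise_sd_log2 = 0.3, seed = 75,
    dir = tempfile())
  de <- readDETable(sim$paths$de)
  sig <- readSignature(sim$paths$signature)
  expect_equal(de$gene, sim$de$gene)
  expect_equal(de$log2fc, sim$de$log2fc, tolerance = 1e-12)
  expect_setequal(sig$up, sim$signature$up)
  expect_setequal(sig$down, sim$signature$down)
  expect_equal(
    concordanceFractionPct(signatureConcordance(de, sig)),
    concordanceFractionPct(signatureConcordance(sim$de, sim$signature)))
})
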