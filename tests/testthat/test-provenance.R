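test_that("aorta-to-blood normalization reproduces the worked example", {
  expect_equal(roundHalfUp(normalizeRecruitment(35.7, 30.9), 1), 86.6)
  expect_equal(normalizeRecruitment(12.3, 12.3), 100)
  expect_equal(normalizeRecruitment(40, 0), 0)
  expect_error(normalizeRecruitment(0, 10), "> 0")
  # homogeneity: common scaling of blood and tissue cancels
  expect_equal(normalizeRecruitment(3 * 35.7, 3 * 30.9),
    normalizeRecruitment(35.7, 30.9))
})

test_that("values above 100% are flagged but never clipped", {
  expect_warning(r <- normalizeRecruitment(20, 25), "unclipped")
  expect_equal(r, 125)
})

test_that("the recruitment chain reproduces the printed count arithmetic", {
  est <- estimateRecruitment(mean_recruitment_pct = 78.6,
    steady_state_count = 20, post_injury_count = 5375)
  expect_equal(accumulatedCount(est), 5355)
  expect_equal(recruitedCount(est), 4209)
  d <- displayValues(est)
  expect_equal(d$recruited_fraction_of_total_pct, 78.3)
  # full-precision slot keeps the unrounded fraction
  expect_equal(recruitedFractionPct(est), 100 * 4209 / 5375)
})

test_that("a blood==tissue mouse yields 100% recruitment of the whole pool", {
  cohort <- data.frame(mouse_id = "m1", blood_chimerism_pct = 28.4,
    tissue_chimerism_pct = 28.4)
  est <- estimateRecruitment(cohort, steady_state_count = 0,
    post_injury_count = 500)
  expect_equal(meanRecruitmentPct(est), 100)
  expect_equal(recruitedCount(est), 500)
  expect_equal(recruitedFractionPct(est), 100)
})

test_that("cohort mean is the mean of per-mouse ratios, not the ratio of means", {
  cohort <- data.frame(mouse_id = c("m1", "m2"),
    blood_chimerism_pct = c(20, 50), tissue_chimerism_pct = c(10, 40))
  est <- estimateRecruitment(cohort, steady_state_count = 0,
    post_injury_count = 100)
  mean_of_ratios <- mean(c(100 * 10 / 20, 100 * 40 / 50))  # 65
  ratio_of_means <- 100 * mean(c(10, 40)) / mean(c(20, 50)) # 71.4...
  expect_equal(meanRecruitmentPct(est), mean_of_ratios)
  expect_false(isTRUE(all.equal(mean_of_ratios, ratio_of_means)))
  expect_equal(perMouseRecruitmentPct(est),
    c(m1 = 50, m2 = 80), ignore_attr = FALSE)
})

test_that("ordering and domain errors are raised", {
  expect_error(estimateRecruitment(mean_recruitment_pct = 50,
    steady_state_count = 100, post_injury_count = 20), ">=")
  expect_error(estimateRecruitment(data.frame(), 0, 10), "non-empty")
})

test_that("bootstrap CI brackets the planted recruitment on a clean cohort", {
  sim <- simulateParabiosis(n_mice = 50, true_recruitment_fraction = 0.6,
    tissue_noise_sd = 5, seed = 61)
  est <- estimateRecruitment(sim$cohort,
    steady_state_count = sim$steady_state_count,
    post_injury_count = sim$post_injury_count, boot = TRUE, seed = 62)
  expect_length(est@ci, 2)
  expect_lt(est@ci[1], est@ci[2])
  expect_lt(abs(meanRecruitmentPct(est) - 60), 6)
})

test_that("noise-free parabiosis recovers the planted fraction exactly", {
  sim <- simulateParabiosis(n_mice = 10, true_recruitment_fraction = 0.6,
    tissue_noise_sd = 0, seed = 63)
  est <- estimateRecruitment(sim$cohort, 20, 5375)
  expect_equal(meanRecruitmentPct(est), 60, tolerance = 1e-12)
  expect_equal(unname(perMouseRecruitmentPct(est)), rep(60, 10))
  # true fraction 1 with no noise: tissue equals blood per mouse
  sim1 <- simulateParabiosis(n_mice = 6, true_recruitment_fraction = 1,
    tissue_noise_sd = 0, seed = 64)
  expect_equal(sim1$cohort$tissue_chimerism_pct,
    sim1$cohort$blood_chimerism_pct)
})

test_that("migration ratios normalize to the nondraining reference", {
  samples <- data.frame(
    organ = c("ALN", "PaLN", "aorta"),
    phc_fraction = c(0.01, 0.02, 0.01),
    is_nondraining_reference = c(TRUE, FALSE, FALSE))
  mr <- migrationRatio(samples)
  expect_equal(mr$ratio, c(1, 2, 1))
  # planted enrichments recovered exactly in noise-free mode
  sim <- simulatePhotoconversion(reference_fraction = 0.02,
    enrichments = c(a = 0.5, b = 1.0, c = 3.0), noise_sd = 0, seed = 65)
  mr2 <- migrationRatio(sim$samples)
  expect_equal(mr2$ratio, c(1, 0.5, 1.0, 3.0))
  # errors: no/zero reference
  bad <- samples; bad$is_nondraining_reference <- FALSE
  expect_error(migrationRatio(bad), "exactly one")
  zero <- samples; zero$phc_fraction[1] <- 0
  expect_error(migrationRatio(zero), "> 0")
})

test_that("noisy photoconversion ratios stay within 3 sd of the enrichments", {
  ref <- 0.05; noise <- 0.002
  sim <- simulatePhotoconversion(reference_fraction = ref,
    enrichments = c(x = 0.5, y = 1, z = 3), noise_sd = noise, seed = 66)
  mr <- migrationRatio(sim$samples)
  expect_true(all(abs(mr$ratio[-1] - c(0.5, 1, 3)) <= 3 * noise / ref))
})
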