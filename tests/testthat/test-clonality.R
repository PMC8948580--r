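test_that("expansion ratio matches the cells-in-expanded-clones definition", {
  expect_equal(expansionRatio(c(1, 1, 1, 1)), 0)
  expect_equal(expansionRatio(7), 1)
  expect_equal(expansionRatio(c(3, 2, 1, 1, 1)), 5 / 8)
  expect_error(expansionRatio(numeric()), "empty")
})

test_that("Gini matches hand-computed values and its finite-n bounds", {
  expect_equal(giniCoefficient(c(5, 5, 5, 5)), 0)
  expect_equal(giniCoefficient(c(3, 1)), 0.25)
  # single-dominant limit hits the exact (n-1)/n upper bound
  expect_equal(giniCoefficient(c(1, 0, 0, 0)), 0.75)
  expect_equal(giniCoefficient(10), 0)
  expect_error(giniCoefficient(c(0, 0)), "zero")
  expect_error(giniCoefficient(c(-1, 2)), "non-negative")
})

test_that("Gini agrees with the pairwise brute-force oracle and stays in bounds", {
  set.seed(42)
  for (i in 1:50) {
    x <- sample(1:20, sample(2:12, 1), replace = TRUE)
    g <- giniCoefficient(x)
    expect_equal(g, gini_bruteforce(x), tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, (length(x) - 1) / length(x) + 1e-12)
  }
})

test_that("Lorenz curve has the stated shape and reproduces the Gini by area", {
  lc <- lorenzCurve(c(1, 1))
  expect_equal(lc$p, c(0, 0.5, 1))
  expect_equal(lc$L, c(0, 0.5, 1))
  lc2 <- lorenzCurve(c(3, 1))
  expect_equal(lc2$L, c(0, 0.25, 1))

  set.seed(7)
  for (i in 1:50) {
    x <- sample(1:30, sample(1:15, 1), replace = TRUE)
    lc <- lorenzCurve(x)
    expect_equal(lc$p[1], 0); expect_equal(lc$L[1], 0)
    expect_equal(tail(lc$p, 1), 1); expect_equal(tail(lc$L, 1), 1)
    expect_true(all(diff(lc$p) >= 0) && all(diff(lc$L) >= 0))
    expect_true(all(lc$L <= lc$p + 1e-12))  # on or below the diagonal
    expect_equal(giniFromLorenz(lc), giniCoefficient(x), tolerance = 1e-9)
  }
})

test_that("statistics are permutation- and scale-invariant, monotone under merging", {
  set.seed(13)
  for (i in 1:20) {
    x <- sample(1:15, sample(3:10, 1), replace = TRUE)
    p <- sample(x)
    expect_equal(expansionRatio(p), expansionRatio(x))
    expect_equal(giniCoefficient(p), giniCoefficient(x))
    expect_equal(giniCoefficient(3.7 * x), giniCoefficient(x))
    # merging two singletons into one size-2 clone
    if (sum(x == 1) >= 2) {
      y <- c(x[-which(x == 1)[1:2]], 2)
      expect_gte(expansionRatio(y), expansionRatio(x))
    }
  }
  # Gini is NOT monotone under that merge once a dominant clone exists:
  # pooling two singletons shrinks the clonotype count and can even the
  # distribution out. Documented counterexample:
  expect_lt(giniCoefficient(c(5, 2)), giniCoefficient(c(5, 1, 1)))
})

make_rep <- function(a_nts, b_nts, sample_id = "s1", ...) {
  contigs <- do.call(rbind, lapply(seq_along(a_nts), function(i)
    paired_contigs(sprintf("%s_c%03d", sample_id, i), a_nts[i], b_nts[i],
      sample_id = sample_id, ...)))
  callClonotypes(pairedCells(filterPairedProductive(contigs)))
}

test_that("repertoire overlap is symmetric set algebra over keys", {
  sim_a <- simulateRepertoire(n_cells = 40, abundance = "dirichlet",
    n_clonotypes = 20, sample_id = "A", seed = 21)
  shared_keys <- sim_a$truth$clonotypes[1:7, ]
  sim_b <- simulateRepertoire(n_cells = 50, abundance = "dirichlet",
    n_clonotypes = 22, sample_id = "B", planted_keys = shared_keys,
    seed = 22)
  ra <- callClonotypes(filterPairedProductive(sim_a$contigs))
  rb <- callClonotypes(filterPairedProductive(sim_b$contigs))

  ov <- repertoireOverlap(ra, rb)
  expect_equal(ov$shared, 7L)
  expect_setequal(ov$shared_keys, sim_b$truth$planted_keys)
  expect_equal(ov$a_only + ov$shared, nClonotypes(ra))
  expect_equal(ov$b_only + ov$shared, nClonotypes(rb))
  ov_rev <- repertoireOverlap(rb, ra)
  expect_equal(ov_rev$shared, ov$shared)
  expect_equal(ov_rev$a_only, ov$b_only)

  # identical and disjoint cases
  self <- repertoireOverlap(ra, ra)
  expect_equal(self$shared, nClonotypes(ra))
  expect_equal(self$a_only, 0L)
  sim_c <- simulateRepertoire(n_cells = 30, abundance = "dirichlet",
    n_clonotypes = 15, sample_id = "C", seed = 23)
  rc <- callClonotypes(filterPairedProductive(sim_c$contigs))
  expect_equal(repertoireOverlap(ra, rc)$shared, 0L)

  # mismatched key configuration is refused
  rb_aa <- callClonotypes(filterPairedProductive(sim_b$contigs),
    key_level = "aa")
  expect_error(repertoireOverlap(ra, rb_aa), "configuration")
})

test_that("clonotypes shared across samples are found with planted truth", {
  base <- simulateRepertoire(n_cells = 30, abundance = "dirichlet",
    n_clonotypes = 15, sample_id = "m1", seed = 31)
  plant <- base$truth$clonotypes[1, , drop = FALSE]
  sims <- lapply(2:3, function(i) simulateRepertoire(n_cells = 30,
    abundance = "dirichlet", n_clonotypes = 15,
    sample_id = paste0("m", i), planted_keys = plant, seed = 30 + i))
  reps <- c(list(callClonotypes(filterPairedProductive(base$contigs))),
    lapply(sims, function(s)
      callClonotypes(filterPairedProductive(s$contigs))))

  shared3 <- sharedClonotypes(reps, min_samples = 3)
  expect_equal(nrow(shared3), 1L)
  expect_equal(shared3$key, plant$key)
  expect_equal(shared3$n_samples, 3L)
  expect_equal(shared3$sample_ids, "m1,m2,m3")

  # min_samples = 2 on a pair agrees with repertoireOverlap
  shared2 <- sharedClonotypes(reps[1:2], min_samples = 2)
  ov <- repertoireOverlap(reps[[1]], reps[[2]])
  expect_setequal(shared2$key, ov$shared_keys)

  expect_error(sharedClonotypes(reps[1]), "at least 2")
})

test_that("all-unique repertoires share nothing", {
  r1 <- make_rep(c("TGTAAATTT", "TGTCCCTTT"), c("TGTGGGTTT", "TGTACGTTT"),
    sample_id = "u1")
  r2 <- make_rep(c("TGTAGGTTT", "TGTCTCTTT"), c("TGTGTGTTT", "TGTATGTTT"),
    sample_id = "u2")
  expect_equal(nrow(sharedClonotypes(list(r1, r2))), 0L)
})

test_that("summary and aggregation report per-sample stats and mean +/- SEM", {
  sims <- lapply(1:3, function(i) simulateRepertoire(n_cells = 40,
    abundance = "powerlaw", n_clonotypes = 20,
    sample_id = paste0("m", i), seed = 40 + i))
  reps <- lapply(sims, function(s)
    callClonotypes(filterPairedProductive(s$contigs)))
  summ <- clonalitySummary(reps)
  expect_equal(nrow(summ), 3L)
  for (i in 1:3) {
    expect_equal(summ$expansion_ratio[i], sims[[i]]$truth$expansion_ratio)
    expect_equal(summ$gini[i], sims[[i]]$truth$gini)
    expect_equal(summ$n_cells[i], sims[[i]]$truth$n_cells)
  }
  agg <- aggregateClonality(summ)
  g <- agg[agg$statistic == "gini", ]
  expect_equal(g$mean, mean(summ$gini))
  expect_equal(g$sem, sd(summ$gini) / sqrt(3))
})

test_that("dirichlet concentration drives Gini toward its limits", {
  # with ~40 cells per clonotype the multinomial sampling floor on the Gini
  # is small, so a huge concentration should land near 0
  even <- simulateRepertoire(n_cells = 400, abundance = "dirichlet",
    n_clonotypes = 10, concentration = 1e4, seed = 51)
  expect_lt(even$truth$gini, 0.2)
  skew <- simulateRepertoire(n_cells = 400, abundance = "dirichlet",
    n_clonotypes = 40, concentration = 0.02, seed = 52)
  expect_gt(skew$truth$gini, 0.6)
  one_hot <- simulateRepertoire(n_cells = 100, abundance = "explicit",
    sizes = 100, seed = 53)
  expect_equal(one_hot$truth$expansion_ratio, 1)
})
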