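# agreement statistics vs independent oracles, plus their invariants

test_that("ICC matches the ANOVA oracle and handles the canonical fixtures", {
  m <- matrix(c(1:6, 2:7, 3:8), ncol = 3)
  expect_equal(icc(m)$estimate, oracle_icc_a1(m), tolerance = 1e-10)
  expect_equal(icc(m, "consistency")$estimate, oracle_icc_c1(m),
               tolerance = 1e-10)

  # identical columns, non-constant rows -> perfect agreement
  id3 <- matrix(rep(c(1, 2.5, 4, 8), 3), ncol = 3)
  expect_equal(icc(id3)$estimate, 1)

  # random tables agree with the oracle
  set.seed(21)
  for (i in 1:25) {
    mm <- matrix(rnorm(8 * 4, sd = 2), 8, 4) +
      matrix(rnorm(8, sd = 3), 8, 4)
    expect_equal(icc(mm)$estimate, oracle_icc_a1(mm), tolerance = 1e-10)
    expect_equal(icc(mm, "consistency")$estimate, oracle_icc_c1(mm),
                 tolerance = 1e-10)
    expect_true(icc(mm)$ci_low <= icc(mm)$estimate)
    expect_true(icc(mm)$ci_high >= icc(mm)$estimate)
  }

  # constant offset on one rater hurts absolute agreement, not consistency
  base <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)[, c(1, 1, 1)]
  shifted <- base
  shifted[, 3] <- shifted[, 3] + 2
  expect_lt(icc(shifted)$estimate, icc(base)$estimate)
  expect_equal(icc(shifted, "consistency")$estimate, 1, tolerance = 1e-12)

  expect_error(icc(matrix(5, 4, 3)), class = "mibg_degenerate")
})

test_that("Fleiss kappa reproduces the hand-evaluated formula", {
  # per-subject pathological counts (3,2,1,0) over 3 raters:
  # P_bar = (1 + 1/3 + 1/3 + 1)/4 = 2/3, Pe = 0.5, kappa = 1/3
  mat <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0), c(0, 0, 0))
  fk <- fleiss_kappa(mat, B = 0)
  expect_equal(fk$estimate, 1 / 3, tolerance = 1e-12)
  expect_equal(fk$p_bar, 2 / 3, tolerance = 1e-12)
  expect_equal(fk$pe, 0.5, tolerance = 1e-12)

  # perfect agreement with both categories present
  perfect <- cbind(c(1, 0, 1, 0), c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(fleiss_kappa(perfect, B = 0)$estimate, 1)

  # one-category degeneracy is flagged, not divided by zero
  ones <- matrix(1, 5, 3)
  expect_true(fleiss_kappa(ones, B = 0)$degenerate)

  # independent uniform ratings have kappa near zero
  big <- matrix(NA, 2000, 3)
  set.seed(22)
  big[] <- sample(0:1, 6000, TRUE)
  expect_lt(abs(fleiss_kappa(big, B = 0)$estimate), 0.05)

  # random matrices agree with the table-route oracle
  set.seed(23)
  for (i in 1:20) {
    m <- matrix(sample(c("a", "b", "c"), 30 * 4, TRUE), 30, 4)
    expect_equal(fleiss_kappa(m, B = 0)$estimate, oracle_fleiss(m),
                 tolerance = 1e-10)
  }
})

test_that("Cohen kappa reproduces direct formula evaluations", {
  # cross-table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  tab <- matrix(c(20, 10, 5, 15), 2)
  expect_equal(cohens_kappa(tab)$estimate, 0.4, tolerance = 1e-12)

  # perfect disagreement
  expect_equal(cohens_kappa(matrix(c(0, 10, 10, 0), 2))$estimate, -1)

  # identical columns with both categories -> 1
  r <- c(1, 0, 1, 1, 0)
  expect_equal(cohens_kappa(r, r)$estimate, 1)

  # degenerate marginals flagged
  expect_true(cohens_kappa(c(1, 1, 1), c(1, 1, 1))$degenerate)

  # vector route equals table route
  set.seed(24)
  a <- sample(0:1, 40, TRUE); b <- sample(0:1, 40, TRUE)
  tab2 <- table(factor(a, 0:1), factor(b, 0:1))
  expect_equal(cohens_kappa(a, b)$estimate, cohens_kappa(tab2)$estimate,
               tolerance = 1e-12)
})

test_that("two-rater Fleiss equals Cohen exactly on marginal-homogeneous data", {
  # symmetric cross-table -> identical marginals for both raters
  r1 <- c(rep(1, 10), rep(1, 5), rep(0, 5), rep(0, 10))
  r2 <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))
  expect_equal(fleiss_kappa(cbind(r1, r2), B = 0)$estimate,
               cohens_kappa(r1, r2)$estimate, tolerance = 1e-12)

  # heterogeneous marginals: both defined, generally different, neither crashes
  set.seed(25)
  a <- rbinom(30, 1, 0.8); b <- rbinom(30, 1, 0.3)
  f <- fleiss_kappa(cbind(a, b), B = 0)$estimate
  c2 <- cohens_kappa(a, b)$estimate
  expect_true(is.finite(f) && is.finite(c2))
})

test_that("interpretive bands match the published systems", {
  expect_identical(interpret_agreement("fleiss", 0.45), "moderate")
  expect_identical(interpret_agreement("fleiss", 0.78), "good")
  expect_identical(interpret_agreement("fleiss", 0.69), "good")
  expect_identical(interpret_agreement("fleiss", 0.85), "very good")
  expect_identical(interpret_agreement("fleiss", 0.15), "poor")
  expect_identical(interpret_agreement("cohen", 0.90), "perfect")
  expect_identical(interpret_agreement("cohen", 0.29), "fair")
  expect_identical(interpret_agreement("cohen", 0.69), "substantial")
  expect_identical(interpret_agreement("cohen", 0.54), "moderate")
  expect_identical(interpret_agreement("icc", 0.94), "excellent")
  expect_identical(interpret_agreement("icc", 0.85), "good")
  expect_identical(interpret_agreement("icc", 0.6), "moderate")
  expect_identical(interpret_agreement("icc", 0.3), "poor")
  expect_error(interpret_agreement("fleiss", 1.5), class = "mibg_argument")
})

test_that("Spearman rho matches the rank-then-correlate oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x^3)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)
  expect_equal(spearman_rho(x, x^3)$p, 0)

  # ties averaged: equals Pearson on average ranks
  x2 <- c(1, 2, 2, 4); y2 <- c(1, 3, 2, 4)
  oracle <- stats::cor(rank(x2), rank(y2))
  expect_equal(spearman_rho(x2, y2)$rho, oracle, tolerance = 1e-12)

  # agrees with cor.test's estimate and t-approximation p-value
  set.seed(26)
  a <- rnorm(30); b <- a + rnorm(30)
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  sp <- spearman_rho(a, b)
  expect_equal(sp$rho, unname(ct$estimate), tolerance = 1e-10)

  expect_true(spearman_rho(rep(1, 5), c(1, 2, 3, 4, 5))$degenerate)
  expect_error(spearman_rho(1:2, 1:2), class = "mibg_argument")
})

test_that("chi-square on 2x2 proportion tables matches hand computation", {
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$p, 1)

  # expert vs inexpert manual pathological counts 32/35 vs 26/35:
  # expected cells (29, 6, 29, 6) -> X^2 = 2*(9/29) + 2*(9/6)
  tab <- rbind(c(32, 3), c(26, 9))
  expect_equal(chi_square_2x2(tab)$statistic, 2 * 9 / 29 + 2 * 9 / 6,
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(tab)$statistic, 3.620689655, tolerance = 1e-8)

  # agrees with stats::chisq.test without correction
  ct <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(chi_square_2x2(tab)$statistic, unname(ct$statistic),
               tolerance = 1e-12)
  expect_equal(chi_square_2x2(tab)$p, ct$p.value, tolerance = 1e-12)
  cty <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(chi_square_2x2(tab, correct = TRUE)$statistic,
               unname(cty$statistic), tolerance = 1e-12)

  # invariant under swapping both rows and both columns
  swapped <- tab[2:1, 2:1]
  expect_equal(chi_square_2x2(swapped)$statistic,
               chi_square_2x2(tab)$statistic, tolerance = 1e-12)

  expect_error(chi_square_2x2(rbind(c(5, 0), c(7, 0))),
               class = "mibg_degenerate")

  # McNemar companion matches stats::mcnemar.test
  mt <- stats::mcnemar.test(tab)
  expect_equal(mcnemar_2x2(tab)$statistic, unname(mt$statistic),
               tolerance = 1e-12)
})

test_that("kappa and ICC estimates stay in [-1, 1] and ignore subject order", {
  set.seed(27)
  for (i in 1:30) {
    n <- sample(4:20, 1); k <- sample(2:5, 1)
    cat_ <- matrix(sample(0:1, n * k, TRUE), n, k)
    cont <- matrix(rnorm(n * k), n, k) + rnorm(n)
    fk <- fleiss_kappa(cat_, B = 0)
    if (!fk$degenerate) expect_true(abs(fk$estimate) <= 1)
    ck <- cohens_kappa(cat_[, 1], cat_[, 2])
    if (!ck$degenerate) expect_true(abs(ck$estimate) <= 1)
    ic <- icc(cont)
    expect_true(abs(ic$estimate) <= 1)

    perm <- sample(n)
    if (!fk$degenerate) {
      expect_equal(fleiss_kappa(cat_[perm, ], B = 0)$estimate, fk$estimate,
                   tolerance = 1e-12)
    }
    expect_equal(icc(cont[perm, ])$estimate, ic$estimate, tolerance = 1e-10)
    if (!ck$degenerate) {
      expect_equal(cohens_kappa(cat_[perm, 1], cat_[perm, 2])$estimate,
                   ck$estimate, tolerance = 1e-12)
    }
  }
})

test_that("bootstrap CI for Fleiss kappa covers a known kappa", {
  # rating process with known kappa: true binary state ~ Bernoulli(0.5),
  # three raters each report it with error probability e independently;
  # pairwise agreement q = (1-e)^2 + e^2, Pe -> 0.5, kappa = 2q - 1
  e <- 0.15
  kappa_true <- 2 * ((1 - e)^2 + e^2) - 1
  n <- 50
  reps <- 500
  covered <- 0
  skipped <- 0
  for (r in seq_len(reps)) {
    seed <- derive_seed(4242, r)
    mat <- with_seed(seed, {
      truth <- rbinom(n, 1, 0.5)
      errs <- matrix(rbinom(n * 3, 1, e), n, 3)
      (truth + errs) %% 2
    })
    fk <- fleiss_kappa(mat, B = 600, seed = seed)
    if (fk$degenerate || is.na(fk$ci_low)) {
      skipped <- skipped + 1
      next
    }
    if (fk$ci_low <= kappa_true && kappa_true <= fk$ci_high) {
      covered <- covered + 1
    }
  }
  coverage <- covered / (reps - skipped)
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})
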