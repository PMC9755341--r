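# synthetic phantom generator: expectation maps, noise, cohorts, raters

test_that("uniform rates yield a constant image and H/M of 1", {
  p <- fast_params(
    lambda_background = 50, lambda_lung = 49.99, lambda_mediastinum = 50,
    lambda_myocardium = 50, lambda_cavity = 50, lambda_liver = 50,
    basal_fraction = 1, poisson_noise = FALSE,
    washout = list(background = 0.8, lung = 0.8, mediastinum = 0.8,
                   myocardium = 0.8, cavity = 0.8, liver = 0.8),
    acquisition_scale = 2
  )
  rec <- generate_phantom(p, seed = 5)
  expect_true(all(abs(rec$early$counts - 100) < 1e-9 |
                    abs(rec$early$counts - 99.98) < 1e-9)) # lung cells
  expect_equal(rec$truth$true_early_hm, 1, tolerance = 1e-6)
  expect_equal(rec$truth$true_late_hm, 1, tolerance = 1e-6)
  expect_true(all(abs(rec$late$counts / rec$early$counts - 0.8) < 1e-9))
})

test_that("constructed constant regions give an exact H/M of 2", {
  img <- matrix(150, 128, 128)
  img[100:120, 60:100] <- 300
  expect_equal(hm_ratio(img, rect_roi(60, 100, 30, 15), rect_roi(5, 5, 13, 20)),
               2)
})

test_that("the generator is a pure function of (params, seed)", {
  p <- fast_params()
  a <- generate_phantom(p, seed = 99)
  b <- generate_phantom(p, seed = 99)
  expect_identical(a$early$counts, b$early$counts)
  expect_identical(a$late$counts, b$late$counts)
  c <- generate_phantom(p, seed = 100)
  expect_false(identical(a$early$counts, c$early$counts))
})

test_that("noise off conserves counts; noise on is Poisson-calibrated", {
  p <- fast_params(poisson_noise = FALSE, acquisition_scale = 3)
  geom <- mibgquant:::build_phantom_geometry(p)
  expected <- mibgquant:::compose_map(geom, p, "early")
  rec <- generate_phantom(p, seed = 1)
  expect_equal(sum(rec$early$counts), sum(expected), tolerance = 1e-12)

  # fixed pixel over N=1000 independent draws: sample mean within 3 SE
  pn <- fast_params(poisson_noise = TRUE)
  geom128 <- mibgquant:::cached_geometry(pn)
  mu <- mibgquant:::compose_map(geom128, pn, "early")
  px <- which(geom128$masks$myocardium, arr.ind = TRUE)[1L, ] # a wall pixel
  draws <- vapply(1:1000, function(i) {
    generate_phantom(pn, seed = i)$early$counts[px[1], px[2]]
  }, numeric(1))
  se <- sqrt(mu[px[1], px[2]] / 1000)
  expect_lt(abs(mean(draws) - mu[px[1], px[2]]), 3 * se)
})

test_that("parameter validation rejects unusable worlds", {
  expect_error(phantom_params(lambda_lung = 7, lambda_mediastinum = 6),
               class = "mibg_params")
  expect_error(phantom_params(matrix_size = 32), class = "mibg_params")
  expect_error(phantom_params(lambda_liver = -1), class = "mibg_params")
  expect_error(
    phantom_params(geometry = list(heart = list(c = c(250, 250),
                                                a = c(44, 32), wall = 10))),
    class = "mibg_params"
  )
  # a zero wall leaves no myocardial annulus
  expect_error(
    generate_phantom(fast_params(geometry = list(
      heart = list(c = c(158, 152), a = c(44, 32), wall = 0)
    ))),
    class = "mibg_geometry"
  )
})

test_that("ground-truth masks are valid and consistent with the hm module", {
  rec <- local_noisefree_record()
  tr <- rec$truth
  expect_true(any(tr$cardiac_mask))
  expect_true(any(tr$mediastinal_mask))
  expect_false(any(tr$cardiac_mask & tr$mediastinal_mask))
  expect_gt(tr$true_early_hm, 0)
  expect_gt(tr$true_late_hm, 0)
  expect_equal(mean(rec$early$counts[tr$cardiac_mask]) /
                 mean(rec$early$counts[tr$mediastinal_mask]),
               tr$true_early_hm, tolerance = 1e-12)
})

test_that("cohorts default to 35 subjects and honour hm_spec point masses", {
  cohort <- generate_cohort(params = fast_params(), seed = 3)
  expect_length(cohort, 35L)

  small <- generate_cohort(5, params = fast_params(), seed = 3)
  small2 <- generate_cohort(5, params = fast_params(), seed = 3)
  expect_identical(lapply(small, function(r) r$early$counts),
                   lapply(small2, function(r) r$early$counts))
  # first five subjects of the bigger cohort share the small cohort's draws
  expect_identical(small[[2]]$early$counts, cohort[[2]]$early$counts)

  low <- generate_cohort(6, hm_spec = list(kind = "hm", value = 1.2),
                         params = fast_params(poisson_noise = FALSE),
                         seed = 4)
  for (rec in low) {
    expect_equal(rec$truth$true_early_hm, 1.2, tolerance = 1e-9)
    expect_true(classify_hm(rec$truth$true_early_hm)$early_pathological)
  }
  expect_error(generate_cohort(0), class = "mibg_argument")
})

test_that("zero-jitter raters reproduce the deterministic placements", {
  rec <- local_noisefree_record()
  null_rater <- rater_profile("null", 0, 0, 0, 0)

  semi <- simulate_rater_rois(rec, null_rater, "semiautomatic", seed = 8)
  ref <- place_semiautomatic_rois(rec$truth$square)
  expect_equal(semi$cardiac, ref$cardiac)
  expect_equal(semi$mediastinal, ref$mediastinal)

  man <- simulate_rater_rois(rec, null_rater, "manual", seed = 8)
  expect_equal(man$cardiac, rec$truth$cardiac_polygon)
  expect_equal(man$mediastinal, rec$truth$mediastinal_rect)
})

test_that("H/M error grows with landmark jitter (Monte-Carlo oracle)", {
  rec <- local_noisefree_record()
  true_semi <- {
    ref <- place_semiautomatic_rois(rec$truth$square)
    hm_ratio(rec$early, ref$cardiac, ref$mediastinal)
  }
  sigmas <- c(0, 1, 2, 4)
  mean_err <- vapply(seq_along(sigmas), function(si) {
    prof <- rater_profile("x", sigma_landmark = sigmas[si], sigma_vertex = 0)
    errs <- vapply(1:200, function(r) {
      rois <- simulate_rater_rois(rec, prof, "semiautomatic",
                                  seed = derive_seed(77, si, r))
      abs(hm_ratio(rec$early, rois$cardiac, rois$mediastinal) - true_semi)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) >= 0))
  expect_equal(mean_err[1], 0, tolerance = 1e-12)
})

test_that("default rater profiles are ordered expert <= moderate <= inexpert", {
  pr <- default_rater_profiles()
  for (field in c("sigma_landmark", "sigma_vertex", "sigma_rect_pos",
                  "sigma_rect_size")) {
    v <- vapply(pr, `[[`, numeric(1), field)
    expect_true(all(diff(v) >= 0))
  }
  expect_error(rater_profile("bad", -1, 0), class = "mibg_params")
})

test_that("cohorts write to disk with ground-truth sidecars", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(2, params = fast_params(), seed = 6)
  write_cohort(cohort, dir, "text")
  expect_true(file.exists(file.path(dir, "S001_early.tsv")))
  expect_true(file.exists(file.path(dir, "S002_late.tsv")))
  back <- read_planar(file.path(dir, "S001_early.tsv"), "text")
  expect_equal(back$counts, cohort[[1]]$early$counts)
  expect_identical(back$phase, "early")
  tr <- jsonlite::read_json(file.path(dir, "S001_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$true_early_hm, cohort[[1]]$truth$true_early_hm,
               tolerance = 1e-12)
})
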