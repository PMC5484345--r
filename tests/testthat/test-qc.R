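test_that("distribution volume is the ratio of curve integrals", {
  t <- seq(0, 4, by = 0.05)
  ca <- parker_aif_curve(t, onset = 0.3)
  expect_equal(distribution_volume(curve_tbl(t, 2 * ca$conc), ca), 2)
  expect_equal(distribution_volume(curve_tbl(t, rep(0, length(t))), ca), 0)
  # net-negative tissue integral gives a negative vd
  expect_lt(distribution_volume(curve_tbl(t, rep(-0.01, length(t))), ca), 0)
  zero <- curve_tbl(t, rep(0, length(t)))
  expect_error(distribution_volume(ca, zero), "zero")
})

test_that("baseline statistics come from the leading samples", {
  C <- curve_tbl(0:9, c(0, 1, rep(5, 8)))
  bl <- baseline_stats(C, 2)
  expect_equal(bl$mean, 0.5)
  expect_equal(bl$sd, sqrt(0.5), tolerance = 1e-12)
  expect_equal(baseline_stats(curve_tbl(0:4, rep(2, 5)), 3)$sd, 0)
  expect_error(baseline_stats(C, 1), ">= 2")
  expect_error(baseline_stats(C, 99), "exceeds")

  # recovered SD matches the injected noise level
  set.seed(3)
  sds <- replicate(400, {
    b <- curve_tbl(1:18, rnorm(18, 0, 0.05))
    baseline_stats(b, 18)$sd
  })
  expect_equal(mean(sds), 0.05, tolerance = 0.01)
})

test_that("empirical CNR follows its definition", {
  C <- curve_tbl(0:3, c(0, 0, 1, 0.5))
  expect_equal(estimate_cnr(C, list(mean = 0, sd = 0.1)), 10)
  expect_equal(estimate_cnr(C, list(mean = 0, sd = 0.2)), 5)
  expect_warning(v <- estimate_cnr(C, list(mean = 0, sd = 0)), "undefined")
  expect_identical(v, Inf)

  # nominal CNR 10 is recovered within sampling error of an 18-point baseline
  cfg <- sim_config("brain", cnr = 10, seed = 21)
  set.seed(cfg$seed)
  ests <- replicate(200, {
    r <- one_replicate(cfg)
    estimate_cnr(r$C, baseline_stats(r$C, 10))
  })
  expect_gt(median(ests), 6)
  expect_lt(median(ests), 14)
})

test_that("voxel classification applies the exclusion rules in order", {
  cfg <- sim_config("brain", cnr = 20, seed = 31)
  set.seed(cfg$seed)
  r <- one_replicate(cfg)
  fit <- fit_ctu_lls(r$C, r$ca)
  qc <- classify_voxel(r$C, r$ca, fit, n_baseline = 10)
  expect_equal(qc$decision, "included")

  # flat pure-noise voxel whose flat fit sits inside the baseline band
  t <- r$C$t
  set.seed(32)
  noise_only <- curve_tbl(t, rnorm(length(t), 0, 0.01))
  flat_fit <- fit_ctu_lls(noise_only, r$ca)
  flat_fit$fitted$conc <- rep(0, length(t))  # degenerate flat model curve
  flat_fit$params$vp <- 0.1
  flat_fit$derived$e <- 0.5
  qc_flat <- classify_voxel(noise_only, r$ca, flat_fit, n_baseline = 10)
  expect_true(qc_flat$decision %in% c("excluded_flat", "excluded_negative_vd"))

  # negative vd takes precedence over everything
  neg <- curve_tbl(t, rep(-0.05, length(t)))
  qc_neg <- classify_voxel(neg, r$ca, flat_fit, n_baseline = 10)
  expect_equal(qc_neg$decision, "excluded_negative_vd")

  # invalid linear solutions map to their categories
  bad_fit <- fit
  bad_fit$params$vp <- -0.1
  expect_equal(classify_voxel(r$C, r$ca, bad_fit, 10)$decision,
               "lls_vp_negative")
  bad_fit$params$vp <- 0.1
  bad_fit$derived$e <- -0.2
  expect_equal(classify_voxel(r$C, r$ca, bad_fit, 10)$decision,
               "lls_E_negative")
  bad_fit$derived$e <- 1.5
  expect_equal(classify_voxel(r$C, r$ca, bad_fit, 10)$decision,
               "lls_E_above_one")
})

test_that("most valid-CTU voxels at CNR 15 survive the QC pipeline", {
  cfg <- sim_config("brain", cnr = 15, seed = 41)
  set.seed(cfg$seed)
  decisions <- replicate(200, {
    r <- one_replicate(cfg)
    fit <- fit_ctu_lls(r$C, r$ca)
    classify_voxel(r$C, r$ca, fit, n_baseline = 10)$decision
  })
  expect_gt(mean(decisions == "included"), 0.95)
})

test_that("classification is a pure function of its inputs", {
  cfg <- sim_config("brain", cnr = 10, seed = 51)
  set.seed(cfg$seed)
  r <- one_replicate(cfg)
  fit <- fit_ctu_lls(r$C, r$ca)
  expect_identical(classify_voxel(r$C, r$ca, fit, 10),
                   classify_voxel(r$C, r$ca, fit, 10))
})
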