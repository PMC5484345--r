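brain <- ctu_params(0.23, 0.05, 0.02)

make_noiseless <- function(p, dt_s = 0.1, total_min = 4 + 1 / 3) {
  t <- seq(0, total_min, by = dt_s / 60)
  ca <- parker_aif_curve(t, onset = 1 / 3)
  list(ca = ca, C = ctu_forward(p, ca))
}

test_that("design matrix has the stated structure", {
  d <- make_noiseless(brain, dt_s = 2)
  A <- build_design_matrix(d$C, d$ca)
  expect_equal(dim(A), c(nrow(d$ca), 3L))
  expect_equal(unname(A[1, ]), c(0, 0, 0))
  # column 3 is the running integral of column 2
  expect_equal(A[, 3], running_trapz(curve_tbl(d$ca$t, A[, 2]))$conc)
  # residual of the true coefficient vector is near zero on noiseless data
  b_true <- c((brain$fp + brain$ps) / brain$vp, brain$fp,
              brain$fp * brain$ps / brain$vp)
  resid <- A %*% b_true - d$C$conc
  expect_lt(max(abs(resid)) / max(d$C$conc), 5e-3)
  expect_error(build_design_matrix(d$C, curve_tbl(d$ca$t + 1, d$ca$conc)),
               "grid")
})

test_that("coefficient back-map is exact and round-trips", {
  m <- coeffs_to_params(alpha = 5, beta = 0.23, gamma = 0.092)
  expect_equal(m$params$vp, 0.05)
  expect_equal(m$params$fp, 0.23)
  expect_equal(m$params$ps, 0.02)
  expect_equal(m$derived$tp, 0.2)
  expect_equal(m$derived$e, 0.08)
  expect_false(m$degenerate)

  # one-compartment limit: gamma = 0
  m0 <- coeffs_to_params(alpha = 4, beta = 0.4, gamma = 0)
  expect_equal(m0$params$ps, 0)
  expect_equal(m0$derived$e, 0)
  expect_equal(m0$params$vp, 0.4 / 4)

  # zero denominators flag degenerate, never error
  expect_true(coeffs_to_params(1, 1, 1)$degenerate)
  expect_true(coeffs_to_params(0, 1, 0.5)$degenerate)

  # params -> coefficients -> params is the identity (1000 random draws)
  set.seed(42)
  for (i in 1:1000) {
    p <- random_ctu_params()
    cf <- ctufit:::params_to_coeffs(p)
    back <- coeffs_to_params(cf[1], cf[2], cf[3])$params
    expect_equal(c(back$fp, back$vp, back$ps), c(p$fp, p$vp, p$ps),
                 tolerance = 1e-10)
  }
})

test_that("linear fit recovers truth at fine sampling and matches a generic solver", {
  for (i in seq_len(nrow(tissue_presets()))) {
    row <- tissue_presets()[i, ]
    p <- ctu_params(row$fp, row$vp, row$ps)
    d <- make_noiseless(p, dt_s = 0.1)
    f <- fit_ctu_lls(d$C, d$ca)
    expect_equal(f$category, "valid")
    expect_lt(abs(f$params$fp / p$fp - 1), 0.005)
    expect_lt(abs(f$params$vp / p$vp - 1), 0.005)
    expect_lt(abs(f$params$ps / p$ps - 1), 0.005)

    # oracle equivalence: generic QR least-squares on the same system
    A <- build_design_matrix(d$C, d$ca)
    b_qr <- qr.coef(qr(A), d$C$conc)
    expect_equal(unname(f$coefficients), unname(b_qr), tolerance = 1e-8)
  }
})

test_that("gamma vanishes for one-compartment data", {
  d <- make_noiseless(ctu_params(0.4, 0.1, 0), dt_s = 0.5)
  f <- fit_ctu_lls(d$C, d$ca)
  # gamma scaled against alpha*beta (the size of E) is tiny
  expect_lt(abs(f$coefficients["gamma"] /
                  (f$coefficients["alpha"] * f$coefficients["beta"])), 1e-4)
})

test_that("linear fit reports invalid categories without clipping", {
  set.seed(99)
  # pure-noise voxel: estimates may land anywhere; category must reflect it
  t <- seq(0, 4, by = 2 / 60)
  ca <- parker_aif_curve(t, onset = 1 / 3)
  seen <- character()
  for (i in 1:50) {
    C <- curve_tbl(t, rnorm(length(t), 0, 0.05))
    f <- fit_ctu_lls(C, ca)
    seen <- c(seen, f$category)
    if (f$category == "vp_negative") expect_lte(f$params$vp, 0)
    if (f$category == "E_negative") expect_lt(f$derived$e, 0)
    if (f$category == "E_above_one") expect_gt(f$derived$e, 1)
  }
  expect_gt(length(setdiff(unique(seen), "valid")), 0)
})

test_that("degenerate systems are flagged rather than inverted", {
  # constant zero AIF makes the normal matrix singular
  t <- seq(0, 2, by = 0.1)
  ca <- curve_tbl(t, rep(0, length(t)))
  C <- curve_tbl(t, rep(0, length(t)))
  f <- fit_ctu_lls(C, ca)
  expect_equal(f$category, "degenerate")
  expect_false(f$converged)
  expect_error(fit_ctu_lls(curve_tbl(0:2, c(0, 1, 1)), curve_tbl(0:2, c(0, 1, 1))),
               "at least 4")
})
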