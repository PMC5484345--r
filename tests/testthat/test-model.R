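brain <- ctu_params(0.23, 0.05, 0.02)

test_that("derived parameters obey the algebraic identities", {
  d <- derived_params(brain)
  expect_equal(d$tp, 0.2)
  expect_equal(d$e, 0.08)
  expect_equal(d$ktrans, 0.0184)

  cervix <- ctu_params(0.57, 0.28, 0.2)
  dc <- derived_params(cervix)
  expect_equal(dc$tp, 0.28 / 0.77)
  expect_equal(dc$e, 0.2 / 0.77)

  # one-compartment limit
  d0 <- derived_params(ctu_params(0.5, 0.1, 0))
  expect_equal(d0$e, 0)
  expect_equal(d0$ktrans, 0)
  expect_equal(d0$tp, 0.1 / 0.5)

  expect_error(derived_params(list(fp = 0, vp = 0.1, ps = 0)), "undefined")
})

test_that("impulse response decays from Fp to the Ktrans plateau", {
  d <- derived_params(brain)
  expect_equal(ctu_irf(brain, 0), brain$fp)
  expect_equal(ctu_irf(brain, 1e6), d$ktrans)
  expect_equal(ctu_irf(brain, d$tp),
               0.23 * exp(-1) + 0.0184 * (1 - exp(-1)))
  # monotone decreasing whenever E < 1
  t <- seq(0, 3, by = 0.01)
  expect_true(all(diff(ctu_irf(brain, t)) < 0))
  expect_error(ctu_irf(brain, -0.1), ">= 0")
})

test_that("exponential convolution matches closed forms and the Riemann oracle", {
  # unit step input: closed form tau * (1 - exp(-t/tau))
  t <- seq(0, 2, by = 0.005)
  step <- curve_tbl(t, rep(1, length(t)))
  out <- exp_convolve(step, tau = 0.5)
  expect_equal(out$conc, 0.5 * (1 - exp(-t / 0.5)), tolerance = 1e-12)

  # very large tau: result approaches the running integral of ca
  ca <- parker_aif_curve(seq(0, 2, by = 0.01), onset = 0.2)
  big <- exp_convolve(ca, tau = 1e6)
  expect_equal(big$conc, running_trapz(ca)$conc, tolerance = 1e-4)

  # brute-force 1-ms Riemann oracle on the Parker AIF
  tau <- 0.2
  t <- seq(0, 1.5, by = 0.02)
  cav <- parker_aif(t, onset = 0.25)
  oracle <- riemann_convolve(t, cav, function(u) exp(-u / tau))
  got <- exp_convolve(curve_tbl(t, cav), tau)$conc
  expect_lt(max(abs(got - oracle)) / max(oracle), 1e-4)

  # uniform-grid filter path agrees with the non-uniform loop path
  t_nu <- sort(c(t, 0.0173))
  ca_nu <- parker_aif(t_nu, onset = 0.25)
  got_nu <- exp_convolve(curve_tbl(t_nu, ca_nu), tau)$conc
  expect_equal(got_nu[match(t, t_nu)], got, tolerance = 1e-8)

  expect_error(exp_convolve(step, tau = 0), "tau")
})

test_that("forward model matches the convolution oracle and nests one-compartment", {
  t <- seq(0, 4, by = 0.01)
  ca <- parker_aif_curve(t, onset = 1 / 3)
  C <- ctu_forward(brain, ca)

  d <- derived_params(brain)
  oracle <- riemann_convolve(t, ca$conc, function(u) {
    brain$fp * exp(-u / d$tp) + d$ktrans * (1 - exp(-u / d$tp))
  })
  expect_lt(max(abs(C$conc - oracle)) / max(C$conc), 1e-4)

  # PS = 0 reduces exactly to the one-compartment model
  p0 <- ctu_params(0.4, 0.1, 0)
  expect_equal(ctu_forward(p0, ca)$conc,
               one_compartment_forward(0.4, 0.1, ca)$conc,
               tolerance = 1e-14)

  # zero input gives zero output; superposition holds to machine precision
  zero <- curve_tbl(t, rep(0, length(t)))
  expect_equal(ctu_forward(brain, zero)$conc, rep(0, length(t)))
  ca2 <- curve_tbl(t, 2 * ca$conc + 0.3)
  lhs <- ctu_forward(brain, curve_tbl(t, ca$conc + ca2$conc))$conc
  rhs <- ctu_forward(brain, ca)$conc + ctu_forward(brain, ca2)$conc
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # non-negative output for non-negative input
  expect_true(all(C$conc >= 0))
})

test_that("one-compartment model matches its step-input closed form", {
  t <- seq(0, 3, by = 0.005)
  step <- curve_tbl(t, rep(1, length(t)))
  out <- one_compartment_forward(0.6, 0.12, step)
  expect_equal(out$conc, 0.12 * (1 - exp(-t * 0.6 / 0.12)), tolerance = 1e-12)
  expect_error(one_compartment_forward(-1, 0.1, step), "fp")
  expect_error(one_compartment_forward(0.5, 0, step), "vp")
})

test_that("running trapezoidal integral is exact for linear integrands", {
  t <- seq(0, 1, by = 0.1)
  expect_equal(running_trapz(curve_tbl(t, rep(1, 11)))$conc, t)
  expect_equal(running_trapz(curve_tbl(t, t))$conc, t^2 / 2)
  expect_error(running_trapz(curve_tbl(0, 1)), "2 samples")

  # second-order convergence on a smooth integrand (Richardson-style check)
  smooth_at <- function(h) {
    t <- seq(0, 4, by = h)
    tail(running_trapz(curve_tbl(t, exp(-(t - 2)^2)))$conc, 1)
  }
  ref_s <- smooth_at(2e-4)
  r_smooth <- abs(smooth_at(0.02) - ref_s) / abs(smooth_at(0.01) - ref_s)
  expect_gt(r_smooth, 3.5)
  expect_lt(r_smooth, 4.5)

  # the Parker AIF has a jump at onset (truncated Gaussian tails), so its
  # integral converges first-order: error still shrinks steadily with h
  int_at <- function(h) {
    t <- seq(0, 4, by = h)
    tail(running_trapz(parker_aif_curve(t, onset = 0.2))$conc, 1)
  }
  ref <- int_at(2e-4)
  e1 <- abs(int_at(0.005) - ref)
  e2 <- abs(int_at(0.01) - ref)
  expect_gt(e2 / e1, 1.8)
  expect_lt(e1, 5e-4)
})
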