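#' Literature tissue parameter sets used by the simulation harness
#'
#' Three published CTU parameter combinations spanning low-flow brain
#' tumour tissue and two higher-flow cervical tumour estimates.
#'
#' @return A tibble with columns `tissue`, `fp`, `vp`, `ps`.
#' @export
#'
#' @examples
#' tissue_presets()
tissue_presets <- function() {
  tibble(tissue = c("brain", "cervix_k", "cervix_d"),
         fp = c(0.23, 0.57, 0.65),
         vp = c(0.05, 0.28, 0.22),
         ps = c(0.02, 0.2, 0.14))
}

lookup_tissue <- function(tissue) {
  if (inherits(tissue, "ctu_params")) return(tissue)
  tp <- tissue_presets()
  row <- tp[tp$tissue == tissue, ]
  if (nrow(row) != 1) {
    abort(sprintf("unknown tissue preset '%s' (use one of: %s)",
                  tissue, paste(tp$tissue, collapse = ", ")))
  }
  ctu_params(row$fp, row$vp, row$ps)
}

#' Simulation configuration
#'
#' Defines one simulated acquisition condition. A noiseless arterial input
#' (Parker population AIF with onset at the end of the baseline) and the
#' matching CTU tissue curve are generated on a fine master grid, then each
#' Monte Carlo replicate downsamples them to the target period `dt_s` with
#' a random onset jitter and adds Gaussian noise sized by the
#' contrast-to-noise ratio `cnr`.
#'
#' @param tissue A preset name (`"brain"`, `"cervix_k"`, `"cervix_d"`) or a
#'   [ctu_params()] object.
#' @param baseline_s Pre-contrast baseline duration in seconds (default 20).
#' @param post_s Post-injection duration in seconds (default 240, i.e. 4 min).
#' @param master_dt_s Master-grid sampling period in seconds (default 0.01).
#' @param dt_s Target sampling period in seconds; must be >= `master_dt_s`.
#' @param cnr Contrast-to-noise ratio (> 0); use `Inf` for noiseless runs.
#' @param n_reps Number of Monte Carlo replicates.
#' @param seed Integer seed making a run fully reproducible.
#' @param aif_noise_mult Multiplier on the AIF noise SD relative to the
#'   tissue noise SD (default 1: same absolute sigma on both curves).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tissue = "brain", baseline_s = 20, post_s = 240,
                       master_dt_s = 0.01, dt_s = 2, cnr = 10,
                       n_reps = 1000L, seed = 1L, aif_noise_mult = 1) {
  if (dt_s < master_dt_s) abort("`dt_s` must be >= `master_dt_s`")
  if (cnr <= 0) abort("`cnr` must be > 0")
  structure(list(tissue = lookup_tissue(tissue), baseline_s = baseline_s,
                 post_s = post_s, master_dt_s = master_dt_s, dt_s = dt_s,
                 cnr = cnr, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), aif_noise_mult = aif_noise_mult),
            class = "sim_config")
}

#' Noiseless master-grid curves for a simulation condition
#'
#' Evaluates the Parker AIF (onset at the end of the baseline) and the CTU
#' tissue response on the master grid `t = 0, dt, 2 dt, ...` covering the
#' acquisition window `[0, baseline + post)`.
#'
#' @param cfg A [sim_config()].
#' @return A list with curve tibbles `ca` and `C` (time in minutes).
#' @export
#'
#' @examples
#' nl <- sim_noiseless(sim_config("brain"))
#' max(nl$C$conc)
sim_noiseless <- function(cfg) {
  total_s <- cfg$baseline_s + cfg$post_s
  t <- seq(0, by = cfg$master_dt_s, length.out = round(total_s / cfg$master_dt_s)) / 60
  ca <- parker_aif_curve(t, onset = cfg$baseline_s / 60)
  C <- ctu_forward(cfg$tissue, ca)
  list(ca = ca, C = C)
}

#' Downsample a master-grid curve with onset jitter
#'
#' Samples the curve at times `t0 + k * dt` (nearest master-grid sample),
#' where the jitter `t0` is drawn uniformly in `[0, dt)` unless supplied.
#' Within one Monte Carlo replicate the same draw is applied to the
#' arterial and tissue curves, emulating a scanner whose acquisition clock
#' is not synchronised to the bolus arrival.
#'
#' @param curve Master-grid curve tibble (uniform spacing).
#' @param dt_s Target sampling period in seconds, >= the master spacing.
#' @param t0_s Optional jitter offset in seconds; drawn from the session
#'   RNG when `NULL`.
#'
#' @return A curve tibble sampled at the jittered grid.
#' @export
downsample_jitter <- function(curve, dt_s, t0_s = NULL) {
  xy <- as_curve_xy(curve)
  h_s <- (xy$t[2] - xy$t[1]) * 60
  if (dt_s < h_s - 1e-12) abort("`dt_s` is finer than the master grid spacing")
  if (is.null(t0_s)) t0_s <- runif(1, 0, dt_s)
  idx <- .jitter_index(length(xy$t), h_s, dt_s, t0_s)
  curve_tbl(xy$t[idx], xy$conc[idx])
}

# indices of the nearest master samples to t0 + k*dt inside [0, total)
.jitter_index <- function(n_master, h_s, dt_s, t0_s) {
  total_s <- n_master * h_s
  n <- ceiling((total_s - t0_s) / dt_s)
  tq <- t0_s + (seq_len(n) - 1) * dt_s
  pmin(round(tq / h_s) + 1, n_master)
}

#' Noise standard deviation implied by a contrast-to-noise ratio
#'
#' The CNR is defined as the maximum concentration difference of the
#' noiseless tissue curve divided by the baseline noise SD, so
#' `sigma = (max(C) - min(C)) / cnr` (the baseline of a noiseless curve is
#' exactly zero, making the difference the enhancement peak).
#'
#' @param C_noiseless Noiseless tissue curve tibble.
#' @param cnr Contrast-to-noise ratio, > 0.
#' @return Noise SD in mM.
#' @export
sigma_from_cnr <- function(C_noiseless, cnr) {
  if (cnr <= 0) abort("`cnr` must be > 0")
  xy <- as_curve_xy(C_noiseless, "C")
  amp <- max(xy$conc) - min(xy$conc)
  if (amp <= 0) abort("flat curve: CNR-based noise level undefined")
  amp / cnr
}

#' Add i.i.d. Gaussian noise to a curve
#'
#' @param curve Curve tibble.
#' @param sigma Noise SD in mM, >= 0. Draws come from the session RNG.
#' @return The curve with noise added to `conc`.
#' @export
add_noise <- function(curve, sigma) {
  if (sigma < 0) abort("`sigma` must be >= 0")
  xy <- as_curve_xy(curve)
  if (sigma == 0) return(curve_tbl(xy$t, xy$conc))
  curve_tbl(xy$t, xy$conc + rnorm(length(xy$conc), 0, sigma))
}

#' Percentage error and precision of a set of estimates
#'
#' Monte Carlo summary statistics relative to a known truth `mu`:
#' `error_pct = 100 (mean(x) - mu) / mu` (systematic deviation) and
#' `precision_pct = 100 sd(x) / mu` (stochastic spread; sample SD).
#'
#' @param estimates Numeric vector of estimates (>= 2 values).
#' @param mu True generating value (nonzero).
#' @return A list with `error_pct` and `precision_pct`.
#' @export
#'
#' @examples
#' error_precision(c(0.9, 1.1), mu = 1)
error_precision <- function(estimates, mu) {
  if (!is.finite(mu) || mu == 0) abort("`mu` must be finite and nonzero")
  if (length(estimates) < 2) abort("need at least 2 estimates")
  list(error_pct = 100 * (mean(estimates) - mu) / mu,
       precision_pct = 100 * sd(estimates) / mu)
}

#' Monte Carlo evaluation of the linear and nonlinear CTU fits
#'
#' Repeats the full measurement chain `n_reps` times: a fresh onset jitter
#' draw, nearest-sample downsampling of the noiseless master curves to
#' `dt_s`, independent Gaussian noise on the tissue and arterial curves
#' (SD from [sigma_from_cnr()]; AIF SD scaled by `aif_noise_mult`), then a
#' fit with each requested method. The nonlinear fit is initialised at the
#' true generating parameters, its best-case configuration. Degenerate
#' linear solves are counted and their estimates carried as-is (no silent
#' dropping); the summary uses all finite estimates.
#'
#' @param cfg A [sim_config()].
#' @param methods Character subset of `c("lls", "nlls")`.
#'
#' @return An object of class `ctu_mc`: use [tidy()] for the per-parameter
#'   error/precision table and [glance()] for run-level counts.
#' @export
#'
#' @examples
#' mc <- run_monte_carlo(sim_config("brain", n_reps = 25, seed = 7))
#' tidy(mc)
run_monte_carlo <- function(cfg, methods = c("lls", "nlls")) {
  methods <- match.arg(methods, c("lls", "nlls"), several.ok = TRUE)
  nl <- sim_noiseless(cfg)
  tm <- nl$ca$t
  ca_m <- nl$ca$conc
  C_m <- nl$C$conc
  h_s <- cfg$master_dt_s
  sigma <- if (is.infinite(cfg$cnr)) 0 else sigma_from_cnr(nl$C, cfg$cnr)
  truth <- cfg$tissue
  init_cfg <- nlls_config(init = truth)

  est <- list(lls = vector("list", cfg$n_reps),
              nlls = vector("list", cfg$n_reps))
  l2 <- list(lls = rep(NA_real_, cfg$n_reps),
             nlls = rep(NA_real_, cfg$n_reps))
  n_degenerate <- 0L

  set.seed(cfg$seed)
  for (r in seq_len(cfg$n_reps)) {
    t0 <- runif(1, 0, cfg$dt_s)
    idx <- .jitter_index(length(tm), h_s, cfg$dt_s, t0)
    n <- length(idx)
    tt <- tm[idx]
    Cr <- C_m[idx] + if (sigma > 0) rnorm(n, 0, sigma) else 0
    car <- ca_m[idx] + if (sigma > 0) rnorm(n, 0, sigma * cfg$aif_noise_mult) else 0
    Ccur <- curve_tbl(tt, Cr)
    cacur <- curve_tbl(tt, car)
    if ("lls" %in% methods) {
      f <- fit_ctu_lls(Ccur, cacur)
      if (f$category == "degenerate") n_degenerate <- n_degenerate + 1L
      est$lls[[r]] <- c(fp = f$params$fp, vp = f$params$vp, ps = f$params$ps)
      l2$lls[r] <- f$residual_l2
    }
    if ("nlls" %in% methods) {
      f <- fit_ctu_nlls(Ccur, cacur, init_cfg)
      est$nlls[[r]] <- c(fp = f$params$fp, vp = f$params$vp, ps = f$params$ps)
      l2$nlls[r] <- f$residual_l2
    }
  }

  truth_v <- c(fp = truth$fp, vp = truth$vp, ps = truth$ps)
  summary <- purrr::map(methods, function(m) {
    mat <- do.call(rbind, est[[m]])
    purrr::map(names(truth_v), function(pn) {
      x <- mat[, pn]
      x <- x[is.finite(x)]
      ep <- error_precision(x, truth_v[[pn]])
      tibble(method = m, parameter = pn, truth = truth_v[[pn]],
             mean = mean(x), sd = sd(x),
             error_pct = ep$error_pct, precision_pct = ep$precision_pct,
             n_used = length(x))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(summary = summary, config = cfg,
                 n_degenerate = n_degenerate,
                 mean_l2 = purrr::map_dbl(l2[methods], ~ mean(.x, na.rm = TRUE))),
            class = "ctu_mc")
}

#' @export
print.ctu_mc <- function(x, ...) {
  cat(sprintf("CTU Monte Carlo: %d reps, dt = %g s, CNR = %g, %d degenerate\n",
              x$config$n_reps, x$config$dt_s, x$config$cnr, x$n_degenerate))
  print(x$summary)
  invisible(x)
}
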