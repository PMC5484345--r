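#' Distribution volume of a tissue curve
#'
#' The ratio of the trapezoidal time integrals of the tissue and arterial
#' curves over the full acquisition window, `vd = int C dt / int ca dt`.
#' A negative value indicates a noise-dominated voxel and triggers
#' exclusion in [classify_voxel()].
#'
#' @param C,ca Curve tibbles on a shared grid.
#' @return Dimensionless ratio.
#' @export
distribution_volume <- function(C, ca) {
  cxy <- as_curve_xy(C, "C")
  axy <- as_curve_xy(ca, "ca")
  stop_if_grid_mismatch(cxy$t, axy$t, "C and ca")
  denom <- sum(diff(axy$t) * (axy$conc[-1] + axy$conc[-length(axy$conc)]) / 2)
  if (denom == 0) abort("AIF integral is zero: distribution volume undefined")
  num <- sum(diff(cxy$t) * (cxy$conc[-1] + cxy$conc[-length(cxy$conc)]) / 2)
  num / denom
}

#' Baseline mean and standard deviation
#'
#' Sample statistics of the first `n_baseline` pre-contrast samples of a
#' concentration curve.
#'
#' @param C Curve tibble.
#' @param n_baseline Number of leading baseline samples (>= 2).
#' @return A list with `mean` and `sd` (mM).
#' @export
baseline_stats <- function(C, n_baseline) {
  xy <- as_curve_xy(C, "C")
  if (n_baseline < 2) abort("`n_baseline` must be >= 2")
  if (n_baseline > length(xy$conc)) {
    abort("`n_baseline` exceeds the number of samples")
  }
  b <- xy$conc[seq_len(n_baseline)]
  list(mean = mean(b), sd = sd(b))
}

#' Empirical contrast-to-noise ratio of a measured curve
#'
#' `(max(C) - baseline mean) / baseline SD`. A zero baseline SD makes the
#' CNR undefined; the function returns `Inf` with a warning.
#'
#' @param C Curve tibble.
#' @param baseline A list with `mean` and `sd`, e.g. from [baseline_stats()].
#' @return Dimensionless CNR.
#' @export
estimate_cnr <- function(C, baseline) {
  xy <- as_curve_xy(C, "C")
  if (baseline$sd <= 0) {
    warn("baseline SD is zero; CNR undefined, returning Inf")
    return(Inf)
  }
  (max(xy$conc) - baseline$mean) / baseline$sd
}

#' Classify a voxel for inclusion in parameter mapping
#'
#' Applies the two-stage exclusion pipeline used for clinical parameter
#' maps, in fixed precedence order:
#' 1. `excluded_negative_vd` — negative distribution volume;
#' 2. `excluded_flat` — the fitted model curve lies entirely within the 95%
#'    confidence band of the baseline noise
#'    (`baseline mean +/- 1.96 baseline SD`), i.e. the fit is
#'    indistinguishable from no enhancement;
#' 3. `lls_vp_negative`, `lls_E_negative`, `lls_E_above_one` — the linear
#'    solution falls outside the model's domain of definition;
#' 4. `included` otherwise.
#'
#' @param C Tissue curve tibble.
#' @param ca Arterial curve tibble on the same grid.
#' @param fit A `ctu_fit` object for this voxel (its fitted curve supplies
#'   the flatness test; its parameters supply the validity tests).
#' @param n_baseline Number of leading baseline samples.
#'
#' @return A tibble with one row: `decision`, `vd`, `cnr`,
#'   `baseline_mean`, `baseline_sd`.
#' @export
classify_voxel <- function(C, ca, fit, n_baseline) {
  vd <- distribution_volume(C, ca)
  bl <- baseline_stats(C, n_baseline)
  cnr <- estimate_cnr(C, bl)
  decision <- if (vd < 0) {
    "excluded_negative_vd"
  } else if (all(is.finite(fit$fitted$conc)) &&
             all(fit$fitted$conc >= bl$mean - 1.96 * bl$sd &
                 fit$fitted$conc <= bl$mean + 1.96 * bl$sd)) {
    "excluded_flat"
  } else if (!is.finite(fit$params$vp) || fit$params$vp <= 0) {
    "lls_vp_negative"
  } else if (fit$derived$e < 0) {
    "lls_E_negative"
  } else if (fit$derived$e > 1) {
    "lls_E_above_one"
  } else {
    "included"
  }
  tibble(decision = decision, vd = vd, cnr = cnr,
         baseline_mean = bl$mean, baseline_sd = bl$sd)
}
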