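#' Kinetic parameters of the compartmental tissue uptake model
#'
#' The compartmental tissue uptake (CTU) model is the three-parameter
#' special case of the two-compartment exchange model that applies when the
#' acquisition is too short for contrast to return from the interstitium:
#' plasma flow `fp` (min^-1), fractional plasma volume `vp`
#' (dimensionless) and permeability-surface-area product `ps` (min^-1).
#'
#' @param fp Plasma flow per unit tissue volume (min^-1), > 0.
#' @param vp Fractional plasma volume, > 0.
#' @param ps Permeability-surface-area product (min^-1), >= 0.
#' @param check If `TRUE` (default) enforce physical validity. The linear
#'   estimator deliberately constructs unchecked parameter sets (negative
#'   values carry diagnostic meaning); it uses `check = FALSE`.
#'
#' @return A named list of class `ctu_params`.
#' @export
#'
#' @examples
#' ctu_params(fp = 0.23, vp = 0.05, ps = 0.02)
ctu_params <- function(fp, vp, ps, check = TRUE) {
  stopifnot(is.numeric(fp), is.numeric(vp), is.numeric(ps))
  if (check) {
    if (!is.finite(fp) || fp <= 0) abort("`fp` must be finite and > 0")
    if (!is.finite(vp) || vp <= 0) abort("`vp` must be finite and > 0")
    if (!is.finite(ps) || ps < 0) abort("`ps` must be finite and >= 0")
  }
  structure(list(fp = fp, vp = vp, ps = ps), class = "ctu_params")
}

#' @export
print.ctu_params <- function(x, ...) {
  cat(sprintf("CTU parameters: Fp = %.4g min^-1, vp = %.4g, PS = %.4g min^-1\n",
              x$fp, x$vp, x$ps))
  invisible(x)
}

#' Derived kinetic quantities of the CTU model
#'
#' Computes the plasma mean transit time `tp = vp / (fp + ps)` (min), the
#' extraction fraction `e = ps / (ps + fp)` (dimensionless, in \[0, 1\] for
#' physical parameters) and the volume transfer constant
#' `ktrans = e * fp` (min^-1).
#'
#' @param p A [ctu_params()] object (or list with fields `fp`, `vp`, `ps`).
#'
#' @return A named list with elements `tp`, `e`, `ktrans`.
#' @export
#'
#' @examples
#' derived_params(ctu_params(0.23, 0.05, 0.02))
derived_params <- function(p) {
  if (!is.finite(p$fp + p$ps) || p$fp + p$ps == 0) {
    abort("transit time undefined: fp + ps must be nonzero and finite")
  }
  e <- p$ps / (p$ps + p$fp)
  list(tp = p$vp / (p$fp + p$ps), e = e, ktrans = e * p$fp)
}

#' CTU impulse response function
#'
#' The tissue response to an ideal bolus:
#' `fp * exp(-t / tp) + ktrans * (1 - exp(-t / tp))`, a vascular washout
#' decaying from `fp` towards the steady uptake plateau `ktrans`.
#'
#' @param p A [ctu_params()] object.
#' @param t Times in minutes, >= 0.
#'
#' @return Numeric vector in min^-1.
#' @export
ctu_irf <- function(p, t) {
  if (any(t < 0)) abort("`t` must be >= 0")
  d <- derived_params(p)
  ex <- exp(-t / d$tp)
  p$fp * ex + d$ktrans * (1 - ex)
}

#' Exact convolution with an exponential kernel
#'
#' Computes `ca (*) exp(-t / tau)` under the assumption that `ca` varies
#' linearly between its samples: on each interval the integrand is a linear
#' function times an exponential, which has a closed form, so the running
#' convolution obeys a first-order recursion with no discretisation error
#' beyond the piecewise-linear interpolant itself. On a uniform grid the
#' recursion is evaluated by a fast recursive filter.
#'
#' @param ca Arterial curve tibble (columns `t` in min, `conc` in mM).
#' @param tau Exponential time constant in minutes, > 0.
#'
#' @return A curve tibble on the same grid, units mM.min.
#' @export
#'
#' @examples
#' step <- curve_tbl(seq(0, 2, by = 0.01), rep(1, 201))
#' head(exp_convolve(step, tau = 0.5))
exp_convolve <- function(ca, tau) {
  xy <- as_curve_xy(ca, "ca")
  curve_tbl(xy$t, .exp_conv(xy$t, xy$conc, tau))
}

# vector kernel: y(t_i) = int_0^{t_i} ca(u) exp(-(t_i - u)/tau) du
.exp_conv <- function(t, x, tau) {
  if (!is.finite(tau) || tau <= 0) abort("`tau` must be finite and > 0")
  n <- length(t)
  if (n < 2) return(numeric(n))
  dt <- diff(t)
  uniform <- diff(range(dt)) <= 1e-10 * dt[1]
  if (uniform) {
    h <- dt[1]
    ee <- exp(-h / tau)
    em1 <- -expm1(-h / tau)             # 1 - ee without cancellation
    a <- tau * em1                      # weight of left sample
    b <- tau * (1 - tau * em1 / h)      # weight of the slope term
    g <- x[-n] * a + (x[-1] - x[-n]) * b
    y <- stats::filter(g, ee, method = "recursive")
    c(0, as.numeric(y))
  } else {
    y <- numeric(n)
    for (i in 2:n) {
      h <- dt[i - 1]
      ee <- exp(-h / tau)
      em1 <- -expm1(-h / tau)
      a <- tau * em1
      b <- tau * (1 - tau * em1 / h)
      y[i] <- y[i - 1] * ee + x[i - 1] * a + (x[i] - x[i - 1]) * b
    }
    y
  }
}

#' Running trapezoidal integral of a curve
#'
#' Cumulative trapezoidal integration anchored at zero at the first sample;
#' the quadrature used for every time integral in the linear estimator and
#' the forward model.
#'
#' @param curve Curve tibble with >= 2 samples.
#' @return A curve tibble of the running integral (units mM.min).
#' @export
running_trapz <- function(curve) {
  xy <- as_curve_xy(curve)
  curve_tbl(xy$t, .cumtrapz(xy$t, xy$conc))
}

.cumtrapz <- function(t, x) {
  n <- length(t)
  if (n < 2) abort("running_trapz needs at least 2 samples")
  c(0, cumsum(diff(t) * (x[-1] + x[-n]) / 2))
}

#' CTU forward model: tissue curve from an arterial input
#'
#' Evaluates the analytical tissue concentration
#' `C(t) = ca(t) (*) [fp e^{-t/tp} + ktrans (1 - e^{-t/tp})]` on the grid of
#' `ca`, using the exact exponential convolution ([exp_convolve()]) for the
#' decaying term and the running trapezoidal integral for the plateau term.
#'
#' @param p A [ctu_params()] object.
#' @param ca Arterial curve tibble.
#'
#' @return Tissue curve tibble `C(t)` in mM on the grid of `ca`.
#' @export
#'
#' @examples
#' t <- seq(0, 4, by = 0.02)
#' ca <- parker_aif_curve(t)
#' C <- ctu_forward(ctu_params(0.23, 0.05, 0.02), ca)
#' max(C$conc)
ctu_forward <- function(p, ca) {
  xy <- as_curve_xy(ca, "ca")
  curve_tbl(xy$t, .ctu_model(xy$t, xy$conc, p$fp, p$vp, p$ps))
}

.ctu_model <- function(t, ca, fp, vp, ps) {
  tp <- vp / (fp + ps)
  ktrans <- ps / (ps + fp) * fp
  (fp - ktrans) * .exp_conv(t, ca, tp) + ktrans * .cumtrapz(t, ca)
}

#' One-compartment (vascular-only) forward model
#'
#' Tissue curve for a purely intravascular tracer:
#' `C(t) = ca(t) (*) fp exp(-t fp / vp)`, the `ps = 0` limit of the CTU
#' model. Used as the simpler comparison model for slowly enhancing voxels.
#'
#' @param fp Plasma flow (min^-1), > 0.
#' @param vp Fractional plasma volume, > 0.
#' @param ca Arterial curve tibble.
#'
#' @return Tissue curve tibble in mM.
#' @export
one_compartment_forward <- function(fp, vp, ca) {
  if (!is.finite(fp) || fp <= 0) abort("`fp` must be > 0")
  if (!is.finite(vp) || vp <= 0) abort("`vp` must be > 0")
  xy <- as_curve_xy(ca, "ca")
  curve_tbl(xy$t, fp * .exp_conv(xy$t, xy$conc, vp / fp))
}
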