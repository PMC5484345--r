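#' Parker population arterial input function parameters
#'
#' Constants of the Parker et al. (2006) population-averaged arterial input
#' function: two Gaussian first- and second-pass terms plus a
#' sigmoid-modulated exponential washout. Units follow the original
#' parameterisation with time in minutes and concentration in mM.
#'
#' @param a1,a2 Gaussian scaling constants (mmol min).
#' @param t1,t2 Gaussian centres (min).
#' @param sigma1,sigma2 Gaussian widths (min); must be strictly positive.
#' @param alpha Amplitude of the exponential component (mM).
#' @param beta Decay constant of the exponential component (min^-1).
#' @param s Sigmoid width constant (min^-1); strictly positive.
#' @param tau Sigmoid centre (min).
#'
#' @return A named list of class `aif_params`.
#' @export
#'
#' @examples
#' p <- parker_params()
#' p$alpha
parker_params <- function(a1 = 0.809, a2 = 0.330,
                          t1 = 0.17046, t2 = 0.365,
                          sigma1 = 0.0563, sigma2 = 0.132,
                          alpha = 1.050, beta = 0.1685,
                          s = 38.078, tau = 0.483) {
  if (sigma1 <= 0 || sigma2 <= 0 || s <= 0) {
    abort("AIF width parameters (sigma1, sigma2, s) must be strictly positive")
  }
  structure(list(a1 = a1, a2 = a2, t1 = t1, t2 = t2,
                 sigma1 = sigma1, sigma2 = sigma2,
                 alpha = alpha, beta = beta, s = s, tau = tau),
            class = "aif_params")
}

#' Evaluate the Parker population arterial input function
#'
#' Evaluates the bi-Gaussian plus sigmoid-modulated-exponential functional
#' form at times `t`, shifted by `onset`. The function is identically zero
#' before the onset (no contrast has arrived).
#'
#' @param t Numeric vector of time stamps in minutes.
#' @param params An [parker_params()] object.
#' @param onset Bolus arrival time in minutes (>= 0). Default 1/3 min (20 s),
#'   the baseline length used throughout the simulation harness.
#'
#' @return Numeric vector of plasma concentrations in mM.
#' @export
#'
#' @examples
#' t <- seq(0, 4, by = 1 / 60)
#' ca <- parker_aif(t, onset = 20 / 60)
#' max(ca)
parker_aif <- function(t, params = parker_params(), onset = 20 / 60) {
  if (anyNA(t) || any(!is.finite(t))) abort("non-finite time values in `t`")
  if (!inherits(params, "aif_params")) abort("`params` must come from parker_params()")
  if (onset < 0) abort("`onset` must be >= 0")
  ts <- t - onset
  out <- numeric(length(t))
  pos <- ts > 0
  if (any(pos)) {
    x <- ts[pos]
    g <- params$a1 / (params$sigma1 * sqrt(2 * pi)) *
      exp(-(x - params$t1)^2 / (2 * params$sigma1^2)) +
      params$a2 / (params$sigma2 * sqrt(2 * pi)) *
      exp(-(x - params$t2)^2 / (2 * params$sigma2^2))
    w <- params$alpha * exp(-params$beta * x) /
      (1 + exp(-params$s * (x - params$tau)))
    out[pos] <- g + w
  }
  out
}

#' Parker AIF as a curve table
#'
#' Convenience wrapper returning the Parker AIF sampled on a grid as a
#' curve tibble (see [curve_tbl()]).
#'
#' @inheritParams parker_aif
#' @return A curve tibble with columns `t` (min) and `conc` (mM).
#' @export
parker_aif_curve <- function(t, params = parker_params(), onset = 20 / 60) {
  curve_tbl(t, parker_aif(t, params, onset))
}

#' Correct an arterial curve for the small-to-large vessel hematocrit
#'
#' Arterial concentrations measured in a large vessel are rescaled to the
#' capillary plasma concentration by a multiplicative hematocrit factor.
#' The conventional value 1.18 corresponds to a large-vessel hematocrit of
#' 0.38 and a small-to-large vessel hematocrit ratio of 0.7.
#'
#' @param ca Arterial curve tibble (columns `t`, `conc`).
#' @param factor Positive multiplicative factor; default 1.18.
#'
#' @return The curve with `conc` scaled by `factor`; time stamps unchanged.
#' @export
#'
#' @examples
#' ca <- curve_tbl(c(0, 1), c(1, 2))
#' hematocrit_correct(ca)$conc
hematocrit_correct <- function(ca, factor = 1.18) {
  xy <- as_curve_xy(ca, "ca")
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    abort("`factor` must be a single positive number")
  }
  curve_tbl(xy$t, xy$conc * factor)
}

#' Full width at half maximum of a curve's main peak
#'
#' Locates the global maximum and the two half-maximum crossings bracketing
#' it, using linear interpolation between samples.
#'
#' @param curve Curve tibble.
#' @return Width in the curve's time unit (minutes).
#' @export
curve_fwhm <- function(curve) {
  xy <- as_curve_xy(curve)
  t <- xy$t
  y <- xy$conc
  i <- which.max(y)
  half <- y[i] / 2
  below_l <- which(y[seq_len(i)] < half)
  below_r <- which(y[i:length(y)] < half)
  if (length(below_l) == 0 || length(below_r) == 0) {
    abort("half-maximum crossings not bracketed by the sampled window")
  }
  l <- max(below_l)
  r <- i - 1 + min(below_r)
  tl <- t[l] + (half - y[l]) / (y[l + 1] - y[l]) * (t[l + 1] - t[l])
  tr <- t[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) * (t[r] - t[r - 1])
  tr - tl
}
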