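#' Design matrix of the linearised CTU model
#'
#' Double time-integration of the CTU differential equations turns the model
#' into a relation that is linear in three coefficients,
#' `C = -alpha * Cbar + beta * cabar + gamma * cabarbar`,
#' where a single bar is the running time integral and the double bar the
#' running double integral. This builds the N x 3 matrix with rows
#' `(-Cbar(t_i), cabar(t_i), cabarbar(t_i))`, all integrals by the running
#' trapezoidal rule anchored at the first sample.
#'
#' @param C Tissue curve tibble.
#' @param ca Arterial curve tibble on the same time grid.
#'
#' @return Numeric matrix (N x 3) with columns `neg_Cbar`, `ca_bar`,
#'   `ca_bbar`; the first row is identically zero.
#' @export
build_design_matrix <- function(C, ca) {
  cxy <- as_curve_xy(C, "C")
  axy <- as_curve_xy(ca, "ca")
  stop_if_grid_mismatch(cxy$t, axy$t, "C and ca")
  Cbar <- .cumtrapz(cxy$t, cxy$conc)
  cabar <- .cumtrapz(axy$t, axy$conc)
  cabb <- .cumtrapz(axy$t, cabar)
  m <- cbind(neg_Cbar = -Cbar, ca_bar = cabar, ca_bbar = cabb)
  m
}

#' Map linear coefficients to CTU kinetic parameters
#'
#' The linear coefficients are `alpha = (ps + fp) / vp`, `beta = fp`,
#' `gamma = fp * ps / vp`. The exact inverse is
#' `vp = beta^2 / (alpha beta - gamma)`, `fp = beta`,
#' `ps = gamma beta / (alpha beta - gamma)`, with `tp = 1 / alpha` and
#' `e = gamma / (alpha beta)`. No clipping or sign correction is applied:
#' negative or out-of-range values are diagnostic (they drive voxel
#' classification) and must survive the mapping.
#'
#' @param alpha,beta,gamma Linear coefficients (min^-1, min^-1, min^-2).
#'
#' @return A list with `params` (unchecked [ctu_params()]), `derived`
#'   (`tp`, `e`, `ktrans`) and `degenerate` (`TRUE` when a denominator
#'   vanishes and the mapping is undefined).
#' @export
#'
#' @examples
#' coeffs_to_params(alpha = 5, beta = 0.23, gamma = 0.092)
coeffs_to_params <- function(alpha, beta, gamma) {
  alpha <- unname(alpha); beta <- unname(beta); gamma <- unname(gamma)
  den <- alpha * beta - gamma
  if (!all(is.finite(c(alpha, beta, gamma))) ||
      den == 0 || alpha == 0 || beta == 0) {
    return(list(params = ctu_params(NA_real_, NA_real_, NA_real_, check = FALSE),
                derived = list(tp = NA_real_, e = NA_real_, ktrans = NA_real_),
                degenerate = TRUE))
  }
  fp <- beta
  vp <- beta^2 / den
  ps <- gamma * beta / den
  e <- gamma / (alpha * beta)
  list(params = ctu_params(fp, vp, ps, check = FALSE),
       derived = list(tp = 1 / alpha, e = e, ktrans = e * fp),
       degenerate = FALSE)
}

# forward map, used by tests and by default_init
params_to_coeffs <- function(p) {
  c(alpha = (p$fp + p$ps) / p$vp, beta = p$fp, gamma = p$fp * p$ps / p$vp)
}

classify_lls <- function(vp, e, degenerate) {
  if (degenerate) return("degenerate")
  if (!is.finite(vp) || !is.finite(e)) return("degenerate")
  if (vp <= 0) return("vp_negative")
  if (e < 0) return("E_negative")
  if (e > 1) return("E_above_one")
  "valid"
}

# analytic inverse of a symmetric 3x3 via the adjugate; returns NULL when
# the determinant is below tol relative to the matrix scale
.solve_sym3 <- function(m, tol = 1e-12) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[1, 3]
  d <- m[2, 2]; e <- m[2, 3]; f <- m[3, 3]
  det <- a * (d * f - e * e) - b * (b * f - c * e) + c * (b * e - c * d)
  scale <- a * d * f
  if (!is.finite(det) || abs(det) <= tol * max(scale, .Machine$double.xmin)) {
    return(NULL)
  }
  adj <- matrix(c(d * f - e * e, c * e - b * f, b * e - c * d,
                  c * e - b * f, a * f - c * c, b * c - a * e,
                  b * e - c * d, b * c - a * e, a * d - b * b), 3, 3)
  adj / det
}

#' Closed-form linear least-squares fit of the CTU model
#'
#' Solves the linearised model `c = A b` by the normal equations with an
#' analytic inversion of the 3 x 3 matrix `A'A` — a single closed-form
#' solve, no iteration or initial guess. The coefficient vector
#' `(alpha, beta, gamma)` is mapped back to `(fp, vp, ps)` exactly
#' ([coeffs_to_params()]) and the solution is categorised: `valid` when
#' `vp > 0` and `0 <= E <= 1`, otherwise one of `vp_negative`,
#' `E_negative`, `E_above_one`, or `degenerate` when the normal matrix is
#' numerically singular (flagged, never an error).
#'
#' @param C Tissue curve tibble.
#' @param ca Arterial curve tibble on the same grid; >= 4 samples.
#'
#' @return An object of class `ctu_fit` (method `"lls"`); see [tidy.ctu_fit()].
#'   The goodness-of-fit `residual_l2` is the L2 norm of `A b - c`, i.e. the
#'   misfit of the linear relation itself.
#' @export
#'
#' @examples
#' t <- seq(0, 4, by = 0.05 / 60)
#' ca <- parker_aif_curve(t)
#' C <- ctu_forward(ctu_params(0.23, 0.05, 0.02), ca)
#' tidy(fit_ctu_lls(C, ca))
fit_ctu_lls <- function(C, ca) {
  cxy <- as_curve_xy(C, "C")
  if (length(cxy$t) < 4) abort("linear fit needs at least 4 time points")
  A <- build_design_matrix(C, ca)
  y <- cxy$conc
  m <- crossprod(A)
  minv <- .solve_sym3(m)
  if (is.null(minv)) {
    b <- c(NA_real_, NA_real_, NA_real_)
    mapped <- coeffs_to_params(NA_real_, NA_real_, NA_real_)
    category <- "degenerate"
    resid <- NA_real_
    fitted <- rep(NA_real_, length(y))
  } else {
    b <- drop(minv %*% crossprod(A, y))
    mapped <- coeffs_to_params(b[1], b[2], b[3])
    category <- classify_lls(mapped$params$vp, mapped$derived$e,
                             mapped$degenerate)
    fitted <- drop(A %*% b)
    resid <- sqrt(sum((fitted - y)^2))
  }
  new_ctu_fit(method = "lls",
              params = mapped$params, derived = mapped$derived,
              coefficients = setNames(b, c("alpha", "beta", "gamma")),
              category = category, residual_l2 = resid,
              fitted = tibble(t = cxy$t, conc = fitted),
              data = curve_tbl(cxy$t, y),
              converged = !identical(category, "degenerate"),
              n_iter = 0L)
}

new_ctu_fit <- function(method, params, derived, coefficients, category,
                        residual_l2, fitted, data, converged, n_iter) {
  structure(list(method = method, params = params, derived = derived,
                 coefficients = coefficients, category = category,
                 residual_l2 = residual_l2, fitted = fitted, data = data,
                 converged = converged, n_iter = n_iter),
            class = "ctu_fit")
}

#' @export
print.ctu_fit <- function(x, ...) {
  cat(sprintf("CTU %s fit (%s): Fp = %.4g, vp = %.4g, PS = %.4g | L2 = %.4g\n",
              toupper(x$method), x$category,
              x$params$fp, x$params$vp, x$params$ps, x$residual_l2))
  invisible(x)
}
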