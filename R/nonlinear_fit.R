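#' Configuration for the nonlinear CTU fit
#'
#' @param lower,upper Bounds on `(fp, vp, ps)`. Defaults constrain all three
#'   to be non-negative (a tiny positive floor on `fp` and `vp` keeps the
#'   plasma transit time defined at the boundary) with no upper bound.
#' @param init Optional [ctu_params()] initial guess; when `NULL`,
#'   [default_init()] seeds the optimiser from the linear fit.
#' @param max_iter Maximum optimiser iterations.
#' @param ftol,ptol Function and parameter convergence tolerances.
#'
#' @return A list of class `nlls_config`.
#' @export
nlls_config <- function(lower = c(fp = 1e-8, vp = 1e-8, ps = 0),
                        upper = c(fp = Inf, vp = Inf, ps = Inf),
                        init = NULL, max_iter = 200L,
                        ftol = 1e-8, ptol = 1e-8) {
  if (!is.null(init)) {
    v <- c(init$fp, init$vp, init$ps)
    if (any(v < lower) || any(v > upper)) {
      abort("`init` must lie within the bounds")
    }
  }
  structure(list(lower = lower, upper = upper, init = init,
                 max_iter = as.integer(max_iter), ftol = ftol, ptol = ptol),
            class = "nlls_config")
}

#' Euclidean distance between two curves on a shared grid
#'
#' @param model,data Curve tibbles on the same time grid.
#' @return `sqrt(sum((model - data)^2))` in mM.
#' @export
l2_norm <- function(model, data) {
  m <- as_curve_xy(model, "model")
  d <- as_curve_xy(data, "data")
  stop_if_grid_mismatch(m$t, d$t, "model and data")
  sqrt(sum((m$conc - d$conc)^2))
}

#' Initial guess for the nonlinear fit from the linear solution
#'
#' The linear estimator finds the global optimum of its own problem in
#' closed form, which makes it a natural seed for the nonlinear fit.
#' Components outside the bounds (the linear fit can return negative
#' values) are projected onto a small positive floor; if the linear solve
#' is degenerate a fixed fallback is returned.
#'
#' @param C,ca Curve tibbles on a shared grid.
#' @param floor_val Replacement for out-of-bounds components.
#' @param fallback [ctu_params()] used when the linear solve is degenerate.
#'
#' @return A valid [ctu_params()] within the default bounds.
#' @export
default_init <- function(C, ca, floor_val = 1e-3,
                         fallback = ctu_params(0.3, 0.1, 0.05)) {
  lls <- tryCatch(fit_ctu_lls(C, ca), error = function(e) NULL)
  if (is.null(lls) || lls$category == "degenerate") return(fallback)
  p <- lls$params
  ctu_params(fp = if (is.finite(p$fp) && p$fp > 0) p$fp else floor_val,
             vp = if (is.finite(p$vp) && p$vp > 0) p$vp else floor_val,
             ps = if (is.finite(p$ps) && p$ps > 0) p$ps else floor_val)
}

#' Bounded nonlinear least-squares fit of the CTU model
#'
#' Minimises the L2 norm between the measured tissue curve and the
#' analytical CTU forward model over `(fp, vp, ps)`, subject to positivity
#' bounds, using bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]). Non-convergence is reported via the `converged`
#' flag with the last iterate returned, never as an error.
#'
#' @param C Tissue curve tibble.
#' @param ca Arterial curve tibble on the same grid.
#' @param config An [nlls_config()]; its `init` field sets the starting
#'   point (default: linear-fit seed via [default_init()]).
#'
#' @return An object of class `ctu_fit` (method `"nlls"`); `residual_l2`
#'   is the L2 norm of the analytical-model misfit.
#' @export
#'
#' @examples
#' t <- seq(0, 4, by = 2 / 60)
#' ca <- parker_aif_curve(t)
#' C <- ctu_forward(ctu_params(0.57, 0.28, 0.2), ca)
#' tidy(fit_ctu_nlls(C, ca))
fit_ctu_nlls <- function(C, ca, config = nlls_config()) {
  cxy <- as_curve_xy(C, "C")
  axy <- as_curve_xy(ca, "ca")
  stop_if_grid_mismatch(cxy$t, axy$t, "C and ca")
  init <- config$init %||% default_init(C, ca)
  p0 <- pmin(pmax(c(init$fp, init$vp, init$ps), config$lower), config$upper)
  t <- cxy$t; cav <- axy$conc; y <- cxy$conc
  resid_fn <- function(p) .ctu_model(t, cav, p[1], p[2], p[3]) - y
  fit <- minpack.lm::nls.lm(
    par = p0, lower = unname(config$lower), upper = unname(config$upper),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = config$max_iter,
                                         ftol = config$ftol,
                                         ptol = config$ptol))
  p <- fit$par
  params <- ctu_params(p[1], p[2], p[3], check = FALSE)
  fitted <- .ctu_model(t, cav, p[1], p[2], p[3])
  new_ctu_fit(method = "nlls",
              params = params, derived = derived_params(params),
              coefficients = params_to_coeffs(params),
              category = "valid",
              residual_l2 = sqrt(sum((fitted - y)^2)),
              fitted = curve_tbl(t, fitted),
              data = curve_tbl(t, y),
              converged = fit$info %in% 1:4,
              n_iter = fit$niter)
}
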