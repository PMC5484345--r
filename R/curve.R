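#' Build a concentration-time curve table
#'
#' A curve is the package's basic data structure: a tibble with a time
#' column `t` in minutes (strictly increasing) and a concentration column
#' `conc` in mM. Tissue curves C(t) and arterial input functions ca(t) are
#' both stored this way.
#'
#' @param t Numeric vector of time stamps in minutes, strictly increasing.
#' @param conc Numeric vector of concentrations in mM, same length as `t`.
#'
#' @return A tibble with columns `t` (min) and `conc` (mM).
#' @export
#'
#' @examples
#' curve_tbl(t = c(0, 0.5, 1), conc = c(0, 1.2, 0.8))
curve_tbl <- function(t, conc) {
  validate_curve(t, conc)
  tibble(t = as.numeric(t), conc = as.numeric(conc))
}

validate_curve <- function(t, conc, what = "curve") {
  if (length(t) != length(conc)) {
    abort(sprintf("%s: `t` (%d) and `conc` (%d) lengths differ",
                  what, length(t), length(conc)))
  }
  if (anyNA(t) || any(!is.finite(t))) {
    abort(sprintf("%s: non-finite time stamps at rows %s", what,
                  paste(utils::head(which(!is.finite(t)), 5), collapse = ", ")))
  }
  if (anyNA(conc) || any(!is.finite(conc))) {
    abort(sprintf("%s: non-finite concentrations at rows %s", what,
                  paste(utils::head(which(!is.finite(conc)), 5), collapse = ", ")))
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    abort(sprintf("%s: time stamps not strictly increasing at row %d",
                  what, which(diff(t) <= 0)[1] + 1))
  }
  invisible(TRUE)
}

# accept either a curve tibble or bare vectors; return list(t, conc)
as_curve_xy <- function(curve, what = "curve") {
  if (is.data.frame(curve)) {
    if (!all(c("t", "conc") %in% names(curve))) {
      abort(sprintf("%s must have columns `t` and `conc`", what))
    }
    t <- curve$t
    conc <- curve$conc
  } else {
    abort(sprintf("%s must be a data frame with columns `t` and `conc`", what))
  }
  validate_curve(t, conc, what)
  list(t = t, conc = conc)
}

same_grid <- function(t1, t2, tol = 1e-9) {
  length(t1) == length(t2) && all(abs(t1 - t2) <= tol * pmax(1, abs(t1)))
}

stop_if_grid_mismatch <- function(t1, t2, what = "curves") {
  if (!same_grid(t1, t2)) {
    abort(sprintf("%s are not on the same time grid", what))
  }
  invisible(TRUE)
}
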