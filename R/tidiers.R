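#' Tidy a CTU fit
#'
#' One row per kinetic quantity (estimated and derived), broom-style.
#'
#' @param x A `ctu_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @export
tidy.ctu_fit <- function(x, ...) {
  tibble(term = c("fp", "vp", "ps", "tp", "e", "ktrans"),
         estimate = c(x$params$fp, x$params$vp, x$params$ps,
                      x$derived$tp, x$derived$e, x$derived$ktrans),
         unit = c("1/min", "", "1/min", "min", "", "1/min"))
}

#' Fit-level summary of a CTU fit
#'
#' @param x A `ctu_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `category`, `residual_l2`,
#'   `converged`, `n_iter`, `n_points`.
#' @export
glance.ctu_fit <- function(x, ...) {
  tibble(method = x$method, category = x$category,
         residual_l2 = x$residual_l2, converged = x$converged,
         n_iter = x$n_iter, n_points = nrow(x$data))
}

#' Tidy a Monte Carlo summary
#'
#' @param x A `ctu_mc` object from [run_monte_carlo()].
#' @param ... Unused.
#' @return The per-(method, parameter) summary tibble with `error_pct`
#'   and `precision_pct`.
#' @export
tidy.ctu_mc <- function(x, ...) x$summary

#' Run-level summary of a Monte Carlo evaluation
#'
#' @param x A `ctu_mc` object.
#' @param ... Unused.
#' @return A one-row tibble with the condition and degenerate-fit count.
#' @export
glance.ctu_mc <- function(x, ...) {
  tibble(n_reps = x$config$n_reps, dt_s = x$config$dt_s,
         cnr = x$config$cnr, seed = x$config$seed,
         n_degenerate = x$n_degenerate)
}
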