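#' Plot a CTU fit against its data
#'
#' @param object A `ctu_fit` object.
#' @param ... Unused.
#' @return A ggplot: measured concentrations as points, fitted curve as a
#'   line.
#' @export
autoplot.ctu_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$data, what = "data"),
    dplyr::mutate(object$fitted, what = "fit"))
  ggplot(df, aes(x = .data$t, y = .data$conc)) +
    geom_point(data = ~ dplyr::filter(.x, .data$what == "data"),
               size = 0.6, alpha = 0.6) +
    geom_line(data = ~ dplyr::filter(.x, .data$what == "fit"),
              colour = "#d94801", linewidth = 0.8) +
    labs(x = "time (min)", y = "concentration (mM)",
         title = sprintf("CTU %s fit (%s)", toupper(object$method),
                         object$category)) +
    theme_minimal()
}

#' Plot Monte Carlo error and precision per parameter
#'
#' @param object A `ctu_mc` object.
#' @param ... Unused.
#' @return A ggplot faceted by parameter, comparing methods.
#' @export
autoplot.ctu_mc <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("error_pct", "precision_pct"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$parameter, y = .data$value,
                 fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    facet_wrap(~metric, scales = "free_y") +
    scale_colour_brewer(palette = "Set1", aesthetics = "fill") +
    labs(x = NULL, y = "%",
         title = sprintf("Monte Carlo summary (dt = %g s, CNR = %g, n = %d)",
                         object$config$dt_s, object$config$cnr,
                         object$config$n_reps)) +
    theme_minimal()
}

#' Plot one or more concentration curves
#'
#' @param curves A curve tibble or named list of curve tibbles.
#' @return A ggplot of concentration against time.
#' @export
plot_curves <- function(curves) {
  if (is.data.frame(curves)) curves <- list(curve = curves)
  df <- purrr::imap(curves, ~ dplyr::mutate(.x, curve = .y)) |>
    purrr::list_rbind()
  ggplot(df, aes(x = .data$t, y = .data$conc, colour = .data$curve)) +
    geom_line() +
    labs(x = "time (min)", y = "concentration (mM)") +
    theme_minimal()
}
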