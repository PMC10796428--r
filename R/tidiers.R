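# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Hill dose-response fit
#' @param x A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("ec50", "hillslope"),
                 estimate = c(x$ec50, x$hillslope))
}

#' One-row summary of a Hill fit
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `ec50`, `hillslope`, `rss`, `sigma`, `n_conc`,
#'   `n_cells`.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, hillslope = x$hillslope, rss = x$rss,
                 sigma = x$sigma, n_conc = nrow(x$data),
                 n_cells = x$n_cells)
}

#' Dose-response curve with cell-averaged points
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  grid <- tibble::tibble(
    conc_uM = 10^seq(log10(min(object$data$conc_uM)),
                     log10(max(object$data$conc_uM)), length.out = 200))
  grid$y <- predict(object, grid$conc_uM)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_uM)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_response - .data$sem,
      ymax = .data$mean_response + .data$sem), width = 0.05) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_response)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$y),
                       colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (uM)",
                  y = "normalized response (% of max)",
                  title = sprintf("Hill fit: EC50 = %.3g, slope = %.2f",
                                  object$ec50, object$hillslope)) +
    ggplot2::theme_minimal()
}

#' Tidy an ACh-calcium response regression
#' @param x A `response_cor` from [correlate_responses()].
#' @param ... Unused.
#' @method tidy response_cor
#' @export
tidy.response_cor <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' One-row summary of a response regression
#' @param x A `response_cor`.
#' @param ... Unused.
#' @method glance response_cor
#' @export
glance.response_cor <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r.squared = x$r^2, p_value = x$p_value, n = x$n)
}

#' Scatter of paired responses with the regression line and 95% band
#' @param object A `response_cor`.
#' @param ... Unused.
#' @method autoplot response_cor
#' @export
autoplot.response_cor <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$ca, y = .data$ach)) +
    ggplot2::geom_ribbon(data = object$band,
                         ggplot2::aes(x = .data$x, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = object$band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "calcium response (DF/F)", y = "ACh response (DF/F)",
                  subtitle = sprintf("r = %.2f, p = %.2g", object$r,
                                     object$p_value)) +
    ggplot2::theme_minimal()
}

#' Event-aligned average trace plot
#' @param aligned Tibble from [align_average()].
#' @return A ggplot of mean +/- SEM around the event start.
#' @export
plot_aligned <- function(aligned) {
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$time_s, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event start (s)", y = "DF/F") +
    ggplot2::theme_minimal()
}

#' Normalized binned seizure-frequency plot
#' @param binned Tibble from [bin_and_normalize()] (optionally several,
#'   row-bound with an `animal` column).
#' @return A ggplot of normalized frequency vs bin start time.
#' @export
plot_binned_effect <- function(binned) {
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$bin_start_min, y = .data$norm_freq)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "pointrange") +
    ggplot2::labs(x = "time from injection (min)",
                  y = "normalized seizure frequency") +
    ggplot2::theme_minimal()
}
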