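# Hill dose-response analysis: baseline-subtracted peak currents,
# within-cell normalization, and nonlinear least-squares fitting of
# Y = 100 / (1 + (EC50 / X)^Hillslope) on cell-averaged data.

#' Hill model response
#'
#' Evaluates `Y = 100 / (1 + (ec50 / x)^hillslope)`, the fractional response
#' (percent of maximum) at agonist concentration `x`.
#'
#' @param x Concentration(s), > 0.
#' @param ec50 Half-maximal concentration, > 0.
#' @param hillslope Hill coefficient, > 0.
#' @return Response in percent of maximum.
#' @examples
#' hill_response(1, ec50 = 1, hillslope = 1)  # 50
#' @export
hill_response <- function(x, ec50, hillslope = 1) {
  stopifnot(ec50 > 0, hillslope > 0)
  if (any(x <= 0)) stop("concentrations must be > 0")
  100 / (1 + (ec50 / x)^hillslope)
}

#' Baseline-subtracted peak drug-induced current
#'
#' The drug-induced amplitude is the extremum of the holding-current trace in
#' the drug-application window minus the mean holding current in the baseline
#' window, preserving sign (inward currents are negative). The trace is
#' lightly smoothed first (the holding-current shift is slow compared with
#' sample noise, whose extreme values would otherwise bias the peak).
#'
#' @param trace Holding-current trace, a [ts_signal()] or numeric vector (pA).
#' @param drug_window,baseline_window Two-element `c(start, end)` windows in
#'   seconds.
#' @param rate Sampling rate (Hz) when `trace` is a plain vector.
#' @param smooth_s Moving-mean smoothing window (s; default 50 ms).
#' @return Amplitude in trace units (signed).
#' @export
peak_drug_amplitude <- function(trace, drug_window, baseline_window,
                                rate = NULL, smooth_s = 0.05) {
  fs <- resolve_rate(trace, rate)
  x <- ts_values(trace)
  if (smooth_s > 0) x <- moving_mean(x, round(smooth_s * fs))
  t <- (seq_along(x) - 1) / fs
  if (drug_window[1] < 0 || drug_window[2] > t[length(t)] + 1 / fs) {
    stop("drug window outside trace")
  }
  base <- mean(x[t >= baseline_window[1] & t < baseline_window[2]])
  seg <- x[t >= drug_window[1] & t < drug_window[2]]
  dev <- seg - base
  dev[which.max(abs(dev))]
}

#' Normalize drug-induced amplitudes to the within-cell peak response
#'
#' Each cell's amplitudes are expressed as percent of that cell's maximal
#' response magnitude, so the within-cell maximum is exactly 100 and inward
#' (negative) current conventions are handled on magnitudes.
#'
#' @param table Tibble with `cell_id`, `conc_uM` and `amplitude_pA` columns.
#' @return The table with a `norm_amplitude` column (percent).
#' @export
normalize_within_cell <- function(table) {
  stopifnot(all(c("cell_id", "conc_uM", "amplitude_pA") %in% names(table)))
  if (any(table$conc_uM <= 0)) stop("concentrations must be positive")
  out <- table |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(norm_amplitude =
                    100 * abs(.data$amplitude_pA) /
                    max(abs(.data$amplitude_pA))) |>
    dplyr::ungroup()
  if (any(!is.finite(out$norm_amplitude))) {
    stop("degenerate normalization: a cell has all-zero amplitudes")
  }
  out
}

#' Fit the Hill dose-response model
#'
#' Cell-normalized responses are averaged across cells at each concentration
#' and fitted by nonlinear least squares to the normalized Hill model
#' `Y = 100 / (1 + (EC50 / X)^Hillslope)`, parameterized in log10(EC50) for
#' stability. Because the within-cell peak used for normalization is itself
#' a noisy estimate of the true plateau (its maximum-selection bias
#' uniformly compresses the normalized curve and would inflate EC50), the
#' plateau scale is co-estimated as a nuisance parameter and the fit is
#' reported on the normalized 0-100 scale. Initialization is a multistart
#' over a grid of EC50 values at the observed concentrations and slopes
#' {0.5, 1, 2}; the best sum-of-squares start wins. EC50 is bounded to the
#' observed concentration range times [1e-2, 1e2] and the slope to
#' (0, 10].
#'
#' @param table Tibble with `cell_id`, `conc_uM` and either `norm_amplitude`
#'   (percent, from [normalize_within_cell()]) or `amplitude_pA` (normalized
#'   on the fly).
#' @param per_cell If `TRUE`, fit each cell separately instead of the
#'   cell-averaged default.
#' @return A `hill_fit` object (or a tibble of per-cell fits): fitted `ec50`,
#'   `hillslope`, residual summary, and the per-concentration mean +/- SEM
#'   table. Supports [tidy()], [glance()], `predict()` and
#'   [ggplot2::autoplot()].
#' @export
fit_hill <- function(table, per_cell = FALSE) {
  if (!"norm_amplitude" %in% names(table)) {
    table <- normalize_within_cell(table)
  }
  if (per_cell) {
    return(table |>
             dplyr::group_by(.data$cell_id) |>
             dplyr::group_modify(function(d, key) {
               f <- fit_hill_avg(dplyr::mutate(d, cell_id = "one"))
               tibble::tibble(ec50 = f$ec50, hillslope = f$hillslope,
                              rss = f$rss)
             }) |>
             dplyr::ungroup())
  }
  fit_hill_avg(table)
}

fit_hill_avg <- function(table) {
  avg <- table |>
    dplyr::group_by(conc_uM = .data$conc_uM) |>
    dplyr::summarise(mean_response = mean(.data$norm_amplitude),
                     sem = stats::sd(.data$norm_amplitude) /
                       sqrt(dplyr::n()),
                     n_cells = dplyr::n(), .groups = "drop")
  if (nrow(avg) < 4) stop("need >= 4 distinct concentrations to fit")
  x <- avg$conc_uM; y <- avg$mean_response
  lo <- c(log10(min(x)) - 2, 1e-3, 50)
  hi <- c(log10(max(x)) + 2, 10, 150)
  model <- function(p) p[3] / (1 + (10^p[1] / x)^p[2])
  sse <- function(p) sum((y - model(p))^2)
  starts <- tidyr::expand_grid(le = log10(x), hs = c(0.5, 1, 2))
  best <- starts[which.min(purrr::pmap_dbl(starts,
                                           function(le, hs)
                                             sse(c(le, hs, 100)))), ]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mean_response ~ plateau / (1 + (10^log_ec50 / conc_uM)^hillslope),
      data = avg,
      start = list(log_ec50 = best$le, hillslope = best$hs, plateau = 100),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to bounded quasi-Newton multistart before giving up
    cand <- purrr::pmap(starts, function(le, hs) {
      stats::optim(c(le, hs, 100), sse, method = "L-BFGS-B",
                   lower = lo, upper = hi)
    })
    opt <- cand[[which.min(purrr::map_dbl(cand, "value"))]]
    if (!is.finite(opt$value)) {
      stop("Hill fit failed to converge after multistart")
    }
    co <- c(log_ec50 = opt$par[1], hillslope = opt$par[2],
            plateau = opt$par[3])
    resid <- y - model(opt$par)
  } else {
    co <- stats::coef(fit)
    resid <- stats::residuals(fit)
  }
  structure(
    list(ec50 = unname(10^co["log_ec50"]),
         hillslope = unname(co["hillslope"]),
         plateau = unname(co["plateau"]),
         rss = sum(resid^2),
         sigma = sqrt(sum(resid^2) / max(1, nrow(avg) - 3)),
         residuals = resid,
         data = avg,
         n_cells = length(unique(table$cell_id))),
    class = "hill_fit"
  )
}

#' Predict from a fitted Hill model
#' @param object A `hill_fit`.
#' @param x Concentration(s), > 0.
#' @param ... Unused.
#' @return Predicted response (percent of maximum).
#' @export
predict.hill_fit <- function(object, x, ...) {
  hill_response(x, object$ec50, object$hillslope)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill dose-response fit: EC50 = %.4g, slope = %.3g (%d concentrations, %d cells, RSS = %.3g)\n",
              x$ec50, x$hillslope, nrow(x$data), x$n_cells, x$rss))
  invisible(x)
}
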