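# Fluorescence-trace analysis: ROI trace extraction, DF/F with a cubic
# time-dependent baseline (temporal smoothing, peak/running/edge exclusion),
# 10 s event-response metrics, the randomized-time-point (>95%) significance
# criterion, 30 s evoked baselines, seizure-aligned averaging, and the
# ACh-calcium response regression.

#' Extract per-ROI mean-intensity traces from an image stack
#'
#' @param frames Numeric array `height x width x frames`.
#' @param roi_masks List of logical `height x width` masks.
#' @return Matrix `frames x ROIs` of mean intensities.
#' @export
extract_traces <- function(frames, roi_masks) {
  stopifnot(length(dim(frames)) == 3)
  sapply(roi_masks, function(m) {
    stopifnot(identical(dim(m), dim(frames)[1:2]))
    if (!any(m)) stop("empty ROI mask")
    apply(frames, 3, function(fr) mean(fr[m]))
  })
}

#' DF/F with a cubic time-dependent baseline
#'
#' The trace is temporally smoothed (moving median), and samples belonging
#' to peaks (iteratively, residuals above `peak_sd` SDs of the current fit),
#' to running periods, and to the first and last `edge_frac` of the
#' recording are excluded; a third-degree polynomial fitted to the remaining
#' samples is the baseline `B(t)`, and `DF/F = (F - B) / B`. DF/F is
#' invariant to multiplicative gain on `F`.
#'
#' @param trace Numeric fluorescence vector (one ROI).
#' @param frame_rate Frames per second (15 typical).
#' @param running_intervals Tibble of `start`, `end` (s) to exclude.
#' @param smooth_s Moving-median window (s), default 5.
#' @param edge_frac Fraction of frames excluded at each end, default 0.05.
#' @param peak_sd Residual SD multiple excluded as peaks, default 2.
#' @param n_iter Fit-exclude iterations, default 3.
#' @return List with `dff`, `baseline`, `coef` (polynomial coefficients on
#'   normalized time) and the final inclusion `mask`.
#' @export
dff <- function(trace, frame_rate, running_intervals = NULL, smooth_s = 5,
                edge_frac = 0.05, peak_sd = 2, n_iter = 3) {
  n <- length(trace)
  stopifnot(n > 16, frame_rate > 0)
  t <- (seq_len(n) - 1) / frame_rate
  u <- t / t[n]
  k <- round(smooth_s * frame_rate)
  if (k %% 2 == 0) k <- k + 1
  sm <- stats::runmed(trace, k)
  mask <- rep(TRUE, n)
  edge <- max(1L, floor(edge_frac * n))
  mask[c(seq_len(edge), (n - edge + 1):n)] <- FALSE
  mask[intervals_to_mask(running_intervals %||% empty_intervals(),
                         n, frame_rate)] <- FALSE
  X <- cbind(1, u, u^2, u^3)
  co <- NULL
  for (it in seq_len(n_iter)) {
    if (sum(mask) < 8) stop("more than 90% of samples excluded from baseline fit")
    co <- stats::lm.fit(X[mask, , drop = FALSE], sm[mask])$coefficients
    resid <- sm - X %*% co
    s <- stats::sd(resid[mask])
    # stop when residuals are numerically negligible (noise-free traces)
    if (s < 1e-9 * mean(abs(sm[mask]))) break
    mask <- mask & (resid < peak_sd * s)   # peaks are positive excursions
  }
  if (mean(!mask) > 0.9) stop("more than 90% of samples excluded from baseline fit")
  baseline <- as.numeric(X %*% co)
  if (any(baseline <= 0)) warning("non-positive fitted baseline")
  list(dff = (trace - baseline) / baseline, baseline = baseline,
       coef = as.numeric(co), mask = mask)
}

#' DF/F for every ROI of a trace matrix
#' @param mat Matrix `frames x ROIs`.
#' @param frame_rate Frames per second.
#' @param ... Passed to [dff()].
#' @return Matrix of DF/F traces, same shape.
#' @export
dff_matrix <- function(mat, frame_rate, ...) {
  apply(mat, 2, function(tr) dff(tr, frame_rate, ...)$dff)
}

#' Event response of a DF/F trace
#'
#' `response = peak(dff in [t0, t0 + post)) - mean(dff in [t0 - pre, t0))`;
#' with `mode = "mean"` the post-window peak is replaced by its mean
#' (average signal change in the 10 s after the event start).
#'
#' @param dff_trace Numeric DF/F vector.
#' @param frame_rate Frames per second.
#' @param t0 Event time (s).
#' @param post,pre Window lengths (s), default 10 each.
#' @param mode `"peak"` (default) or `"mean"`.
#' @return Response (DF/F units); `NA` with a "truncated" attribute when the
#'   windows fall outside the trace.
#' @export
event_response <- function(dff_trace, frame_rate, t0, post = 10, pre = 10,
                           mode = c("peak", "mean")) {
  mode <- match.arg(mode)
  n <- length(dff_trace)
  i_pre0 <- floor((t0 - pre) * frame_rate) + 1
  i0 <- floor(t0 * frame_rate) + 1
  i_post1 <- floor((t0 + post) * frame_rate)
  if (i_pre0 < 1 || i_post1 > n) {
    return(structure(NA_real_, truncated = TRUE))
  }
  post_seg <- dff_trace[i0:i_post1]
  base <- mean(dff_trace[i_pre0:(i0 - 1)])
  (if (mode == "peak") max(post_seg) else mean(post_seg)) - base
}

#' Significance of event responses against a randomized-time-point null
#'
#' The null distribution is built from responses at `n_random` uniformly
#' random valid time points of the same session; an event is significant iff
#' its response strictly exceeds the 95th percentile of that null (the
#' ">95% of responses at randomly selected time points" criterion).
#'
#' @param dff_trace Numeric DF/F vector.
#' @param frame_rate Frames per second.
#' @param event_times Event times (s).
#' @param n_random Number of random probe points (>= 100; default 1000).
#' @param seed Integer seed for the probe draw.
#' @param exclude_near_events Exclude probes within +/- `post` of true
#'   events (default FALSE, the literal procedure).
#' @param post,pre,mode Passed to [event_response()].
#' @param prob Null percentile (default 0.95).
#' @return Tibble with `event_t0`, `response`, `significant`, `null_q`, plus
#'   the null responses in attribute `"null_responses"`.
#' @export
permutation_significance <- function(dff_trace, frame_rate, event_times,
                                     n_random = 1000, seed = NULL,
                                     exclude_near_events = FALSE,
                                     post = 10, pre = 10, mode = "peak",
                                     prob = 0.95) {
  stopifnot(n_random >= 100)
  if (!is.null(seed)) set.seed(seed)
  n <- length(dff_trace)
  t_max <- n / frame_rate - post
  if (t_max <= pre) stop("trace too short for response windows")
  draw <- function(m) stats::runif(m, pre, t_max)
  probes <- draw(n_random)
  if (exclude_near_events && length(event_times)) {
    for (it in 1:20) {
      bad <- vapply(probes, function(p)
        any(abs(p - event_times) < post), logical(1))
      if (!any(bad)) break
      probes[bad] <- draw(sum(bad))
    }
  }
  null_resp <- vapply(probes, function(p)
    event_response(dff_trace, frame_rate, p, post, pre, mode), numeric(1))
  q <- stats::quantile(null_resp, prob, na.rm = TRUE, names = FALSE)
  out <- tibble::tibble(
    event_t0 = event_times,
    response = vapply(event_times, function(t0)
      event_response(dff_trace, frame_rate, t0, post, pre, mode),
      numeric(1))) |>
    dplyr::mutate(significant = !is.na(.data$response) & .data$response > q,
                  null_q = q)
  attr(out, "null_responses") <- null_resp
  out
}

#' Evoked response relative to a 30 s pre-stimulation baseline
#'
#' `delta = peak(dff during the seizure window) - mean(dff in the 30 s
#' before stimulation start)`.
#'
#' @param dff_trace Numeric DF/F vector.
#' @param frame_rate Frames per second.
#' @param stim_start Stimulation start (s).
#' @param seizure_window `c(start, end)` of the seizure (s); required.
#' @param baseline_s Baseline length before `stim_start` (default 30 s).
#' @return Response delta (DF/F units).
#' @export
evoked_response <- function(dff_trace, frame_rate, stim_start,
                            seizure_window, baseline_s = 30) {
  if (missing(seizure_window) || is.null(seizure_window)) {
    stop("seizure window annotation required")
  }
  n <- length(dff_trace)
  ib0 <- floor((stim_start - baseline_s) * frame_rate) + 1
  if (ib0 < 1) stop("30 s pre-stimulation window unavailable")
  ib1 <- floor(stim_start * frame_rate)
  is0 <- floor(seizure_window[1] * frame_rate) + 1
  is1 <- min(n, floor(seizure_window[2] * frame_rate))
  max(dff_trace[is0:is1]) - mean(dff_trace[ib0:ib1])
}

#' Event-triggered average trace with per-timepoint SEM
#'
#' Segments of each DF/F trace around each event start are averaged;
#' truncated events (windows outside the trace) are excluded.
#'
#' @param dff_traces Numeric vector or list of vectors (e.g. sessions).
#' @param frame_rate Frames per second.
#' @param event_starts Event times (s) or list of per-trace event vectors.
#' @param window `c(pre, post)` seconds around the event start.
#' @return Tibble with `time_s` (0 = event start), `mean`, `sem`, `n`.
#' @export
align_average <- function(dff_traces, frame_rate, event_starts,
                          window = c(-10, 20)) {
  if (!is.list(dff_traces)) {
    dff_traces <- list(dff_traces)
    event_starts <- list(event_starts)
  }
  n_pre <- round(-window[1] * frame_rate)
  n_post <- round(window[2] * frame_rate)
  segs <- list()
  for (s in seq_along(dff_traces)) {
    tr <- dff_traces[[s]]
    for (t0 in event_starts[[s]]) {
      i0 <- floor(t0 * frame_rate) + 1
      idx <- (i0 - n_pre):(i0 + n_post - 1)
      if (idx[1] < 1 || idx[length(idx)] > length(tr)) next
      segs[[length(segs) + 1]] <- tr[idx]
    }
  }
  if (!length(segs)) stop("zero usable (non-truncated) events")
  M <- do.call(rbind, segs)
  tibble::tibble(
    time_s = (seq_len(ncol(M)) - 1 - n_pre) / frame_rate,
    mean = colMeans(M),
    sem = apply(M, 2, stats::sd) / sqrt(nrow(M)),
    n = nrow(M))
}

#' Regression of ACh on calcium event responses
#'
#' Ordinary least squares of paired per-event responses with Pearson
#' correlation and 95% confidence band.
#'
#' @param ach_responses,ca_responses Paired numeric vectors (n >= 3).
#' @return A `response_cor` object: `slope`, `intercept`, `r`, `p_value`,
#'   the fitted `lm`, and a confidence-band tibble. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @export
correlate_responses <- function(ach_responses, ca_responses) {
  ok <- stats::complete.cases(ach_responses, ca_responses)
  x <- ca_responses[ok]; y <- ach_responses[ok]
  if (length(x) < 3) stop("need at least 3 paired responses")
  if (stats::sd(x) == 0) stop("zero variance in calcium responses")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  grid <- tibble::tibble(x = seq(min(x), max(x), length.out = 100))
  band <- stats::predict(fit, newdata = grid, interval = "confidence",
                         level = 0.95)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = unname(ct$estimate), p_value = ct$p.value,
         n = length(x), fit = fit,
         band = dplyr::bind_cols(grid, tibble::as_tibble(band)),
         data = tibble::tibble(ca = x, ach = y)),
    class = "response_cor")
}

#' @export
print.response_cor <- function(x, ...) {
  cat(sprintf("ACh ~ Ca response regression: slope = %.3g, r = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$r, x$p_value, x$n))
  invisible(x)
}
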