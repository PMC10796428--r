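# Hippocampal LFP oscillation analysis: accelerometer-defined active periods,
# multitaper band power (theta 4-10, low gamma 20-55, high gamma 55-90 Hz)
# restricted to active periods, best-channel selection, and sharp-wave-ripple
# detection (90-200 Hz, 5 SD seed / 1 SD extension) with per-event features.

# ---- DPSS (Slepian) tapers --------------------------------------------------

# Discrete prolate spheroidal sequences from the standard symmetric
# tridiagonal formulation; eigenvectors of the tridiagonal matrix with
# diagonal ((N-1-2i)/2)^2 cos(2*pi*W) and off-diagonal i(N-i)/2.
dpss_env <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpss_env[[key]])) return(dpss_env[[key]])
  W <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # normalize and fix sign (positive mean for symmetric tapers)
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  }
  dpss_env[[key]] <- v
  v
}

# one-sided multitaper PSD of one window (density, units^2/Hz)
mt_psd_window <- function(x, fs, tapers) {
  n <- length(x)
  x <- x - mean(x)
  S <- rowMeans(sapply(seq_len(ncol(tapers)), function(j) {
    Mod(stats::fft(x * tapers[, j]))^2 / fs
  }))
  nf <- floor(n / 2) + 1
  S1 <- S[seq_len(nf)]
  if (n %% 2 == 0) S1[2:(nf - 1)] <- 2 * S1[2:(nf - 1)]
  else S1[2:nf] <- 2 * S1[2:nf]
  list(freq = (seq_len(nf) - 1) * fs / n, psd = S1)
}

#' Multitaper band power of an LFP trace
#'
#' Multitaper PSD (2 s windows, time-bandwidth 3, 5 tapers, 50% overlap by
#' default) integrated over the requested band and averaged across all
#' windows falling inside the supplied intervals (e.g. active periods). The
#' trace is decimated with an anti-alias filter before spectral analysis
#' when heavily oversampled for the band. A pure sinusoid of amplitude A in
#' the band integrates to A^2/2.
#'
#' @param x A [ts_signal()] or numeric vector.
#' @param band `c(low, high)` in Hz; must be below Nyquist.
#' @param intervals Optional tibble of `start`, `end` (s); default whole
#'   trace.
#' @param rate Sampling rate (Hz) for plain vectors.
#' @param window_s Window length (s).
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @param overlap Window overlap fraction.
#' @return Band power (signal units squared).
#' @export
multitaper_band_power <- function(x, band, intervals = NULL, rate = NULL,
                                  window_s = 2, nw = 3, k = 5,
                                  overlap = 0.5) {
  fs <- resolve_rate(x, rate)
  v <- ts_values(x)
  if (band[2] >= fs / 2) stop("band beyond Nyquist frequency")
  stopifnot(band[1] >= 0, band[2] > band[1])
  # decimate when oversampled; fixed floor keeps estimates comparable
  target <- max(250, 4 * band[2])
  fac <- max(1L, floor(fs / target))
  if (fac > 1) {
    d <- decimate_signal(v, fs, fac)
    v <- d$values; fs <- d$rate
  }
  nwin <- round(window_s * fs)
  if (length(v) < nwin) stop("trace shorter than one analysis window")
  tapers <- dpss_tapers(nwin, nw, k)
  ints <- intervals %||% intervals(0, length(v) / fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  powers <- c()
  for (r in seq_len(nrow(ints))) {
    i0 <- max(1L, floor(ints$start[r] * fs) + 1L)
    i1 <- min(length(v), floor(ints$end[r] * fs))
    if (i1 - i0 + 1 < nwin) next
    for (s in seq(i0, i1 - nwin + 1, by = step)) {
      sp <- mt_psd_window(v[s:(s + nwin - 1)], fs, tapers)
      df <- sp$freq[2] - sp$freq[1]
      idx <- sp$freq >= band[1] & sp$freq < band[2]
      powers <- c(powers, sum(sp$psd[idx]) * df)
    }
  }
  if (!length(powers)) stop("no interval long enough for one window")
  mean(powers)
}

#' Detect active (locomotion) periods from a 3-axis accelerometer
#'
#' Axes are high-pass filtered (gravity removed), combined as a vector-norm
#' motion magnitude, smoothed, and thresholded at a multiple of the
#' magnitude's noise floor (its median). Periods continuously elevated for
#' strictly more than `min_dur_s` (default 5 s) are active; brief
#' sub-threshold gaps below `max_gap_s` are bridged.
#'
#' @param accel 3-channel [ts_signal()].
#' @param min_dur_s Minimum continuous elevation (s, strict).
#' @param thresh_mult Threshold as a multiple of the smoothed-magnitude
#'   median (default 2).
#' @param smooth_s Smoothing window (s).
#' @param max_gap_s Sub-threshold gaps shorter than this are bridged (s).
#' @param hp_hz Gravity-removal high-pass cutoff (Hz).
#' @return Interval tibble of active periods; the complement is inactive.
#' @export
detect_active_periods <- function(accel, min_dur_s = 5, thresh_mult = 2,
                                  smooth_s = 0.25, max_gap_s = 0.5,
                                  hp_hz = 1) {
  stopifnot(inherits(accel, "ts_signal"), ncol(accel$values) == 3)
  fs <- accel$rate
  hp <- apply(accel$values, 2, function(ch) highpass(ch, hp_hz, rate = fs))
  mag <- sqrt(rowSums(hp^2))
  sm <- sqrt(moving_mean(mag^2, round(smooth_s * fs)))   # smoothed RMS
  thr <- thresh_mult * stats::median(sm)
  runs <- merge_intervals(mask_to_intervals(sm > thr, fs), max_gap_s)
  runs[runs$end - runs$start > min_dur_s, , drop = FALSE]
}

#' Complement of a set of intervals within a recording
#' @param int Interval tibble.
#' @param duration_s Recording duration (s).
#' @return Interval tibble covering `[0, duration_s)` minus `int`.
#' @export
complement_intervals <- function(int, duration_s) {
  if (is.null(int) || nrow(int) == 0) return(intervals(0, duration_s))
  int <- merge_intervals(int)
  starts <- c(0, int$end)
  ends <- c(int$start, duration_s)
  keep <- ends > starts
  intervals(starts[keep], ends[keep])
}

#' Select the analysis channel of a multichannel recording
#'
#' `mode = "theta"`: channel with the greatest 4-10 Hz multitaper power
#' (optionally restricted to active periods). `mode = "ripple"`: channel
#' with the greatest mean ripple amplitude. Ties go to the lowest index with
#' a message.
#'
#' @param x Multichannel [ts_signal()].
#' @param mode `"theta"` or `"ripple"`.
#' @param intervals Optional restriction intervals (active periods for
#'   theta; inactive for ripples).
#' @param ... Passed to [multitaper_band_power()] or [detect_ripples()].
#' @return Integer channel index, with the per-channel scores as attribute
#'   `"scores"`.
#' @export
select_channel <- function(x, mode = c("theta", "ripple"), intervals = NULL,
                           ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "ts_signal"))
  scores <- vapply(seq_len(ncol(x$values)), function(ch) {
    v <- x$values[, ch]
    if (mode == "theta") {
      multitaper_band_power(v, c(4, 10), intervals = intervals,
                            rate = x$rate, ...)
    } else {
      ev <- detect_ripples(v, inactive = intervals, rate = x$rate, ...)
      if (nrow(ev) == 0) 0 else mean(ev$mean_amplitude)
    }
  }, numeric(1))
  best <- which(scores == max(scores))
  if (length(best) > 1) message("channel tie; selecting lowest index")
  structure(best[1], scores = scores)
}

#' Detect sharp-wave ripples
#'
#' The trace is band-pass filtered 90-200 Hz; its Hilbert-envelope magnitude
#' is smoothed (10 ms). Events seed where the smoothed envelope rises more
#' than `seed_sd` (default 5) robust filtered-trace SDs beyond the envelope
#' noise floor (its median), and extend to the contiguous period where the
#' envelope stays more than `extend_sd` robust envelope-SDs above that
#' floor. Overlapping or abutting events merge, and events outside the
#' supplied inactive periods are discarded.
#'
#' @param x A [ts_signal()] or numeric vector.
#' @param inactive Interval tibble of immobility periods (default: whole
#'   trace).
#' @param rate Sampling rate (Hz) for plain vectors; >= 1000 required.
#' @param band Ripple band (Hz).
#' @param seed_sd Seed threshold in robust filtered-trace SD units.
#' @param extend_sd Extension threshold in robust envelope-SD units above
#'   the envelope median.
#' @param smooth_s Envelope smoothing (s).
#' @param edge_guard_s Events touching the first or last `edge_guard_s`
#'   seconds are discarded (filter and envelope edge transients).
#' @return Tibble of `ripple_event`s: `start`, `end`, `duration_s`,
#'   `intra_freq_hz`, `mean_amplitude`, `peak_sd`.
#' @export
detect_ripples <- function(x, inactive = NULL, rate = NULL,
                           band = c(90, 200), seed_sd = 5, extend_sd = 1,
                           smooth_s = 0.01, edge_guard_s = 0.1) {
  fs <- resolve_rate(x, rate)
  if (fs < 1000) stop("ripple detection requires rate >= 1000 Hz")
  v <- ts_values(x)
  filt <- bandpass(v, band[1], band[2], rate = fs)
  env <- analytic_envelope(filt)
  sm <- moving_mean(env, round(smooth_s * fs))
  sigma <- robust_sd(filt)
  floor_env <- stats::median(sm)
  seed_thr <- floor_env + seed_sd * sigma
  ext_thr <- floor_env + extend_sd * robust_sd(sm)

  above_ext <- sm > ext_thr
  r <- rle(above_ext)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ks <- which(r$values)
  evs <- purrr::map(ks, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    pk <- max(sm[i0:i1])
    if (pk <= seed_thr) return(NULL)
    tibble::tibble(start = (i0 - 1) / fs, end = i1 / fs,
                   peak_sd = pk / sigma)
  })
  evs <- dplyr::bind_rows(evs)
  if (nrow(evs) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          duration_s = numeric(), intra_freq_hz = numeric(),
                          mean_amplitude = numeric(), peak_sd = numeric()))
  }
  merged <- merge_intervals(evs[, c("start", "end")], max_gap = 0)
  dur <- length(v) / fs
  keep_edge <- merged$start >= edge_guard_s & merged$end <= dur - edge_guard_s
  evs_in <- function(i) evs$start < merged$end[i] & evs$end > merged$start[i]
  merged <- merged[keep_edge, , drop = FALSE]
  if (nrow(merged) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          duration_s = numeric(), intra_freq_hz = numeric(),
                          mean_amplitude = numeric(), peak_sd = numeric()))
  }
  merged$peak_sd <- vapply(seq_len(nrow(merged)), function(i) {
    max(evs$peak_sd[evs$start < merged$end[i] & evs$end > merged$start[i]])
  }, numeric(1))
  if (!is.null(inactive)) {
    ctr <- (merged$start + merged$end) / 2
    merged <- merged[in_intervals(ctr, inactive), , drop = FALSE]
  }
  feat <- purrr::map(seq_len(nrow(merged)), function(i) {
    ripple_features(filt, merged$start[i], merged$end[i], rate = fs,
                    band = band, prefiltered = TRUE)
  })
  merged |>
    dplyr::mutate(duration_s = .data$end - .data$start,
                  intra_freq_hz = purrr::map_dbl(feat, "intra_freq_hz"),
                  mean_amplitude = purrr::map_dbl(feat, "mean_amplitude")) |>
    dplyr::select("start", "end", "duration_s", "intra_freq_hz",
                  "mean_amplitude", "peak_sd")
}

#' Intra-ripple frequency and mean amplitude of one event
#'
#' Intra-ripple frequency is the PSD-peak frequency of the band-filtered
#' event segment by Welch's method (a single Hann-tapered segment when the
#' event is shorter than two segments); the mean amplitude is the average
#' Hilbert-envelope magnitude over the event. Events shorter than 3 cycles
#' at the low band edge return missing features.
#'
#' @param x Trace ([ts_signal()] or numeric); filtered already if
#'   `prefiltered = TRUE`.
#' @param start,end Event span (s).
#' @param rate Sampling rate for plain vectors.
#' @param band Ripple band (Hz).
#' @param prefiltered Set when `x` is already band-passed.
#' @return List with `intra_freq_hz` and `mean_amplitude` (NA when too
#'   short).
#' @export
ripple_features <- function(x, start, end, rate = NULL, band = c(90, 200),
                            prefiltered = FALSE) {
  fs <- resolve_rate(x, rate)
  v <- ts_values(x)
  if (!prefiltered) v <- bandpass(v, band[1], band[2], rate = fs)
  i0 <- max(1L, floor(start * fs) + 1L)
  i1 <- min(length(v), ceiling(end * fs))
  seg <- v[i0:i1]
  if (length(seg) / fs < 3 / band[1]) {
    return(list(intra_freq_hz = NA_real_, mean_amplitude = NA_real_))
  }
  sp <- welch_psd(seg, fs)
  idx <- sp$freq >= band[1] & sp$freq <= band[2]
  list(intra_freq_hz = sp$freq[idx][which.max(sp$psd[idx])],
       mean_amplitude = mean(analytic_envelope(seg)))
}

# Welch PSD: 50%-overlapping Hann segments; one segment if the signal is
# short
welch_psd <- function(x, fs, seg_len = NULL) {
  n <- length(x)
  if (is.null(seg_len)) seg_len <- if (n >= 512) 256 else n
  seg_len <- min(seg_len, n)
  step <- max(1L, seg_len %/% 2)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  wpow <- mean(w^2)
  starts <- seq(1, n - seg_len + 1, by = step)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- seg - mean(seg)
    acc <- acc + Mod(stats::fft(seg * w))^2 / (fs * seg_len * wpow)
  }
  S <- acc / length(starts)
  nf <- floor(seg_len / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / seg_len, psd = S[seq_len(nf)])
}
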