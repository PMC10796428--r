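#' Uniformly sampled signal container
#'
#' Lightweight container for a single- or multi-channel, uniformly sampled
#' signal (LFP/EEG, accelerometer axes, fluorescence clock-aligned traces).
#' Channels are columns; samples are rows.
#'
#' @param values Numeric vector (single channel) or matrix (samples x channels).
#' @param rate Sampling rate in Hz.
#' @param t0 Time of the first sample in seconds.
#' @param units Signal units label (informational).
#' @param channels Optional character vector of channel labels.
#' @return A `ts_signal` object.
#' @examples
#' x <- ts_signal(sin(2 * pi * 7 * seq(0, 1, by = 1e-3)), rate = 1000)
#' x
#' @export
ts_signal <- function(values, rate, t0 = 0, units = "a.u.", channels = NULL) {
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  stopifnot(is.numeric(rate), rate > 0, nrow(values) > 0)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(values)))
  stopifnot(length(channels) == ncol(values))
  structure(
    list(values = values, rate = rate, t0 = t0, units = units,
         channels = channels),
    class = "ts_signal"
  )
}

#' @export
print.ts_signal <- function(x, ...) {
  cat(sprintf("<ts_signal> %d samples x %d channel(s) @ %g Hz (%.3f s), units: %s\n",
              nrow(x$values), ncol(x$values), x$rate,
              nrow(x$values) / x$rate, x$units))
  invisible(x)
}

n_samples <- function(ts) nrow(ts$values)

ts_duration <- function(ts) n_samples(ts) / ts$rate

#' Sample times of a signal
#' @param ts A `ts_signal`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) ts$t0 + (seq_len(n_samples(ts)) - 1) / ts$rate

ts_values <- function(x, channel = 1) {
  if (inherits(x, "ts_signal")) x$values[, channel] else as.numeric(x)
}

resolve_rate <- function(x, rate) {
  if (inherits(x, "ts_signal")) x$rate
  else if (is.null(rate)) stop("`rate` must be supplied for plain numeric input")
  else rate
}

#' Convert a `ts_signal` to a tibble
#'
#' @param x A `ts_signal`.
#' @param ... Unused.
#' @return Tibble with `time_s` and one column per channel.
#' @importFrom tibble as_tibble
#' @method as_tibble ts_signal
#' @export
as_tibble.ts_signal <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  names(out) <- x$channels
  dplyr::bind_cols(tibble::tibble(time_s = ts_time(x)), out)
}

# ---- interval helpers (half-open [start, end) in seconds) -------------------

#' Build an interval table
#' @param start,end Numeric vectors of interval starts and ends (seconds).
#' @return Tibble with columns `start`, `end`.
#' @export
intervals <- function(start = numeric(), end = numeric()) {
  stopifnot(length(start) == length(end), all(end > start | length(start) == 0))
  tibble::tibble(start = as.numeric(start), end = as.numeric(end))
}

empty_intervals <- function() intervals()

# logical sample mask -> half-open intervals
mask_to_intervals <- function(mask, rate, t0 = 0) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  intervals(t0 + (starts[keep] - 1) / rate, t0 + ends[keep] / rate)
}

intervals_to_mask <- function(int, n, rate, t0 = 0) {
  mask <- logical(n)
  if (is.null(int) || nrow(int) == 0) return(mask)
  for (i in seq_len(nrow(int))) {
    i0 <- max(1L, floor((int$start[i] - t0) * rate) + 1L)
    i1 <- min(n, ceiling((int$end[i] - t0) * rate))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

# merge intervals whose gap is < max_gap (and any overlaps)
merge_intervals <- function(int, max_gap = 0) {
  if (nrow(int) < 2) return(int)
  int <- dplyr::arrange(int, .data$start)
  out_s <- int$start[1]; out_e <- int$end[1]
  s <- numeric(); e <- numeric()
  for (i in 2:nrow(int)) {
    if (int$start[i] - out_e < max_gap || int$start[i] <= out_e) {
      out_e <- max(out_e, int$end[i])
    } else {
      s <- c(s, out_s); e <- c(e, out_e)
      out_s <- int$start[i]; out_e <- int$end[i]
    }
  }
  intervals(c(s, out_s), c(e, out_e))
}

# are time points inside any interval?
in_intervals <- function(t, int) {
  if (is.null(int) || nrow(int) == 0) return(rep(FALSE, length(t)))
  vapply(t, function(ti) any(ti >= int$start & ti < int$end), logical(1))
}

interval_overlap <- function(a_start, a_end, b) {
  any(pmin(a_end, b$end) - pmax(a_start, b$start) > 0)
}

# ---- filtering and envelopes ------------------------------------------------

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase), with
#' reflected padding to suppress edge transients. DC is removed by the
#' pass-band itself.
#'
#' @param x A `ts_signal` or numeric vector.
#' @param low,high Band edges in Hz; `0 < low < high < rate / 2`.
#' @param rate Sampling rate in Hz (ignored when `x` is a `ts_signal`).
#' @param order Filter order (default 4).
#' @return Filtered signal, same type as `x`.
#' @export
bandpass <- function(x, low, high, rate = NULL, order = 4) {
  fs <- resolve_rate(x, rate)
  if (!(low > 0 && high > low && high < fs / 2)) {
    stop("invalid band: need 0 < low < high < rate/2")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  apply_zero_phase(x, bf, fs, pad_s = min(3 / low, 10))
}

highpass <- function(x, cutoff, rate = NULL, order = 2) {
  fs <- resolve_rate(x, rate)
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  apply_zero_phase(x, bf, fs, pad_s = min(3 / cutoff, 10))
}

lowpass <- function(x, cutoff, rate = NULL, order = 4) {
  fs <- resolve_rate(x, rate)
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  apply_zero_phase(x, bf, fs, pad_s = 1)
}

apply_zero_phase <- function(x, bf, fs, pad_s) {
  filt1 <- function(v) {
    n <- length(v)
    np <- min(n - 1, max(8L, round(pad_s * fs)))
    padded <- c(2 * v[1] - v[(np + 1):2], v, 2 * v[n] - v[(n - 1):(n - np)])
    out <- signal::filtfilt(bf, padded)
    out[(np + 1):(np + n)]
  }
  if (inherits(x, "ts_signal")) {
    x$values <- apply(x$values, 2, filt1)
    x
  } else {
    filt1(as.numeric(x))
  }
}

# magnitude of the analytic signal (FFT construction)
analytic_envelope <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# centered moving mean with shrinking edges (cumsum trick)
moving_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  half <- w %/% 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# MAD-scaled robust standard deviation
robust_sd <- function(x) stats::mad(x, na.rm = TRUE)

# integer-factor decimation with anti-alias lowpass
decimate_signal <- function(x, rate, factor) {
  factor <- as.integer(factor)
  if (factor <= 1) return(list(values = x, rate = rate))
  x <- lowpass(x, cutoff = 0.4 * rate / factor, rate = rate, order = 8)
  list(values = x[seq(1, length(x), by = factor)], rate = rate / factor)
}

# 1/f-amplitude ("pink") Gaussian noise, unit SD; uses the current RNG stream
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- seq(0, n - 1)
  f <- pmin(k, n - k) / n          # folded frequency in cycles/sample
  f[1] <- f[2]                      # avoid DC blow-up; DC zeroed below
  X <- X / sqrt(f / f[2])
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  x / stats::sd(x)
}

tukey_window <- function(n, taper_frac = 0.1) {
  taper_frac <- min(max(taper_frac, 0), 1)
  w <- rep(1, n)
  nt <- floor(taper_frac * n / 2)
  if (nt > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nt) / nt))
    w[seq_len(nt)] <- ramp
    w[(n - nt + 1):n] <- rev(ramp)
  }
  w
}
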