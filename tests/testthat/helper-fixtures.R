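# Shared fixtures and scoring helpers, all generated in code.

# score detected intervals against planted ground truth by positive overlap
score_intervals <- function(detected, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(pmin(detected$end, truth$end[i]) -
          pmax(detected$start, truth$start[i]) > 0)
  }, logical(1))
  false_pos <- vapply(seq_len(nrow(detected)), function(i) {
    !any(pmin(detected$end[i], truth$end) -
           pmax(detected$start[i], truth$start) > 0)
  }, logical(1))
  list(sensitivity = if (nrow(truth)) mean(hit) else NA_real_,
       n_false = sum(false_pos))
}

# planted-seizure session used by the detector tests: 10 seizures, 15 s each
seizure_session_plan <- function(n_seizures = 10, dur = 15, gap = 45,
                                 t0 = 30) {
  starts <- t0 + (seq_len(n_seizures) - 1) * (dur + gap)
  intervals(starts, starts + dur)
}

# expected band-power fraction of the pink-noise generator: the generating
# filter scales Fourier amplitudes by 1/sqrt(f), so the discrete variance
# fraction in a band is the ratio of 1/f bin sums (independent oracle for
# the simulated spectrum)
pink_band_fraction <- function(n, rate, low, high) {
  k <- seq(0, n - 1)
  f <- pmin(k, n - k) / n * rate
  p <- ifelse(f > 0, 1 / f, 0)
  sum(p[f >= low & f < high]) / sum(p)
}

# periodogram band power (plain FFT sum, independent of package internals)
periodogram_band_power <- function(x, rate, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n^2
  f <- (seq_len(n) - 1) * rate / n
  sum(p[f >= low & f < high | (rate - f) >= low & (rate - f) < high])
}
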