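# Electrically evoked seizure thresholds: escalation schedule, evoked-seizure
# classification (sustained >= 6 s elevated-amplitude signal with 2-4 Hz and
# 20-50 Hz components beginning < 10 s after stimulation), threshold
# extraction, and within-animal vehicle normalization.

#' Stimulation escalation schedule
#'
#' Amplitudes rise from 10 uA in 10 uA steps to 100 uA, then 20 uA steps to
#' 240 uA, then 30 uA steps, never exceeding `stop_uA` (400 uA).
#'
#' @param start_uA,stop_uA Schedule limits (uA).
#' @return Increasing numeric vector of stimulus amplitudes (uA).
#' @examples
#' stimulation_schedule()
#' @export
stimulation_schedule <- function(start_uA = 10, stop_uA = 400) {
  amps <- start_uA
  repeat {
    a <- amps[length(amps)]
    step <- if (a < 100) 10 else if (a < 240) 20 else 30
    nxt <- a + step
    if (nxt > stop_uA) break
    amps <- c(amps, nxt)
  }
  amps
}

#' Classify the post-stimulus LFP response as an evoked seizure
#'
#' A response is an evoked seizure when (a) the smoothed broadband amplitude
#' envelope stays above `k_env` robust SDs beyond the pre-stimulus baseline
#' envelope for at least `min_duration_s` contiguous seconds, (b) within that
#' period both the 2-4 Hz and the 20-50 Hz band powers exceed their baseline
#' values by at least `band_factor`, and (c) the elevation begins within
#' `onset_max_s` of stimulation end. The 1 s stimulus window is blanked, not
#' modeled.
#'
#' @param lfp A [ts_signal()] or numeric LFP trace.
#' @param stim_end_t Time stimulation ceased (s).
#' @param rate Sampling rate (Hz) for plain vectors.
#' @param stim_duration_s Stimulus-train duration blanked before
#'   `stim_end_t` (default 1 s).
#' @param baseline_s Pre-stimulus baseline length (default 30 s).
#' @param k_env Envelope threshold in baseline robust-SD units (default 3).
#' @param band_factor Required band-power elevation factor (default 4).
#' @param min_duration_s Minimum sustained duration (default 6 s).
#' @param onset_max_s Maximum latency from stimulation end (default 10 s).
#' @param band Broadband envelope band (Hz).
#' @param smooth_s Envelope smoothing window (s).
#' @return List with `is_seizure`, `onset_t`, `duration_s`.
#' @export
classify_evoked <- function(lfp, stim_end_t, rate = NULL,
                            stim_duration_s = 1, baseline_s = 30,
                            k_env = 3, band_factor = 4, min_duration_s = 6,
                            onset_max_s = 10, band = c(1, 50),
                            smooth_s = 0.5) {
  fs <- resolve_rate(lfp, rate)
  v <- ts_values(lfp)
  n <- length(v)
  t <- (seq_len(n) - 1) / fs
  if (stim_end_t <= 0 || stim_end_t >= n / fs) stop("stim_end outside trace")
  stim_start_t <- stim_end_t - stim_duration_s
  # blank the stimulus artifact (plus a small guard band)
  blank <- t >= stim_start_t - 0.05 & t < stim_end_t + 0.05
  v[blank] <- 0

  filt <- bandpass(v, band[1], band[2], rate = fs)
  env <- moving_mean(abs(filt), round(smooth_s * fs))
  base_idx <- t >= max(0, stim_start_t - baseline_s) & t < stim_start_t
  thr <- stats::median(env[base_idx]) + k_env * robust_sd(env[base_idx])

  post <- which(t >= stim_end_t + 0.05)
  above <- env[post] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= round(min_duration_s * fs))
  no <- list(is_seizure = FALSE, onset_t = NA_real_, duration_s = NA_real_)
  for (k in runs) {
    onset <- t[post[starts[k]]]
    if (onset - stim_end_t >= onset_max_s) next
    i0 <- post[starts[k]]; i1 <- post[ends[k]]
    bp_ev <- band_power_fft(v[i0:i1], fs, list(c(2, 4), c(20, 50)))
    bidx <- which(base_idx)
    bp_base <- band_power_fft(v[bidx], fs, list(c(2, 4), c(20, 50)))
    if (all(bp_ev > band_factor * pmax(bp_base, 1e-24))) {
      return(list(is_seizure = TRUE, onset_t = onset,
                  duration_s = (i1 - i0 + 1) / fs))
    }
  }
  no
}

# mean power spectral density integrated over bands, plain periodogram
band_power_fft <- function(x, fs, bands) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x * tukey_window(n, 0.2))
  # compensate taper power loss
  wpow <- mean(tukey_window(n, 0.2)^2)
  p <- Mod(X)^2 / (n^2 * wpow)
  f <- (seq_len(n) - 1) * fs / n
  vapply(bands, function(b) {
    idx <- f >= b[1] & f < b[2]
    2 * sum(p[idx])
  }, numeric(1))
}

#' Seizure threshold of an escalating stimulation session
#'
#' Classifies the response to each stimulus and returns the first amplitude
#' whose response is an evoked seizure; `NA` (censored) if none by the end
#' of the schedule.
#'
#' @param lfp Session LFP ([ts_signal()]).
#' @param stim_table Tibble with `amplitude_uA` and `stim_end_t` (s), in
#'   escalation order.
#' @param ... Passed to [classify_evoked()].
#' @return List with `threshold_uA` (NA if censored), `duration_s` of the
#'   threshold seizure, and the per-trial classification tibble `trials`.
#' @export
find_threshold <- function(lfp, stim_table, ...) {
  stopifnot(all(c("amplitude_uA", "stim_end_t") %in% names(stim_table)))
  trials <- stim_table |>
    dplyr::rowwise() |>
    dplyr::mutate(cls = list(classify_evoked(lfp, .data$stim_end_t, ...))) |>
    dplyr::ungroup() |>
    dplyr::mutate(is_seizure = purrr::map_lgl(.data$cls, "is_seizure"),
                  duration_s = purrr::map_dbl(.data$cls, "duration_s")) |>
    dplyr::select(-"cls")
  hit <- which(trials$is_seizure)[1]
  list(threshold_uA = if (is.na(hit)) NA_real_ else trials$amplitude_uA[hit],
       duration_s = if (is.na(hit)) NA_real_ else trials$duration_s[hit],
       trials = trials)
}

#' Within-animal vehicle-normalized threshold (or duration) shifts
#'
#' Replicate trials are first averaged within animal and treatment; the
#' shift is then the drug value divided by the vehicle value of the same
#' animal (ratio, the default) or their difference.
#'
#' @param df Tibble with `animal`, `treatment` (must contain `"vehicle"` and
#'   one drug level) and `value` columns.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return Tibble with one row per animal: `vehicle`, `drug`, `shift`.
#' @export
normalize_shift <- function(df, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(all(c("animal", "treatment", "value") %in% names(df)))
  wide <- df |>
    dplyr::group_by(.data$animal, .data$treatment) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(role = ifelse(.data$treatment == "vehicle",
                                "vehicle", "drug")) |>
    dplyr::select(-"treatment") |>
    tidyr::pivot_wider(names_from = "role", values_from = "value")
  if (!"vehicle" %in% names(wide) || any(is.na(wide$vehicle))) {
    stop("missing vehicle value for at least one animal")
  }
  dplyr::mutate(wide, shift = if (mode == "ratio")
    .data$drug / .data$vehicle else .data$drug - .data$vehicle)
}
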