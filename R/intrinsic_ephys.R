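# Intrinsic-excitability metrics from current-clamp sweeps: AP detection with
# a dV/dt threshold rule, AP width at half-height (100 kHz resampling),
# input resistance, ramp rheobase with the 500 pA no-spike assignment, RMP,
# QC exclusion rules, and drug time-binned summaries.

#' Detect action potentials and per-event thresholds
#'
#' Events are detected where dV/dt exceeds `detect_dvdt` (mV/ms) on the way
#' to a voltage peak. The per-event threshold is the voltage at the first
#' sample of the contiguous run, ending at the peak, where dV/dt exceeds
#' 3x the SD of dV/dt over the quiescent pre-injection segment of the sweep.
#'
#' @param voltage A [ts_signal()] or numeric vector (mV).
#' @param rate Sampling rate (Hz, >= 10000) for plain vectors.
#' @param baseline_window Quiescent window `c(start, end)` in seconds used
#'   for the dV/dt SD (default the first 0.5 s).
#' @param detect_dvdt Event-detection dV/dt level, mV/ms (default 20).
#' @param thresh_sd_mult Multiplier of the quiescent dV/dt SD defining the
#'   threshold localization rule (default 3).
#' @param min_isi_s Minimum separation between detected events (s).
#' @return Tibble with `t_peak`, `i_peak`, `v_peak`, `t_thresh`, `v_thresh`.
#' @export
detect_aps <- function(voltage, rate = NULL, baseline_window = c(0, 0.5),
                       detect_dvdt = 20, thresh_sd_mult = 3,
                       min_isi_s = 0.002) {
  fs <- resolve_rate(voltage, rate)
  v <- ts_values(voltage)
  if (all(is.na(v))) stop("all-NaN voltage trace")
  n <- length(v)
  t <- (seq_len(n) - 1) / fs
  dvdt <- c(0, diff(v)) * fs / 1000          # mV/ms
  qidx <- t >= baseline_window[1] & t < baseline_window[2]
  sd_q <- stats::sd(dvdt[qidx])
  loc_level <- thresh_sd_mult * sd_q

  fast <- dvdt > detect_dvdt
  # sustained for 2 samples to reject single-sample noise
  fast <- fast & c(fast[-1], FALSE)
  r <- rle(fast)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  starts <- run_start[r$values]

  out <- list()
  last_t <- -Inf
  for (s in starts) {
    # advance to the voltage peak: first sample where dvdt turns negative
    i <- s
    while (i < n && dvdt[i + 1] > 0) i <- i + 1
    if (t[i] - last_t < min_isi_s) next
    last_t <- t[i]
    # walk back through the contiguous dvdt > loc_level run to its onset;
    # dvdt[j] is the step from sample j-1 to j, so the voltage before the
    # first supra-level step is v[j - 1]
    j <- i
    while (j > 2 && dvdt[j - 1] > loc_level) j <- j - 1
    out[[length(out) + 1]] <- tibble::tibble(
      t_peak = t[i], i_peak = i, v_peak = v[i],
      t_thresh = t[j - 1], v_thresh = v[j - 1])
  }
  if (!length(out)) {
    return(tibble::tibble(t_peak = numeric(), i_peak = integer(),
                          v_peak = numeric(), t_thresh = numeric(),
                          v_thresh = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Action-potential width at half-height
#'
#' The spike segment is resampled to 100 kHz (spline interpolation) and the
#' width is the time the voltage exceeds the half-height between the event's
#' threshold and peak voltages.
#'
#' @param voltage A [ts_signal()] or numeric vector (mV).
#' @param spike One row of [detect_aps()] output (or a list with `i_peak`,
#'   `v_peak`, `v_thresh`).
#' @param rate Sampling rate (Hz) for plain vectors.
#' @param resample_hz Resampling rate, default 1e5.
#' @param window_s Half-window around the peak to consider (s).
#' @return Width in milliseconds.
#' @export
ap_width <- function(voltage, spike, rate = NULL, resample_hz = 1e5,
                     window_s = 0.005) {
  fs <- resolve_rate(voltage, rate)
  v <- ts_values(voltage)
  if (spike$v_peak <= spike$v_thresh) stop("spike peak <= threshold")
  i0 <- max(1L, spike$i_peak - round(window_s * fs))
  i1 <- min(length(v), spike$i_peak + round(window_s * fs))
  t_seg <- (i0:i1 - 1) / fs
  fine_t <- seq(t_seg[1], t_seg[length(t_seg)], by = 1 / resample_hz)
  fine_v <- stats::spline(t_seg, v[i0:i1], xout = fine_t)$y
  half <- (spike$v_thresh + spike$v_peak) / 2
  above <- fine_v >= half
  # contiguous run containing the peak
  ip <- which.min(abs(fine_t - (spike$i_peak - 1) / fs))
  if (!above[ip]) ip <- which.max(fine_v)
  a <- ip; while (a > 1 && above[a - 1]) a <- a - 1
  b <- ip; while (b < length(above) && above[b + 1]) b <- b + 1
  (b - a + 1) / resample_hz * 1000
}

#' Classify a cell as putative fast-spiking from its AP width
#' @param width_ms AP width(s) in ms.
#' @return Logical; widths of 1 ms or less are putative fast-spiking
#'   interneurons.
#' @export
is_fast_spiking <- function(width_ms) width_ms <= 1

#' Input resistance from hyperpolarizing step(s)
#'
#' `R_in = dV_steady / dI`, with the steady state taken as the mean over the
#' last 25% of each hyperpolarizing step and the reference as the mean over
#' the 100 ms immediately preceding the step. For the step-series protocol
#' the estimate is averaged across the four hyperpolarizing steps.
#'
#' @param sweep List with `voltage` ([ts_signal()] or numeric, mV), `current`
#'   (pA command vector) and optionally `meta`.
#' @param rate Sampling rate (Hz) if `voltage` is a plain vector.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweep, rate = NULL) {
  fs <- resolve_rate(sweep$voltage, rate)
  v <- ts_values(sweep$voltage)
  cur <- sweep$current
  stopifnot(length(v) == length(cur))
  steps <- constant_current_steps(cur, fs)
  steps <- steps[steps$level < 0, , drop = FALSE]
  if (nrow(steps) == 0) stop("no hyperpolarizing current step in command")
  est <- vapply(seq_len(nrow(steps)), function(k) {
    i0 <- steps$i0[k]; i1 <- steps$i1[k]
    n_ss <- max(1L, round(0.25 * (i1 - i0 + 1)))
    v_ss <- mean(v[(i1 - n_ss + 1):i1])
    pre0 <- max(1L, i0 - round(0.1 * fs))
    v_pre <- mean(v[pre0:(i0 - 1)])
    (v_ss - v_pre) / steps$level[k] * 1000   # mV/pA -> MOhm
  }, numeric(1))
  mean(est)
}

# runs of constant nonzero current lasting >= 50 ms (excludes ramps)
constant_current_steps <- function(cur, fs, min_s = 0.05, tol = 1e-9) {
  d <- c(0, diff(cur))
  const <- abs(d) < tol & abs(cur) > tol
  r <- rle(const)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= round(min_s * fs)
  tibble::tibble(i0 = starts[keep], i1 = ends[keep],
                 level = cur[starts[keep]])
}

#' Rheobase from the ramp segment of a sweep
#'
#' The rheobase is the command current being delivered at the first AP
#' evoked during the ramp; sweeps with no detected ramp APs are assigned
#' 500 pA. Spikes occurring before ramp onset are flagged and excluded.
#'
#' @param sweep List with `voltage`, `current` and `meta` (needs
#'   `ramp_start_s`, `ramp_end_s` or a detectable ramp).
#' @param spikes Optional precomputed [detect_aps()] table.
#' @param no_spike_pA Value assigned when no ramp AP is detected (500 pA).
#' @param rate Sampling rate (Hz) for plain-vector voltage.
#' @return List with `rheobase_pA`, `n_ramp_spikes`, `flagged_pre_ramp`.
#' @export
rheobase_from_ramp <- function(sweep, spikes = NULL, no_spike_pA = 500,
                               rate = NULL) {
  fs <- resolve_rate(sweep$voltage, rate)
  if (!is.null(sweep$meta$ramp_start_s)) {
    r0 <- sweep$meta$ramp_start_s; r1 <- sweep$meta$ramp_end_s
  } else {
    ramp <- detect_ramp(sweep$current, fs)
    r0 <- ramp[1]; r1 <- ramp[2]
  }
  if (is.null(spikes)) spikes <- detect_aps(sweep$voltage, rate = fs)
  pre <- spikes$t_thresh < r0
  ramp_spikes <- spikes[!pre & spikes$t_thresh < r1, , drop = FALSE]
  if (nrow(ramp_spikes) == 0) {
    return(list(rheobase_pA = no_spike_pA, n_ramp_spikes = 0L,
                flagged_pre_ramp = sum(pre)))
  }
  i_first <- round(ramp_spikes$t_thresh[1] * fs) + 1
  list(rheobase_pA = sweep$current[i_first],
       n_ramp_spikes = nrow(ramp_spikes),
       flagged_pre_ramp = sum(pre))
}

# longest monotone-increasing command segment
detect_ramp <- function(cur, fs) {
  d <- diff(cur)
  inc <- d > 1e-12
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  if (!length(cand)) stop("no ramp found in command waveform")
  k <- cand[which.max(r$lengths[cand])]
  c(starts[k] - 1, ends[k]) / fs
}

#' Resting membrane potential
#'
#' Mean voltage over the 500 ms window immediately preceding the first
#' current injection of the sweep.
#'
#' @param sweep List with `voltage` and `current`.
#' @param window_s Required pre-injection window length (default 0.5 s).
#' @param rate Sampling rate (Hz) for plain-vector voltage.
#' @return RMP in mV.
#' @export
rmp <- function(sweep, window_s = 0.5, rate = NULL) {
  fs <- resolve_rate(sweep$voltage, rate)
  v <- ts_values(sweep$voltage)
  first_inj <- which(abs(sweep$current) > 1e-9)[1]
  if (is.na(first_inj)) first_inj <- length(v) + 1L
  if ((first_inj - 1) / fs < window_s) {
    stop("pre-injection segment shorter than ", window_s, " s")
  }
  i1 <- first_inj - 1L
  mean(v[(i1 - round(window_s * fs) + 1):i1])
}

#' Quality-control filter for cells and sweeps
#'
#' Cell-level exclusions: no APs detected in the initial sweep, or input
#' resistance above `r_in_max` (default 500 MOhm). Sweep-level exclusion:
#' RMP above `rmp_max` (default -40 mV).
#'
#' @param cells Tibble with `cell_id`, `aps_initial_sweep`, `r_in`.
#' @param sweeps Tibble with `cell_id`, `sweep`, `rmp`.
#' @param r_in_max,rmp_max Exclusion limits (MOhm, mV).
#' @return List with `cells` and `sweeps` (retained rows) and `exclusions`
#'   (tibble of level, id and reason).
#' @export
qc_filter <- function(cells, sweeps, r_in_max = 500, rmp_max = -40) {
  bad_cells <- cells |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$aps_initial_sweep == 0 ~ "no APs in initial sweep",
      .data$r_in > r_in_max ~ sprintf("R_in > %g MOhm", r_in_max),
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$reason))
  keep_cells <- dplyr::anti_join(cells, bad_cells, by = "cell_id")
  sweeps2 <- dplyr::semi_join(sweeps, keep_cells, by = "cell_id")
  bad_sweeps <- sweeps2 |>
    dplyr::filter(.data$rmp > rmp_max) |>
    dplyr::mutate(reason = sprintf("RMP > %g mV", rmp_max))
  keep_sweeps <- dplyr::anti_join(sweeps2, bad_sweeps,
                                  by = c("cell_id", "sweep"))
  exclusions <- dplyr::bind_rows(
    dplyr::transmute(bad_cells, level = "cell", id = .data$cell_id,
                     reason = .data$reason),
    dplyr::transmute(bad_sweeps, level = "sweep",
                     id = paste(.data$cell_id, .data$sweep, sep = "/"),
                     reason = .data$reason))
  list(cells = keep_cells, sweeps = keep_sweeps, exclusions = exclusions)
}

#' Time-binned drug-response summary of per-sweep metrics
#'
#' Per-neuron metric means in the bins Baseline = [-60, 0) s, Drug =
#' [60, 180) s and Wash = [480 s, end) relative to drug onset; AP counts are
#' additionally normalized to the neuron's Baseline mean. Empty bins give
#' missing values, not zeros.
#'
#' @param metrics Tibble with `cell_id`, `t_s` (sweep time, s) and metric
#'   columns; `ap_count` (if present) is normalized.
#' @param t_drug_onset Drug-application time (s) on the same clock as `t_s`.
#' @param bins Named list of half-open bins in seconds relative to onset.
#' @return Tibble, one row per neuron x bin, with per-metric means and
#'   `norm_ap_count` when applicable.
#' @export
time_bin_summary <- function(metrics, t_drug_onset,
                             bins = list(Baseline = c(-60, 0),
                                         Drug = c(60, 180),
                                         Wash = c(480, Inf))) {
  stopifnot(all(c("cell_id", "t_s") %in% names(metrics)))
  value_cols <- setdiff(names(metrics), c("cell_id", "t_s", "sweep"))
  rel <- metrics$t_s - t_drug_onset
  metrics$bin <- NA_character_
  for (b in names(bins)) {
    metrics$bin[rel >= bins[[b]][1] & rel < bins[[b]][2]] <- b
  }
  out <- metrics |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$cell_id, .data$bin) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::complete(cell_id = unique(metrics$cell_id), bin = names(bins)) |>
    dplyr::mutate(bin = factor(.data$bin, levels = names(bins)))
  if ("ap_count" %in% value_cols) {
    out <- out |>
      dplyr::group_by(.data$cell_id) |>
      dplyr::mutate(norm_ap_count = .data$ap_count /
                      .data$ap_count[.data$bin == "Baseline"]) |>
      dplyr::ungroup()
  }
  dplyr::arrange(out, .data$cell_id, .data$bin)
}

#' Per-dose normalized firing frequency for cultured neurons
#'
#' For each 90 s dose epoch, APs inside a stable 60 s sub-window are counted
#' and divided by 60 to give a firing frequency, which is then normalized to
#' the baseline-epoch frequency. The stable window is the 60 s sub-window
#' minimizing holding-current drift (range of the holding trace) when a
#' holding signal is supplied; otherwise it is centred in the epoch.
#'
#' @param spike_times Numeric vector of AP times (s).
#' @param epochs Tibble with `dose_uM` (0 or NA = baseline), `start_s`,
#'   `end_s`.
#' @param holding Optional holding-current [ts_signal()] used to pick the
#'   stable window.
#' @param window_s Counting-window length (default 60 s).
#' @return Tibble with `dose_uM`, `window_start_s`, `freq_hz`, `norm_freq`.
#'   Normalization to a zero baseline frequency is flagged as `NA` with a
#'   warning.
#' @export
culture_ap_frequency <- function(spike_times, epochs, holding = NULL,
                                 window_s = 60) {
  stopifnot(all(c("dose_uM", "start_s", "end_s") %in% names(epochs)))
  pick_window <- function(s0, s1) {
    if (s1 - s0 <= window_s) return(s0)
    if (is.null(holding)) return(s0 + (s1 - s0 - window_s) / 2)
    h <- ts_values(holding); fs <- holding$rate
    cand <- seq(s0, s1 - window_s, by = 1)
    drift <- vapply(cand, function(w0) {
      seg <- h[(round(w0 * fs) + 1):min(length(h), round((w0 + window_s) * fs))]
      diff(range(seg))
    }, numeric(1))
    cand[which.min(drift)]
  }
  out <- epochs |>
    dplyr::rowwise() |>
    dplyr::mutate(window_start_s = pick_window(.data$start_s, .data$end_s),
                  freq_hz = sum(spike_times >= .data$window_start_s &
                                  spike_times < .data$window_start_s +
                                  window_s) /
                    min(window_s, .data$end_s - .data$start_s)) |>
    dplyr::ungroup()
  is_base <- is.na(out$dose_uM) | out$dose_uM == 0
  base_freq <- mean(out$freq_hz[is_base])
  if (!is.finite(base_freq) || base_freq == 0) {
    warning("baseline firing frequency is zero; normalization undefined")
    base_freq <- NA_real_
  }
  dplyr::mutate(out, norm_freq = .data$freq_hz / base_freq)
}

#' Full metric set for one step-plus-ramp sweep
#'
#' Convenience wrapper computing RMP, input resistance, ramp rheobase, AP
#' count and first-AP threshold/width for a single sweep.
#'
#' @param sweep A sweep as produced by [make_patch_sweep()]`$sweep`.
#' @return One-row tibble of sweep metrics.
#' @export
sweep_metrics <- function(sweep) {
  fs <- sweep$voltage$rate
  spikes <- detect_aps(sweep$voltage)
  rb <- rheobase_from_ramp(sweep, spikes = spikes)
  w <- if (nrow(spikes) > 0) {
    ap_width(sweep$voltage, spikes[1, ])
  } else NA_real_
  tibble::tibble(
    rmp = rmp(sweep),
    r_in = input_resistance(sweep),
    rheobase_pA = rb$rheobase_pA,
    ap_count = nrow(spikes),
    ap_threshold = if (nrow(spikes)) spikes$v_thresh[1] else NA_real_,
    ap_width_ms = w,
    fast_spiking = if (is.na(w)) NA else is_fast_spiking(w))
}
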