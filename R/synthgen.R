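# Synthetic-data generators. Every generator plants ground truth and returns
# it alongside the data so downstream detectors can be scored exactly.

# stereotyped interictal spike: sharp positive deflection with a slower
# opposite after-wave; peak amplitude exactly 1
interictal_waveform <- function(rate, sigma_s = 0.005) {
  t <- seq(-6 * sigma_s, 12 * sigma_s, by = 1 / rate)
  w <- exp(-t^2 / (2 * sigma_s^2)) -
    0.35 * exp(-(t - 2.4 * sigma_s)^2 / (2 * (2 * sigma_s)^2))
  w / max(w)
}

# add `amp * wave` into x centred so the waveform peak lands at index i0
add_waveform <- function(x, i0, wave, amp) {
  ipk <- which.max(wave)
  idx <- (i0 - ipk + 1):(i0 - ipk + length(wave))
  ok <- idx >= 1 & idx <= length(x)
  x[idx[ok]] <- x[idx[ok]] + amp * wave[ok]
  x
}

#' Simulate an LFP trace with planted seizures, spikes, ripples and states
#'
#' Background is 1/f ("pink") Gaussian noise scaled to `noise_sd` (white
#' optional). Planted component amplitudes are expressed in multiples of the
#' background SD *within the component's detection band* (1-50 Hz for
#' interictal/seizure spikes and the 35 Hz component, 90-200 Hz for
#' ripples), so an "8 SD" event is 8 SD in the units the detectors
#' threshold on. Components:
#' * seizures: spike-and-wave at 3 Hz - a mildly amplitude-modulated train
#'   of epileptiform spikes (default 8x SD) riding a 3 Hz slow wave (default
#'   4x SD) - plus a 35 Hz narrowband component (default 4x SD), the
#'   electrographic signature of evoked and spontaneous hippocampal seizures
#'   (rhythmic 2-4 Hz bursting with a 20-50 Hz component);
#' * isolated interictal spikes;
#' * ripples: Tukey-windowed 90-200 Hz sinusoid packets;
#' * oscillation epochs (e.g. theta during locomotion): windowed sinusoids.
#'
#' @param duration_s Recording duration (s).
#' @param rate_hz Sampling rate in Hz (>= 1000).
#' @param noise_sd Background SD in signal units.
#' @param seizure_plan Tibble with `start`, `end` (s); pairwise disjoint.
#' @param spike_plan Tibble with `time` (s) and optional `amp` (SD units,
#'   default 8).
#' @param ripple_plan Tibble with `time` (packet centre, s) and optional
#'   `duration` (s, default 0.08), `freq` (Hz, default 150), `amp`
#'   (SD units, default 8).
#' @param oscillation_plan Tibble with `start`, `end`, `freq` (Hz), `amp`
#'   (SD units).
#' @param noise_color `"pink"` (default) or `"white"`.
#' @param seizure_amp,seizure_slow_amp,seizure_fast_amp Spike-train, 3 Hz
#'   slow-wave and 35 Hz component amplitudes of planted seizures, in
#'   detection-band background-SD units.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return List with `signal` (a [ts_signal()]) and `truth` (ground-truth
#'   list: `seizure_intervals`, `spike_times`, `ripple_events`,
#'   `oscillation_intervals`, `noise_sd`).
#' @examples
#' sim <- make_lfp(60, 1000, seizure_plan = intervals(10, 30), seed = 1)
#' nrow(sim$truth$seizure_intervals)
#' @export
make_lfp <- function(duration_s, rate_hz = 1000, noise_sd = 1,
                     seizure_plan = NULL, spike_plan = NULL,
                     ripple_plan = NULL, oscillation_plan = NULL,
                     noise_color = c("pink", "white"),
                     seizure_amp = 8, seizure_slow_amp = 4,
                     seizure_fast_amp = 4, seed = NULL) {
  noise_color <- match.arg(noise_color)
  stopifnot(duration_s > 0, rate_hz >= 1000)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * rate_hz)

  check_in <- function(t, what) {
    if (any(t < 0 | t >= duration_s)) {
      stop(sprintf("%s outside recording duration", what))
    }
  }
  if (!is.null(seizure_plan) && nrow(seizure_plan) > 0) {
    check_in(seizure_plan$start, "seizure"); check_in(seizure_plan$end - 1e-9, "seizure")
    sp <- dplyr::arrange(seizure_plan, .data$start)
    if (nrow(sp) > 1 && any(sp$start[-1] < sp$end[-nrow(sp)])) {
      stop("planted seizures overlap")
    }
    seizure_plan <- sp
  }
  if (!is.null(spike_plan) && nrow(spike_plan) > 0) check_in(spike_plan$time, "spike")
  if (!is.null(ripple_plan) && nrow(ripple_plan) > 0) check_in(ripple_plan$time, "ripple")

  x <- noise_sd * (if (noise_color == "pink") pink_noise(n) else stats::rnorm(n))
  tt <- (seq_len(n) - 1) / rate_hz
  iis <- interictal_waveform(rate_hz)
  # background SD in each detection band, so planted amplitudes are in the
  # units the detectors threshold on
  need_spk <- (!is.null(spike_plan) && nrow(spike_plan) > 0) ||
    (!is.null(seizure_plan) && nrow(seizure_plan) > 0)
  sd_spk <- if (need_spk) {
    # compensate the spike waveform's attenuation through the detection
    # band, so a planted "8 SD" spike peaks at ~8 band-SDs after filtering
    wpad <- c(numeric(round(0.5 * rate_hz)), iis,
              numeric(round(0.5 * rate_hz)))
    att <- max(abs(bandpass(wpad, 1, 50, rate = rate_hz)))
    robust_sd(bandpass(x, 1, 50, rate = rate_hz)) / att
  } else NA_real_
  sd_rip <- if ((!is.null(ripple_plan) && nrow(ripple_plan) > 0) &&
                rate_hz / 2 > 200) {
    robust_sd(bandpass(x, 90, 200, rate = rate_hz))
  } else NA_real_

  spike_times <- numeric(0)
  if (!is.null(spike_plan) && nrow(spike_plan) > 0) {
    amp <- if ("amp" %in% names(spike_plan)) spike_plan$amp else rep(8, nrow(spike_plan))
    for (i in seq_len(nrow(spike_plan))) {
      i0 <- round(spike_plan$time[i] * rate_hz) + 1
      x <- add_waveform(x, i0, iis, amp[i] * sd_spk)
    }
    spike_times <- spike_plan$time
  }

  seizure_intervals <- empty_intervals()
  if (!is.null(seizure_plan) && nrow(seizure_plan) > 0) {
    for (i in seq_len(nrow(seizure_plan))) {
      s0 <- seizure_plan$start[i]; s1 <- seizure_plan$end[i]
      st <- seq(s0 + 0.05, s1 - 0.05, by = 1 / 3)
      mod <- 0.8 + 0.2 * sin(2 * pi * 0.8 * (st - s0))   # mild AM, stays >= 6x SD
      for (k in seq_along(st)) {
        x <- add_waveform(x, round(st[k] * rate_hz) + 1, iis,
                          seizure_amp * mod[k] * sd_spk)
      }
      idx <- which(tt >= s0 & tt < s1)
      win <- tukey_window(length(idx), 0.1)
      # slow wave phase-locked so its peaks coincide with the spikes
      x[idx] <- x[idx] + seizure_slow_amp * sd_spk * win *
        cos(2 * pi * 3 * (tt[idx] - s0 - 0.05))
      x[idx] <- x[idx] + seizure_fast_amp * sd_spk * win *
        sin(2 * pi * 35 * tt[idx])
    }
    seizure_intervals <- intervals(seizure_plan$start, seizure_plan$end)
  }

  ripple_events <- tibble::tibble(start = numeric(), end = numeric(),
                                  freq = numeric(), amplitude = numeric())
  if (!is.null(ripple_plan) && nrow(ripple_plan) > 0) {
    dur <- if ("duration" %in% names(ripple_plan)) ripple_plan$duration else rep(0.08, nrow(ripple_plan))
    frq <- if ("freq" %in% names(ripple_plan)) ripple_plan$freq else rep(150, nrow(ripple_plan))
    amp <- if ("amp" %in% names(ripple_plan)) ripple_plan$amp else rep(8, nrow(ripple_plan))
    for (i in seq_len(nrow(ripple_plan))) {
      s0 <- ripple_plan$time[i] - dur[i] / 2
      idx <- which(tt >= s0 & tt < s0 + dur[i])
      # 20 ms tapers so the envelope edge sits close to the planted extent
      x[idx] <- x[idx] + amp[i] * sd_rip *
        tukey_window(length(idx), min(0.5, 2 * 0.02 / dur[i])) *
        sin(2 * pi * frq[i] * (tt[idx] - s0))
    }
    ripple_events <- tibble::tibble(start = ripple_plan$time - dur / 2,
                                    end = ripple_plan$time + dur / 2,
                                    freq = frq, amplitude = amp * sd_rip)
  }

  oscillation_intervals <- empty_intervals()
  if (!is.null(oscillation_plan) && nrow(oscillation_plan) > 0) {
    for (i in seq_len(nrow(oscillation_plan))) {
      idx <- which(tt >= oscillation_plan$start[i] & tt < oscillation_plan$end[i])
      x[idx] <- x[idx] + oscillation_plan$amp[i] * noise_sd *
        tukey_window(length(idx), 0.1) *
        sin(2 * pi * oscillation_plan$freq[i] * tt[idx])
    }
    oscillation_intervals <- intervals(oscillation_plan$start, oscillation_plan$end)
  }

  list(
    signal = ts_signal(x, rate_hz, units = "uV"),
    truth = list(seizure_intervals = seizure_intervals,
                 spike_times = spike_times,
                 ripple_events = ripple_events,
                 oscillation_intervals = oscillation_intervals,
                 noise_sd = noise_sd)
  )
}

#' Simulate a 3-axis head-mounted accelerometer trace
#'
#' Stationary Gaussian noise per axis around a constant offset, with noise SD
#' elevated (default 5x) inside the planted active (locomotion) intervals.
#'
#' @param duration_s Duration (s).
#' @param rate_hz Sampling rate (Hz).
#' @param active_intervals Tibble with `start`, `end` (s) of active periods.
#' @param active_mult Noise-SD multiplier inside active periods.
#' @param seed Integer seed.
#' @return A 3-channel [ts_signal()] with the planted intervals attached as
#'   attribute `"active_intervals"`.
#' @export
make_accelerometer <- function(duration_s, rate_hz = 500,
                               active_intervals = NULL, active_mult = 5,
                               seed = NULL) {
  stopifnot(duration_s > 0, rate_hz > 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(active_intervals) && nrow(active_intervals) > 0 &&
      (any(active_intervals$start < 0) || any(active_intervals$end > duration_s))) {
    stop("active interval outside duration")
  }
  n <- round(duration_s * rate_hz)
  mask <- intervals_to_mask(active_intervals %||% empty_intervals(), n, rate_hz)
  sd_t <- ifelse(mask, active_mult, 1)
  vals <- sapply(1:3, function(a) 0.2 * a + stats::rnorm(n, sd = sd_t))
  out <- ts_signal(vals, rate_hz, units = "g", channels = c("x", "y", "z"))
  attr(out, "active_intervals") <- active_intervals %||% empty_intervals()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# leaky integrate-and-fire forward-Euler simulation; pastes a stereotyped
# 2 ms action-potential waveform at each threshold crossing
simulate_lif <- function(current_pA, rate, R_m, C_m, V_rest, V_thresh,
                         noise_sd = 0.2, v_peak = 30, refrac_s = 0.003) {
  n <- length(current_pA)
  dt <- 1 / rate
  tau <- R_m * C_m * 1e-6              # MOhm * pF -> seconds
  v <- numeric(n)
  v[1] <- V_rest
  spike_idx <- integer(0)
  # AP shape: 0.3 ms linear upstroke to v_peak, 0.9 ms downstroke to AHP
  n_up <- max(2L, round(0.0003 * rate))
  n_dn <- max(2L, round(0.0009 * rate))
  n_ref <- max(n_up + n_dn, round(refrac_s * rate))
  i <- 1L
  while (i < n) {
    dv <- (V_rest - v[i] + R_m * current_pA[i] * 1e-3) / tau * dt
    v[i + 1] <- v[i] + dv
    if (v[i + 1] >= V_thresh) {
      spike_idx <- c(spike_idx, i + 1L)
      ap <- c(seq(V_thresh, v_peak, length.out = n_up),
              seq(v_peak, V_rest - 3, length.out = n_dn))
      idx <- i + seq_along(ap)
      idx <- idx[idx <= n]
      v[idx] <- ap[seq_along(idx)]
      i_end <- min(n, i + n_ref)
      if (i_end > max(idx)) v[(max(idx) + 1):i_end] <- V_rest - 3
      v[i_end] <- V_rest - 3
      i <- i_end
    } else {
      i <- i + 1L
    }
  }
  if (noise_sd > 0) v <- v + stats::rnorm(n, sd = noise_sd)
  list(voltage = v, spike_idx = spike_idx)
}

build_protocol_current <- function(protocol, rate) {
  if (protocol == "step_plus_ramp") {
    # 500 ms rest, -100 pA 200 ms step, 300 ms gap, 2 s ramp -150 -> +500 pA,
    # rest to 5 s total
    seg <- c(rest1 = 0.5, step = 0.2, gap = 0.3, ramp = 2.0)
    n_tot <- round(5 * rate)
    cur <- numeric(n_tot)
    i0 <- round(seg[["rest1"]] * rate)
    cur[(i0 + 1):(i0 + round(seg[["step"]] * rate))] <- -100
    ir <- round((seg[["rest1"]] + seg[["step"]] + seg[["gap"]]) * rate)
    nr <- round(seg[["ramp"]] * rate)
    cur[(ir + 1):(ir + nr)] <- seq(-150, 500, length.out = nr)
    list(current = cur,
         meta = list(protocol = "step_plus_ramp", pre_s = 0.5,
                     ramp_start_s = 1.0, ramp_end_s = 3.0,
                     ramp_range = c(-150, 500)))
  } else if (protocol == "step_series") {
    # 500 ms rest + 500 ms step, for steps -200..700 pA in 50 pA increments
    steps <- seq(-200, 700, by = 50)
    cur <- unlist(lapply(steps, function(s) c(numeric(round(0.5 * rate)),
                                              rep(s, round(0.5 * rate)))))
    list(current = cur,
         meta = list(protocol = "step_series", pre_s = 0.5, steps_pA = steps))
  } else stop("unknown protocol: ", protocol)
}

#' Simulate a current-clamp sweep from a leaky integrate-and-fire cell
#'
#' Protocols: `"step_plus_ramp"` (500 ms rest; -100 pA, 200 ms step; 300 ms
#' gap; 2 s ramp from -150 to +500 pA; 5 s sweep) or `"step_series"`
#' (500 ms steps from -200 to 700 pA in 50 pA increments, four of them
#' hyperpolarizing). Sampled at 10 kHz. Ground-truth rheobase is the command
#' current at the first ramp spike of the simulation itself, i.e. adjusted
#' for ramp kinetics.
#'
#' @param protocol `"step_plus_ramp"` or `"step_series"`.
#' @param cell_params List with `R_m` (MOhm), `C_m` (pF), `V_rest` (mV),
#'   `V_thresh` (mV).
#' @param noise_sd Voltage noise SD (mV).
#' @param rate_hz Sampling rate (Hz), default 10000.
#' @param seed Integer seed.
#' @return List with `sweep` (list: `voltage` [ts_signal()], `current` pA
#'   vector, `meta`) and `truth` (spike times, rheobase, cell parameters).
#' @export
make_patch_sweep <- function(protocol = c("step_plus_ramp", "step_series"),
                             cell_params = list(R_m = 100, C_m = 150,
                                                V_rest = -65, V_thresh = -45),
                             noise_sd = 0.2, rate_hz = 10000, seed = NULL) {
  protocol <- match.arg(protocol)
  p <- cell_params
  stopifnot(p$R_m > 0, p$C_m > 0)
  if (p$V_thresh <= p$V_rest) stop("nonphysical cell: V_thresh <= V_rest")
  if (!is.null(seed)) set.seed(seed)
  prot <- build_protocol_current(protocol, rate_hz)
  sim <- simulate_lif(prot$current, rate_hz, p$R_m, p$C_m, p$V_rest,
                      p$V_thresh, noise_sd)
  spike_t <- (sim$spike_idx - 1) / rate_hz
  rheo <- NA_real_
  if (protocol == "step_plus_ramp") {
    m <- prot$meta
    in_ramp <- spike_t >= m$ramp_start_s & spike_t < m$ramp_end_s
    if (any(in_ramp)) rheo <- prot$current[sim$spike_idx[which(in_ramp)[1]]]
  }
  list(
    sweep = list(voltage = ts_signal(sim$voltage, rate_hz, units = "mV"),
                 current = prot$current, meta = prot$meta),
    truth = list(spike_times = spike_t, rheobase_pA = rheo,
                 cell_params = p)
  )
}

#' Half-log-spaced concentration grid
#' @param from,to Grid limits (same units as the concentrations).
#' @return Numeric vector of concentrations at half-log10 spacing.
#' @export
half_log_doses <- function(from = 1e-3, to = 10) {
  10^seq(log10(from), log10(to), by = 0.5)
}

#' Simulate a per-cell dose-response table under the Hill model
#'
#' Per-cell normalized-scale responses are
#' `100 / (1 + (ec50 / X)^hillslope) * (1 + eps)` with
#' `eps ~ Normal(0, noise_cv)`; raw inward-current amplitudes (negative pA)
#' are obtained by scaling with a per-cell maximal current.
#'
#' @param ec50 True EC50 (same units as `concentrations`, typically uM).
#' @param hillslope True Hill slope (> 0).
#' @param concentrations Positive concentration grid (half-log spacing
#'   recommended, see [half_log_doses()]).
#' @param n_cells Number of cells.
#' @param noise_cv Multiplicative noise CV (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `cell_id`, `conc_uM`, `amplitude_pA` and the
#'   generating `true_response`.
#' @export
make_dose_response <- function(ec50, hillslope = 1, concentrations,
                               n_cells = 8, noise_cv = 0.05, seed = NULL) {
  stopifnot(ec50 > 0, hillslope > 0, all(concentrations > 0))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  cell_max <- -stats::rlnorm(n_cells, log(500), 0.3)   # inward convention, pA
  tidyr::expand_grid(cell_id = paste0("cell", seq_len(n_cells)),
                     conc_uM = concentrations) |>
    dplyr::mutate(
      true_response = hill_response(.data$conc_uM, ec50, hillslope),
      noisy = .data$true_response *
        (1 + stats::rnorm(dplyr::n(), sd = noise_cv)),
      amplitude_pA = cell_max[match(.data$cell_id,
                                    paste0("cell", seq_len(n_cells)))] *
        .data$noisy / 100
    ) |>
    dplyr::select("cell_id", "conc_uM", "amplitude_pA", "true_response")
}

#' Simulate a paired ACh / calcium imaging session
#'
#' Per-ROI fluorescence is `F(t) = B(t) * (1 + s(t)) + B(t) * noise`, where
#' `B(t)` is a cubic drift baseline and `s(t)` a sum of exponential-decay
#' transients at the planted seizure times, so the planted transient
#' amplitudes are in DF/F units. ACh transient amplitudes are the calcium
#' amplitudes scaled by `ach_ca_coupling`. An LFP trace with seizures planted
#' at the same times is generated alongside.
#'
#' @param n_rois Number of ROIs per channel.
#' @param duration_s Session duration (s).
#' @param frame_rate Imaging frame rate (Hz), default 15.
#' @param seizure_times Onset times (s) of seizure-coupled transients.
#' @param transient_amp Calcium DF/F amplitude of each transient.
#' @param decay_s Transient exponential decay constant (s).
#' @param ach_ca_coupling Scale of ACh vs calcium amplitudes (>= 0).
#' @param drift_coeffs Optional n_rois x 4 matrix of cubic drift coefficients
#'   on normalized time u = t / duration (columns: intercept, u, u^2, u^3).
#'   Defaults to gentle random drifts.
#' @param running_intervals Tibble with `start`, `end` (s).
#' @param noise_sd DF/F-scale noise SD.
#' @param seizure_duration_s Planted LFP seizure duration (s).
#' @param seed Integer seed.
#' @return List: `ach`, `ca` (frames x ROIs matrices), `frame_rate`,
#'   `running_intervals`, `lfp` ([ts_signal()]), `truth`.
#' @export
make_imaging_session <- function(n_rois = 10, duration_s = 600,
                                 frame_rate = 15, seizure_times = numeric(),
                                 transient_amp = 0.5, decay_s = 3,
                                 ach_ca_coupling = 1, drift_coeffs = NULL,
                                 running_intervals = NULL, noise_sd = 0.02,
                                 seizure_duration_s = 10, seed = NULL) {
  if (ach_ca_coupling < 0) stop("ach_ca_coupling must be >= 0")
  stopifnot(duration_s > 0, frame_rate > 0)
  if (length(seizure_times) &&
      any(seizure_times < 0 | seizure_times >= duration_s)) {
    stop("seizure time outside duration")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * frame_rate)
  tt <- (seq_len(n) - 1) / frame_rate
  u <- tt / duration_s
  if (is.null(drift_coeffs)) {
    drift_coeffs <- cbind(stats::runif(n_rois, 80, 120),
                          stats::runif(n_rois, -0.2, 0.2),
                          stats::runif(n_rois, -0.2, 0.2),
                          stats::runif(n_rois, -0.2, 0.2))
    drift_coeffs[, 2:4] <- drift_coeffs[, 2:4] * drift_coeffs[, 1]
  }
  stopifnot(ncol(drift_coeffs) == 4, nrow(drift_coeffs) == n_rois)

  kern <- function(amp) {
    s <- numeric(n)
    for (t0 in seizure_times) {
      idx <- which(tt >= t0)
      s[idx] <- s[idx] + amp * exp(-(tt[idx] - t0) / decay_s)
    }
    s
  }
  s_ca <- kern(transient_amp)
  s_ach <- kern(transient_amp * ach_ca_coupling)

  build <- function(sig) {
    sapply(seq_len(n_rois), function(r) {
      B <- drift_coeffs[r, 1] + drift_coeffs[r, 2] * u +
        drift_coeffs[r, 3] * u^2 + drift_coeffs[r, 4] * u^3
      B * (1 + sig) + B * stats::rnorm(n, sd = noise_sd)
    })
  }
  ca <- build(s_ca)
  ach <- build(s_ach)

  lfp <- NULL
  if (length(seizure_times)) {
    plan <- intervals(seizure_times,
                      pmin(seizure_times + seizure_duration_s, duration_s))
    lfp <- make_lfp(duration_s, 1000, seizure_plan = plan,
                    seed = sample.int(2^31 - 1, 1))$signal
  }
  list(
    ach = ach, ca = ca, frame_rate = frame_rate,
    running_intervals = running_intervals %||% empty_intervals(),
    lfp = lfp,
    truth = list(
      transients = tibble::tibble(t0 = seizure_times,
                                  amp_ca = rep(transient_amp,
                                               length(seizure_times)),
                                  amp_ach = rep(transient_amp * ach_ca_coupling,
                                                length(seizure_times))),
      drift_coeffs = drift_coeffs, decay_s = decay_s,
      coupling = ach_ca_coupling)
  )
}

#' Step effect profile for seizure-timeline simulations
#'
#' Builds an `effect(t_h)` rate multiplier that drops to `multiplier` for
#' `effect_duration_h` hours after each injection and is 1 elsewhere.
#'
#' @param injections_h Injection times (hours from session start).
#' @param multiplier Rate multiplier in the effect window (>= 0).
#' @param effect_duration_h Effect duration per injection (h).
#' @return A function of time (hours) returning the multiplier.
#' @export
step_effect <- function(injections_h, multiplier, effect_duration_h = 4) {
  stopifnot(multiplier >= 0)
  function(t_h) {
    on <- vapply(t_h, function(t) any(t >= injections_h &
                                        t < injections_h + effect_duration_h),
                 logical(1))
    ifelse(on, multiplier, 1)
  }
}

#' Simulate a spontaneous-seizure timeline (nonhomogeneous Poisson)
#'
#' Event onsets are drawn by thinning from rate
#' `baseline_rate_per_h * effect(t)`; durations are lognormal
#' (default meanlog = log 20 s, sdlog = 0.5, typical of chronic hippocampal
#' electrographic seizures).
#'
#' @param baseline_rate_per_h Baseline seizure rate (events/h), >= 0.
#' @param effect Function of time in hours returning a nonnegative rate
#'   multiplier (default constant 1). See [step_effect()].
#' @param injections_h Injection times (h), recorded in the log.
#' @param duration_h Session duration (h).
#' @param dur_meanlog,dur_sdlog Lognormal duration parameters (log-seconds).
#' @param seed Integer seed.
#' @return A seizure log: list with `seizures` (tibble `start_s`, `end_s`,
#'   `duration_s`), `injections_h`, `duration_h`, `baseline_rate_per_h`.
#' @export
make_seizure_timeline <- function(baseline_rate_per_h = 20,
                                  effect = function(t_h) rep(1, length(t_h)),
                                  injections_h = numeric(),
                                  duration_h = 6,
                                  dur_meanlog = log(20), dur_sdlog = 0.5,
                                  seed = NULL) {
  stopifnot(baseline_rate_per_h >= 0, duration_h > 0)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, duration_h, length.out = 2001)
  lam_max <- baseline_rate_per_h * max(effect(grid), 1e-12)
  n_cand <- stats::rpois(1, lam_max * duration_h)
  cand <- sort(stats::runif(n_cand, 0, duration_h))
  keep <- stats::runif(n_cand) <
    baseline_rate_per_h * effect(cand) / lam_max
  onset_h <- cand[keep]
  dur_s <- stats::rlnorm(length(onset_h), dur_meanlog, dur_sdlog)
  start_s <- onset_h * 3600
  end_s <- pmin(start_s + dur_s, duration_h * 3600)
  list(
    seizures = tibble::tibble(start_s = start_s, end_s = end_s,
                              duration_s = end_s - start_s),
    injections_h = injections_h,
    duration_h = duration_h,
    baseline_rate_per_h = baseline_rate_per_h
  )
}
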