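# Semi-automatic EEG seizure detector: band-pass filtering, SD-relative
# interictal spike detection with amplitude/width/template criteria combined
# by Boolean logic, artifact rejection, ISI-based clustering and a strict
# duration gate ("spike clusters > 3 s with inter-spike interval < 1 s").

#' Spike-detection criteria
#'
#' @param band Band-pass edges (Hz) for the detection filter.
#' @param amp_thresh Amplitude threshold in robust background-SD units.
#' @param width_range_ms Admissible half-amplitude widths (ms), `min < max`.
#' @param templates Optional list of numeric template waveforms.
#' @param min_corr Minimum normalized cross-correlation for the template
#'   criterion, in (0, 1].
#' @param boolean_expr Character Boolean expression over the criterion names
#'   `amplitude`, `width`, `template` (e.g. `"amplitude & width"`). When no
#'   templates are supplied the default reduces to `AND(amplitude, width)`.
#' @return A `spike_criteria` list.
#' @export
spike_criteria <- function(band = c(1, 50), amp_thresh = 5,
                           width_range_ms = c(3, 200), templates = NULL,
                           min_corr = 0.7,
                           boolean_expr = if (is.null(templates))
                             "amplitude & width" else
                               "amplitude & width & template") {
  stopifnot(amp_thresh > 0, width_range_ms[1] < width_range_ms[2],
            min_corr > 0, min_corr <= 1)
  if (!nzchar(boolean_expr)) stop("empty Boolean expression")
  structure(list(band = band, amp_thresh = amp_thresh,
                 width_range_ms = width_range_ms, templates = templates,
                 min_corr = min_corr, boolean_expr = boolean_expr),
            class = "spike_criteria")
}

#' Cluster criteria for turning spike trains into seizures
#'
#' @param max_isi Spikes closer than this join one cluster (s; strict `<`).
#' @param min_duration Clusters strictly longer than this are seizures
#'   (s; default 3, alternative 6).
#' @param inter_cluster_interval Clusters separated by less than this merge
#'   (s; defaults to `max_isi`).
#' @return A `cluster_criteria` list.
#' @export
cluster_criteria <- function(max_isi = 1, min_duration = 3,
                             inter_cluster_interval = max_isi) {
  stopifnot(max_isi > 0, min_duration > 0)
  structure(list(max_isi = max_isi, min_duration = min_duration,
                 inter_cluster_interval = inter_cluster_interval),
            class = "cluster_criteria")
}

#' Detect interictal spikes in an LFP/EEG trace
#'
#' The trace is band-pass filtered, a robust background SD (MAD-scaled, over
#' the whole filtered trace, so the seizures themselves do not inflate it) is
#' estimated, and candidate events are contiguous excursions of the absolute
#' filtered signal above `amp_thresh` x SD. Each candidate's half-amplitude
#' width and best template correlation are evaluated, and the named criteria
#' are combined with the criteria's Boolean expression. Detection is
#' invariant to amplitude scaling and DC offset by construction.
#'
#' @param x A [ts_signal()] or numeric vector.
#' @param criteria A [spike_criteria()] object.
#' @param rate Sampling rate (Hz) for plain vectors.
#' @return Tibble with `time` (peak time, s), `amplitude_sd` (peak in SD
#'   units), `width_ms`, `template_corr`, and the per-criterion logicals.
#' @export
detect_spikes <- function(x, criteria = spike_criteria(), rate = NULL) {
  fs <- resolve_rate(x, rate)
  filt <- bandpass(ts_values(x), criteria$band[1], criteria$band[2], rate = fs)
  sigma <- robust_sd(filt)
  if (sigma == 0) {
    return(tibble::tibble(time = numeric(), amplitude_sd = numeric(),
                          width_ms = numeric(), template_corr = numeric(),
                          amplitude = logical(), width = logical(),
                          template = logical(), keep = logical()))
  }
  a <- abs(filt)
  above <- a > criteria$amp_thresh * sigma
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ks <- which(r$values)
  n_ev <- length(ks)
  ev_time <- numeric(n_ev); ev_amp <- numeric(n_ev)
  ev_width <- numeric(n_ev); ev_tc <- rep(NA_real_, n_ev)
  lag_max <- round(0.005 * fs)
  for (j in seq_len(n_ev)) {
    k <- ks[j]
    i0 <- starts[k]; i1 <- ends[k]
    ip <- i0 + which.max(a[i0:i1]) - 1
    pk <- a[ip]
    # half-amplitude width of this deflection
    half <- pk / 2
    lo <- ip; while (lo > 1 && a[lo - 1] >= half) lo <- lo - 1
    hi <- ip; while (hi < length(a) && a[hi + 1] >= half) hi <- hi + 1
    ev_time[j] <- (ip - 1) / fs
    ev_amp[j] <- pk / sigma
    ev_width[j] <- (hi - lo + 1) / fs * 1000
    if (!is.null(criteria$templates)) {
      ev_tc[j] <- max(vapply(criteria$templates, function(tmpl) {
        m <- length(tmpl)
        # max normalized cross-correlation over small lags around the peak
        best <- 0
        for (lag in -lag_max:lag_max) {
          j0 <- ip - (which.max(abs(tmpl)) - 1) + lag
          idx <- j0:(j0 + m - 1)
          ok <- idx >= 1 & idx <= length(filt)
          seg <- filt[idx[ok]]
          if (length(seg) < 3 || stats::sd(seg) == 0) next
          best <- max(best, abs(stats::cor(seg, tmpl[ok])))
        }
        best
      }, numeric(1)))
    }
  }
  ev <- tibble::tibble(time = ev_time, amplitude_sd = ev_amp,
                       width_ms = ev_width, template_corr = ev_tc)
  ev <- ev |>
    dplyr::mutate(
      amplitude = TRUE,   # candidates exist by the amplitude criterion
      width = .data$width_ms >= criteria$width_range_ms[1] &
        .data$width_ms <= criteria$width_range_ms[2],
      template = if (is.null(criteria$templates)) NA else
        .data$template_corr >= criteria$min_corr)
  keep <- with(ev, eval(parse(text = criteria$boolean_expr),
                        list(amplitude = amplitude, width = width,
                             template = template)))
  dplyr::mutate(ev, keep = keep) |> dplyr::filter(.data$keep)
}

#' Reject artifactual spike detections
#'
#' Each event's surrounding window is screened by named artifact rules
#' combined with OR logic: a saturation rule (a sustained run of samples
#' pinned near the window extreme, as produced by amplifier clipping) and a
#' broadband rule (excess high-frequency power relative to the detection
#' band, as produced by movement/cable artifacts).
#'
#' @param x The raw trace ([ts_signal()] or numeric).
#' @param spikes Spike table from [detect_spikes()].
#' @param rate Sampling rate (Hz) for plain vectors.
#' @param window_s Screening half-window around each event (s).
#' @param sat_run_s Minimum pinned-run duration for the saturation rule (s).
#' @param sat_tol Relative tolerance defining "pinned at the extreme".
#' @param broadband_ratio High-band (> 100 Hz) to low-band (1-50 Hz) power
#'   ratio above which the window is artifactual.
#' @return The spike table with rejected rows removed; removals with reasons
#'   in attribute `"rejections"`.
#' @export
reject_artifacts <- function(x, spikes, rate = NULL, window_s = 0.5,
                             sat_run_s = 0.02, sat_tol = 0.02,
                             broadband_ratio = 2) {
  fs <- resolve_rate(x, rate)
  v <- ts_values(x)
  if (nrow(spikes) == 0) {
    attr(spikes, "rejections") <- tibble::tibble(time = numeric(),
                                                 reason = character())
    return(spikes)
  }
  can_broadband <- fs / 2 > 110
  # filter the whole trace once; per-window powers come from cumulative sums
  if (can_broadband) {
    cs_hi <- c(0, cumsum(highpass(v, 100, rate = fs)^2))
    cs_lo <- c(0, cumsum(bandpass(v, 1, 50, rate = fs)^2))
  }
  reason <- rep(NA_character_, nrow(spikes))
  for (i in seq_len(nrow(spikes))) {
    i0 <- max(1L, round(spikes$time[i] * fs) + 1 - round(window_s * fs))
    i1 <- min(length(v), round(spikes$time[i] * fs) + 1 + round(window_s * fs))
    seg <- v[i0:i1]
    pk <- max(abs(seg))
    pinned <- abs(seg) > (1 - sat_tol) * pk
    rp <- rle(pinned)
    if (max(rp$lengths[rp$values], 0) >= round(sat_run_s * fs)) {
      reason[i] <- "saturation"
      next
    }
    if (can_broadband) {
      p_hi <- (cs_hi[i1 + 1] - cs_hi[i0]) / (i1 - i0 + 1)
      p_lo <- (cs_lo[i1 + 1] - cs_lo[i0]) / (i1 - i0 + 1)
      if (p_hi / max(p_lo, 1e-24) > broadband_ratio) {
        reason[i] <- "broadband"
      }
    }
  }
  out <- spikes[is.na(reason), , drop = FALSE]
  attr(out, "rejections") <- tibble::tibble(time = spikes$time[!is.na(reason)],
                                            reason = reason[!is.na(reason)])
  out
}

#' Cluster spikes into seizures with the duration gate
#'
#' Greedy chaining: consecutive spikes with a gap strictly below `max_isi`
#' join one cluster; a cluster spans [first spike, last spike]; clusters
#' separated by less than `inter_cluster_interval` merge; clusters whose
#' span is strictly greater than `min_duration` are returned as seizures.
#'
#' @param spike_times Numeric spike times (s) or a [detect_spikes()] table.
#' @param criteria A [cluster_criteria()] object.
#' @return Tibble with `start`, `end`, `duration_s`, `n_spikes`.
#' @export
cluster_spikes <- function(spike_times, criteria = cluster_criteria()) {
  if (is.data.frame(spike_times)) spike_times <- spike_times$time
  if (is.unsorted(spike_times)) {
    warning("spike times unsorted; sorting")
    spike_times <- sort(spike_times)
  }
  if (!length(spike_times)) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          duration_s = numeric(), n_spikes = integer()))
  }
  gap <- diff(spike_times)
  new_cluster <- c(TRUE, gap >= criteria$max_isi)   # strict "< max_isi" joins
  cl <- cumsum(new_cluster)
  clusters <- tibble::tibble(t = spike_times, cl = cl) |>
    dplyr::group_by(.data$cl) |>
    dplyr::summarise(start = min(.data$t), end = max(.data$t),
                     n_spikes = dplyr::n(), .groups = "drop")
  # merge clusters closer than the inter-cluster interval
  if (nrow(clusters) > 1) {
    g <- cumsum(c(TRUE, clusters$start[-1] - clusters$end[-nrow(clusters)] >=
                    criteria$inter_cluster_interval))
    clusters <- clusters |>
      dplyr::mutate(g = g) |>
      dplyr::group_by(.data$g) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       n_spikes = sum(.data$n_spikes), .groups = "drop")
  }
  clusters |>
    dplyr::mutate(duration_s = .data$end - .data$start) |>
    dplyr::filter(.data$duration_s > criteria$min_duration) |>
    dplyr::select("start", "end", "duration_s", "n_spikes")
}

#' End-to-end seizure detection on an LFP trace
#'
#' [detect_spikes()] then [reject_artifacts()] then [cluster_spikes()].
#'
#' @param x A [ts_signal()] or numeric vector.
#' @param spike_crit,cluster_crit Criteria objects.
#' @param rate Sampling rate for plain vectors.
#' @param artifact_rejection Apply [reject_artifacts()] (default TRUE).
#' @return Seizure interval tibble as from [cluster_spikes()].
#' @export
detect_seizures <- function(x, spike_crit = spike_criteria(),
                            cluster_crit = cluster_criteria(), rate = NULL,
                            artifact_rejection = TRUE) {
  spikes <- detect_spikes(x, spike_crit, rate = rate)
  if (artifact_rejection) spikes <- reject_artifacts(x, spikes, rate = rate)
  cluster_spikes(spikes, cluster_crit)
}

#' Per-bin seizure frequency and mean duration
#'
#' Seizures are assigned to half-open bins (a seizure belongs to the bin
#' containing its start) aligned to the injection time.
#'
#' @param seizures Tibble with `start`, `end` (s) or `start_s`, `end_s`.
#' @param injection_s Injection time (s).
#' @param session Two-element session span `c(start, end)` in seconds.
#' @param bin_s Bin width (default 1800 s = 30 min).
#' @return Tibble with `bin`, `bin_start_s`, `n`, `freq_per_bin`,
#'   `mean_duration_s`.
#' @export
seizure_metrics <- function(seizures, injection_s, session, bin_s = 1800) {
  sz <- normalize_seizure_cols(seizures)
  if (nrow(sz) &&
      (any(sz$start < session[1]) || any(sz$start >= session[2]))) {
    stop("seizure outside session span")
  }
  first_bin <- floor((session[1] - injection_s) / bin_s)
  last_bin <- ceiling((session[2] - injection_s) / bin_s) - 1
  all_bins <- tibble::tibble(bin = first_bin:last_bin)
  sz |>
    dplyr::mutate(bin = floor((.data$start - injection_s) / bin_s)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_duration_s = mean(.data$end - .data$start),
                     .groups = "drop") |>
    dplyr::right_join(all_bins, by = "bin") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L),
                  bin_start_s = injection_s + .data$bin * bin_s,
                  freq_per_bin = .data$n) |>
    dplyr::arrange(.data$bin) |>
    dplyr::select("bin", "bin_start_s", "n", "freq_per_bin",
                  "mean_duration_s")
}

normalize_seizure_cols <- function(seizures) {
  if (all(c("start_s", "end_s") %in% names(seizures))) {
    tibble::tibble(start = seizures$start_s, end = seizures$end_s)
  } else {
    tibble::tibble(start = seizures$start, end = seizures$end)
  }
}
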