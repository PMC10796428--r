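# Filtering, interictal-spike detection with Boolean criteria, artifact
# rejection, ISI clustering with the strict duration gate, and binned
# seizure metrics.

test_that("zero-phase band-pass preserves in-band and rejects out-of-band
           tones", {
  rate <- 1000
  t <- seq(0, 10, by = 1 / rate)
  in_band <- sin(2 * pi * 10 * t)
  out <- bandpass(in_band, 5, 50, rate = rate)
  mid <- seq(2 * rate, 8 * rate)
  expect_lt(abs(sqrt(mean(out[mid]^2)) / sqrt(0.5) - 1), 0.05)

  hi <- sin(2 * pi * 300 * t)
  att <- bandpass(hi, 5, 50, rate = rate)
  expect_lt(20 * log10(sqrt(mean(att[mid]^2)) / sqrt(0.5)), -20)

  expect_equal(bandpass(rep(0, 1000), 5, 50, rate = rate), rep(0, 1000))
  expect_error(bandpass(in_band, 50, 5, rate = rate), "invalid band")
})

test_that("planted interictal spikes are all detected; detection is scale-
           and offset-invariant", {
  times <- seq(10, 590, length.out = 50)
  sim <- make_lfp(600, 1000, spike_plan = tibble::tibble(time = times),
                  seed = 41)
  sp <- detect_spikes(sim$signal)
  sc <- vapply(times, function(tt) any(abs(sp$time - tt) < 0.05),
               logical(1))
  expect_true(all(sc))

  sp10 <- detect_spikes(ts_signal(sim$signal$values * 10 + 250, 1000))
  expect_equal(sp10$time, sp$time)
  expect_equal(sp10$amplitude_sd, sp$amplitude_sd, tolerance = 1e-4)
})

test_that("amplitude-threshold false positives on noise are rare and
           bounded", {
  sim <- make_lfp(100, 1000, seed = 42)
  # at a reduced 3.5 SD threshold, crossings behave like the Gaussian tail:
  # compare with a generous analytic bound on the filtered trace
  crit <- spike_criteria(amp_thresh = 3.5, width_range_ms = c(0.1, 1000),
                         boolean_expr = "amplitude")
  n35 <- nrow(detect_spikes(sim$signal, crit))
  n_eff <- 100 * 49   # duration x detection bandwidth (independent samples)
  # order-of-magnitude bound: excursion counts scale with the Gaussian tail
  bound <- 10 * n_eff * 2 * stats::pnorm(-3.5)
  expect_lt(n35, bound)
  # at the default 5 SD threshold detections are rarer still
  n5 <- nrow(detect_spikes(sim$signal,
                           spike_criteria(amp_thresh = 5,
                                          width_range_ms = c(0.1, 1000),
                                          boolean_expr = "amplitude")))
  expect_lte(n5, n35)
  expect_lte(n5, 2)
})

test_that("Boolean criteria combine amplitude, width and template", {
  expect_error(spike_criteria(boolean_expr = ""), "empty")
  times <- seq(10, 50, by = 10)
  sim <- make_lfp(60, 1000, spike_plan = tibble::tibble(time = times),
                  seed = 43)
  # a width gate excluding the planted ~10-20 ms spikes removes everything
  narrow <- spike_criteria(width_range_ms = c(0.5, 2))
  expect_equal(nrow(detect_spikes(sim$signal, narrow)), 0)
  # template criterion with the true waveform accepts the spikes
  tmpl <- seizr:::interictal_waveform(1000)
  crit_t <- spike_criteria(templates = list(tmpl), min_corr = 0.6)
  expect_equal(nrow(detect_spikes(sim$signal, crit_t)), 5)
})

test_that("artifact rejection removes clipped windows but keeps real
           spikes", {
  times <- seq(10, 50, by = 10)
  sim <- make_lfp(60, 1000, spike_plan = tibble::tibble(time = times),
                  seed = 44)
  v <- sim$signal$values[, 1]
  # clipped square artifact at t = 30 s
  v[29950:30250] <- max(abs(v)) * 1.5
  x <- ts_signal(v, 1000)
  sp <- detect_spikes(x)
  kept <- reject_artifacts(x, sp)
  rej <- attr(kept, "rejections")
  expect_true(any(abs(rej$time - 30) < 0.3))
  expect_true(all(rej$reason == "saturation"))
  # genuine spikes survive
  for (tt in times[times != 30]) {
    expect_true(any(abs(kept$time - tt) < 0.05))
  }
  # empty input passes through
  empty <- sp[0, ]
  expect_equal(nrow(reject_artifacts(x, empty)), 0)
})

test_that("clustering applies the strict <1 s ISI and >3 s duration rules", {
  # spikes every 0.5 s spanning 3.5 s: one seizure
  cl <- cluster_spikes(seq(0, 3.5, by = 0.5))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$duration_s, 3.5)

  # span 2.9 s excluded, 3.1 s included (strict "> 3 s")
  expect_equal(nrow(cluster_spikes(seq(0, 2.9, by = 0.29))), 0)
  expect_equal(nrow(cluster_spikes(seq(0, 3.1, by = 0.31))), 1)

  # gap of exactly 1.0 s splits clusters (strict "< 1 s")
  spikes <- c(seq(0, 4, by = 0.5), seq(5, 9, by = 0.5))
  cl2 <- cluster_spikes(spikes, cluster_criteria(inter_cluster_interval = 0.99))
  expect_equal(nrow(cl2), 2)
  # but a 0.99 s gap joins them
  spikes3 <- c(seq(0, 4, by = 0.5), seq(4.99, 9, by = 0.5))
  expect_equal(nrow(cluster_spikes(spikes3)), 1)

  expect_warning(cluster_spikes(c(5, 1, 2, 3, 4, 5.5, 0,
                                  0.5, 1.5, 2.5, 3.5, 4.5)), "unsorted")
})

test_that("re-clustering the member spikes of a seizure reproduces its
           interval", {
  sim <- make_lfp(300, 1000,
                  seizure_plan = intervals(c(50, 200), c(70, 220)),
                  seed = 45)
  sp <- detect_spikes(sim$signal)
  cl <- cluster_spikes(sp)
  for (i in seq_len(nrow(cl))) {
    members <- sp$time[sp$time >= cl$start[i] & sp$time <= cl$end[i]]
    again <- cluster_spikes(members)
    expect_equal(again$start, cl$start[i])
    expect_equal(again$end, cl$end[i])
  }
})

test_that("end-to-end detection recovers planted seizures with no false
           positives and a nested 6 s gate", {
  for (s in 1:3) {
    plan <- seizure_session_plan()
    sim <- make_lfp(630, 1000, seizure_plan = plan, seed = 50 + s)
    sz3 <- detect_seizures(sim$signal)
    sc <- score_intervals(sz3, sim$truth$seizure_intervals)
    expect_equal(sc$sensitivity, 1)
    expect_equal(sc$n_false, 0)
    # 6 s duration gate returns a subset of the 3 s detections
    sz6 <- detect_seizures(sim$signal,
                           cluster_crit = cluster_criteria(min_duration = 6))
    expect_lte(nrow(sz6), nrow(sz3))
    for (i in seq_len(nrow(sz6))) {
      expect_true(any(abs(sz6$start[i] - sz3$start) < 1e-9))
    }
  }
})

test_that("binned seizure metrics assign starts to half-open bins", {
  sz <- intervals(c(100, 200, 300, 400), c(130, 230, 330, 430))
  out <- seizure_metrics(sz, injection_s = 0, session = c(0, 1800),
                        bin_s = 1800)
  expect_equal(out$n, 4)
  expect_equal(out$mean_duration_s, 30)

  # a seizure starting exactly at a bin edge belongs to the right bin
  sz2 <- intervals(1800, 1830)
  out2 <- seizure_metrics(sz2, injection_s = 0, session = c(0, 3600),
                          bin_s = 1800)
  expect_equal(out2$n, c(0, 1))

  expect_error(seizure_metrics(intervals(5000, 5100), injection_s = 0,
                               session = c(0, 3600)), "outside")

  # planted timeline: binned rates match the generating profile
  eff <- step_effect(2, 0.25, 3)
  log <- make_seizure_timeline(30, eff, 2, 6, seed = 46)
  out3 <- seizure_metrics(tibble::tibble(start = log$seizures$start_s,
                                         end = log$seizures$end_s),
                          injection_s = 2 * 3600, session = c(0, 6 * 3600),
                          bin_s = 3600)
  pre <- mean(out3$n[out3$bin < 0])
  post <- mean(out3$n[out3$bin %in% 0:2])
  expect_lt(abs(pre - 30) / 30, 0.4)
  expect_lt(abs(post - 7.5) / 7.5, 0.75)
})
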