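# AP detection/threshold/width, input resistance, rheobase, RMP, QC and
# time-binned summaries on simulated current-clamp sweeps.

std_cell <- list(R_m = 100, C_m = 150, V_rest = -65, V_thresh = -45)

test_that("AP detection finds planted spikes and localizes thresholds", {
  flat <- rep(-65, 10000)
  expect_equal(nrow(detect_aps(flat, rate = 10000)), 0)
  expect_error(detect_aps(rep(NaN, 1000), rate = 10000), "NaN")

  sw <- make_patch_sweep(cell_params = std_cell, seed = 31)
  spikes <- detect_aps(sw$sweep$voltage)
  expect_equal(nrow(spikes), length(sw$truth$spike_times))
  expect_lt(max(abs(spikes$t_peak - sw$truth$spike_times)), 5e-4)
  # threshold voltage within 2 mV of the planted V_thresh
  expect_lt(max(abs(spikes$v_thresh - std_cell$V_thresh)), 2)
})

test_that("AP width matches closed-form geometry and is offset-invariant", {
  rate <- 10000
  # symmetric triangular spike, 2 ms base: half-height width = 1 ms
  tri <- c(rep(0, 100), seq(0, 60, length.out = 11),
           seq(60, 0, length.out = 11)[-1], rep(0, 100))
  spike <- list(i_peak = which.max(tri), v_peak = 60, v_thresh = 0)
  expect_equal(ap_width(tri, spike, rate = rate), 1.0, tolerance = 0.02)

  # Gaussian spike sigma = 0.3 ms: FWHM = 2 * sigma * sqrt(2 ln 2)
  t <- seq(-5e-3, 5e-3, by = 1 / rate)
  g <- 80 * exp(-t^2 / (2 * (3e-4)^2))
  gs <- list(i_peak = which.max(g), v_peak = 80, v_thresh = 0)
  fwhm <- 2 * 3e-4 * sqrt(2 * log(2)) * 1000
  expect_equal(ap_width(g, gs, rate = rate), fwhm, tolerance = 0.02)

  # invariant to voltage offset and to finer uniform resampling
  go <- g - 62
  gso <- list(i_peak = which.max(g), v_peak = 80 - 62, v_thresh = -62)
  expect_equal(ap_width(go, gso, rate = rate),
               ap_width(g, gs, rate = rate), tolerance = 1e-6)
  t2 <- seq(-5e-3, 5e-3, by = 1 / 40000)
  g2 <- 80 * exp(-t2^2 / (2 * (3e-4)^2))
  gs2 <- list(i_peak = which.max(g2), v_peak = 80, v_thresh = 0)
  expect_equal(ap_width(g2, gs2, rate = 40000),
               ap_width(g, gs, rate = rate), tolerance = 0.02)

  expect_error(ap_width(g, list(i_peak = which.max(g), v_peak = -10,
                                v_thresh = 0), rate = rate),
               "peak")
})

test_that("fast-spiking classification boundary is exact at 1 ms", {
  expect_true(is_fast_spiking(1))
  expect_true(is_fast_spiking(0.4))
  expect_false(is_fast_spiking(1.0001))
})

test_that("input resistance recovers R_m from hyperpolarizing steps", {
  sw <- make_patch_sweep(cell_params = std_cell, seed = 32)
  expect_equal(input_resistance(sw$sweep), 100, tolerance = 0.02)

  # step-series protocol averages the four hyperpolarizing steps
  ss <- make_patch_sweep("step_series", cell_params = std_cell, seed = 33)
  expect_equal(input_resistance(ss$sweep), 100, tolerance = 0.02)

  # no hyperpolarizing step: degenerate
  zero <- sw$sweep
  zero$current <- rep(0, length(zero$current))
  expect_error(input_resistance(zero), "hyperpolarizing")
})

test_that("R_in estimator is unbiased across membrane resistances", {
  for (R in c(50, 100, 300)) {
    cp <- list(R_m = R, C_m = 100, V_rest = -65, V_thresh = -45)
    est <- vapply(1:33, function(s)
      input_resistance(make_patch_sweep(cell_params = cp, noise_sd = 0.4,
                                        seed = 400 + s)$sweep),
      numeric(1))
    expect_lt(abs(mean(est) - R) / R, 0.03)
  }
})

test_that("ramp rheobase matches ground truth and the 500 pA rule", {
  sw <- make_patch_sweep(cell_params = std_cell, seed = 34)
  rb <- rheobase_from_ramp(sw$sweep)
  expect_lt(abs(rb$rheobase_pA - sw$truth$rheobase_pA), 10)

  # no spikes anywhere: exactly 500 pA assigned
  quiet <- make_patch_sweep(cell_params = list(R_m = 100, C_m = 150,
                                               V_rest = -65, V_thresh = 0),
                            seed = 35)
  expect_equal(rheobase_from_ramp(quiet$sweep)$rheobase_pA, 500)
  expect_length(quiet$truth$spike_times, 0)
})

test_that("measured rheobase is monotone in the planted threshold", {
  rheo <- vapply(c(-50, -45, -40, -35), function(vt) {
    sw <- make_patch_sweep(cell_params = list(R_m = 100, C_m = 150,
                                              V_rest = -65, V_thresh = vt),
                           noise_sd = 0.1, seed = 36)
    rheobase_from_ramp(sw$sweep)$rheobase_pA
  }, numeric(1))
  expect_true(all(diff(rheo) > 0))
})

test_that("RMP is the 500 ms pre-injection mean and requires that window", {
  sw <- make_patch_sweep(cell_params = std_cell, noise_sd = 0, seed = 37)
  expect_equal(rmp(sw$sweep), -65, tolerance = 1e-6)
  noisy <- make_patch_sweep(cell_params = std_cell, noise_sd = 0.5,
                            seed = 38)
  expect_equal(rmp(noisy$sweep), -65,
               tolerance = 3 * 0.5 / sqrt(5000) / 65)
  short <- sw$sweep
  short$current <- c(rep(-100, 1000), short$current[-(1:1000)])
  expect_error(rmp(short), "shorter")
})

test_that("QC excludes silent-initial-sweep cells, high R_in and drifted
           sweeps", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                          aps_initial_sweep = c(5, 0, 3, 4),
                          r_in = c(120, 150, 600, 90))
  sweeps <- tidyr::expand_grid(cell_id = cells$cell_id, sweep = 1:3) |>
    dplyr::mutate(rmp = c(-65, -65, -39, rep(-65, 9)))
  qc <- qc_filter(cells, sweeps)
  expect_setequal(qc$cells$cell_id, c("a", "d"))
  expect_equal(sum(qc$exclusions$level == "cell"), 2)
  # sweep with RMP -39 mV (> -40) excluded
  expect_equal(sum(qc$exclusions$level == "sweep"), 1)
  expect_equal(nrow(qc$sweeps), 5)

  # all-pass cohort: zero exclusions
  qc0 <- qc_filter(dplyr::mutate(cells, aps_initial_sweep = 3, r_in = 100),
                   dplyr::mutate(sweeps, rmp = -65))
  expect_equal(nrow(qc0$exclusions), 0)
})

test_that("time-binned summaries use the drug bins and baseline
           normalization", {
  # sweeps every 10 s from -70 s to 600 s around onset at t = 100
  tt <- seq(30, 700, by = 10)
  m <- tidyr::expand_grid(cell_id = c("n1", "n2"), t_s = tt) |>
    dplyr::mutate(r_in = 100, ap_count = 10)
  out <- time_bin_summary(m, t_drug_onset = 100)
  expect_equal(nrow(out), 6)
  expect_true(all(out$r_in == 100))
  expect_true(all(out$norm_ap_count == 1))

  # step change at onset shows in Drug, not Baseline
  m2 <- m |>
    dplyr::mutate(ap_count = ifelse(t_s >= 100, 4, 10))
  out2 <- time_bin_summary(m2, t_drug_onset = 100)
  base <- dplyr::filter(out2, bin == "Baseline")
  drug <- dplyr::filter(out2, bin == "Drug")
  expect_true(all(base$ap_count == 10))
  expect_true(all(drug$ap_count == 4))
  expect_true(all(base$norm_ap_count == 1))
  expect_true(all(drug$norm_ap_count == 0.4))

  # empty bin -> missing, not zero
  m3 <- dplyr::filter(m, t_s < 580)
  out3 <- time_bin_summary(m3, t_drug_onset = 100)
  expect_true(all(is.na(dplyr::filter(out3, bin == "Wash")$ap_count)))
})

test_that("culture firing frequency normalizes per-dose rates to baseline", {
  set.seed(39)
  epochs <- tibble::tibble(dose_uM = c(0, 0.1, 1, 10),
                           start_s = c(0, 90, 180, 270),
                           end_s = c(90, 180, 270, 360))
  # constant-rate Poisson firing: ratios ~ 1
  st <- cumsum(stats::rexp(3000, rate = 8))
  st <- st[st < 360]
  out <- culture_ap_frequency(st, epochs)
  expect_lt(max(abs(out$norm_freq - 1)), 0.2)
  # default window is centred in each epoch
  expect_equal(out$window_start_s, epochs$start_s + 15)

  # firing silenced at the top dose: ratio 0
  st2 <- st[st < 270]
  out2 <- culture_ap_frequency(st2, epochs)
  expect_equal(out2$norm_freq[4], 0)

  # zero baseline: flagged undefined
  expect_warning(culture_ap_frequency(st[st >= 90], epochs), "zero")
})

test_that("sweep_metrics summarizes a sweep consistently with ground truth", {
  sw <- make_patch_sweep(cell_params = std_cell, seed = 40)
  m <- sweep_metrics(sw$sweep)
  expect_equal(m$ap_count, length(sw$truth$spike_times))
  expect_equal(m$r_in, 100, tolerance = 0.02)
  expect_equal(m$rmp, -65, tolerance = 0.05)
  expect_lt(abs(m$rheobase_pA - sw$truth$rheobase_pA), 10)
})
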