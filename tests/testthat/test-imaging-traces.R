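# ROI trace extraction, DF/F cubic baseline, event responses, permutation
# significance, evoked responses, aligned averaging and the ACh-Ca
# regression.

test_that("trace extraction averages each ROI mask per frame", {
  frames <- array(7, dim = c(8, 8, 5))
  m1 <- matrix(FALSE, 8, 8); m1[1:3, 1:3] <- TRUE
  tr <- extract_traces(frames, list(m1))
  expect_equal(as.numeric(tr), rep(7, 5))

  # two disjoint blobs give independent traces
  frames2 <- array(0, dim = c(8, 8, 3))
  m2 <- matrix(FALSE, 8, 8); m2[6:8, 6:8] <- TRUE
  frames2[1:3, 1:3, ] <- 1
  frames2[6:8, 6:8, 2] <- 5
  tr2 <- extract_traces(frames2, list(m1, m2))
  expect_equal(tr2[, 1], rep(1, 3))
  expect_equal(tr2[, 2], c(0, 5, 0))

  # planted blob transient recovers its timing
  frames3 <- array(stats::rnorm(8 * 8 * 50, 100, 0.1), dim = c(8, 8, 50))
  frames3[1:3, 1:3, 25] <- 160
  tr3 <- extract_traces(frames3, list(m1))
  expect_equal(which.max(tr3), 25)

  expect_error(extract_traces(frames, list(matrix(FALSE, 8, 8))), "empty")
})

test_that("cubic drift is removed to near-zero DF/F and planted transients
           are preserved", {
  # pure cubic drift, no transients: |DF/F| < 0.01 everywhere
  ses0 <- make_imaging_session(n_rois = 3, duration_s = 600,
                               noise_sd = 0, seed = 91)
  for (r in 1:3) {
    d <- dff(ses0$ca[, r], 15)
    expect_lt(max(abs(d$dff)), 0.01)
    # fitted baseline matches the planted drift closely
    n <- nrow(ses0$ca)
    u <- ((seq_len(n) - 1) / 15) / 600
    B_true <- cbind(1, u, u^2, u^3) %*% ses0$truth$drift_coeffs[r, ]
    expect_lt(max(abs(d$baseline - B_true) / B_true), 0.02)
  }

  # 0.5-amplitude transients on the drift: recovered within 5%
  ses <- make_imaging_session(n_rois = 1, duration_s = 600,
                              seizure_times = c(100, 300, 480),
                              transient_amp = 0.5, noise_sd = 0.005,
                              seed = 92)
  d <- dff(ses$ca[, 1], 15)
  for (t0 in c(100, 300, 480)) {
    expect_lt(abs(event_response(d$dff, 15, t0) - 0.5) / 0.5, 0.05)
  }

  # constant trace: baseline constant, DF/F identically 0
  dc <- dff(rep(50, 900), 15)
  expect_equal(dc$dff, rep(0, 900))
  expect_equal(dc$baseline, rep(50, 900), tolerance = 1e-9)

  # DF/F is invariant to multiplicative gain
  dg <- dff(3.7 * ses$ca[, 1], 15)
  expect_equal(dg$dff, d$dff, tolerance = 1e-9)
})

test_that("running periods are excluded from the baseline fit", {
  # strong sustained elevation during running would drag a naive baseline
  ses <- make_imaging_session(n_rois = 1, duration_s = 400, noise_sd = 0,
                              seed = 93)
  f <- ses$ca[, 1]
  run <- intervals(150, 250)
  idx <- seq(150 * 15 + 1, 250 * 15)
  f[idx] <- f[idx] * 1.8
  d <- dff(f, 15, running_intervals = run)
  outside <- setdiff(seq_along(f), idx)
  expect_lt(max(abs(d$dff[outside])), 0.02)
})

test_that("event responses implement peak-over-baseline with window
           flagging", {
  flat <- rep(0, 600)
  expect_equal(event_response(flat, 15, 20), 0)

  stepped <- c(rep(0, 300), rep(1, 300))
  expect_equal(event_response(stepped, 15, 20), 1)

  # mean mode averages the post window instead of taking its peak
  tt <- (0:599) / 15
  dec <- ifelse(tt >= 20, 0.8 * exp(-(tt - 20) / 3), 0)
  expect_equal(event_response(dec, 15, 20), 0.8, tolerance = 0.05)
  expect_lt(event_response(dec, 15, 20, mode = "mean"), 0.8)

  tr <- event_response(flat, 15, 2)   # pre window truncated
  expect_true(is.na(tr))
  expect_true(attr(tr, "truncated"))
})

test_that("permutation criterion is strict and flags planted transients", {
  # all-zero trace: every response equals the 95th percentile, so the
  # strict ">" means nothing is significant
  zero <- rep(0, 1500)
  out0 <- permutation_significance(zero, 15, event_times = c(30, 50),
                                   n_random = 200, seed = 94)
  expect_false(any(out0$significant))

  ses <- make_imaging_session(n_rois = 1, duration_s = 600,
                              seizure_times = c(150, 400),
                              transient_amp = 0.5, noise_sd = 0.02,
                              seed = 95)
  d <- dff(ses$ca[, 1], 15)
  out <- permutation_significance(d$dff, 15, c(150, 400), seed = 96)
  expect_true(all(out$significant))
  expect_error(permutation_significance(rep(0, 100), 15, 10, seed = 1),
               "short")
})

test_that("the >95% criterion is calibrated to ~5% on event-free sessions", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    ses <- make_imaging_session(n_rois = 1, duration_s = 600,
                                noise_sd = 0.02, seed = 700 + s)
    d <- dff(ses$ca[, 1], 15)
    probes <- seq(20, 570, length.out = 20)
    out <- permutation_significance(d$dff, 15, probes, n_random = 500,
                                    seed = 800 + s)
    hits <- hits + sum(out$significant); total <- total + nrow(out)
  }
  frac <- hits / total
  expect_lt(abs(frac - 0.05), 1.96 * sqrt(0.05 * 0.95 / total) + 0.015)
})

test_that("evoked responses use the 30 s pre-stimulation baseline", {
  flat <- rep(0, 1500)
  expect_equal(evoked_response(flat, 15, stim_start = 50,
                               seizure_window = c(52, 64)), 0)

  tt <- (0:1499) / 15
  rise <- ifelse(tt >= 52 & tt < 64, 0.9, 0)
  expect_equal(evoked_response(rise, 15, 50, c(52, 64)), 0.9)
  expect_error(evoked_response(rise, 15, 50, NULL), "annotation")
  expect_error(evoked_response(rise, 15, 10, c(12, 20)), "unavailable")
})

test_that("aligned averages converge to the planted kernel with SEM
           bookkeeping", {
  fr <- 15
  kern <- function(tt) ifelse(tt >= 0, exp(-tt / 3), 0)
  n <- 600 * fr
  tt <- (seq_len(n) - 1) / fr
  events <- seq(30, 570, length.out = 21)
  base <- rowSums(sapply(events, function(e) 0.5 * kern(tt - e)))
  set.seed(97)
  noisy <- base + stats::rnorm(n, sd = 0.1)
  al <- align_average(noisy, fr, events, window = c(-5, 15))
  expect_equal(unique(al$n), 21)
  post <- al$time_s >= 0.5
  truth <- 0.5 * kern(al$time_s[post])
  rmse <- sqrt(mean((al$mean[post] - truth)^2))
  expect_lt(rmse, 3 * 0.1 / sqrt(21))

  # identical events: SEM is zero; single event equals its segment
  ident <- align_average(base, fr, events[2:4], window = c(-1, 5))
  expect_lt(max(ident$sem), 1e-7)
  one <- align_average(base, fr, events[5], window = c(-1, 5))
  i0 <- floor(events[5] * fr) + 1
  expect_equal(one$mean, base[(i0 - fr):(i0 + 5 * fr - 1)])
  expect_error(align_average(base, fr, -100, window = c(-1, 5)), "usable")
})

test_that("ACh-Ca regression recovers exact and coupled relationships", {
  x <- c(0.1, 0.2, 0.5, 0.8, 1.2)
  fit <- correlate_responses(2 * x, x)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r, 1)

  expect_error(correlate_responses(c(1, 2, 3), c(1, 1, 1)), "variance")

  # synthetic coupling 0.8 with noise
  set.seed(98)
  ca <- stats::runif(112, 0.2, 1.5)
  ach <- 0.8 * ca + stats::rnorm(112, sd = 0.08)
  fit2 <- correlate_responses(ach, ca)
  expect_equal(fit2$slope, 0.8, tolerance = 0.08)
  expect_gt(fit2$r, 0.9)
  gl <- glance(fit2)
  expect_equal(gl$n, 112)
  expect_s3_class(ggplot2::autoplot(fit2), "ggplot")
})

test_that("the regression CI covers zero at the nominal rate under the
           null", {
  cover <- vapply(1:200, function(s) {
    set.seed(4000 + s)
    ca <- stats::rnorm(112)
    ach <- stats::rnorm(112)
    fit <- correlate_responses(ach, ca)
    ci <- stats::confint(fit$fit)["x", ]
    ci[1] < 0 && ci[2] > 0
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.05)
})
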