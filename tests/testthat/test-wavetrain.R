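test_that("local maxima are strict 8-neighbour peaks inside the valid cone", {
  freqs <- seq(1, 20, by = 1)
  z <- matrix(0, 20, 100)
  z[8, 40] <- 1
  z[15, 70] <- 2
  sg <- toy_spectrogram(z, freqs)
  pk <- find_local_maxima(sg)
  expect_equal(nrow(pk), 2)
  expect_setequal(pk$f_central_hz, c(8, 15))
  # constant matrix -> no peaks (plateaus are not maxima)
  sgc <- toy_spectrogram(matrix(1, 20, 100), freqs)
  expect_equal(nrow(find_local_maxima(sgc)), 0)
  # plateau of two equal cells -> neither is a peak
  zp <- matrix(0, 20, 100)
  zp[8, 40] <- zp[8, 41] <- 1
  expect_equal(nrow(find_local_maxima(toy_spectrogram(zp, freqs))), 0)
  # outside the valid interval peaks are dropped
  sgm <- toy_spectrogram(z, freqs)
  sgm$valid_lo <- rep(50L, 20)
  expect_equal(find_local_maxima(sgm)$f_central_hz, 15)
  # unsmoothed input is an error
  expect_error(find_local_maxima(toy_spectrogram(z, freqs,
                                                 smoothed = FALSE)),
               "smoothed")
})

test_that("half-max measurement matches the Gaussian FWHM closed form", {
  fs <- 100
  freqs <- seq(5, 25, by = 0.1)
  nt <- 1000
  s_t <- 0.3
  s_f <- 1.5
  tax <- (seq_len(nt) - 1) / fs
  z <- exp(-outer((freqs - 15)^2 / (2 * s_f^2),
                  (tax - 5)^2 / (2 * s_t^2), "+"))
  sg <- toy_spectrogram(z, freqs, fs)
  pk <- find_local_maxima(sg)
  expect_equal(nrow(pk), 1)
  ev <- measure_wavetrain(sg, pk$fi, pk$ti)
  expect_true(is.na(ev$rejected_code))
  expect_equal(ev$duration_s, 2 * sqrt(2 * log(2)) * s_t, tolerance = 0.02)
  expect_equal(ev$bandwidth_hz, 2 * sqrt(2 * log(2)) * s_f,
               tolerance = 0.02)
  expect_equal(ev$duration_periods, ev$duration_s * 15, tolerance = 1e-9)
})

test_that("peaks cut by the record edge or engulfed by neighbours reject", {
  fs <- 100
  freqs <- seq(5, 25, by = 0.5)
  nt <- 400
  tax <- (seq_len(nt) - 1) / fs
  # blob whose half-max region runs past the end of the record
  z <- exp(-outer((freqs - 15)^2 / 8, (tax - 3.98)^2 / 2, "+"))
  sg <- toy_spectrogram(z, freqs, fs)
  pk <- find_local_maxima(sg)
  ev <- measure_wavetrain(sg, pk$fi[1], pk$ti[1])
  expect_equal(ev$rejected_code, "edge_time")
  # smaller peak on the flank of a dominant one: walking toward the large
  # peak, the slice rises above the small peak's own maximum before ever
  # dropping below its half-maximum -> engulfed
  tprof <- exp(-(tax - 1)^2 / 0.02) + 0.3 * exp(-(tax - 1.3)^2 / 0.02)
  z2 <- outer(exp(-(freqs - 15)^2 / 8), tprof)
  sg2 <- toy_spectrogram(z2, freqs, fs)
  pk2 <- find_local_maxima(sg2)
  expect_gte(nrow(pk2), 2)
  small <- which.min(pk2$psd_max)
  ev2 <- measure_wavetrain(sg2, pk2$fi[small], pk2$ti[small])
  expect_match(ev2$rejected_code, "engulfed")
})

test_that("the short-train filter drops strictly below a tenth period", {
  ev <- empty_frame <- data.frame(duration_periods = c(0.05, 0.1, 0.2))
  out <- filter_short(ev)
  expect_equal(out$duration_periods, c(0.1, 0.2))
  expect_equal(nrow(filter_short(ev[0, , drop = FALSE])), 0)
})

test_that("box selection is closed, monotone and composable", {
  set.seed(41)
  wtc <- simulate_event_cohort(3, 3, duration_s = 60)
  ev <- wtc$events
  bA <- parameter_box(min_freq = 8, max_freq = 20)
  bB <- parameter_box(min_psd = 20, max_psd = 200, min_duration = 1)
  # unbounded box is the identity
  expect_identical(select_box(ev, parameter_box()), ev)
  # closed interval membership
  ev2 <- data.frame(subject_id = "s", group = "g", arm = NA, muscle = NA,
                    t_peak_s = 1:3, f_central_hz = c(5, 10, 25),
                    psd_max = 1, duration_s = 1, duration_periods = 1,
                    bandwidth_hz = 1, rejected_code = NA)
  expect_equal(select_box(ev2, bA)$f_central_hz, 10)
  edge <- ev2
  edge$f_central_hz <- c(8, 20, 20.0001)
  expect_equal(nrow(select_box(edge, bA)), 2)
  # nested boxes -> non-increasing counts
  wide <- parameter_box(min_freq = 5, max_freq = 30)
  narrow <- parameter_box(min_freq = 10, max_freq = 20)
  expect_gte(nrow(select_box(ev, wide)), nrow(select_box(ev, narrow)))
  # composition equals intersection
  lhs <- select_box(select_box(ev, bA), bB)
  rhs <- select_box(ev, box_int <- parameter_box(
    min_freq = 8, max_freq = 20, min_psd = 20, max_psd = 200,
    min_duration = 1))
  expect_identical(lhs, rhs)
  expect_error(parameter_box(min_freq = 10, max_freq = 5), "min_freq")
})

test_that("rates divide counts by the valid duration", {
  ev <- data.frame(duration_periods = rep(1, 45))
  expect_equal(rate_per_second(ev, 90), 0.5)
  expect_equal(rate_per_second(ev[0, , drop = FALSE], 90), 0)
  expect_equal(rate_per_second(ev, 45), 1)
})

test_that("detection is deterministic and every event satisfies invariants", {
  set.seed(77)
  rec <- burst_in_noise_record(12, 2, amplitude = 40, sigma = 5)
  wt1 <- detect_wavetrains(rec, fmin = 2, fmax = 40, fstep = 0.2)
  wt2 <- detect_wavetrains(rec, fmin = 2, fmax = 40, fstep = 0.2)
  expect_identical(wt1$events, wt2$events)
  ev <- wt1$events
  expect_gt(nrow(ev), 0)
  expect_true(all(diff(ev$t_peak_s) >= 0))
  expect_true(all(ev$duration_periods >= 0.1))
  expect_true(all(ev$psd_max > 0 & ev$duration_s > 0 & ev$bandwidth_hz > 0))
  expect_true(all(ev$f_central_hz > 2 & ev$f_central_hz < 40))
  # the injected burst is among the detections
  expect_true(any(abs(ev$f_central_hz - 12) < 1 & abs(ev$t_peak_s - 6) < 1))
})

test_that("noise-only records stay below the calibrated false-positive ceiling", {
  # ceiling calibrated by simulation: smoothed white-noise spectrograms
  # carry on the order of one spurious maximum per resolution cell,
  # about 4.5/s over the 1-50 Hz grid at 125 Hz; scale-free in sigma
  set.seed(13)
  rec <- signal_record(rnorm(30 * 125, 0, 4), 125,
                       stage = "decimated_envelope")
  wt <- detect_wavetrains(rec, fmin = 1, fmax = 50, fstep = 0.2)
  expect_lt(rate_per_second(wt), 7)
  rec2 <- rec
  rec2$samples <- rec$samples * 100
  wt2 <- detect_wavetrains(rec2, fmin = 1, fmax = 50, fstep = 0.2)
  expect_equal(nrow(wt2$events), nrow(wt$events))
})

test_that("cohort pooling tracks subjects and rejects duplicates", {
  set.seed(5)
  r1 <- burst_in_noise_record(10, 2, dur = 8)
  r2 <- burst_in_noise_record(14, 2, dur = 8)
  r1$subject_id <- "a"
  r1$group <- "control"
  r2$subject_id <- "b"
  r2$group <- "patient"
  w1 <- detect_wavetrains(r1, fmin = 2, fmax = 30, fstep = 0.5)
  w2 <- detect_wavetrains(r2, fmin = 2, fmax = 30, fstep = 0.5)
  wtc <- wavetrain_cohort(list(w1, w2))
  expect_equal(nrow(wtc$subjects), 2)
  expect_equal(nrow(wtc$events), nrow(w1$events) + nrow(w2$events))
  r <- cohort_rates(wtc)
  expect_equal(r$n_events[r$subject_id == "a"], nrow(w1$events))
  w2$subject_id <- "a"
  expect_error(wavetrain_cohort(list(w1, w2)), "duplicated")
})
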