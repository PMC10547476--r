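make_square <- function(period, duty, segment_length = 40, dt = 0.1,
                        noise_sd = 0, seed = NULL, drift = 0) {
  make_trace(wave_spec("slow", period = period, duty = duty, baseline = 1,
                       amplitude = 0.5, noise_sd = noise_sd,
                       drift_slope = drift, seed = seed),
             segment_length = segment_length, sampling_interval = dt)
}

test_that("linear detrending removes a pure line exactly and is idempotent", {
  time <- seq(0, 39.9, 0.1)
  tr <- islet_trace(time, 2 + 0.05 * time, "I1")
  det <- detrend_segment(tr, detrend_settings("linear"))
  expect_lt(diff(range(det$values)), 1e-9)
  expect_equal(mean(det$values), mean(tr$values), tolerance = 1e-12)
  again <- detrend_segment(det, detrend_settings("linear"))
  expect_equal(again$values, det$values, tolerance = 1e-12)
})

test_that("moving-median detrending recovers a drifting square wave's amplitude", {
  tr <- make_square(period = 4, duty = 0.5, drift = 0.02)
  det <- detrend_segment(tr, detrend_settings("moving_median", window = 12))
  # per-cycle peak-to-trough against the noiseless, drift-free generator output
  clean <- make_square(period = 4, duty = 0.5)
  cyc <- rep(1:10, each = 40)
  rng <- function(v) tapply(v, cyc, max) - tapply(v, cyc, min)
  expect_true(all(abs(rng(det$values) - rng(clean$values)) <
                    0.02 * diff(range(clean$values))))
})

test_that("a constant trace passes through detrending unchanged", {
  tr <- islet_trace(seq(0, 39.9, 0.1), rep(1.4, 400), "I1")
  det <- detrend_segment(tr, detrend_settings("moving_median", window = 10))
  expect_equal(det$values, tr$values, tolerance = 1e-12)
})

test_that("pulse detection counts supra-threshold runs", {
  tr <- make_square(period = 4, duty = 0.5)
  pulses <- detect_oscillations(tr)
  expect_equal(nrow(pulses), 10L)
  expect_equal(sum(pulses$complete), 9L)  # first burst starts on frame 1
  expect_true(all(diff(pulses$peak_time) > 0))
  # constant elevated trace: no pulses at all
  flat <- islet_trace(seq(0, 39.9, 0.1), rep(1.5, 400), "I1")
  expect_equal(nrow(detect_oscillations(flat)), 0L)
})

test_that("mixed slow-plus-fast waves count slow bursts only at the 50% level", {
  tr <- make_trace(wave_spec("mixed", period = 6, duty = 0.5, period_fast = 1,
                             baseline = 1, amplitude = 0.5), 42, 0.1)
  pulses <- detect_oscillations(tr)
  v <- tr$values
  thr <- attr(pulses, "baseline") + 0.5 * attr(pulses, "amplitude")
  expect_equal(nrow(pulses), brute_force_run_count(v, thr))
  expect_equal(nrow(pulses), 7L)  # one run per slow cycle
})

test_that("waveform parameters recover the generator's period and duty", {
  tr <- make_square(period = 4, duty = 0.3)
  params <- compute_waveform_params(detect_oscillations(tr), tr)
  expect_equal(params$regime, "oscillating")
  expect_lt(abs(params$period_min - 4), 0.1)
  expect_lt(abs(params$active_min - 1.2), 0.1)
  expect_lt(abs(params$silent_min - 2.8), 0.1)
  expect_lt(abs(params$plateau_fraction - 0.3), 0.03)
  expect_gte(params$pulse_min, params$active_min)
})

test_that("plateau and silent segments get the edge-case parameter codes", {
  flat_hi <- islet_trace(seq(0, 39.9, 0.1), rep(1.5, 400), "I1")
  p <- compute_waveform_params(detect_oscillations(flat_hi), flat_hi,
                               baseline_ref = 1)
  expect_equal(p$regime, "plateau")
  expect_equal(p$plateau_fraction, 1)
  expect_equal(p$period_min, 0)
  expect_equal(p$active_min, 40)
  expect_equal(p$pulse_min, 40)
  flat_lo <- islet_trace(seq(0, 39.9, 0.1), rep(1.0, 400), "I2")
  s <- compute_waveform_params(detect_oscillations(flat_lo), flat_lo,
                               baseline_ref = 1)
  expect_equal(s$regime, "silent")
  expect_equal(s$plateau_fraction, 0)
  expect_equal(s$period_min, 40)
  expect_equal(s$active_min, 0)
  expect_equal(s$pulse_min, 0)
})

test_that("a single-pulse segment reports durations but no period", {
  # one 2-min burst in the middle of a 40-min segment
  time <- seq(0, 39.9, 0.1)
  v <- 1 + 0.5 * (time >= 19 & time < 21)
  tr <- islet_trace(time, v, "I1")
  p <- compute_waveform_params(detect_oscillations(tr), tr, baseline_ref = 1)
  expect_equal(p$regime, "oscillating")
  expect_true(is.na(p$period_min))
  expect_true(is.na(p$silent_min))
  expect_true(is.na(p$plateau_fraction))
  expect_lt(abs(p$active_min - 2), 0.15)
  expect_equal(p$speed_class, "none")
})

test_that("speed classification follows the 2- and 10-minute boundaries", {
  expect_equal(classify_speed(1, "oscillating"), "fast")
  expect_equal(classify_speed(5, "oscillating"), "slow")
  expect_equal(classify_speed(c(1.99, 2, 10, 10.5),
                              rep("oscillating", 4)),
               c("fast", "slow", "slow", "none"))
  expect_equal(classify_speed(0, "plateau"), "none")
  expect_equal(classify_speed(40, "silent"), "none")
  expect_equal(classify_speed(NA_real_, "oscillating"), "none")
})

test_that("the silent-plus-active identity holds exactly for oscillating records", {
  coh <- two_strain_cohort(noise_sd = 0.01, seed = 21)
  params <- extract_params(coh)
  osc <- params[params$regime == "oscillating" & !is.na(params$period_min), ]
  expect_gt(nrow(osc), 0L)
  expect_equal(osc$silent_min + osc$active_min, osc$period_min,
               tolerance = 1e-12)
  expect_true(all(osc$plateau_fraction > 0 & osc$plateau_fraction < 1))
})

test_that("parameters are recovered across the noiseless period-duty grid", {
  for (period in c(0.5, 1, 4, 10)) {
    for (duty in c(0.1, 0.5, 0.9)) {
      dt <- min(0.1, period * duty / 2, period * (1 - duty) / 2)
      tr <- make_trace(wave_spec("slow", period = period, duty = duty,
                                 baseline = 1, amplitude = 0.5),
                       segment_length = 40, sampling_interval = dt)
      p <- compute_waveform_params(detect_oscillations(tr), tr)
      expect_lt(abs(p$period_min - period), dt + 1e-9,
                label = sprintf("period error at (%g, %g)", period, duty))
      expect_lt(abs(p$plateau_fraction - duty), 2 * dt / period + 1e-9,
                label = sprintf("duty error at (%g, %g)", period, duty))
    }
  }
})

test_that("estimated active duration is monotone in generator duty", {
  est <- vapply(seq(0.15, 0.85, by = 0.1), function(duty) {
    tr <- make_square(period = 4, duty = duty)
    compute_waveform_params(detect_oscillations(tr), tr)$active_min
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("median period error stays small under 10% amplitude noise", {
  errs <- vapply(1:20, function(seed) {
    tr <- make_square(period = 4, duty = 0.5, noise_sd = 0.05, seed = seed)
    det <- detrend_segment(tr, detrend_settings("moving_median", window = 12))
    p <- compute_waveform_params(detect_oscillations(det), det)
    abs(p$period_min - 4) / 4
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("animal summaries average islets, edge codes included", {
  params <- data.frame(
    islet_id = c("a1", "a2", "b1"),
    strain = "S", sex = "F", animal = c("A", "A", "B"),
    segment = "8G",
    plateau_fraction = c(0.2, 0.4, 0.5),
    period_min = c(4, NA, 5),
    stringsAsFactors = FALSE)
  out <- summarize_animal(params, value_cols = c("plateau_fraction", "period_min"))
  expect_equal(out$plateau_fraction[out$animal == "A"], 0.3)
  expect_equal(out$period_min[out$animal == "A"], 4)  # NA period dropped
  expect_equal(out$plateau_fraction[out$animal == "B"], 0.5)
  expect_equal(out$n_islets, c(2L, 1L))
  # mean of a plateau (edge code 1) and an oscillating islet
  mixed <- params
  mixed$plateau_fraction <- c(1, 0.5, 0)
  out2 <- summarize_animal(mixed, value_cols = "plateau_fraction")
  expect_equal(out2$plateau_fraction[out2$animal == "A"], 0.75)
})

test_that("the full extraction pipeline is deterministic", {
  coh <- two_strain_cohort(noise_sd = 0.02, seed = 33)
  expect_identical(extract_params(coh), extract_params(coh))
})
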