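test_that("pulse detection recovers rectangular pulse features exactly", {
  fs <- 1e6
  # all-baseline waveform
  quiet <- rect_waveform(data.frame(t0 = numeric(0), len = numeric(0),
                                    h = numeric(0))[0, ], fs = fs)
  quiet$samples <- quiet$samples + 0.1
  expect_equal(nrow(detect_pulses(quiet, threshold = 1)), 0L)
  # single rectangular pulse: height h, duration T, area h*T
  w <- rect_waveform(data.frame(t0 = 3e-4, len = 5e-5, h = 2), fs = fs,
                     baseline = 0.1)
  p <- detect_pulses(w, threshold = 1, hysteresis = 0.2)
  expect_equal(nrow(p), 1L)
  expect_equal(p$height, 2, tolerance = 1e-12)
  expect_lt(abs(p$width - 5e-5), 2 / fs)
  expect_lt(abs(p$area - 2 * 5e-5), 2 * 2 / fs)
  expect_lt(p$t_rise, p$t_fall)
  # two separated pulses with hand-computed features
  w2 <- rect_waveform(data.frame(t0 = c(1e-4, 5e-4), len = c(4e-5, 8e-5),
                                 h = c(1.5, 3)), fs = fs, baseline = 0.1)
  p2 <- detect_pulses(w2, threshold = 0.8, hysteresis = 0.1)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$height, c(1.5, 3), tolerance = 1e-12)
  expect_lt(abs(p2$area[1] - 1.5 * 4e-5), 2 * 1.5 / fs)
  expect_lt(abs(p2$area[2] - 3 * 8e-5), 2 * 3 / fs)
  expect_lt(abs((p2$t_rise[2] - p2$t_rise[1]) - 4e-4), 2 / fs)
  expect_error(detect_pulses(list(samples = 1, sampling_rate = 1)), "short")
})

test_that("event grouping assembles the expected sub-pulse multiplets", {
  fs <- 1e6
  # R1: isolated pulses, one event each
  w <- rect_waveform(data.frame(t0 = c(1, 3, 5) * 1e-4, len = 2e-5, h = 2),
                     fs = fs)
  ev <- group_events(detect_pulses(w, 1, 0.2), "R1")
  expect_equal(nrow(ev), 3L)
  expect_true(all(ev$flag == "clean"))
  expect_true(all(ev$n_pulses == 1L))
  # R3 triplets at the 55 um / v sub-spot pitch
  v <- 4.8
  pitch_t <- 55e-6 / v
  starts <- c(0, pitch_t, 2 * pitch_t)
  trip <- rect_waveform(
    data.frame(t0 = 2e-4 + c(starts, 2e-3 + starts),
               len = c(2e-6, 1e-5, 2e-6), h = 2), fs = 1e7, duration = 4e-3)
  ev3 <- group_events(detect_pulses(trip, 1, 0.2), "R3",
                      nominal_velocity = v)
  expect_equal(nrow(ev3), 2L)
  expect_true(all(ev3$n_pulses == 3L))
  expect_true(all(ev3$flag == "clean"))
  expect_equal(ev3$total_area[1],
               sum(detect_pulses(trip, 1, 0.2)$area[1:3]), tolerance = 1e-12)
  # a fourth pulse inside the gap window flags the group as coincident
  quad <- rect_waveform(
    data.frame(t0 = 2e-4 + c(starts, 3 * pitch_t), len = 2e-6, h = 2),
    fs = 1e7, duration = 2e-3)
  ev4 <- group_events(detect_pulses(quad, 1, 0.2), "R3",
                      nominal_velocity = v)
  expect_equal(ev4$flag, "coincident")
  # missing sub-pulse flags incomplete
  duo <- rect_waveform(data.frame(t0 = 2e-4 + starts[1:2], len = 2e-6, h = 2),
                       fs = 1e7, duration = 2e-3)
  ev2 <- group_events(detect_pulses(duo, 1, 0.2), "R3", nominal_velocity = v)
  expect_equal(ev2$flag, "incomplete")
})

test_that("time-of-flight velocity follows (L/T1 + L/T2)/2", {
  mk <- function(rises, falls) data.frame(t_rise = rises, t_fall = falls)
  # symmetric intervals: 110 um / 22.92 us = 4.80 m/s
  ev <- mk(c(0, 22.92e-6), c(3e-6, 25.92e-6))
  expect_equal(estimate_velocity(ev, 110e-6), 110e-6 / 22.92e-6,
               tolerance = 1e-12)
  expect_equal(round(estimate_velocity(ev, 110e-6), 2), 4.80)
  # asymmetric intervals average the two single-edge estimates
  ev2 <- mk(c(0, 20e-6), c(2e-6, 27e-6))
  expect_equal(estimate_velocity(ev2, 110e-6), (5.5 + 4.4) / 2,
               tolerance = 1e-12)
  # T1 = T2 reduces to L/T1 exactly
  ev3 <- mk(c(0, 10e-6), c(1e-6, 11e-6))
  expect_identical(estimate_velocity(ev3, 110e-6),
                   110e-6 / 10e-6)
  expect_error(estimate_velocity(mk(0, 1e-6), 110e-6), "two sub-pulses")
  expect_error(estimate_velocity(mk(c(0, 0), c(2e-6, 1e-6)), 110e-6),
               "non-positive")
})

test_that("the 90-percent gate and CV match hand and analytic oracles", {
  # constant areas
  g0 <- gate_and_cv(rep(7, 50))
  expect_equal(g0$cv, 0)
  expect_equal(g0$n_gated, 45L)
  # hand-worked example: floor(0.9 * 6) = 5 retained, sd/mean = 15.81%
  g <- gate_and_cv(c(8, 9, 10, 11, 12, 100), min_events = 6L)
  expect_equal(g$n_gated, 5L)
  expect_equal(g$mean_area, 10)
  expect_equal(g$cv, stats::sd(8:12) / 10, tolerance = 1e-12)
  expect_equal(round(100 * g$cv, 2), 15.81)
  # truncated-normal analytic check: central 90 percent of N(100, 10)
  set.seed(123)
  a <- stats::rnorm(1e4, 100, 10)
  gn <- gate_and_cv(a)
  z <- stats::qnorm(0.95)
  analytic <- 0.1 * sqrt(1 - 2 * z * stats::dnorm(z) / 0.9)
  expect_lt(abs(gn$cv - analytic), 0.003)
  expect_error(gate_and_cv(1:5), "insufficient")
  # tie-breaking prefers the smaller area
  gt <- gate_and_cv(c(5, 15, 10, 10, 10, 10, 10, 10, 10, 10),
                    retain = 0.9)
  expect_equal(gt$gate_bounds, c(5, 10))
})

test_that("grouped event areas match the span integral (additivity)", {
  spot <- ideal_spot_model("R3")
  pop <- bead_population(concentration = 5e4 * 1e6, brightness_cv = 0.05)
  acq <- acquisition_config(duration = 0.3, rng_seed = 21, noise = FALSE)
  run <- simulate_run(spot, pop, 4.8, ul_per_min(60), acq)
  an <- analyze_waveform(run, "R3", 4.8)
  clean <- an$events[an$events$flag == "clean", ]
  expect_gte(nrow(clean), 10)
  dt <- 1 / run$sampling_rate
  pad <- round(5e-6 / 4.8 / dt)   # one bead radius of margin
  for (k in seq_len(min(10, nrow(clean)))) {
    i1 <- max(1L, round(clean$t_start[k] / dt) - pad)
    i2 <- min(length(run$samples), round(clean$t_end[k] / dt) + pad)
    span <- sum(run$samples[i1:i2] - run$baseline) * dt
    expect_lt(abs(clean$total_area[k] / span - 1), 5e-3)
  }
})

test_that("an R1 analysis leaves the velocity column empty", {
  spot <- ideal_spot_model("R1")
  pop <- bead_population(concentration = 1e5 * 1e6)
  run <- simulate_run(spot, pop, 4.8, ul_per_min(60),
                      acquisition_config(duration = 0.1, rng_seed = 2))
  an <- analyze_waveform(run, "R1", 4.8)
  expect_true(all(is.na(an$events$velocity)))
  expect_gt(an$stats$n_clean, 0)
})

test_that("velocity estimates sharpen as detector noise vanishes", {
  spot <- ideal_spot_model("R2")
  pop <- bead_population(concentration = 1e5 * 1e6, brightness_cv = 0,
                         lateral_offset_sd = 0)
  cv_for <- function(noise, snr = 20) {
    acq <- acquisition_config(duration = 0.25, rng_seed = 31, noise = noise,
                              snr = snr)
    run <- simulate_run(spot, pop, 4.8, ul_per_min(60), acq)
    an <- analyze_waveform(run, "R2", 4.8)
    an$stats$velocity_cv
  }
  noisy <- cv_for(TRUE, snr = 10)
  mid <- cv_for(TRUE, snr = 40)
  clean <- cv_for(FALSE)
  expect_gt(noisy, mid)
  expect_gt(mid, clean)
  expect_lt(clean, 1e-3)   # < 0.1 percent in the noise-free limit
})
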