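test_that("transit profiles follow convolution support arithmetic", {
  spot <- ideal_spot_model("R1", pitch = 0.25e-6)
  # point bead: the profile is the raw 10 um intensity bar
  p0 <- transit_profile(spot, 0, 0)
  supp <- range(p0$s[p0$excitation > max(p0$excitation) / 2])
  expect_lt(abs(diff(supp) - 10e-6), 2 * p0$pitch)
  # 5 um bead on the 10 um bar: trapezoid, base 15 um, plateau 5 um
  p5 <- transit_profile(spot, 0, 5e-6)
  base <- range(p5$s[p5$excitation > max(p5$excitation) * 1e-6])
  plateau <- range(p5$s[p5$excitation > max(p5$excitation) * 0.995])
  expect_lt(abs(diff(base) - 15e-6), 3 * p5$pitch)
  expect_lt(abs(diff(plateau) - 5e-6), 3 * p5$pitch)
  # brute-force convolution oracle at a lateral offset (radius chosen off
  # the pixel lattice so no pixel sits exactly on the disc boundary)
  off <- 4e-6; dia <- 3.1e-6
  pr <- transit_profile(spot, off, dia)
  x <- grid_coords(ncol(spot$intensity), spot$pitch)
  y <- grid_coords(nrow(spot$intensity), spot$pitch)
  r <- dia / 2
  ks <- which(abs(x - off) <= r)
  oracle <- vapply(seq_along(y), function(i) {
    tot <- 0; cnt <- 0
    for (j in ks) for (di in which(abs(y - y[i]) <= r)) {
      if ((x[j] - off)^2 + (y[di] - y[i])^2 <= r^2) {
        tot <- tot + spot$intensity[di, j]; cnt <- cnt + 1
      }
    }
    if (cnt > 0) tot / cnt else 0
  }, numeric(1))
  expect_lt(max(abs(pr$excitation - oracle)) / max(oracle), 1e-10)
})

test_that("three-rectangle spots give three lobes with 10:50:10 areas", {
  spot <- ideal_spot_model("R3", pitch = 0.5e-6)
  p <- transit_profile(spot, 0, 0)
  lobe <- function(lo, hi) sum(p$excitation[p$s >= lo & p$s < hi]) * p$pitch
  side1 <- lobe(-80e-6, -30e-6)
  mid <- lobe(-30e-6, 30e-6)
  side2 <- lobe(30e-6, 80e-6)
  expect_equal(mid / side1, 5, tolerance = 1e-6)
  expect_equal(side2 / side1, 1, tolerance = 1e-6)
})

test_that("noise-free pulses scale exactly with brightness and velocity", {
  spot <- ideal_spot_model("R1")
  pr <- transit_profile(spot, 0, 5e-6)
  acq <- acquisition_config(sampling_rate = 1e8, noise = FALSE,
                            baseline_frac = 0)
  ev <- simulate_event(pr, 4.8, brightness = 2, acquisition = acq)
  # flat top: plateau constant to near machine precision
  plateau <- ev$samples[ev$samples > max(ev$samples) * 0.999999]
  expect_gt(length(plateau), 5)
  expect_lt(diff(range(plateau)) / max(plateau), 1e-9)
  # area = brightness * spatial integral / velocity (quadrature error only)
  area <- sum(ev$samples) / acq$sampling_rate
  expect_equal(area, 2 * sum(pr$excitation) * pr$pitch / 4.8,
               tolerance = 1e-3)
  # doubling velocity halves width and area, leaves height unchanged
  ev2 <- simulate_event(pr, 9.6, brightness = 2, acquisition = acq)
  area2 <- sum(ev2$samples) / acq$sampling_rate
  expect_equal(area2, area / 2, tolerance = 1e-3)
  expect_equal(max(ev2$samples), max(ev$samples), tolerance = 1e-6)
  w1 <- sum(ev$samples > max(ev$samples) / 2) / acq$sampling_rate
  w2 <- sum(ev2$samples > max(ev2$samples) / 2) / acq$sampling_rate
  expect_equal(w2, w1 / 2, tolerance = 5e-3)
  # base width at the reference operating point: (10 + 5) um / 4.8 m/s,
  # up to the one-pixel anti-aliased skirt of the rasterized bar
  base <- range(ev$t[ev$samples > max(ev$samples) * 1e-9])
  expect_lt(abs(diff(base) - 15e-6 / 4.8), 3 * spot$pitch / 4.8)
  # too-coarse sampling is rejected
  expect_error(simulate_event(pr, 4.8, acquisition = acquisition_config(
    sampling_rate = 1e6, noise = FALSE)), "coarse")
})

test_that("bead arrivals form the configured Poisson process", {
  spot <- ideal_spot_model("R1")
  pop <- bead_population()   # 5e6 per ml
  acq <- acquisition_config(duration = 0.25, rng_seed = 42, noise = FALSE)
  run <- simulate_run(spot, pop, 4.8, ul_per_min(60), acq)
  # rate = 5e6/ml * 60 ul/min = 5000 events/s
  lambda <- 5e6 * 1e6 * ul_per_min(60) * acq$duration
  expect_equal(lambda, 1250)
  expect_gte(nrow(run$truth), stats::qpois(5e-4, lambda))
  expect_lte(nrow(run$truth), stats::qpois(1 - 5e-4, lambda))
  expect_false(is.unsorted(run$truth$t0))
  # zero concentration: baseline-only waveform, empty truth table
  run0 <- simulate_run(spot, bead_population(concentration = 0), 4.8,
                       ul_per_min(60), acq)
  expect_equal(nrow(run0$truth), 0L)
  expect_true(all(run0$samples == run0$baseline))
  # determinism under a fixed seed
  run_b <- simulate_run(spot, pop, 4.8, ul_per_min(60), acq)
  expect_identical(run$samples, run_b$samples)
  expect_identical(run$truth, run_b$truth)
})

test_that("ideal spot, no noise and no spread give identical event areas", {
  spot <- ideal_spot_model("R1")
  pop <- bead_population(concentration = 1e5 * 1e6, brightness_cv = 0,
                         lateral_offset_sd = 0)
  acq <- acquisition_config(duration = 0.3, rng_seed = 9, noise = FALSE,
                            sampling_rate = 1e8)
  run <- simulate_run(spot, pop, 4.8, ul_per_min(60), acq)
  an <- analyze_waveform(run, "R1", 4.8)
  expect_gte(an$stats$n_clean, 15)
  expect_lt(an$stats$gated$cv, 1e-3)
})

test_that("illumination roughness inflates the area CV monotonically", {
  pop <- bead_population(concentration = 1e5 * 1e6, brightness_cv = 0)
  cvs <- vapply(c(0.05, 0.15, 0.3), function(a) {
    spot <- roughen_spot(ideal_spot_model("R1"), a, corr_length = 5e-6,
                         seed = 3)
    run <- simulate_run(spot, pop, 4.8, ul_per_min(60),
                        acquisition_config(duration = 0.4, rng_seed = 5,
                                           noise = FALSE))
    analyze_waveform(run, "R1", 4.8)$stats$gated$cv
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
  # with non-zero intrinsic brightness CV the measured CV must exceed it
  spot <- roughen_spot(ideal_spot_model("R1"), 0.15, corr_length = 5e-6,
                       seed = 3)
  pop2 <- bead_population(concentration = 1e5 * 1e6, brightness_cv = 0.03)
  run2 <- simulate_run(spot, pop2, 4.8, ul_per_min(60),
                       acquisition_config(duration = 0.4, rng_seed = 6,
                                          noise = FALSE))
  expect_gt(analyze_waveform(run2, "R1", 4.8)$stats$gated$cv, 0.03)
})

test_that("roughen_spot preserves power and hits the requested amplitude", {
  spot <- ideal_spot_model("R2")
  r <- roughen_spot(spot, 0.2, 5e-6, seed = 1)
  expect_equal(sum(r$intensity) * r$pitch^2, spot$total_power,
               tolerance = 1e-9)
  expect_identical(roughen_spot(spot, 0), spot)
})
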