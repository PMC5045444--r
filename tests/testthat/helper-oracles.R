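# Independent oracles and small fixtures shared across the test files.

# Brute-force double-sum evaluation of the Fraunhofer integral on the same
# sample-centred grid convention as propagate_to_focal(): no FFT involved.
brute_force_focal <- function(values, dx, wavelength, focal_length) {
  n <- nrow(values)
  lf <- wavelength * focal_length
  coords <- (seq_len(n) - (n %/% 2 + 1)) * dx
  du <- lf / (n * dx)
  freqs <- (seq_len(n) - (n %/% 2 + 1)) * du
  u <- matrix(0i, n, n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      ph <- exp(-2i * pi * (outer(coords * freqs[p], coords * freqs[q], "+")) / lf)
      u[p, q] <- sum(values * ph) * dx^2 / lf
    }
  }
  u
}

# A small optical system used when the full 128-zone design is overkill.
toy_config <- function(zones = 32L, levels = 16L) {
  optical_config(zones_per_side = zones, phase_levels = levels)
}

# Hand-built target object with an arbitrary amplitude (bypasses rectangle
# rasterization); used for fixed-point tests of the iteration.
raw_target <- function(amplitude, signal_region, pitch) {
  amp <- amplitude / sqrt(sum(amplitude^2) * pitch^2)
  structure(list(kind = "custom", amplitude = amp,
                 signal_region = signal_region,
                 geometry = data.frame(cx = 0, cy = 0, width = 1, height = 1),
                 pitch = pitch),
            class = "target_spot")
}

# Rectangular test waveform: baseline plus rectangular pulses given as
# (start time, duration, height).
rect_waveform <- function(pulses, fs = 1e6, duration = 1e-3, baseline = 0) {
  n <- round(duration * fs)
  x <- rep(baseline, n)
  for (k in seq_len(nrow(pulses))) {
    i1 <- round(pulses$t0[k] * fs) + 1L
    i2 <- round((pulses$t0[k] + pulses$len[k]) * fs)
    x[i1:i2] <- baseline + pulses$h[k]
  }
  list(samples = x, sampling_rate = fs, duration = duration)
}
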