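#' Illumination spot model for the transit simulator
#'
#' A non-negative intensity map on a calibrated focal grid (rows = along
#' flow y, columns = across flow x), scaled so that it integrates to the
#' delivered optical power. Build one from an ideal target pattern
#' ([ideal_spot_model()]) or from a designed focal field
#' ([spot_model_from_field()]).
#'
#' @param intensity Non-negative matrix.
#' @param pitch Sample pitch in metres.
#' @param total_power Delivered power in watts (default 20 mW).
#' @return An object of class `spot_model`.
#' @export
spot_model <- function(intensity, pitch, total_power = 20e-3) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  if (any(intensity < 0)) stop("intensity must be non-negative", call. = FALSE)
  tot <- sum(intensity) * pitch^2
  if (tot <= 0) stop("intensity map is empty", call. = FALSE)
  structure(list(intensity = intensity * total_power / tot,
                 pitch = pitch, total_power = total_power),
            class = "spot_model")
}

#' @rdname spot_model
#' @param spot_kind `"R1"`, `"R2"` or `"R3"`.
#' @param n Grid size; by default just large enough to hold the pattern
#'   plus a 15 um margin.
#' @export
ideal_spot_model <- function(spot_kind = c("R1", "R2", "R3"),
                             pitch = 0.815e-6, n = NULL,
                             total_power = 20e-3) {
  spot_kind <- match.arg(spot_kind)
  extent <- max(50e-6, switch(spot_kind, R1 = 10e-6, R2 = 120e-6,
                              R3 = 120e-6))
  if (is.null(n)) n <- 2L * ceiling((extent / 2 + 15e-6) / pitch) + 2L
  tgt <- make_target(spot_kind, n = n, pitch = pitch)
  spot_model(tgt$amplitude^2, pitch, total_power)
}

#' @rdname spot_model
#' @param focal Focal-plane [complex_field()] (e.g. from
#'   [mask_focal_field()]).
#' @export
spot_model_from_field <- function(focal, total_power = 20e-3) {
  stopifnot(inherits(focal, "complex_field"))
  spot_model(Mod(focal$values)^2, focal$sample_pitch, total_power)
}

#' Impose a smooth multiplicative roughness on a spot
#'
#' Multiplies the intensity by `max(0, 1 + f)` where `f` is Gaussian-
#' correlated noise of standard deviation `amplitude` and correlation
#' length `corr_length`. Used to emulate non-uniform (RMSI > 0) real spots
#' when studying how illumination non-uniformity inflates the measured
#' fluorescence CV.
#'
#' @param spot A [spot_model()].
#' @param amplitude Relative roughness standard deviation (>= 0).
#' @param corr_length Correlation length in metres.
#' @param seed RNG seed for the noise field.
#' @return A roughened [spot_model()] of the same total power.
#' @export
roughen_spot <- function(spot, amplitude, corr_length = 5e-6, seed = 0L) {
  stopifnot(inherits(spot, "spot_model"))
  if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
  if (amplitude == 0) return(spot)
  n <- nrow(spot$intensity)
  set.seed(seed)
  f <- matrix(stats::rnorm(n * n), n, n)
  sig <- corr_length / spot$pitch
  k <- seq(-ceiling(3 * sig), ceiling(3 * sig))
  g <- exp(-k^2 / (2 * sig^2)); g <- g / sum(g)
  # separable Gaussian smoothing with edge renormalization
  smooth1 <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    wsum <- numeric(nrow(m))
    for (j in seq_along(k)) {
      src <- seq_len(nrow(m)) + k[j]
      ok <- src >= 1L & src <= nrow(m)
      out[ok, ] <- out[ok, ] + g[j] * m[src[ok], ]
      wsum[ok] <- wsum[ok] + g[j]
    }
    out / wsum
  }
  f <- smooth1(f)          # along flow
  f <- t(smooth1(t(f)))    # across flow
  f <- f / stats::sd(f) * amplitude
  spot_model(spot$intensity * pmax(0, 1 + f), spot$pitch, spot$total_power)
}

#' Bead population parameters
#'
#' @param diameter Bead diameter in metres (default 5 um).
#' @param concentration Beads per m^3 (default 5e6 per ml = 5e12 per m^3).
#' @param brightness_cv Intrinsic relative spread of per-bead brightness
#'   (log-normal, mean 1).
#' @param lateral_offset_sd Standard deviation of the bead's across-flow
#'   position in metres (Gaussian, truncated to the focused stream width).
#' @param stream_width Focused-stream width in metres (offsets truncated to
#'   +/- half of it); default 15 um, mid-range of a 10-23 um focused core.
#' @return An object of class `bead_population`.
#' @export
bead_population <- function(diameter = 5e-6, concentration = 5e6 * 1e6,
                            brightness_cv = 0.05,
                            lateral_offset_sd = 15e-6 / 4,
                            stream_width = 15e-6) {
  if (any(c(diameter, concentration, stream_width) < 0) ||
      brightness_cv < 0 || lateral_offset_sd < 0)
    stop("population parameters must be non-negative", call. = FALSE)
  structure(list(diameter = diameter, concentration = concentration,
                 brightness_cv = brightness_cv,
                 lateral_offset_sd = lateral_offset_sd,
                 stream_width = stream_width),
            class = "bead_population")
}

#' Acquisition and detector-noise configuration
#'
#' The detector model is linear gain plus Poisson shot noise and additive
#' Gaussian noise on a constant baseline. Noise amplitudes are anchored to
#' the zero-offset plateau of the simulated spot: the shot-noise scale is
#' chosen so the plateau signal-to-noise ratio equals `snr`, the additive
#' noise standard deviation is `additive_frac` of the plateau and the
#' baseline sits at `baseline_frac` of it.
#'
#' @param sampling_rate Samples per second (default 10 MHz).
#' @param gain Linear detector gain (arbitrary units).
#' @param snr Plateau signal-to-noise ratio set by the shot noise.
#' @param additive_frac Additive noise sd as a fraction of the plateau.
#' @param baseline_frac Baseline level as a fraction of the plateau.
#' @param duration Acquisition length in seconds.
#' @param rng_seed Seed for all stochastic draws of the run.
#' @param noise Master switch; `FALSE` gives a noise-free waveform.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(sampling_rate = 1e7, gain = 1, snr = 20,
                               additive_frac = 0.01, baseline_frac = 0.02,
                               duration = 1, rng_seed = 0L, noise = TRUE) {
  if (sampling_rate <= 0 || gain <= 0 || snr <= 0 || duration <= 0)
    stop("'sampling_rate', 'gain', 'snr' and 'duration' must be positive",
         call. = FALSE)
  structure(list(sampling_rate = sampling_rate, gain = gain, snr = snr,
                 additive_frac = additive_frac,
                 baseline_frac = baseline_frac, duration = duration,
                 rng_seed = as.integer(rng_seed), noise = isTRUE(noise)),
            class = "acquisition_config")
}

# Uniform projected-area disc kernel of the bead on the spot grid,
# normalized to sum 1 (so the excitation is the mean intensity seen by the
# bead footprint). A bead smaller than one pixel degenerates to the
# identity kernel.
disc_kernel <- function(diameter, pitch) {
  r <- diameter / 2
  m <- floor(r / pitch)
  if (m < 1) return(matrix(1, 1, 1))
  off <- (-m):m * pitch
  k <- outer(off^2, off^2, "+") <= r^2
  k <- k * 1
  k / sum(k)
}

# Intensity map convolved with the bead's disc kernel (direct shift-and-add;
# kernels are small). Zero padding outside the map.
convolved_intensity <- function(spot, diameter) {
  ker <- disc_kernel(diameter, spot$pitch)
  m <- (nrow(ker) - 1L) / 2L
  n <- nrow(spot$intensity)
  if (2L * m + 1L > n)
    stop("bead larger than the spot map extent", call. = FALSE)
  if (m == 0L) return(spot$intensity)
  out <- matrix(0, n, n)
  for (i in seq_len(nrow(ker))) {
    di <- i - m - 1L
    for (j in seq_len(ncol(ker))) {
      w <- ker[i, j]
      if (w == 0) next
      dj <- j - m - 1L
      rs <- max(1L, 1L - di):min(n, n - di)
      cs <- max(1L, 1L - dj):min(n, n - dj)
      out[rs, cs] <- out[rs, cs] + w * spot$intensity[rs + di, cs + dj]
    }
  }
  out
}

#' Excitation profile of a bead transit
#'
#' Convolves the spot intensity with the bead's uniform projected-area disc
#' kernel and extracts the along-flow profile at the bead's across-flow
#' offset: `excitation(s)` is the mean intensity over the bead footprint
#' when the bead centre sits at along-flow position `s`. For a point bead
#' this is simply the intensity column at the offset; a finite bead
#' broadens each w-um-thick bar into a trapezoid of base `w + d` and
#' plateau `|w - d|`.
#'
#' @param spot A [spot_model()].
#' @param lateral_offset Across-flow bead position in metres (within the
#'   map extent).
#' @param bead_diameter Bead diameter in metres.
#' @return List with `s` (along-flow positions, m), `excitation` (W/m^2
#'   scale) and `pitch`.
#' @export
transit_profile <- function(spot, lateral_offset = 0, bead_diameter = 0) {
  stopifnot(inherits(spot, "spot_model"))
  conv <- convolved_intensity(spot, bead_diameter)
  profile_at_offset(conv, spot$pitch, lateral_offset)
}

# Linear interpolation between adjacent columns of the convolved map.
profile_at_offset <- function(conv, pitch, offset) {
  n <- ncol(conv)
  x <- grid_coords(n, pitch)
  if (offset < x[1] || offset > x[n])
    stop("lateral offset outside the spot map extent", call. = FALSE)
  j <- findInterval(offset, x, rightmost.closed = TRUE)
  w <- (offset - x[j]) / pitch
  exc <- if (j < n) conv[, j] * (1 - w) + conv[, j + 1L] * w else conv[, n]
  list(s = grid_coords(nrow(conv), pitch), excitation = exc, pitch = pitch)
}

#' Render one bead transit as a sampled waveform segment
#'
#' Maps the spatial excitation profile to time through the bead velocity
#' (`position = velocity * (t - t0)`, `t0` the instant the bead centre
#' crosses the spot origin), scales by gain and per-bead brightness, and
#' optionally applies the detector noise model. Pulse duration scales as
#' `1/velocity` and noise-free pulse area as `brightness / velocity`.
#'
#' @param profile A [transit_profile()].
#' @param velocity Bead speed in m/s (> 0).
#' @param brightness Relative bead brightness (1 = nominal).
#' @param acquisition An [acquisition_config()].
#' @param t0 Crossing time of the spot origin in seconds.
#' @param noise_ref Plateau reference for the noise model (defaults to the
#'   profile maximum times gain).
#' @return List with `t` (sample times), `samples` (signal units) and
#'   `sampling_rate`.
#' @export
simulate_event <- function(profile, velocity, brightness = 1,
                           acquisition = acquisition_config(),
                           t0 = 0, noise_ref = NULL) {
  if (velocity <= 0) stop("'velocity' must be positive", call. = FALSE)
  if (!any(profile$excitation > 0))
    stop("excitation profile is identically zero", call. = FALSE)
  fs <- acquisition$sampling_rate
  supp <- range(profile$s[profile$excitation > 0])
  n_pulse <- (diff(supp) / velocity) * fs
  if (is.finite(n_pulse) && n_pulse < 10)
    stop("sampling too coarse: fewer than 10 samples across the pulse",
         call. = FALSE)
  tmin <- t0 + profile$s[1] / velocity
  tmax <- t0 + profile$s[length(profile$s)] / velocity
  t <- seq(ceiling(tmin * fs), floor(tmax * fs)) / fs
  sig <- acquisition$gain * brightness *
    stats::approx(profile$s / velocity + t0, profile$excitation, xout = t,
                  yleft = 0, yright = 0)$y
  ref <- if (is.null(noise_ref)) acquisition$gain * max(profile$excitation)
         else noise_ref
  base <- acquisition$baseline_frac * ref
  out <- sig + base
  if (acquisition$noise) out <- add_detector_noise(out, ref, acquisition)
  list(t = t, samples = out, sampling_rate = fs)
}

add_detector_noise <- function(x, ref, acquisition) {
  scale <- ref / acquisition$snr^2          # Poisson shot-noise quantum
  x <- stats::rpois(length(x), x / scale) * scale
  x + stats::rnorm(length(x), 0, acquisition$additive_frac * ref)
}

#' Simulate a full acquisition run
#'
#' Bead arrivals form a Poisson process with rate
#' `concentration * sample_rate`; each bead draws a log-normal brightness
#' (mean 1, CV = `brightness_cv`), a truncated-Gaussian lateral offset, and
#' is rendered onto a shared timeline at the common transit `velocity`
#' (overlapping transits sum). The detector baseline and noise are applied
#' once to the summed timeline. The per-event ground truth is returned for
#' recovery tests.
#'
#' @param spot A [spot_model()].
#' @param population A [bead_population()].
#' @param velocity Transit velocity of the focused stream in m/s.
#' @param sample_rate Sample volumetric flow rate in m^3/s (e.g.
#'   `ul_per_min(60)`).
#' @param acquisition An [acquisition_config()] (supplies duration, seed,
#'   noise model).
#' @return An object of class `cyto_waveform`: `samples`, `sampling_rate`,
#'   `baseline`, `noise_ref`, `duration`, `velocity` and `truth` (data
#'   frame: `id`, `t0`, `velocity`, `brightness`, `offset`).
#' @export
simulate_run <- function(spot, population, velocity,
                         sample_rate = ul_per_min(60),
                         acquisition = acquisition_config()) {
  stopifnot(inherits(spot, "spot_model"),
            inherits(population, "bead_population"),
            inherits(acquisition, "acquisition_config"))
  if (velocity <= 0 || sample_rate <= 0)
    stop("'velocity' and 'sample_rate' must be positive", call. = FALSE)
  fs <- acquisition$sampling_rate
  dur <- acquisition$duration
  set.seed(acquisition$rng_seed)

  rate <- population$concentration * sample_rate
  n_ev <- stats::rpois(1, rate * dur)
  t0 <- sort(stats::runif(n_ev, 0, dur))
  sdlog <- sqrt(log(1 + population$brightness_cv^2))
  brightness <- stats::rlnorm(n_ev, -sdlog^2 / 2, sdlog)
  offs <- rtruncnorm(n_ev, population$lateral_offset_sd,
                     population$stream_width / 2)

  conv <- convolved_intensity(spot, population$diameter)
  ref0 <- profile_at_offset(conv, spot$pitch, 0)
  noise_ref <- acquisition$gain * max(ref0$excitation)
  n_samp <- round(dur * fs)
  wav <- numeric(n_samp)
  smin <- min(ref0$s); smax <- max(ref0$s)
  for (k in seq_len(n_ev)) {
    prof <- profile_at_offset(conv, spot$pitch, offs[k])
    i1 <- max(1L, ceiling((t0[k] + smin / velocity) * fs))
    i2 <- min(n_samp, floor((t0[k] + smax / velocity) * fs))
    if (i2 < i1) next
    tt <- seq.int(i1, i2) / fs
    wav[i1:i2] <- wav[i1:i2] + acquisition$gain * brightness[k] *
      stats::approx(prof$s / velocity + t0[k], prof$excitation, xout = tt,
                    yleft = 0, yright = 0)$y
  }
  base <- acquisition$baseline_frac * noise_ref
  wav <- wav + base
  if (acquisition$noise) wav <- add_detector_noise(wav, noise_ref, acquisition)
  truth <- data.frame(id = seq_len(n_ev), t0 = t0,
                      velocity = rep_len(velocity, n_ev),
                      brightness = brightness, offset = offs)
  structure(list(samples = wav, sampling_rate = fs, baseline = base,
                 noise_ref = noise_ref, duration = dur, velocity = velocity,
                 truth = truth),
            class = "cyto_waveform")
}

# Gaussian draw truncated to [-bound, bound] via inverse-CDF sampling
# (exact, vectorized, no rejection loop).
rtruncnorm <- function(n, sd, bound) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(numeric(n))
  p <- stats::pnorm(c(-bound, bound), sd = sd)
  stats::qnorm(stats::runif(n, p[1], p[2]), sd = sd)
}

#' @export
print.cyto_waveform <- function(x, ...) {
  cat(sprintf("<cyto_waveform> %.3g s at %.3g MHz (%d samples), %d true events\n",
              x$duration, x$sampling_rate / 1e6, length(x$samples),
              nrow(x$truth)))
  invisible(x)
}
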