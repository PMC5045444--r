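#' Optical configuration of the diffractive beam-shaping system
#'
#' Bundles the physical parameters of the phase element + focusing lens:
#' a square multi-level diffractive element of side `aperture_side`
#' (identified with the incident beam diameter) divided into
#' `zones_per_side` x `zones_per_side` square phase zones, illuminated at
#' `wavelength` and focused by a lens of focal length `focal_length`. The
#' etched relief supports `phase_levels` discrete phase values (a power of
#' two, one per etch level combination).
#'
#' Defaults reproduce the reference design: 488 nm, f = 10 mm, D = 3 mm,
#' 128 x 128 zones (zone pitch 23.4 um), 16 phase levels, fused-quartz
#' refractive index 1.4632 at 488 nm.
#'
#' @param wavelength Laser wavelength in metres.
#' @param focal_length Lens focal length in metres.
#' @param aperture_side Side of the square element / beam extent in metres.
#' @param zones_per_side Number of phase zones along one side.
#' @param phase_levels Number of quantized phase levels (power of two).
#' @param refractive_index Substrate refractive index (> 1).
#' @param oversampling Simulation samples per zone side (integer >= 1).
#' @param aperture_profile Incident amplitude profile: `"uniform"` (default)
#'   or `"gaussian"` (truncated TEM00 with 1/e^2 intensity diameter equal to
#'   `aperture_side`).
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength = 488e-9,
                           focal_length = 10e-3,
                           aperture_side = 3e-3,
                           zones_per_side = 128L,
                           phase_levels = 16L,
                           refractive_index = 1.4632,
                           oversampling = 1L,
                           aperture_profile = c("uniform", "gaussian")) {
  aperture_profile <- match.arg(aperture_profile)
  num <- list(wavelength = wavelength, focal_length = focal_length,
              aperture_side = aperture_side, zones_per_side = zones_per_side,
              phase_levels = phase_levels,
              refractive_index = refractive_index, oversampling = oversampling)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  zones_per_side <- as.integer(zones_per_side)
  phase_levels <- as.integer(phase_levels)
  oversampling <- as.integer(oversampling)
  if (phase_levels < 2L || bitwAnd(phase_levels, phase_levels - 1L) != 0L)
    stop("'phase_levels' must be a power of two >= 2", call. = FALSE)
  if (oversampling < 1L)
    stop("'oversampling' must be an integer >= 1", call. = FALSE)
  structure(list(wavelength = wavelength,
                 focal_length = focal_length,
                 aperture_side = aperture_side,
                 zones_per_side = zones_per_side,
                 phase_levels = phase_levels,
                 refractive_index = refractive_index,
                 oversampling = oversampling,
                 aperture_profile = aperture_profile),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("Optical configuration\n")
  cat(sprintf("  wavelength      : %.1f nm\n", x$wavelength * 1e9))
  cat(sprintf("  focal length    : %.3g mm\n", x$focal_length * 1e3))
  cat(sprintf("  aperture side   : %.3g mm (%d zones of %.2f um, %s profile)\n",
              x$aperture_side * 1e3, x$zones_per_side,
              zone_pitch(x) * 1e6, x$aperture_profile))
  cat(sprintf("  phase levels    : %d\n", x$phase_levels))
  cat(sprintf("  focal sampling  : %.3f um (lambda f / D)\n",
              focal_sampling_interval(x) * 1e6))
  invisible(x)
}

#' Focal-plane sampling interval lambda*f/D
#'
#' The natural focal-plane pixel of the Fourier pair formed by a square
#' aperture of side `D` and a lens of focal length `f`: du = lambda*f/D.
#' For the default design this is 1.63 um.
#'
#' @param config An [optical_config()].
#' @return Sampling interval in metres.
#' @export
focal_sampling_interval <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$wavelength * config$focal_length / config$aperture_side
}

#' Phase-zone pitch of the element
#'
#' Side of one square phase zone, `aperture_side / zones_per_side`
#' (23.4 um for the default 3 mm / 128 design).
#'
#' @param config An [optical_config()].
#' @return Zone pitch in metres.
#' @export
zone_pitch <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  config$aperture_side / config$zones_per_side
}

#' Complex optical field on a calibrated grid
#'
#' A square matrix of complex amplitudes with a physical sample pitch.
#' Row index maps to the along-flow axis (y), column index to the
#' across-flow axis (x); the grid is sample-centred on the optical axis
#' (zero coordinate at index `floor(n/2) + 1`).
#'
#' @param values Square complex (or numeric) matrix of amplitudes.
#' @param sample_pitch Physical distance between samples in metres.
#' @param plane `"aperture"` or `"focal"`.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, sample_pitch,
                          plane = c("aperture", "focal")) {
  plane <- match.arg(plane)
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("'values' must be a square matrix", call. = FALSE)
  if (!is.complex(values)) {
    if (!is.numeric(values))
      stop("'values' must be complex or numeric", call. = FALSE)
    values <- values + 0i
  }
  if (!is.numeric(sample_pitch) || length(sample_pitch) != 1L ||
      !is.finite(sample_pitch) || sample_pitch <= 0)
    stop("'sample_pitch' must be a single positive number", call. = FALSE)
  if (any(!is.finite(Mod(values))))
    stop("field values must be finite", call. = FALSE)
  structure(list(values = values, sample_pitch = sample_pitch, plane = plane),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<complex_field> %s plane, %d x %d samples, pitch %.4g um, energy %.4g\n",
              x$plane, n, n, x$sample_pitch * 1e6, field_energy(x)))
  invisible(x)
}

#' Total energy of a field
#'
#' Discrete energy sum(|E|^2) * pitch^2, the quantity conserved by
#' [propagate_to_focal()].
#'
#' @param field A [complex_field()].
#' @return Energy (arbitrary units consistent across planes).
#' @export
field_energy <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  sum(Mod(field$values)^2) * field$sample_pitch^2
}

#' Sample-centred physical coordinates of an n-point grid
#'
#' Zero lies at index `floor(n/2) + 1`, matching the centring convention of
#' the shifted FFT used for propagation.
#'
#' @param n Number of samples.
#' @param pitch Sample pitch in metres.
#' @return Numeric vector of length `n`.
#' @export
grid_coords <- function(n, pitch) {
  (seq_len(n) - (n %/% 2 + 1L)) * pitch
}

# 2D fftshift: move the zero-frequency sample (index 1) to the grid centre.
fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c(seq.int(n1 %/% 2 + 1L, n1), seq_len(n1 %/% 2))
  i2 <- c(seq.int(n2 %/% 2 + 1L, n2), seq_len(n2 %/% 2))
  m[i1, i2, drop = FALSE]
}

# Inverse of fftshift2 (differs from it for odd sizes).
ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  i1 <- c(seq.int((n1 + 1L) %/% 2 + 1L, n1), seq_len((n1 + 1L) %/% 2))
  i2 <- c(seq.int((n2 + 1L) %/% 2 + 1L, n2), seq_len((n2 + 1L) %/% 2))
  m[i1, i2, drop = FALSE]
}

# Embed a square matrix in the centre of a larger zero matrix so that the
# centre sample (floor(n/2)+1) stays the centre sample.
pad_center <- function(m, n_out) {
  n <- nrow(m)
  if (n_out == n) return(m)
  if (n_out < n) stop("padded size smaller than input", call. = FALSE)
  off <- (n_out - n) %/% 2
  out <- matrix(0i, n_out, n_out)
  out[off + seq_len(n), off + seq_len(n)] <- m
  out
}

#' Incident aperture field on the element grid
#'
#' Builds the illumination amplitude A(x, y) sampled on the zone grid
#' (optionally oversampled), normalized to unit total energy. A TEM00
#' source has constant phase, so the field is real and non-negative:
#' uniform over the square aperture, or a truncated Gaussian with 1/e^2
#' intensity diameter equal to the aperture side.
#'
#' @param config An [optical_config()].
#' @return A [complex_field()] in the aperture plane.
#' @export
aperture_field <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  n <- config$zones_per_side * config$oversampling
  dx <- config$aperture_side / n
  if (config$aperture_profile == "uniform") {
    amp <- matrix(1, n, n)
  } else {
    w0 <- config$aperture_side / 2   # 1/e^2 intensity radius
    r2 <- outer(grid_coords(n, dx)^2, grid_coords(n, dx)^2, "+")
    amp <- exp(-r2 / w0^2)
  }
  amp <- amp / sqrt(sum(amp^2) * dx^2)
  complex_field(amp, dx, "aperture")
}

#' Propagate an aperture field to the lens focal plane
#'
#' Scalar Fraunhofer propagation through the focusing lens: the focal field
#' is the scaled Fourier transform of the aperture field,
#' U(u, v) = (1/lambda f) FT\[G(x, y)\] evaluated at spatial frequencies
#' (u/lambda f, v/lambda f). Implemented as a centred FFT with physical
#' scaling `dx^2/(lambda f)` so the transform is unitary in energy
#' (Parseval) and the focal sample pitch is `lambda f / (N dx)` for an
#' N-point (optionally zero-padded) grid; with no padding and one sample
#' per zone this is the classical lambda*f/D interval.
#'
#' @param field Aperture-plane [complex_field()].
#' @param config An [optical_config()].
#' @param pad_factor Integer >= 1; zero-pad the aperture to
#'   `pad_factor * n` samples before transforming, refining the focal pitch
#'   by the same factor.
#' @return Focal-plane [complex_field()].
#' @export
propagate_to_focal <- function(field, config, pad_factor = 1L) {
  stopifnot(inherits(field, "complex_field"), inherits(config, "optical_config"))
  if (field$plane != "aperture")
    stop("'field' must be an aperture-plane field", call. = FALSE)
  pad_factor <- as.integer(pad_factor)
  if (pad_factor < 1L) stop("'pad_factor' must be >= 1", call. = FALSE)
  n <- nrow(field$values)
  N <- n * pad_factor
  dx <- field$sample_pitch
  lf <- config$wavelength * config$focal_length
  g <- pad_center(field$values, N)
  u <- fftshift2(stats::fft(ifftshift2(g))) * dx^2 / lf
  complex_field(u, lf / (N * dx), "focal")
}

#' Back-propagate a focal field to the aperture plane
#'
#' Exact inverse of [propagate_to_focal()]; optionally crops the central
#' `out_n` x `out_n` samples (undoing zero padding).
#'
#' @param field Focal-plane [complex_field()].
#' @param config An [optical_config()].
#' @param out_n Output grid size (defaults to the input size).
#' @return Aperture-plane [complex_field()].
#' @export
propagate_to_aperture <- function(field, config, out_n = NULL) {
  stopifnot(inherits(field, "complex_field"), inherits(config, "optical_config"))
  if (field$plane != "focal")
    stop("'field' must be a focal-plane field", call. = FALSE)
  N <- nrow(field$values)
  lf <- config$wavelength * config$focal_length
  du <- field$sample_pitch
  dx <- lf / (N * du)
  g <- fftshift2(stats::fft(ifftshift2(field$values), inverse = TRUE)) /
    (N^2 * dx^2 / lf)
  if (!is.null(out_n)) {
    out_n <- as.integer(out_n)
    off <- (N - out_n) %/% 2
    g <- g[off + seq_len(out_n), off + seq_len(out_n), drop = FALSE]
  }
  complex_field(g, dx, "aperture")
}
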