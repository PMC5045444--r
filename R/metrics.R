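#' Diffraction efficiency of a focal spot
#'
#' Fraction of the incident beam energy delivered into the signal region:
#' `eta = sum(|U|^2 over region) * du^2 / total input energy`. The input
#' energy is taken from the aperture field (equal to the total focal energy
#' by Parseval).
#'
#' @param focal Focal-plane [complex_field()].
#' @param aperture Aperture-plane [complex_field()] of the same propagation
#'   (or any field whose [field_energy()] is the input energy).
#' @param region Logical matrix on the focal grid marking the signal region.
#' @return Efficiency in \[0, 1\]. An empty region gives 0.
#' @export
diffraction_efficiency <- function(focal, aperture, region) {
  stopifnot(inherits(focal, "complex_field"))
  check_region(focal, region)
  if (!any(region)) return(0)
  e_in <- if (inherits(aperture, "complex_field")) field_energy(aperture)
          else as.numeric(aperture)
  sum(Mod(focal$values[region])^2) * focal$sample_pitch^2 / e_in
}

check_region <- function(field, region) {
  if (!is.logical(region) || !is.matrix(region) ||
      !all(dim(region) == dim(field$values)))
    stop("'region' must be a logical matrix matching the field grid",
         call. = FALSE)
  invisible(TRUE)
}

#' RMS amplitude and intensity uniformity errors
#'
#' Relative root-mean-square deviation of the focal amplitude (`RMSA`) or
#' intensity (`RMSI`) from its mean over the signal region:
#' `sqrt(mean((q - mean(q))^2)) / mean(q)` with `q = |U|` or `|U|^2` over
#' the region samples (the area weights of the continuous definition cancel
#' between numerator and denominator). Zero iff the quantity is constant on
#' the region; invariant under any global rescaling of the field.
#'
#' @param focal Focal-plane [complex_field()].
#' @param region Logical matrix marking the (non-empty) signal region.
#' @return Non-negative scalar.
#' @export
rms_amplitude_error <- function(focal, region) {
  region_rms(Mod(focal$values), focal, region)
}

#' @rdname rms_amplitude_error
#' @export
rms_intensity_error <- function(focal, region) {
  region_rms(Mod(focal$values)^2, focal, region)
}

region_rms <- function(q, field, region) {
  check_region(field, region)
  if (!any(region)) stop("'region' is empty", call. = FALSE)
  v <- q[region]
  m <- mean(v)
  if (m <= 0) stop("mean over the region is zero", call. = FALSE)
  sqrt(mean((v - m)^2)) / m
}

#' Measure rectangle dimensions of a spot by half-maximum crossings
#'
#' For each hinted rectangle, extracts the one-dimensional intensity profile
#' through the local intensity centroid along each axis -- averaged over a
#' band spanning the central half of the transverse dimension, as a beam
#' profiler would, so residual flat-top ripple does not masquerade as an
#' edge -- then locates the half-maximum crossings by linear interpolation
#' between samples and reports the crossing-to-crossing distances. Exact
#' (to a fraction of a sample) for ideal flat-top profiles, and robust to
#' symmetric edge blur.
#'
#' @param intensity Non-negative matrix on a calibrated grid (rows = along
#'   flow y, columns = across flow x), e.g. `Mod(focal$values)^2`.
#' @param pitch Sample pitch in metres.
#' @param geometry Hint rectangles as in [make_target()] (`cx`, `cy`,
#'   `width`, `height` in metres), one per expected sub-spot.
#' @param inflate Search-window inflation factor applied to each hint
#'   rectangle (must stay below the spacing to neighbouring sub-spots).
#' @return Data frame with one row per rectangle: measured `width` and
#'   `height` (m) and the relative errors `width_err`, `height_err` against
#'   the hint.
#' @export
measure_dimensions <- function(intensity, pitch, geometry, inflate = 1.6) {
  stopifnot(is.matrix(intensity), is.numeric(intensity))
  n <- nrow(intensity)
  x <- grid_coords(ncol(intensity), pitch)
  y <- grid_coords(n, pitch)
  out <- geometry[c("cx", "cy", "width", "height")]
  out$width_meas <- out$height_meas <- NA_real_
  for (k in seq_len(nrow(geometry))) {
    ix <- which(abs(x - geometry$cx[k]) <= inflate * geometry$width[k] / 2)
    iy <- which(abs(y - geometry$cy[k]) <= inflate * geometry$height[k] / 2)
    if (length(ix) < 3L || length(iy) < 3L)
      stop("hint window too small on this grid", call. = FALSE)
    w <- intensity[iy, ix, drop = FALSE]
    tot <- sum(w)
    if (tot <= 0) stop("no intensity inside the hint window", call. = FALSE)
    cx <- sum(colSums(w) * x[ix]) / tot
    cy <- sum(rowSums(w) * y[iy]) / tot
    bx <- ix[abs(x[ix] - cx) <= geometry$width[k] / 4]
    by <- iy[abs(y[iy] - cy) <= geometry$height[k] / 4]
    out$width_meas[k] <- half_max_extent(
      x[ix], colMeans(intensity[by, ix, drop = FALSE]))
    out$height_meas[k] <- half_max_extent(
      y[iy], rowMeans(intensity[iy, bx, drop = FALSE]))
  }
  data.frame(width = out$width_meas,
             height = out$height_meas,
             width_err = out$width_meas / geometry$width - 1,
             height_err = out$height_meas / geometry$height - 1)
}

# Distance between the two outermost half-maximum crossings of a sampled
# profile, by linear interpolation. Errors if the profile never drops below
# half its maximum on both sides of the peak.
half_max_extent <- function(coords, prof) {
  if (length(prof) < 3L || max(prof) <= 0)
    stop("dimension measurement failed: degenerate profile", call. = FALSE)
  half <- max(prof) / 2
  i0 <- which.max(prof)
  lo <- which(prof[seq_len(i0)] < half)
  hi <- which(prof[seq.int(i0, length(prof))] < half) + i0 - 1L
  if (length(lo) == 0L || length(hi) == 0L)
    stop("dimension measurement failed: profile never crosses half maximum",
         call. = FALSE)
  il <- max(lo)                       # last sample below half on the left
  ih <- min(hi)                       # first sample below half on the right
  xl <- coords[il] + (half - prof[il]) / (prof[il + 1L] - prof[il]) *
    (coords[il + 1L] - coords[il])
  xr <- coords[ih - 1L] + (half - prof[ih - 1L]) / (prof[ih] - prof[ih - 1L]) *
    (coords[ih] - coords[ih - 1L])
  xr - xl
}

#' Full quantitative evaluation of a designed spot
#'
#' Convenience wrapper computing diffraction efficiency, RMSA, RMSI and the
#' per-rectangle half-maximum dimensions of a focal field against its
#' target.
#'
#' @param focal Focal-plane [complex_field()].
#' @param target A `target_spot` on the *same* grid as `focal` (use
#'   [retarget()] after padded propagation).
#' @param aperture Aperture field or input energy for the efficiency.
#' @return A list of class `spot_metrics`: `eta`, `rmsa`, `rmsi`, `dims`
#'   (data frame from [measure_dimensions()]).
#' @export
evaluate_spot <- function(focal, target, aperture) {
  stopifnot(inherits(target, "target_spot"))
  S <- target$signal_region
  intens <- Mod(focal$values)^2
  structure(list(eta = diffraction_efficiency(focal, aperture, S),
                 rmsa = rms_amplitude_error(focal, S),
                 rmsi = rms_intensity_error(focal, S),
                 dims = measure_dimensions(intens, focal$sample_pitch,
                                           target$geometry)),
            class = "spot_metrics")
}

#' @export
print.spot_metrics <- function(x, ...) {
  cat(sprintf("<spot_metrics> eta = %.3f, RMSA = %.3f, RMSI = %.3f\n",
              x$eta, x$rmsa, x$rmsi))
  for (k in seq_len(nrow(x$dims)))
    cat(sprintf("  rect %d: %.2f x %.2f um (err %+.1f%%, %+.1f%%)\n", k,
                x$dims$width[k] * 1e6, x$dims$height[k] * 1e6,
                100 * x$dims$width_err[k], 100 * x$dims$height_err[k]))
  invisible(x)
}
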