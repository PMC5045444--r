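#' Desired focal-plane spot patterns
#'
#' Builds the target amplitude for the three rectangular quasi-flat-top
#' illumination spots, rasterized on a focal grid of `n` x `n` samples at
#' `pitch` metres:
#'
#' * `R1`: a single 50 um x 10 um rectangle centred on the optical axis,
#'   long side across the flow.
#' * `R2`: two such rectangles whose leading edges along the flow axis are
#'   110 um apart (so a bead crosses them 110 um apart in space).
#' * `R3`: `R2` plus a 50 um x 50 um square centred between them, leaving
#'   25 um gaps on each side.
#'
#' Rectangles are rasterized with area-coverage weighting: a pixel crossed
#' by an edge receives its covered fraction, and the target amplitude is the
#' square root of coverage, so the target *intensity* falls through half
#' maximum exactly on the geometric edge. The boolean `signal_region` marks
#' every pixel with non-zero coverage and is the U_S support used by the
#' uniformity metrics and the design algorithm's focal constraint. Total
#' target energy is normalized to 1.
#'
#' @param spot_kind `"R1"`, `"R2"`, `"R3"`, or `"custom"` (geometry must then
#'   be supplied).
#' @param n Focal grid size (samples per side).
#' @param pitch Focal sample pitch in metres (e.g.
#'   [focal_sampling_interval()]).
#' @param geometry Optional data frame overriding the default rectangles,
#'   with columns `cx`, `cy` (centre), `width` (across flow, x) and
#'   `height` (along flow, y), all in metres.
#' @param edge_pitch Leading-edge separation along the flow for R2/R3
#'   (metres; default 110 um, the time-of-flight baseline L).
#' @return An object of class `target_spot` with fields `kind`, `amplitude`,
#'   `signal_region`, `geometry`, `pitch`.
#' @export
make_target <- function(spot_kind = c("R1", "R2", "R3", "custom"),
                        n, pitch, geometry = NULL, edge_pitch = 110e-6) {
  spot_kind <- match.arg(spot_kind)
  if (is.null(geometry)) {
    geometry <- switch(spot_kind,
      R1 = data.frame(cx = 0, cy = 0, width = 50e-6, height = 10e-6),
      R2 = data.frame(cx = c(0, 0), cy = c(-edge_pitch / 2, edge_pitch / 2),
                      width = 50e-6, height = 10e-6),
      R3 = data.frame(cx = c(0, 0, 0),
                      cy = c(-edge_pitch / 2, 0, edge_pitch / 2),
                      width = c(50e-6, 50e-6, 50e-6),
                      height = c(10e-6, 50e-6, 10e-6)),
      custom = stop("'geometry' must be supplied for a custom spot",
                    call. = FALSE))
  }
  target_spot(geometry, n, pitch, kind = spot_kind)
}

#' Rasterize a rectangle set into a target spot
#'
#' Low-level constructor behind [make_target()]; accepts any axis-aligned
#' rectangle list.
#'
#' @inheritParams make_target
#' @param kind Label stored on the object.
#' @return A `target_spot`.
#' @export
target_spot <- function(geometry, n, pitch, kind = "custom") {
  stopifnot(is.data.frame(geometry),
            all(c("cx", "cy", "width", "height") %in% names(geometry)),
            nrow(geometry) >= 1L)
  if (any(geometry$width <= 0) || any(geometry$height <= 0))
    stop("rectangle dimensions must be positive", call. = FALSE)
  n <- as.integer(n)
  x <- grid_coords(n, pitch)   # across flow (columns)
  y <- grid_coords(n, pitch)   # along flow (rows)
  half <- pitch / 2
  if (any(geometry$cx - geometry$width / 2 < min(x) - half) ||
      any(geometry$cx + geometry$width / 2 > max(x) + half) ||
      any(geometry$cy - geometry$height / 2 < min(y) - half) ||
      any(geometry$cy + geometry$height / 2 > max(y) + half))
    stop("target geometry exceeds the focal grid extent", call. = FALSE)
  if (pitch > min(geometry$width, geometry$height) / 2)
    stop("grid too coarse: need >= 2 samples across the thinnest rectangle",
         call. = FALSE)
  cov <- matrix(0, n, n)
  for (k in seq_len(nrow(geometry))) {
    cx <- pmax(0, (pmin(x + half, geometry$cx[k] + geometry$width[k] / 2) -
                     pmax(x - half, geometry$cx[k] - geometry$width[k] / 2))) / pitch
    cy <- pmax(0, (pmin(y + half, geometry$cy[k] + geometry$height[k] / 2) -
                     pmax(y - half, geometry$cy[k] - geometry$height[k] / 2))) / pitch
    cov <- pmax(cov, outer(cy, cx))   # rows = y, cols = x
  }
  amp <- sqrt(cov)
  amp <- amp / sqrt(sum(amp^2) * pitch^2)
  structure(list(kind = kind,
                 amplitude = amp,
                 signal_region = cov > 0,
                 geometry = geometry,
                 pitch = pitch),
            class = "target_spot")
}

#' @export
print.target_spot <- function(x, ...) {
  cat(sprintf("<target_spot> %s: %d rectangle(s) on %d x %d grid, pitch %.3g um\n",
              x$kind, nrow(x$geometry), nrow(x$amplitude), ncol(x$amplitude),
              x$pitch * 1e6))
  cat(sprintf("  signal region: %d px (%.1f um^2)\n",
              sum(x$signal_region), sum(x$signal_region) * (x$pitch * 1e6)^2))
  invisible(x)
}

#' Resample a target onto another grid
#'
#' Re-rasterizes the stored geometry on a new grid (used to evaluate a
#' design on a finer focal pitch than it was optimized on).
#'
#' @param target A `target_spot`.
#' @param n New grid size.
#' @param pitch New sample pitch (m).
#' @return A `target_spot` on the new grid.
#' @export
retarget <- function(target, n, pitch) {
  stopifnot(inherits(target, "target_spot"))
  target_spot(target$geometry, n, pitch, kind = target$kind)
}
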