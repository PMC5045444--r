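#' Rectangular channel segment
#'
#' One laminar segment of the focusing chip's resistance network: an
#' `a x b` rectangular duct of length `l`, possibly split into
#' `parallel_count` identical parallel branches (four feed branches for the
#' vertical sheath, two for the horizontal sheath), with an optional
#' pressure-drop correction factor `K_P` for high-aspect-ratio geometry.
#' `carries_sample = TRUE` marks the downstream segments shared with the
#' sample stream.
#'
#' @param width Channel width a in metres.
#' @param height Channel height b in metres.
#' @param length Channel length l in metres.
#' @param parallel_count Number of identical parallel branches (>= 1).
#' @param K_P Pressure correction factor (default 1; 1.4 for the
#'   high-aspect-ratio horizontal segments of the reference chip).
#' @param carries_sample Does the segment also carry the sample flow?
#' @return An object of class `channel_segment`.
#' @export
channel_segment <- function(width, height, length, parallel_count = 1L,
                            K_P = 1, carries_sample = FALSE) {
  if (any(c(width, height, length) <= 0) || parallel_count < 1L || K_P <= 0)
    stop("segment dimensions, parallel_count and K_P must be positive",
         call. = FALSE)
  structure(list(width = width, height = height, length = length,
                 parallel_count = as.integer(parallel_count), K_P = K_P,
                 carries_sample = isTRUE(carries_sample)),
            class = "channel_segment")
}

#' Hydraulic diameter of a rectangular duct
#'
#' `d = 2ab / (a + b)`; reduces to the side for a square duct and is
#' symmetric in its arguments.
#'
#' @param a,b Cross-section sides in metres (> 0).
#' @return Hydraulic diameter in metres.
#' @export
hydraulic_diameter <- function(a, b) {
  if (any(a <= 0) || any(b <= 0))
    stop("duct sides must be positive", call. = FALSE)
  2 * a * b / (a + b)
}

#' Working-fluid and flow-rate configuration
#'
#' Fluid properties default to distilled water at 20 degrees C. The dynamic
#' viscosity is derived as `mu = nu * rho`. `K_Q` is the split correction
#' factor of the sheath-partition model (0.75 for the reference chip,
#' obtained from CFD and injected here as a constant).
#'
#' @param kinematic_viscosity nu in m^2/s.
#' @param density rho in kg/m^3.
#' @param sample_rate Sample flow rate Q_S in m^3/s.
#' @param sheath_rate Total sheath flow rate Q_SH in m^3/s.
#' @param K_Q Split correction factor.
#' @return An object of class `flow_config`.
#' @export
flow_config <- function(kinematic_viscosity = 1.004e-6, density = 998,
                        sample_rate = ul_per_min(60),
                        sheath_rate = 7.2e-6 / 60, K_Q = 0.75) {
  if (any(c(kinematic_viscosity, density, sample_rate, sheath_rate) <= 0))
    stop("fluid properties and flow rates must be positive", call. = FALSE)
  structure(list(kinematic_viscosity = kinematic_viscosity,
                 density = density,
                 dynamic_viscosity = kinematic_viscosity * density,
                 sample_rate = sample_rate,
                 sheath_rate = sheath_rate,
                 K_Q = K_Q),
            class = "flow_config")
}

#' Convert microlitres per minute to m^3/s
#'
#' @param x Flow rate in ul/min.
#' @return Flow rate in m^3/s.
#' @export
ul_per_min <- function(x) x * 1e-9 / 60

#' Sheath-channel network of the focusing chip
#'
#' The vertical path is the ordered chain feeding the vertical focusing
#' stage (four parallel feed branches, then the shared segments also
#' carrying the sample flow); the horizontal path feeds the horizontal
#' stage (two parallel branches).
#'
#' @param vertical_path,horizontal_path Lists of [channel_segment()]s.
#' @return An object of class `channel_network`.
#' @export
channel_network <- function(vertical_path, horizontal_path) {
  ok <- function(p) length(p) >= 1L &&
    all(vapply(p, inherits, logical(1), "channel_segment"))
  if (!ok(vertical_path) || !ok(horizontal_path))
    stop("paths must be non-empty lists of channel_segment objects",
         call. = FALSE)
  structure(list(vertical_path = vertical_path,
                 horizontal_path = horizontal_path),
            class = "channel_network")
}

#' A synthetic example of the focusing-chip network
#'
#' Segment lengths of the fabricated chip are not tabulated anywhere in
#' machine-readable form, so this constructor returns a *synthetic* but
#' hydraulically plausible network: 150 um-thick sheath channels with four
#' vertical feed branches, shared vertical segments matching the 310 x 163
#' um straight channel, and two high-aspect horizontal branches carrying
#' `K_P = 1.4`. Lengths are chosen so that the sheath split ratio
#' `Q_HS/Q_VS` evaluates near the design optimum of 8. Override any segment
#' for a real chip.
#'
#' @return A [channel_network()].
#' @export
example_network <- function() {
  channel_network(
    vertical_path = list(
      channel_segment(300e-6, 150e-6, 20e-3, parallel_count = 4L),
      channel_segment(310e-6, 163e-6, 2.0e-3, carries_sample = TRUE),
      channel_segment(310e-6, 163e-6, 3.0e-3, carries_sample = TRUE)
    ),
    horizontal_path = list(
      channel_segment(1000e-6, 150e-6, 6.0e-3, parallel_count = 2L, K_P = 1.4),
      channel_segment(1000e-6, 150e-6, 4.0e-3, parallel_count = 2L, K_P = 1.4)
    )
  )
}

# Geometric resistance term of one segment, l / (parallel_count * A * d^2),
# the building block of both the pressure drop and the split ratio.
segment_geom_term <- function(seg) {
  A <- seg$width * seg$height
  d <- hydraulic_diameter(seg$width, seg$height)
  seg$length / (seg$parallel_count * A * d^2)
}

#' Laminar pressure drop along a channel path
#'
#' Sums `32 * nu * rho * K_P * (l / d^2) * (Q_seg / A)` over the segments,
#' with the path flow divided equally among parallel branches and the
#' sample flow added in segments that carry it. Setting
#' `include_sample = FALSE` reproduces the simplifying approximation that
#' drops the (small) sample rate against the sheath rate in the shared
#' segments.
#'
#' @param path List of [channel_segment()]s.
#' @param Q_path Path flow rate in m^3/s (>= 0).
#' @param fluid A [flow_config()].
#' @param include_sample Keep the sample flow in shared segments (default
#'   `TRUE`, the exact form).
#' @return Pressure drop in pascals.
#' @export
path_pressure_drop <- function(path, Q_path, fluid, include_sample = TRUE) {
  stopifnot(inherits(fluid, "flow_config"))
  if (Q_path < 0) stop("'Q_path' must be >= 0", call. = FALSE)
  dp <- 0
  for (seg in path) {
    Q_seg <- Q_path / seg$parallel_count +
      if (seg$carries_sample && include_sample) fluid$sample_rate else 0
    A <- seg$width * seg$height
    d <- hydraulic_diameter(seg$width, seg$height)
    dp <- dp + 32 * fluid$kinematic_viscosity * fluid$density * seg$K_P *
      seg$length / d^2 * Q_seg / A
  }
  dp
}

#' Sheath flow split ratio Q_HS / Q_VS
#'
#' Because both sheath paths see the same inlet pressure and meet at the
#' confluence, equal pressure drops fix the split between the horizontal
#' (Q_HS) and vertical (Q_VS) sheath flows as the ratio of the vertical
#' geometric resistance sum to the K_P-corrected horizontal one, plus the
#' correction constant K_Q:
#' `Q_HS/Q_VS = sum_v l/(pc A d^2) / sum_h K_P l/(pc A d^2) + K_Q`.
#' Invariant under a common scaling of all lengths; tends to `K_Q` as the
#' vertical resistance vanishes.
#'
#' @param network A [channel_network()].
#' @param fluid A [flow_config()] (supplies K_Q).
#' @return Dimensionless split ratio.
#' @export
flow_split_ratio <- function(network, fluid) {
  stopifnot(inherits(network, "channel_network"),
            inherits(fluid, "flow_config"))
  rv <- sum(vapply(network$vertical_path, segment_geom_term, numeric(1)))
  rh <- sum(vapply(network$horizontal_path,
                   function(s) s$K_P * segment_geom_term(s), numeric(1)))
  if (rh == 0) stop("horizontal path resistance is zero", call. = FALSE)
  rv / rh + fluid$K_Q
}

#' Partition the total sheath flow between the two focusing stages
#'
#' @param network A [channel_network()].
#' @param fluid A [flow_config()] (supplies the total sheath rate Q_SH).
#' @return List with `ratio` (= Q_HS/Q_VS), `Q_HS` and `Q_VS` in m^3/s.
#' @export
split_sheath_flow <- function(network, fluid) {
  r <- flow_split_ratio(network, fluid)
  list(ratio = r,
       Q_HS = fluid$sheath_rate * r / (1 + r),
       Q_VS = fluid$sheath_rate / (1 + r))
}

#' Laminar velocity profile in a rectangular duct
#'
#' Evaluates the classical Fourier-series solution for fully developed
#' pressure-driven flow in an `a x b` duct, in axis-centred coordinates
#' (`y` across the width, `|y| <= a/2`; `z` across the height,
#' `|z| <= b/2`):
#' \deqn{v = \frac{4 b^2}{\mu \pi^3}\left(-\frac{dP}{dx}\right)
#'   \sum_{n \ge 0} \frac{(-1)^n}{(2n+1)^3}
#'   \left[1 - \frac{\cosh((2n+1)\pi y / b)}{\cosh((2n+1)\pi a / 2b)}\right]
#'   \cos\frac{(2n+1)\pi z}{b}.}
#' The series tail is bounded by `sum 1/(2n+1)^3`, so 100 terms give far
#' better than single-precision accuracy away from the walls.
#'
#' @param y,z Evaluation coordinates in metres (vectors recycled together).
#' @param a Duct width in metres.
#' @param b Duct height in metres.
#' @param pressure_gradient Driving `-dP/dx` in Pa/m (> 0 for flow in +x).
#' @param mu Dynamic viscosity in Pa.s.
#' @param n_terms Number of series terms (>= 25).
#' @return Velocity in m/s (vector).
#' @export
duct_velocity <- function(y, z, a, b, pressure_gradient = 1,
                          mu = 1.004e-6 * 998, n_terms = 100L) {
  if (a <= 0 || b <= 0) stop("duct sides must be positive", call. = FALSE)
  if (n_terms < 25L) stop("'n_terms' must be >= 25", call. = FALSE)
  if (any(abs(y) > a / 2 + 1e-12 * a) || any(abs(z) > b / 2 + 1e-12 * b))
    stop("(y, z) outside the duct cross-section", call. = FALSE)
  len <- max(length(y), length(z))
  v <- numeric(len)
  yy <- rep_len(y, len); zz <- rep_len(z, len)
  for (n in seq_len(n_terms) - 1L) {
    m <- 2 * n + 1
    k <- m * pi / b
    v <- v + (-1)^n / m^3 *
      (1 - cosh_ratio(k * yy, k * a / 2)) * cos(k * zz)
  }
  4 * b^2 / (mu * pi^3) * pressure_gradient * v
}

# cosh(x)/cosh(x0) computed in log space to avoid overflow for large
# arguments (thin ducts, high series terms).
cosh_ratio <- function(x, x0) {
  ax <- abs(x)
  (exp(ax - x0) + exp(-ax - x0)) / (1 + exp(-2 * x0))
}

# Cross-section average of the unit-gradient profile, from the term-wise
# analytic integral of the series.
duct_mean_unit <- function(a, b, mu, n_terms = 100L) {
  s <- 0
  for (n in seq_len(n_terms) - 1L) {
    m <- 2 * n + 1
    k <- m * pi / b
    s <- s + 1 / m^3 * (2 / k) * (a - (2 / k) * tanh(k * a / 2))
  }
  4 * b^2 / (mu * pi^3) * s / (a * b)
}

#' Ratio of centreline (maximum) to average duct velocity
#'
#' `V_MAX / V_AVR` for a rectangular duct, from the series profile: 2.096
#' for a square duct, decreasing monotonically toward the plane-Poiseuille
#' value 1.5 as the aspect ratio grows.
#'
#' @param a,b Duct sides in metres.
#' @param n_terms Series terms.
#' @return Dimensionless ratio in (1.5, 2.097\].
#' @export
max_to_mean_ratio <- function(a, b, n_terms = 100L) {
  mu <- 1  # cancels in the ratio
  duct_velocity(0, 0, a, b, pressure_gradient = 1, mu = mu,
                n_terms = n_terms) /
    duct_mean_unit(a, b, mu, n_terms = n_terms)
}

#' Centreline velocity of the focused sample stream
#'
#' The focused sample travels on the duct axis, so its speed is the duct's
#' maximum velocity: `V_MAX = (V_MAX/V_AVR) * Q_total / (a * b)`.
#'
#' @param Q_total Total volumetric rate through the duct in m^3/s.
#' @param a,b Duct sides in metres.
#' @param n_terms Series terms.
#' @return List with `V_AVR`, `ratio` and `V_MAX` (m/s).
#' @export
centerline_velocity <- function(Q_total, a, b, n_terms = 100L) {
  if (Q_total <= 0) stop("'Q_total' must be positive", call. = FALSE)
  v_avr <- Q_total / (a * b)
  r <- max_to_mean_ratio(a, b, n_terms = n_terms)
  list(V_AVR = v_avr, ratio = r, V_MAX = r * v_avr)
}
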