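---
title: "Models and methods behind flowspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flowspot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flowspot)
```

This vignette records the models the package implements, the defaults it
ships, and the reasoning behind the choices that were genuinely open. It is
the place to look before changing a parameter.

## 1. Optical model

The element + lens system is treated in the scalar Fraunhofer regime: the
field in the lens focal plane is the scaled Fourier transform of the field
leaving the element,

$$U(u,v) = \frac{1}{\lambda f}\,\mathrm{FT}\!\left[A(x,y)\,
  e^{i\Phi_0 + i\Phi_B(x,y)}\right],$$

with the natural focal pixel $\lambda f/D$ (1.63 µm for 488 nm, $f$ = 10 mm,
$D$ = 3 mm). Assumptions: thin element (pure phase, no etch-depth error),
monochromatic TEM$_{00}$ illumination (so $\Phi_0$ is constant), aberration-
free lens, and evaluation exactly in the focal plane. Vector-diffraction
effects at the 23.4 µm zone pitch (≈ 48 λ) are negligible. Defocus, which in
the real instrument deforms the spot, is deliberately out of scope: the
simulator exposes lateral bead offset but not axial misalignment.

Two incident profiles are supported. The default is a uniform square beam
filling the element — consistent with identifying the beam diameter with the
element side, which is what makes $\lambda f / D$ the focal sampling
interval. A truncated Gaussian (1/e² intensity diameter equal to the element
side) is available via `aperture_profile = "gaussian"` for sensitivity
studies.

`propagate_to_focal()` is a centred FFT with physical scaling
$dx^2/\lambda f$; it conserves energy to machine precision (the test suite
asserts 1e−10) and matches a brute-force evaluation of the double integral
on small grids to 1e−8, which pins down the sign, centring and scaling
conventions independently of the FFT.

## 2. Target rasterization

Targets are unions of axis-aligned rectangles. Pixels crossed by an edge
receive their covered *area fraction*, and the target amplitude is the
square root of coverage, so the target **intensity** passes through half
maximum exactly on the geometric edge. Consequences:

* the coverage integral preserves the exact rectangle area (the R1 and R3
  area tests exploit this);
* the boolean `signal_region` (all pixels with non-zero coverage) overshoots
  the geometric rectangle by at most a one-pixel perimeter ring;
* the uniformity metrics, which are evaluated over `signal_region`, include
  the dim anti-aliased edge pixels. A *perfect* R1 design therefore has
  RMSA ≈ 0.12 on the default grid. Reported RMSA/RMSI values are comparable
  between designs on the same grid but are not "interior ripple" figures.

Geometry defaults: R1 is one 50 µm × 10 µm rectangle (long side across the
flow); R2 places two of them with leading edges 110 µm apart along the flow
— the same 110 µm that serves as the velocimetry baseline $L$; R3 adds a
50 µm square centred between them, which fills the 110 µm span symmetrically
and leaves 25 µm gaps. Only the 50 × 10 rectangles, the 50 µm square side
and the 110 µm pitch are fixed by the instrument concept; the 25 µm gaps are
the package's symmetric-fill default and can be overridden through the
`geometry` argument.

## 3. The design iteration

`gs_design()` is a Gerchberg–Saxton / alternating-projection loop with three
standard "modified GS" ingredients:

1. **Signal window + freedom region.** The focal amplitude is constrained
   only on `signal_region`; the complement is left untouched, giving the
   optimizer somewhere to dump the energy it cannot shape.
2. **Amplitude feedback.** The imposed amplitude is
   $T + \beta (T - c\,|U|)$ with $c$ the least-squares scale between the
   achieved and target amplitudes, recomputed each iteration
   (non-accumulating). $\beta = 0.7$ by default. An accumulating variant
   (adding the correction to a running target) was tried and discarded: it
   diverges slowly over long runs. With $\beta = 0$ the loop is a pure
   alternating projection and the signal-region amplitude mismatch is
   provably non-increasing — the property suite asserts exactly that, in
   that mode.
3. **Staged quantization.** After the continuous stage the aperture phase is
   snapped to 64, then 32, then the final 16 levels, with a few
   re-optimization iterations per stage, which recovers most of the
   uniformity lost to hard one-shot quantization.

**Design grid.** The iteration zero-pads the aperture ×2, so the focal
constraint acts on the $\lambda f/2D$ (0.81 µm) grid. This matters: a focal
field whose aperture support is $D$ is fully determined by its
$\lambda f/D$ samples, so constraining only those samples leaves the
intensity *between* them free to ripple — designs constrained on the coarse
grid look perfect at the sample points and are unusable in between. Padding
×2 samples the intensity at its Nyquist rate; metrics of a finished mask are
then evaluated on the same fine pitch via `mask_focal_field()` (oversample
2, pad 2).

**Initial phase.** The default is the geometric beam-mapping guess — the
separable quadratic whose ray mapping stretches the square aperture onto the
target bounding box ($u(x) = W_x x / D$, i.e.
$\Phi(x,y) = \pi (W_x x^2 + W_y y^2)/(\lambda f D)$, plus a linear tilt for
off-axis targets) — with a small (±0.05 rad) seeded random perturbation.
Starting from pure random phase consistently stalls in a speckled-phase
local minimum whose fine-grid intensity is unusable, a classic failure mode
of flat-top phase retrieval; the random mode is retained as
`initial_phase = "random"` for comparison, and all modes are bit-reproducible
from `rng_seed`. With the defaults the quantized R1 design measures within
≈ 1 % of 50 µm × 10 µm at η ≈ 0.77 (asserted at the 2 % level in the
acceptance tests).

Smaller numerical choices: quantization snaps to the nearest of the $2^N$
levels with exact midpoints rounding to the lower level (determinism); the
continuous stage stops early when the RMSI change drops below
`convergence_tol` (default 1e−9), otherwise the best-so-far design is
returned with `converged = FALSE`; flow direction is +y (matrix rows),
grids are sample-centred on the optical axis with zero at index
`floor(n/2) + 1`.

## 4. Dimension measurement

`measure_dimensions()` reports half-maximum crossing distances, located by
linear interpolation, on profiles through the intensity centroid of each
hinted rectangle. The profile along each axis is averaged over a band
spanning the central half of the *other* dimension — what a beam-profiler
analysis does — because on a single pixel row the residual flat-top ripple
of a quantized design can dip below half of the row's own maximum and
truncate the measurement. Half-maximum crossings are exact for ideal
flat-tops, insensitive to symmetric edge blur (both properties are tested),
and parameter-free.

## 5. Chip hydraulics

Each channel segment contributes the laminar resistance
$32 \nu \rho K_P\, l / (d^2 A)$ with $d = 2ab/(a+b)$; parallel feed branches
divide the path flow; the segments shared with the sample stream may either
carry it (exact form, default) or drop it (the common small-$Q_S$
approximation, `include_sample = FALSE`). Equal inlet pressures and a common
confluence force equal path pressure drops, giving the sheath split

$$\frac{Q_{HS}}{Q_{VS}} =
  \frac{\sum_v l/(p\,A\,d^2)}{K_P \sum_h l/(p\,A\,d^2)} + K_Q .$$

$K_P = 1.4$ and $K_Q = 0.75$ are correction factors obtained upstream from
CFD; they enter as injected constants and no CFD is performed here. The
fluid defaults are distilled water at 20 °C (ν = 1.004e−6 m²/s,
ρ = 998 kg/m³).

The duct velocity profile is the classical Fourier series in axis-centred
coordinates ($|y| \le a/2$, $|z| \le b/2$). The series coordinate
convention is pinned by two analytic limits rather than trusted from any
single source: the parallel-plate limit $V_{MAX}/V_{AVR} \to 1.5$ and the
square-duct value 2.096, both asserted in the tests; the cross-section mean
uses the term-wise analytic integral, and a dense-quadrature oracle checks
that integrating the profile recovers the flow rate to 0.1 %. One hundred
series terms are the default; the tail is bounded by
$\sum_{n>N} (2n+1)^{-3}$, far below single precision at $N = 100$. For the
fabricated 310 µm × 163 µm straight channel the packaged flow stage computes
$V_{MAX}/V_{AVR} \approx 2.01$ (and 4.8 m/s centreline velocity at
60 µl/min + 7.2 ml/min); design documents sometimes quote 2.05 for this
chip without stating which cross-section it refers to, so the package
reports its own Eq.-derived value and the tests anchor on the analytic
limits, not on 2.05.

`example_network()` is *synthetic*: the real chip's segment lengths are
published only graphically, so the packaged network uses plausible lengths
chosen once so the split ratio lands near the stated design optimum of 8.
Real chips should override every segment.

## 6. Waveform simulator

What it emulates:

* **Arrivals** — Poisson process at rate concentration × sample flow
  (5 × 10⁶ /ml × 60 µl/min = 5000 /s at the reference point).
* **Transit** — the bead sees the mean spot intensity over its projected
  disc (uniform disc kernel, no refraction or absorption), evaluated along
  its flow line at a truncated-Gaussian lateral offset (sd = stream
  width / 4, width 15 µm — the midpoint of a 10–23 µm focused core).
  Emission is proportional to instantaneous excitation; long-exposure
  benefit appears through integrated pulse area, not photokinetics.
* **Brightness** — log-normal with mean 1 and CV `brightness_cv`
  (default 5 %).
* **Detector** — linear gain, Poisson shot noise scaled so the R1-plateau
  SNR is 20, additive Gaussian noise at 1 % of plateau, baseline at 2 %.
  These noise figures are declared defaults, not measurements. Sampling is
  10 MHz (≥ 30 samples across the shortest pulse at the 4.8 m/s operating
  point), not the GHz rate of a bench oscilloscope; both are configurable,
  and the constructor rejects configurations that would put fewer than 10
  samples across a pulse.

What it does **not** emulate: defocus or spot deformation, scatter
channels, spectral overlap, photobleaching/saturation, bead refraction, or
electronic pulse shaping. Passing tests therefore establish the internal
consistency of the processing chain and the *mechanisms* (e.g. that
illumination non-uniformity inflates the area CV, and that larger
illuminated areas average it away, giving CV(R3) ≤ CV(R2) ≤ CV(R1) on
matched rough spots); they do not reproduce any instrument's measured CV
curves.

`roughen_spot()` provides the controlled non-uniformity for those mechanism
tests: a Gaussian-correlated multiplicative field of chosen amplitude and
correlation length, power-renormalized.

## 7. Pulse analysis

* **Detection** is threshold-with-hysteresis. The default threshold is
  two-pass: a noise floor at median + 5 robust SD finds the pulses, then the
  threshold is raised to 30 % of the estimated pulse level. The second pass
  matters for velocimetry: on the shallow foot of the pulse the
  noise-triggered first crossing is systematically early and jittery, which
  at 0.7 m/s biased velocity estimates by over 1 %; at 30 % of pulse height
  the edges are steep and the bias disappears (the recovery test asserts
  < 1 % across 0.7–9.0 m/s).
* **Per-pulse baseline** is the median of sub-threshold samples in windows
  displaced one pulse-width before and after the pulse (displacement keeps
  the window off the pulse's own sub-threshold skirt). The **area**
  integrates the baseline-subtracted samples over the threshold span
  extended by 25 % of the pulse width on each side, capped at the
  neighbouring pulses, so the skirt is counted; grouped-event areas match
  the event-span integral to 0.5 %.
* **Grouping** merges pulses separated by less than 1.5 × (sub-spot pitch /
  nominal velocity) — 110 µm for R2, 55 µm for R3; R1 pulses are never
  merged. Events with the expected 1/2/3 sub-pulses are `clean`; others are
  flagged `incomplete` or `coincident` and excluded from CV and velocity
  statistics (reported separately).
* **Velocity** is $(L/T_1 + L/T_2)/2$ with $T_1$/$T_2$ the rising/falling
  threshold-crossing intervals between the first and last sub-pulse and
  $L = 110$ µm. For three sub-pulses, first-to-last with the full $L$ is
  used; at uniform velocity the first-to-second convention with $L/2$ is
  identical.
* **Gated CV** retains the ⌊0.9 n⌋ events *closest to the median* area
  (ties toward the smaller area, then input order) and reports the n−1
  sample SD over the mean. Centring the gate on the median rather than the
  mean avoids the circularity of a mean-centred window under outliers; a
  mean-centred mode is available. The closed-form check: for the central
  90 % of a Normal population the gated CV is
  $\sigma\sqrt{1 - 2 z \phi(z)/0.9}/\mu$ with $z = \Phi^{-1}(0.95)$, about
  7.9 % for σ/µ = 10 %.

## 8. Problem sizes and reproducibility

The test suite runs the full 128-zone reference design for the fidelity
check and scales everything stochastic to what statistics require:
0.25–0.5 s acquisitions at 1–4 × 10⁵ /ml for recovery and CV-mechanism
tests (hundreds of events each, standard errors a few ×10⁻³), a full
1-second run at the reference concentration for the throughput check, and
five roughness realizations for the CV-ordering comparison. All randomness
in a pipeline run flows from one root seed (design and simulation stages
derive fixed offsets from it), and `run_pipeline()` writes a manifest with
the seeds and MD5 checksums of every output, so identical configurations
are bit-identical end to end.

## 9. Known limitations

* The design iteration is a local method; quality depends on the initial
  phase, and the geometric-mapping default is tuned for convex, roughly
  centred rectangle unions. Exotic layouts may need a custom
  `initial_phase`.
* Reported RMSA/RMSI include the anti-aliased target edge (Section 2);
  compare like with like.
* Fabrication errors (etch depth, alignment), which dominate the uniformity
  loss of real elements, are not modelled, so measured elements will show
  higher RMSA/RMSI than these designs.
* The hydraulic model is a 1D resistance network: it predicts splits and
  mean/centreline velocities, not the focused-core shape, which requires
  CFD.
* Coincidence handling is flag-and-exclude; there is no doublet
  deconvolution.
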