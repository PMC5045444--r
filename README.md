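# flowspot

Computational toolkit for a micro flow cytometer whose illumination comes
from **multi-level diffractive phase elements** instead of cylindrical-lens
optics. Conventional elliptical Gaussian spots illuminate a cell differently
depending on its path; a *rectangular quasi-flat-top* spot does not. The
package is for instrument builders and simulation users who want to

1. **design** the quantized phase masks that put such spots in a lens focal
   plane,
2. **model** the 3D hydrodynamic-focusing chip that carries the beads
   through them, and
3. **simulate and analyse** the resulting photomultiplier (PMT) pulse
   trains, including time-of-flight velocimetry and gated CV statistics.

Three stock spot layouts are built in: `R1` (one 50 µm × 10 µm rectangle,
highest intensity and throughput), `R2` (two such rectangles with leading
edges 110 µm apart, enabling per-bead velocimetry) and `R3` (`R2` plus a
central 50 µm square for long exposure and the most stable intensity
statistics).

## The core algorithms

**Mask design.** The focal field is the scaled Fourier transform of the
field leaving the element, `U(u,v) = FT[A(x,y) e^{iΦ_B(x,y)}]/(λf)`, so the
design problem is phase retrieval: find `Φ_B` such that `|U|` matches a
target amplitude on the spot region. `gs_design()` solves it with a modified
Gerchberg–Saxton iteration — amplitude constraints alternately imposed in
the aperture plane (incident beam profile) and the focal plane (target
amplitude on the signal window only, with a feedback-boosted correction;
everything outside the window is left free) — followed by staged phase
quantization (64 → 32 → 16 levels) so the returned mask is directly
manufacturable. The relief map follows from `h = λ Φ_B / (2π(n−1))`; with
`N = 4` lithography masks (16 levels) on quartz (`n = 1.4632` at 488 nm) the
etch step is `λ/(2^N (n−1)) = 66 nm`. Spot quality is scored by the
diffraction efficiency `η` (energy fraction in the signal window) and the
relative RMS errors of amplitude (`RMSA`) and intensity (`RMSI`), plus
half-maximum dimension measurement.

**Chip hydraulics.** Every sheath channel is a laminar rectangular duct with
resistance `32νρ l/(d²A)` (`d = 2ab/(a+b)` the hydraulic diameter). Equal
pressure drops across the vertical- and horizontal-focusing paths fix the
sheath split `Q_HS/Q_VS` as a resistance ratio plus a CFD-derived correction
(`K_P = 1.4`, `K_Q = 0.75`, injected constants). The focused sample rides
the duct centreline, so its speed is the channel's maximum velocity, from
the classical Fourier-series duct profile (`V_MAX/V_AVR` = 2.096 for a
square duct, → 1.5 for parallel plates).

**Signal simulation and pulse analysis.** Beads arrive as a Poisson process
(rate = concentration × sample flow), each with a log-normal brightness and
a truncated-Gaussian lateral offset; the transit profile is the spot
intensity convolved with the bead's projected-area disc; detection applies
Poisson shot noise and additive Gaussian noise. `analyze_waveform()`
extracts pulses (two-pass threshold with hysteresis), groups the 1/2/3
sub-pulses of an event, estimates per-bead velocity as `(L/T₁ + L/T₂)/2`
from the rising/falling-edge intervals (`L = 110 µm`), and reports the CV of
pulse areas inside a 90-percent gate.

## Worked example

```r
library(flowspot)

## 1. design the R1 mask at the reference optics
oc     <- optical_config()           # 488 nm, f = 10 mm, D = 3 mm, 128 zones, 16 levels
dg     <- design_grid(oc)
target <- make_target("R1", n = dg$n, pitch = dg$pitch)
design <- gs_design(target, oc, gs_options(rng_seed = 0))

## 2. evaluate the quantized mask on a fine focal grid
focal   <- mask_focal_field(design$mask, oc, oversample = 2, pad_factor = 2)
evaluate_spot(focal, retarget(target, nrow(focal$values), focal$sample_pitch),
              design$aperture)
#> <spot_metrics> eta = 0.771, RMSA = 0.141, RMSI = 0.247
#>   rect 1: 49.54 x 10.13 um (err -0.9%, +1.3%)

## 3. chip hydraulics at 60 ul/min sample + 7.2 ml/min sheath
fluid <- flow_config()
split_sheath_flow(example_network(), fluid)$ratio        # sheath split Q_HS/Q_VS
#> [1] 7.96
centerline_velocity(fluid$sample_rate + fluid$sheath_rate,
                    310e-6, 163e-6)$V_MAX                # focused-stream speed
#> [1] 4.80                                               # m/s

## 4. simulate 0.2 s of acquisition and analyse it
spot <- ideal_spot_model("R1")
run  <- simulate_run(spot, bead_population(), velocity = 4.8,
                     sample_rate = ul_per_min(60),
                     acquisition = acquisition_config(duration = 0.2, rng_seed = 0))
analyze_waveform(run, "R1", nominal_velocity = 4.8)
#> <pulse_analysis> R1: 1025 events (1025 clean, 0 incomplete, 0 coincident), 5125 eps
#>   gated CV = 4.21% (n = 922)
```

The designed spot is within ~1 % of its 50 µm × 10 µm specification while
collecting 77 % of the beam energy; the example chip splits the sheath
close to the design-optimal ratio of 8 and delivers a 4.8 m/s focused
stream; and a 5 × 10⁶ /ml bead suspension at 60 µl/min yields ≈ 5000
detected events per second with a ~4 % gated area CV at the default 5 %
intrinsic brightness spread.

An end-to-end, reproducible run of all five stages (design → evaluate →
flow → simulate → analyse, with a manifest of seeds and checksums) is
`run_pipeline(default_config("R1"), "out/")`, or from a shell:

```sh
Rscript inst/cli/flowspot.R run --spot R2 --seed 1 --out out/
```

## Package layout

| Area | Key functions |
|---|---|
| Mask design | `optical_config`, `make_target`, `gs_design`, `quantize_phase`, `phase_to_relief`, `mask_focal_field` |
| Spot metrics | `evaluate_spot`, `diffraction_efficiency`, `rms_amplitude_error`, `rms_intensity_error`, `measure_dimensions` |
| Hydraulics | `channel_segment`, `channel_network`, `flow_split_ratio`, `path_pressure_drop`, `duct_velocity`, `centerline_velocity` |
| Simulation | `spot_model`, `ideal_spot_model`, `roughen_spot`, `transit_profile`, `simulate_event`, `simulate_run` |
| Pulse analysis | `detect_pulses`, `group_events`, `estimate_velocity`, `gate_and_cv`, `analyze_waveform` |
| Pipeline | `default_config`, `read_config`, `run_pipeline`, CLI in `inst/cli/flowspot.R` |

The methods vignette (`vignettes/flowspot-methods.Rmd`) documents the
models, the default parameters and their provenance, the numerical choices,
and what the synthetic-data tests do and do not establish about real
hardware.
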