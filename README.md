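# polonaise

Quantification of the bilateral vortex-like cell flows of early amniote
gastrulation, with a synthetic ground-truth simulator for validating the
entire measurement chain.

## The problem

Before and during formation of the primitive streak — the first midline
structure of the amniote embryo — the avian epiblast moves in a
stereotypical large-scale pattern: two counter-rotating vortices arranged
bilaterally about the future midline (the "polonaise movements").
Experiments that perturb streak morphogenesis (Wnt/PCP suppression,
mitotic arrest, ectopic induction of a second axis) change measurable
properties of this flow: the distance between the left and right rotation
centers, and how long the pattern persists. Quantifying those properties
from time-lapse microscopy of fluorescently tagged epiblast cells takes a
chain of methods — PIV, field averaging, vorticity and streamline
analysis, vortex detection, group statistics — and each link needs
validation against known ground truth. This package implements the whole
chain plus the ground truth.

## What is inside

* **Synthetic tissue flow** — analytic vortex-pair models on a circular
  embryonic disc. Each rotation center is a Lamb–Oseen-style vortex,
  u_θ(r) ∝ (1 − exp(−α r²/r_c²))/r, mirrored across the midline, with
  time-dependent amplitude envelopes; presets emulate control (persistent
  strengthening flow, separation 860.2 µm), `ddep` (wider separation,
  1008.4 µm), `aphidicolin` (flow decays by 2.2 h), and `vg1` (a second
  pair, rotated 180°, overrides the authentic flow after ~1 h). Tracers
  are advected by 4th-order Runge–Kutta and rendered into noisy 16-bit
  movies (`build_flow_model()`, `generate_condition()`).
* **Two-pass PIV** — windowed FFT cross-correlation, 64 px then 32 px
  interrogation windows at 50 % overlap with discrete window offsetting,
  Tukey-weighted windows with correlation-plane correction, three-point
  Gaussian sub-pixel peaks, normalized-median-test validation, Laplace
  interpolation of outliers, and unit calibration to µm/s
  (`two_pass_piv()`, `piv_series()`, `calibrate()`).
* **Field analysis** — time averaging, vorticity ω = ∂v/∂x − ∂u/∂y
  (positive = counter-clockwise; |ω| is twice the local angular
  velocity), divergence, streamlines, and sliding maximum-intensity
  trajectory projections (`time_average()`, `vorticity()`,
  `streamlines()`, `flowtrace_projection()`).
* **Vortex metrics** — core detection from vorticity extrema, bilateral
  pattern detection about a midline, left–right separation, sliding-window
  persistence/duration, and pooled t / Welch / ANOVA group comparisons
  (`detect_polonaise()`, `measure_separation()`, `polonaise_duration()`,
  `compare_groups()`).
* **Nucleus quantification** — labeled fractions (BrdU/TUNEL-style) on
  the standard 3×3 grid of 800 µm squares: count per square, then average
  (`generate_nuclei()`, `place_grid()`, `detect_spots()`,
  `labeled_fraction()`).
* **Pipeline** — `run_pipeline()` drives simulate → PIV → fields →
  metrics → statistics from one config, deterministically; a thin CLI
  lives in `inst/cli/polonaise.R`.

## Worked example

Simulate a control embryo movie (60 frames = 3 h at one frame per
3 min), measure its flow by PIV, and extract the vortex-pair metrics:

```r
library(polonaise)

sim <- generate_condition("control", imaging_params(frame_count = 60),
                          n_particles = 8000, seed = 1)
series <- piv_series(sim$stack, piv_params(), stride = 3)
avg <- time_average(series, 0, 6 * 3600)
pat <- detect_polonaise(avg, params = polonaise_params(max_core_radius = 1350))
pat
#> <polonaise_pattern> detected (authentic axis)
#>   separation: 883.3 μm
#>   left core:  (-416.6, -0.4) um, sign +1, peak 1.76e-03 1/s
#>   right core: (466.7, -0.4) um, sign -1, peak -1.76e-03 1/s
measure_separation(pat)
#> [1] 883.285
```

The generator placed the rotation centers 860.2 µm apart; the full
measurement chain recovers 883.3 µm (+2.7 %, about half a vector-grid
spacing), with the left core rotating counter-clockwise (+1) and the
right core clockwise (−1), as configured. Comparing recovered separations
across conditions works exactly as for embryo measurements:

```r
compare_groups(list(control = c(6.5, 7.7, 5.3, 6.5),
                    treated = c(2.2, 3.4, 1.0, 2.2)))
#> <group_comparison> Student's t (pooled, two-tailed)
#>   control: n = 4, mean = 6.5, sd = 0.9798
#>   treated: n = 4, mean = 2.2, sd = 0.9798
#>   statistic = 6.207, df = 6, p = 0.000807
```

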