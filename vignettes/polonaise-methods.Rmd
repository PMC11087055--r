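---
title: "Quantifying bilateral vortex-like tissue flows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bilateral vortex-like tissue flows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Before and during primitive streak (PS) formation, the avian epiblast
exhibits a large-scale cell flow: a bilateral pair of counter-rotating
vortices arranged symmetrically about the future midline, classically
called the polonaise movements. This package provides the quantitative
tool chain for characterizing such flows from time-lapse fluorescence
microscopy — particle image velocimetry (PIV), vorticity and streamline
analysis, vortex-pair metrics, and grid-based nucleus counting — together
with a synthetic ground-truth generator that emulates the main
experimental conditions, so that every stage of the chain can be validated
end to end. This vignette explains the models, the tunable parameters, and
the design choices.

## The synthetic flow model

The generator's ground truth is an analytic, time-modulated velocity
field on a circular embryonic disc (default radius 1500 µm). Each
rotation center is a finite-core vortex with a Lamb–Oseen-style azimuthal
speed profile,

$$u_\theta(r) \;=\; \frac{U}{1 - e^{-\alpha}}\,
  \frac{1 - e^{-\alpha (r/r_c)^2}}{r/r_c},
  \qquad \alpha \approx 1.2564,$$

scaled so that the maximum speed $U$ (`peak_speed`) is attained at the
core radius $r_c$. This profile is smooth, has finite vorticity at the
center, and is the standard choice for synthesizing vortical flows; the
superposition of purely azimuthal profiles is exactly divergence-free,
matching the (nearly) incompressible in-plane motion of the epiblast
sheet. A bilateral pair consists of two such vortices of opposite
circulation mirrored across the midline. A cosine taper of width 150 µm
brings the velocity smoothly to exactly zero at the disc edge; the taper
necessarily introduces a compensating ring of opposite-signed vorticity
at the margin (any bounded vortex must carry zero net circulation), which
is why analyses restrict core detection to the disc interior.

Time dependence enters through a per-pair amplitude envelope in $[0,1]$:

* **control / ddep** — a smoothstep ramp over 1 h, then a persistent
  plateau: the flow strengthens over time and is maintained.
* **aphidicolin** — the same ramp, then a cosine ramp down to zero over
  the half hour preceding `t_decay` = 2.2 h: under mitotic arrest the
  flow initiates normally but ceases early. `t_decay` marks the time at
  which the flow has stopped.
* **vg1 / vg1_aphidicolin** — a second vortex pair, rotated 180° about
  the disc center (the induced axis), crossfades in from
  `secondary_onset` = 1 h while the authentic pair fades out, emulating
  an ectopically induced flow that overrides the original pattern after
  the authentic pattern has persisted for about an hour.

The preset separations are 860.2 µm (control) and 1008.4 µm (ddep, the
Wnt/PCP-suppressed condition with a wider left–right rotation distance);
these are the condition definitions, and end-to-end tests check that the
pipeline recovers them. Default `peak_speed` is 0.2 µm/s: absolute tissue
speeds are a free parameter here, and this value yields peak
displacements of ~11 px per 3-min frame at the default optics
(3.25 µm/px) — multi-pixel, yet comfortably within the 64/32 px
interrogation windows, which is the regime windowed PIV is designed for.
It remains configurable, as does the left/right handedness of the
rotations (default: counter-clockwise on the left in anterior-up view),
which is a convention, not a claim about real embryos.

Tracer particles stand in for sparsely labeled epiblast cells: seeded
uniformly over the disc, advected with one classical 4th-order
Runge–Kutta step per frame interval (validated against a 100×-finer
oracle in the tests), and rendered as isotropic Gaussian spots
(σ = 2 px) over a constant background with Gaussian or Poisson–Gaussian
noise, clipped to 16 bits. All randomness flows through a single seed;
identical seeds give bit-identical movies.

**What the generator does not emulate:** cell division and ingression,
neighbor exchange, spot-size and brightness heterogeneity, photobleaching,
drift, or out-of-plane motion. Passing tests therefore demonstrate that
the measurement chain is correct and unbiased on flows of the modeled
class, not that it is robust to every artifact of real microscopy.

## Two-pass PIV

Velocities are estimated by windowed cross-correlation between
consecutive frames: a first pass with 64 px windows at 50 % overlap, whose
validated field predicts integer window offsets for a second pass with
32 px windows at 50 % overlap (discrete window offsetting; no image
deformation). Numerical choices that matter:

* **Preprocessing.** A moving-average high-pass (default kernel 15 px,
  configurable) suppresses slowly varying background and emphasizes the
  particles.
* **Normalization.** Windows are mean-subtracted and variance-normalized,
  so the correlation is illumination-invariant; zero-variance windows are
  flagged invalid rather than raising errors.
* **Window weighting.** Plain top-hat windows bias displacements toward
  zero because particles truncated at window edges correlate
  asymmetrically. Each window is therefore weighted with a Tukey
  (tapered-cosine, α = 0.5) profile and the correlation plane is divided
  by the taper's autocorrelation, which removes the weighting's own bias;
  the divisor is floored at 10 % of its peak to avoid amplifying noise at
  extreme lags. On ground-truth translations this reduces the mean bias
  from ≈0.1 px to below 0.02 px.
* **Sub-pixel estimation.** Three-point Gaussian fit per axis on the
  correlation peak, with a parabolic fallback when a neighbor is
  non-positive; estimates are clamped to ±1 px around the integer peak.
* **Validation.** An absolute displacement cap (half the first-pass
  window) and a normalized median test (3×3 neighborhood, ε = 0.1,
  threshold 2.0) mark outliers; invalid nodes are filled by iterative
  neighbor averaging (Laplace fill, tolerance 10⁻⁶) and flagged
  `interpolated`; a final 3×3 smoothing is optional (on by default).
  Nodes whose window would extend beyond the image are not padded; the
  grid simply stops.
* **Calibration.** Fields are produced in px/frame and converted once to
  µm/s (`calibrate()` refuses to calibrate twice). Image rows increase
  downward; `as_physical_field()` flips to the y-up anterior-up frame in
  which all field analysis is done, so that positive vorticity is
  counter-clockwise on screen.

## Field analysis and vortex metrics

Vorticity $\omega = \partial v/\partial x - \partial u/\partial y$ and
divergence are computed by central differences (one-sided at the border
ring, which is flagged lower-confidence; derivatives touching an invalid
node are invalid rather than filled). For rigid rotation at angular
velocity $\Omega$ the discrete estimator returns $2\Omega$ exactly up to
rounding, which the tests assert. Streamlines integrate the normalized
direction field with 4th-order steps of half a grid spacing and bilinear
interpolation, terminating on grid exit, stagnation, closure (returning
within one step of the seed), or a step cap. Streak ("Flowtrace"-style)
projections are sliding maximum-intensity projections over a window of
frames (10 frames ≈ 30 min by default), optionally with a recency-coded
second channel; for unsteady flow such particle-path streaks do not
coincide with instantaneous streamlines, and both views are provided.

Rotation centers are detected as local extrema of the vorticity of the
time-averaged field, with |ω| above a threshold, non-maximum suppression
within 200 µm, and sub-grid refinement by a vorticity-weighted centroid
over the extremum's 3×3 neighborhood. This is a deliberate substitution:
identifying centers manually from streamline plots (as done interactively
in microscopy practice) has no algorithmic definition, while vorticity
extrema are deterministic and grid-local. The detection threshold
defaults to 20 % of the movie-wide 95th percentile of |ω| — scale-free
across conditions, so weakening flows stop being "detected" when their
rotation fades into the field's own background. A bilateral pattern
requires the strongest opposite-signed pair with one core on each side of
the midline, both inside the disc interior (the taper ring and the empty
image corners carry no tissue signal and are excluded via
`max_core_radius`). Separation is the Euclidean distance between the two
core positions. Duration slides a 30-min averaging window across the
field series, detects the pattern per window, and scores the maximal
contiguous detected run from the first detection; one undetected window
may be bridged (configurable) so that a single noisy window does not
truncate a run. Reported durations include the averaging window at the
run end and are therefore quantized by the window stride.

Group comparisons use the pooled two-tailed Student's t test by default,
with Welch's t and one-way ANOVA available; degenerate all-constant input
returns p = 1 (equal means) or p = 0 by convention rather than erroring.

## Nucleus quantification

Labeled fractions (BrdU/TUNEL-style assays) are quantified on a 3×3 grid
of 800 µm squares centered on the disc. The summary statistic is the
mean of per-square fractions — squares are counted, then averaged — with
empty squares excluded; the pooled ratio is reported alongside. Spot
detection is Gaussian-smoothed local-maximum detection with non-maximum
suppression at the spot scale, so nuclei closer than one suppression
radius merge into a single detection; on Poisson-placed synthetic fields
this produces a small, density-dependent undercount that the tests
quantify. Squares are axis-aligned and edge squares are included as-is;
grid orientation is a convention.

## Problem sizes and reproducibility

The test suite and the acceptance script validate the chain end to end on
60-frame movies (3 h of imaging at 3-min intervals, 1024×1024 px,
8000 tracers), analyzing every third frame pair; these sizes preserve the
full measurement chain while keeping a complete multi-condition study to
a few minutes per run. The pipeline is deterministic: a rerun with an
identical configuration (including its seeds) reproduces every report
metric bit for bit, which the tests assert. Longer movies (the 200-frame,
10-h default) change nothing but runtime.

## Known limitations

* Separation accuracy is limited by the pass-2 grid spacing (16 px ≈
  52 µm at default optics) and the centroid refinement; recovered
  separations are accurate to a few percent, not to single microns.
* The duration metric inherits the averaging-window quantization
  (±½ window) and depends on the scale-free threshold; durations of
  flows that fade gradually are defined only up to that convention.
* The PIV engine is two-pass discrete-offsetting by design; iterative
  image-deformation schemes would improve strong-shear accuracy but are
  out of scope.
* Vorticity highlights any local rotation, including curved but
  non-closed flow, so a vorticity extremum is not by itself evidence of a
  closed vortex; the streamline topology view complements it.
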