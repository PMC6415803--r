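---
title: "Methods: flower morphospace geometry, simulated foraging trials, and fitness estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flower morphospace geometry, simulated foraging trials, and fitness estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corolla)
```

## The morphospace model

An artificial flower is a surface of revolution generated by a
four-parameter curve,

$$z(r) \;=\; L\left(\frac{r - r_0}{R}\right)^{e^{c}},
  \qquad r_0 \le r \le r_0 + R,$$

where `z` is the longitudinal axis (mm), `r` the radial distance from the
central axis (mm), `r0` the nectary radius (the nectary diameter is
`2*r0`), `L` the flower length, `R` the lateral corolla extent, and `c` a
dimensionless curvature parameter (not mathematical curvature). Writing the
exponent as `e^c` gives the family its useful limits:

* `c = 0`: `e^0 = 1`, a straight-sided **cone**;
* `c = 1`: exponent `e`, a **bowl**;
* `c` large and negative: exponent near 0, a **trumpet** hugging the floor
  before rising sharply at the lip;
* `c = -Inf`: exponent 0 exactly — the **flat disc** limit, `z = L`
  everywhere except the nectary rim.

The boundary conditions `z(r0) = 0` (finite `c`) and `z(r0 + R) = L` hold
for every member. `c = -Inf` is represented by IEEE `-Inf` and handled as
the analytic limit, never by evaluating `exp(c)` numerically; users
therefore cannot land in the grey zone where a "very negative" float
silently underflows. `corolla_profile()` refuses radii outside
`[r0, r0 + R]`.

Morphospace grids fix `L` (20 mm) and the overall diameter
`2*(R + r0)` (55 mm) so that nectary diameter trades off against lateral
extent: `sample_grid()` takes curvatures and nectary diameters and returns
shapes curvature-major. The canonical grid crosses eight curvatures
(`-Inf, -4, -3, -2, -1, 0, 0.375, 1`) with six nectary diameters
(1–7 mm), 48 shapes.

### Meshing and STL export

`build_mesh()` produces the printable solid. The generating curve is
sampled radially, offset by the wall thickness (default 1 mm) along the
local surface normal — a normal offset, not a vertical one, so the printed
shell has uniform thickness even on near-vertical trumpet walls — and
joined to a nectary bore tube of inner radius `r0`. The resulting closed
polygon in the (radius, height) plane is revolved about the z-axis. Because
a closed polygon revolved through a full turn has torus topology, every
edge is shared by exactly two triangles: the mesh is watertight by
construction, which `mesh_is_watertight()` verifies explicitly. Vertices
are shifted so the lowest point is at z = 0.

Numerical choices:

* default tessellation `n_angular = 128`, `n_radial = 64`, keeping the
  chord error below 0.05 mm at the 27.5 mm outer radius;
* the flat-disc limit is meshed directly as a 1 mm-thick annulus with the
  bore below it rather than through the power-law path;
* the bore depth below the corolla is not constrained by the shape equation;
  it is exposed as `bore_depth` (default 20 mm, a plausible nectar tube);
* a wall thicker than the nectary diameter would close the bore, so
  `wall_thickness >= 2*r0` is rejected as degenerate.

`write_stl()`/`read_stl()` implement the binary STL layout directly
(80-byte header, float32 facets). STL is unit-less by convention; all
coordinates are mm.

## What the synthetic data emulate

No public recordings accompany the experiments this package models, so the
generators are first-class, tested code with exhaustive ground truth. They
emulate the *statistical structure* the analysis relies on, not the
appearance of real footage; passing tests demonstrate that the analysis
chain recovers known truth under that structure, not that it would segment
real, low-light video of a specific moth.

### Stage 1: array foraging trials

A trial presents a 6 x 6 array of 36 flowers (centers 30.5 cm apart), six
morphologies at equal frequency, 20 uL of nectar each. The generator
exposes exactly the two quantities the stage-1 analysis estimates:

* a per-morph **visit rate** (visits/min); visits arrive as a Poisson
  process;
* a per-morph **success probability** `p`: each visit to a still-full
  flower of the morph empties it with probability `p`. A morph has six
  flowers and each empties at most once, so per-morph emptied counts are
  `min(6, Binomial(visits, p))`.

Two end rules are implemented: `MOTH_LEAVES` (the trial runs for a fixed
duration, default 10 min) and `ALL_OF_ONE_MORPH_EMPTIED` (stop when some
morph is fully emptied, duration-capped). The default rates
(0.62 visits/min for extreme curvatures, 0.43 for gentle trumpets) encode
the observed visitation pattern — extreme shapes draw roughly 45% more
approaches — and place expected per-morph visits (about 4–6 per trial)
below the six-flower pool, so per-visit success stays effectively
Bernoulli(`p`) and the success-rate estimator is unbiased. Default success
probabilities peak for trumpet shapes and collapse for extreme shapes at
narrow nectary diameters, mirroring the observed interaction. What counted
as a "visit" in manual scoring of real trials is ambiguous; the simulator
sidesteps this by emitting visit events directly and documents the
ambiguity here.

### Stage 2: the instrumented flower

`simulate_stage2()` generates one trial's three channels on a common clock
starting at 0 s:

* **accelerometer**, 1 kHz, three axes, raw ADC counts with a known
  calibration (offsets ~500 counts, sensitivities ~100 counts/g) and a 2 s
  quiescent pre-roll as the calibration window. Noise is 0.3 g RMS about
  the 1 g gravity baseline, so quiescent total acceleration never
  approaches the 3 g hit threshold (an 11-sigma excursion would be
  needed). Each contact injects
  `amp * exp(-dt/tau) * cos(2*pi*f*dt)` along a random horizontal
  direction: `f = 18.4` Hz is the support wire's natural frequency, and the
  peak sits at the contact time. The decay constant `tau = 25` ms is chosen
  so the oscillation's half-period rebound (27 ms) falls inside the
  detector's 50 ms separation window — one physical contact can never be
  double-counted, which is what makes exact count recovery a fair
  requirement. Contact amplitudes are uniform on 4–8 g; amplitudes at or
  below 3 g are rejected at configuration because the injected truth would
  be undetectable in principle. Contacts are placed with the minimum
  separation built into the sampling (uniform gaps over the residual visit
  span), so the configured per-visit Poisson mean is also the realized
  mean.
* **infrared beam**, 1 kHz binary; state 1 means the beam is received
  (nectar absent). Emptying raises it; the refiller lowers it ~2 s later.
  Occasional 1–3 ms glitches exercise the analysis-side debounce.
* **trajectory / video**, 5 fps. During visits the moth wanders inside the
  125 mm radius (an autoregressive walk clipped at 115 mm); between visits
  it is out of frame. `render_frames()` paints a bright elliptical Gaussian
  blob at the true position over a static scene (smooth illumination
  gradient, dark flower mark), plus per-frame sensor noise and small
  distractor specks strictly below the blob-detection area threshold.

Visit durations are log-normal (median 8 s by default; positive and
right-skewed, as real visit durations are; no published distribution
exists to copy). Inter-visit gaps are exponential, truncated between 1 s
(so distinct visits stay separated by several frames) and 230 s (below the
idle timeout). A trial is truncated at the 25th emptying — the refiller's
capacity — and otherwise ends by the 240 s idle rule; the recorded
channels stop a few seconds after the last event because a four-minute
idle tail carries no information, while the nominal termination time is
reported in the truth record.

## The analysis chain

### Vision

`locate_moth()` follows the classic static-camera recipe: absolute
difference against a moth-free reference frame, threshold, connected
components, centroid of the largest component. The threshold defaults to
Otsu's method on the difference image, floored at 10/255 so noise-only
frames cannot promote a spurious component; the classic recipe specifies
no threshold, so the floor is our choice. Components below
`min_area_px = 30` are ignored (sensor specks are far smaller than a moth
blob). `track()` converts pixel centroids to mm relative to the flower
center; coordinates are image-plane mm from a top-down camera with no
perspective correction.

`segment_visits()` marks frames with the centroid inside 125 mm — the span
of a hawkmoth body plus extended proboscis — and takes maximal runs as
visits, merging out-of-radius gaps of at most `gap_frames` (default 1
frame, 0.2 s) to absorb single-frame dropouts. Whether brief exits were
merged in the original analysis is unstated, hence the explicit knob.
Visit intervals are half-open `[start, end)`; frame indices are 0-based;
`duration = n_frames / fps`.

### Signals

A single static window cannot identify a six-parameter affine calibration,
so `calibrate_accel()` supports the two identifiable modes: known per-axis
sensitivities (datasheet counts/g) with offsets estimated from a z-up
static window, or known zero-g offsets with a shared scale set so the
static magnitude is 1 g. Either way the calibrated static-window magnitude
is 1 g, and windows with more than 0.5 g of per-axis SD are refused.

`detect_hits()` thresholds the total acceleration
`sqrt(ax^2 + ay^2 + az^2)` at 3 g — including the static 1 g gravity
component, as the >3 g rule is conventionally applied to the full
magnitude; a gravity-subtracted variant is available by flag — and accepts
local maxima at least 50 ms apart (about one ring-down period of the
18.4 Hz wire; the separation rule is this package's own addition, needed
to avoid double-counting). Hits are attributed to the visit interval containing
them; hits outside every visit are reported separately, never silently
dropped. Sustained sub-threshold contact does not count: only >3 g peaks
proxy contacts with the reproductive parts.

`beam_events()` debounces state runs shorter than 20 ms (mechanical
switching noise at 1 kHz sampling) and labels transitions EMPTIED/REFILLED
(stage 2) or PROBE (stage 1, where any beam break marks a nectary probe).

### Fitness metrics

* **Visitation frequency** (plant fitness, stage 1): mean visits per morph
  per trial, SEM across trials.
* **Foraging success rate** (pollinator fitness, stage 1): per trial,
  emptied/visits per morph; morphs with zero visits in a trial are excluded
  from that trial's contribution (never coded as zero), and the mean and
  SEM are taken across contributing trials. Whether the original analysis
  averaged per-trial rates or pooled counts before testing is unstated;
  per-trial is the default and a pooled alternative is provided. The
  exclusion changes only `n` bookkeeping and can never inject NaN into the
  downstream ANOVA, which drops missing cells listwise.
* **Energy-gain rate** (pollinator fitness, stage 2): nectar acquisition is
  all-or-none — a feeding visit takes the full reservoir, 20 uL of 20% w/v
  sucrose = 0.004 g = 64.8 J at 16.2 kJ/g (% w/v means grams per 100 mL) —
  divided by the visit's time within the 125 mm radius. Metabolic
  expenditure is 2–3% of acquired energy and ignored by default
  (`expenditure_frac` turns it on).
* **Hits per visit** (plant fitness, stage 2): accelerometer hits in the
  visit. Stage-2 means and SEMs are across *visits* (the published
  convention for these panels), stage-1 across *trials*.

### Statistics

The stage-1 two-way ANOVA (curvature x diameter) uses Type II sums of
squares by default because the zero-visit exclusions leave the design
unbalanced; on balanced designs Types I/II/III agree, which the tests
verify. A constant response returns F = 0, p = 1 rather than 0/0. The sex
comparison of proboscis length is a pooled-variance Student t computed
from summary statistics (`df = n1 + n2 - 2`); with the published summaries
(82.19 ± 3.92 mm SD, n = 27 males; 82.77 ± 2.55, n = 31 females) the pooled
form gives |t| = 0.676 against the printed 0.67, whereas Welch gives
0.657 — hence pooled. The size-weighted pooled mean is 82.5 mm.
Fitness-proboscis relationships are ordinary least squares with the overall
F-test; `simulate_moth_profiles()` generates profiles with opposing true
slopes (pollinator fitness rising, plant fitness falling with proboscis
length) for end-to-end exercise of the regression layer.

## The end-to-end pipeline

`run_pipeline()` composes everything for the stage-2 design: four
curvatures (`-Inf, -3, -1, 1`) at a 3 mm nectary diameter (`L` 30 mm, `R`
23.5 mm), 15 moths per curvature, 5 visits per trial by default. Per-trial
sub-seeds are drawn once from the root seed, so results are reproducible
and independent of execution order; rerunning with the same seed gives
byte-identical output tables. Generator conditions per curvature — feeding
probabilities (0.885 trumpet, 0.65 gentle trumpet, 0.325 bowl, 0.24 flat)
and contact intensities (18–28.7 hits/visit, highest for the flat disc) —
encode the published fitness surfaces: with the log-normal durations
(median 9.6 s) the implied energy-gain means are about 6.4, 4.7, 2.3 and
1.7 J/s/visit. Frames are rendered at 320 x 240 px and 1.25 mm/px in the
pipeline (the stand-alone generator defaults to a webcam-like 640 x 480 at
0.8 mm/px); the smaller camera keeps the 125 mm radius inside the field of
view and a full 60-trial run under five minutes on one CPU. Each stage
failure is re-raised naming the stage and trial. `analyze_bundle_dir()`
runs the identical chain from a recorded directory layout (CSV channels,
PNG frames, JSON sidecars).

## Known limitations

* The renderer draws a single elliptical blob: no wing articulation,
  occlusion, motion blur, or lighting flicker, and only one animal. The
  tracking guarantees proven here (sub-pixel centroids, exact visit
  counts) are therefore upper bounds on real-footage performance.
* All-or-none energy at low feeding probability makes per-visit energy
  rates strongly bimodal; at 75 visits per morph their SEMs are a few
  tenths of a J/s, so small-sample means wander accordingly. The live
  experiments' printed means are not reproducible at desk scale and are
  not asserted anywhere; the package asserts parameter recovery instead.
* The accelerometer model treats contacts as isolated ring-downs on a
  quiescent baseline; overlapping contacts closer than the wire's
  ring-down are not modelled (the generator enforces the separation).
* Trajectories, tracking and the presence radius are 2-D top-down,
  matching the overhead-camera design; flight height is not represented.
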