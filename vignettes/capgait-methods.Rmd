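---
title: "capgait: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capgait: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(capgait)
```

This vignette documents the analysis chain implemented by **capgait**, the
parameters it exposes, and the numerical and problem-size choices made in
the package's own validation runs. Code chunks are illustrative and not
evaluated when the vignette is built.

## 1. The sensor floor

The floor is a grid of square capacitive modules. Each module contains
eight triangular sensor fields, formed by cutting the square along its two
diagonals and its two edge midlines. Approximating each field by a right
triangle, the eight field centroids lie at all sign combinations of
$(\pm 2h/3, \pm h/3)$ and $(\pm h/3, \pm 2h/3)$ around the module centre,
with $h$ half the edge length. The package fixes the slot order $j = 1..8$
as: quadrants counter-clockwise from $(+x, +y)$, x-major triangle before
y-major within each quadrant. Any fixed order works — downstream learning
only needs a stable association between slot and position — but it must
never change between recording and analysis.

Three module sizes are relevant: 1 m × 0.5 m (16 fields/m²),
0.5 m × 0.5 m (32 fields/m²), and the gait-resolution 0.38 m × 0.38 m
module (≈ 55 fields/m², field area ≈ 0.018 m²). All package experiments
use the 0.38 m module.

```{r geometry}
fieldsPerSquareMeter(0.38, 0.38)   # ~55.4
fieldArea(0.38)                    # ~0.01805 m^2
lay <- makeFloorGrid(4, 18, 0.38)  # a 1.52 m x 6.84 m corridor
```

## 2. Event-based state reconstruction

The floor samples capacitances at 10 Hz but only *emits* a message for a
module when at least one of its eight fields changed beyond an emission
threshold since the module's last report; the message then carries all
eight current values. The floor-wide snapshot at any time — the
`SensorState` — is the fold of all messages received so far, starting from
an all-zero state (`initState()`, `applyMessage()`). `replayMessages()`
folds a time-ordered stream into a `StateSeries` with one state per
message; unsorted streams are an error, never silently re-sorted, and a
message older than its module's last update is rejected. Replaying an
emitted stream reconstructs every field's sampled value to within the
emission threshold at every tick — this round-trip bound is verified in the
test suite.

## 3. Walker-local transformation

Gait is invariant under translation and rotation of the floor, so each
state is moved into the walker's frame before learning:

1. **Sparsify** (`sparsify()`): keep fields with capacitance strictly above
   `cThreshold = 0.03` (3 % of the measuring range), suppressing baseline
   fluctuations.
2. **Track** (`trackedPosition()`): the capacitance-weighted centroid of
   the active fields. Valid for a single walker; states with no active
   field carry the previous position forward.
3. **Orient** (`walkingAngle()`): one signed angle per walk, from the first
   to the last tracked position, such that rotating by it maps the walking
   direction onto $(0, 1)$.
4. **Transform and cut** (`toLocal()`): translate to the tracked position,
   rotate by the walking angle, drop fields at distance ≥ `radius` from the
   walker.
5. **Resample** (`makeGrid()`, `resampleToGrid()`): deposit each local
   activation on its nearest point of a fixed lattice (spacing `spacing`,
   strictly inside `radius`); colliding deposits keep the maximum; exact
   ties go to the lower x, then lower y point. The lattice is unrolled in a
   fixed meander order (rows from most negative y upward, alternating x
   direction) so every network input index always means the same relative
   position.

`preprocessWalk()` runs the chain over a walk's `StateSeries` and returns
one activation vector per state. Two properties pin the implementation
down and are enforced in tests: the output is invariant under rigid
motions of the floor frame, and a sufficiently fine lattice conserves
every in-radius activation value exactly.

## 4. Dataset construction

Recordings are out-and-back walks. `segmentWalks()` splits each recording
at the turning point (the extremum of displacement along the dominant axis
of the tracked trajectory) and removes all states whose tracked position
lies within `trimRadius = 0.5` m of the turn, where gait is not steady.
`buildWindowSet()` slides a 30-step window with stride 1 over each walk's
vector series (a walk with $n$ vectors yields $n - 29$ windows; windows
never cross walks).

`makeSplits()` builds the two leave-one-out designs without leakage:

* **idiosyncratic** — all walks of one participant; each fold tests one
  walk, validates on the next walk in a fixed rotation, trains on the rest;
* **generalised** — each fold tests all walks of one participant,
  validates on the next participant in a fixed rotation, trains on the
  rest. No participant ever appears in two sets of the same fold.

## 5. Network and training

The model (`networkConfig()`, `buildNetwork()`, `trainNetwork()`) is an
LSTM layer of output size 20 (only the final-step output is forwarded),
four dense ReLU layers of 20 units, and a head of two softmax units
(classification, binary cross-entropy) or one ReLU unit (regression, mean
squared error). Training uses Adam (learning rate $10^{-3}$) with early
stopping on the validation loss: any strict improvement resets the
patience counter (default patience 12, max 60 epochs) and the best-epoch
weights are returned. The implementation is in compiled code
(RcppArmadillo) with exact backpropagation through time; gradients are
verified against central finite differences in the test suite, and
training is bit-reproducible given a seed.

Two numerical choices matter in practice:

* **Regression target scaling.** Heel-rise counts are in the tens, while
  Adam's per-parameter step is bounded near the learning rate, so raw
  counts are unreachable within a scaled-down epoch budget. `runExperiment()`
  therefore trains the regression head on targets divided by the
  training-set mean and rescales predictions afterwards; with the output
  bias initialised to 1, the network starts at the training mean.
* **Pooled correlation on normalised predictions.** In
  leave-one-participant-out regression, rescaling each fold by its own
  training mean injects a leave-one-out anti-correlation into pooled
  per-participant correlations (a high-count participant is missing from
  exactly their own fold's scale). Correlation is scale-free, so the pooled
  Pearson correlation is computed on the fold-normalised predictions;
  RMSE uses the rescaled ones.

Metrics (`evaluateClassification()`, `evaluateRegression()`) report ratios
with zero denominators as `NA`, never silently as 0, and the Pearson
correlation as `NA` when either side is constant.

## 6. The synthetic simulator

No public recordings of this kind of floor are available, so the package
ships a generative simulator whose purpose is to exercise the analysis
chain end to end, not to be biomechanically accurate.

**What it emulates.** Straight ~6 m out-and-back walks over the modular
floor; alternating left/right footfalls with configurable step length,
width, timing variability, lateral sway, double support and stance
asymmetry (`gaitParams()`); an elliptical foot whose capacitance
contribution to a field is proportional to the covered area fraction
(`footprintToCapacitance()`, deterministic sub-sampling); gradual
loading/unloading of the foot over a `ramp` of 0.2 s, emulating heel-to-toe
roll-over rather than an instantaneous on/off; 10 Hz sampling; additive
Gaussian sensor noise; and change-triggered per-module message emission
(`emitMessages()`). Walking modes are multiplicative/additive shifts of
the baseline parameters (`modeLibrary()`): the default `closed_eyes`
perturbation slows walking and doubles spatial/temporal variability; the
`"strong"` library triples those variability factors for clearly separated
synthetic conditions; the `"none"` library zeroes every perturbation and is
the null condition in which all modes are statistically identical.

**Simulator parameter defaults** (all configurable):

| parameter | default | rationale |
|---|---|---|
| `speed` | 1.35 m/s | relaxed adult walking speed |
| `stepLength` | 0.70 m | typical adult step |
| `stepWidth` | 0.12 m | lateral separation of footfall lines |
| `doubleSupport` | 0.2 | fraction of the step both feet are grounded |
| `stepTimeCV` | 0.03 | healthy step-timing variability |
| `sway` | 0.015 m | lateral footfall noise |
| `sampleRate` | 10 Hz | floor sampling rate |
| `emissionThreshold` | 0.02 | below the 0.03 analysis threshold, so a footfall can never be silently invisible to the tracker |
| `gain` | 0.9 | capacitance of a fully covered field |
| `footLength`, `footWidth` | 0.26 m, 0.10 m | shoe-sized ellipse |
| `ramp` | 0.2 s | roll-over loading time |
| `noiseSD` | 0.005 | see below |
| `pathLength` | 6 m | straight-walk length |

The sensor-noise default deserves a note: with the 0.02 emission
threshold, a noise SD of 0.01 would make baseline noise alone trigger a
message from roughly 30 % of all modules at every tick
($P(|N(0,0.01)| > 0.02) \approx 4.5\,\%$ per field, eight fields per
module), drowning the event-based design in noise traffic. The default of
0.005 keeps noise-triggered messages negligible while still perturbing
every reported value.

**Heel-rise coupling.** `generateCohort()` draws a latent strength per
participant; heel-rise counts are a bounded linear-plus-noise function of
it, and with `uhrCoupling = 1` the same latent shifts baseline walking
speed (±8 % per SD) and step length (±5 % per SD). With `uhrCoupling = 0`
counts and gait are independent — the null for the regression sanity
check.

**What it does not emulate.** Real capacitance electrodynamics, foot
shape, weight transfer within the sole, multi-person scenes, floor
occlusions or cut modules, sensor drift, radio loss or message reordering,
or clinically calibrated effect sizes — the mode perturbations are
qualitative knobs, not measured effects.

## 7. Validation problem sizes (scaled down)

The package's acceptance runs — `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` — use a desk-scale configuration chosen for a
single-CPU budget; these are the package's own choices:

* floor: 4 × 18 modules of 0.38 m (a 1.52 m × 6.84 m corridor);
* receptive-field grid: spacing 0.25 m, radius 1.0 m (45 grid points)
  instead of a finer production grid such as 0.10 m;
* up to 60 evenly spaced windows per walk instead of the full stride-1 set;
* training: max 25 epochs, patience 6, batch 64 instead of the default
  60/12/32 (early stopping on a single rotating validation participant is
  noisy, so the ratio of patience to epochs is kept at the default's);
* cohorts: 12 participants × 2 modes × 5 repetitions × 2 directions,
  results averaged over 3 training seeds, for both the mode-recovery and
  the heel-rise designs.

## 8. Limitations

* The tracker assumes exactly one walker; overlapping walkers merge into
  one centroid.
* The walking angle is constant per walk; curved paths need per-state
  orientation estimation.
* Synthetic results do not transfer to clinical claims; the simulator
  validates the pipeline's mechanics, not its diagnostic value.
* With 12-participant cohorts, pooled per-participant correlations carry
  substantial sampling noise even after seed averaging; treat the
  regression sanity check as a smoke test, not an effect-size estimate.
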