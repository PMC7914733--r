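# capgait

Gait analysis for event-based capacitive sensor floors.

A capacitive sensor floor is a grid of square modules laid under the floor
covering, each module carrying eight triangular electrode fields whose
capacitance rises when a body part is above them. The floor samples at
10 Hz but transmits *events*: a module reports its eight values only when
at least one of them changed beyond a threshold since its last report.
Walking across such a floor leaves a stream of messages from which the
walker's footfalls, trajectory, and gait dynamics can be reconstructed —
without cameras or body-worn sensors, which makes the modality attractive
for long-term, unobtrusive gait monitoring in clinical and home settings.

**capgait** implements the full analysis chain:

1. **State reconstruction** — fold the message stream into per-event
   snapshots of all field capacitances (`replayMessages()`), with strict
   ordering checks and a per-field footfall map (`footfallMap()`).
2. **Walker-local transform** — threshold the state, track the walker by
   capacitance-weighted centroid, rotate/translate activations into the
   walker's frame (walking direction = +y), and resample them onto a fixed
   receptive-field lattice in a fixed unroll order (`preprocessWalk()`).
   The result is one activation vector per event, invariant under rigid
   motions of the floor.
3. **Dataset construction** — segment out-and-back recordings at the
   turning point with a 0.5 m trim, slide 30-step windows with stride 1,
   and build leakage-free leave-one-walk-out (idiosyncratic) and
   leave-one-participant-out (generalised) cross-validation designs
   (`segmentWalks()`, `makeSplits()`).
4. **Sequence model** — an LSTM(20) → 4 × dense(20, ReLU) network with a
   softmax head for binary walking-mode classification or a ReLU head for
   heel-rise-count regression, trained with Adam and early stopping.
   Implemented from scratch in RcppArmadillo with finite-difference-verified
   gradients and bit-reproducible training (`runExperiment()`).
5. **Synthetic simulator** — no public recordings of such floors exist, so
   the package generates them: parametric footfall sequences, elliptical
   foot-to-field area coverage, stance loading ramps, 10 Hz sampling with
   change-triggered emission, and walking-mode perturbation libraries
   (`simulateRecording()`, `generateCohort()`).

The pipeline also runs from the command line via YAML-configured stages
(`runSimulate()` → `runPreprocess()` → `runTrainEval()`; see
`inst/scripts/capgait-pipeline.R`).

## Worked example

```r
library(capgait)

## a 1.52 m x 6.84 m corridor of gait-resolution modules
floor <- makeFloorGrid(4, 18, edge = 0.38)
floor
#> FloorLayout with 72 modules / 576 triangular fields
#>   module edge(s): 0.38 m
#>   extent: x [0.00, 1.52] m, y [0.00, 6.84] m

## simulate one out-and-back recording of a relaxed walker
set.seed(1)
rec <- simulateRecording(gaitParams(), floor, simConfig())
nrow(rec$messages)
#> [1] 152

## replay the event stream into a state series
series <- replayMessages(floor, rec$messages)
series
#> StateSeries: 152 states over 576 fields; t in [0.80, 10.80] s

## where did feet touch the floor?
map <- footfallMap(series)
summary(map$max_c[map$max_c > 0])
#>     Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> 0.000231 0.005843 0.007718 0.089118 0.089353 0.622329

## split at the turning point and preprocess the outbound walk
walks <- segmentWalks(series)
length(walks)
#> [1] 2
mat <- preprocessWalk(walks[[1]], spacing = 0.25, radius = 1.0)
dim(mat)
#> [1] 64 45
attr(mat, "theta")   # outbound pass runs along +y, so theta ~ 0
#> [1] -0.002152505

## 30-step windows for the network
length(windowStarts(nrow(mat), 30))
#> [1] 35
```

From here, `generateCohort()` builds a multi-participant study,
`cohortToWalks()` turns it into labelled walk matrices, and
`runExperiment("gen_mode", ...)` or `runExperiment("gen_uhr", ...)` trains
and evaluates the cross-validated designs.

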