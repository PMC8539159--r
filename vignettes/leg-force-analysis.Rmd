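---
title: "From footrest forces to velocity models: the kayakforce pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From footrest forces to velocity models: the kayakforce pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kayakforce)
library(ggplot2)
```

## The measurement problem

In sprint kayaking the paddle force must be reacted somewhere inside the
boat, and a large part of that reaction passes through the legs into the
footrest: the paddler pushes with the stroke-side leg on every stroke. An
instrumented footrest with one load cell per side records two force
channels — left and right leg push, in newtons, typically sampled at
1000 Hz — while a GPS unit logs boat velocity in km/h. `kayakforce` turns
such recordings into the five leg-force characteristics used to describe a
bout (stroke rate, mean force, peak force, impulse per stroke cycle,
impulse over 10 s), the cycle-normalized ensemble force profile, and linear
models linking those characteristics to paddling velocity.

Because footrest recordings of competitive paddlers are not freely
available, the package also contains a synthetic generator whose output has
closed-form ground truth. Every stage of the pipeline is tested against
that truth.

## Signal model of the synthetic generator

A session is modelled as two alternating half-sine pulse trains on a
constant baseline:

* each push is a half-sine of amplitude $P$ (above baseline) and width
  $w$; its impulse above baseline is exactly $2 P w / \pi$;
* stroke rate counts both sides, so at $SR$ strokes/min one side pushes
  every $60/SR$ s and a full cycle (left push + right push) lasts
  $2 \cdot 60/SR$ s. At 125 strokes/min the cycle is 0.96 s, the regime of
  a maximal-effort bout;
* the right train is offset from the left by half a cycle, so in a
  left-anchored profile the right peak falls near 50% of the cycle;
* the baseline default is 20 N. Published profiles show non-zero troughs —
  the feet are strapped to the footrest, keeping the load cells slightly
  loaded — but no trough level is reported anywhere we know of, so this is
  a modelling choice, not a literature value;
* measurement noise is additive i.i.d. Gaussian. Real load-cell noise is
  coloured and the paddler adds low-frequency variability; the 20 Hz
  low-pass stage removes most of both, and for testing purposes the
  i.i.d. model is the simplest signal that exercises it.

The default session (20 s at 125 strokes/min, per-side peaks near 400 N,
push duty 0.75) reproduces the published maximal-effort ranges: peak force
around 330–400 N and per-cycle impulse in the mid-500 N·s. What the
generator deliberately does *not* emulate: stroke-to-stroke variability in
timing and amplitude, left/right technique asymmetries beyond independent
peak amplitudes, leg-*pull* (negative) forces through the foot strap, and
the acceleration transient of a standing start. Tests passing on synthetic
sessions therefore validate the numerics of the pipeline, not its
robustness to every pathology of field data.

```{r profile, fig.width = 6, fig.height = 3.5}
sess <- generate_force_session(session_spec(duration = 20, noise_sd = 15,
                                            seed = 1))
rec <- extract_features(sess$trace, generate_velocity_trace(20, 19.7))
autoplot(attr(rec, "profile"))
```

## Preprocessing decisions

**Filter.** A fourth-order low-pass Butterworth filter with a 20 Hz cutoff
is the standard treatment for footrest/force-plate signals; leg-push events
live well below 10 Hz. We apply it forward and backward (zero-phase), so
peak timing — which anchors segmentation — is not shifted; the price is
that the effective gain is the squared magnitude response,
$|H(f)|^2 = 1/(1 + (f/20)^8)$ for this design. Whether published analyses
used zero-phase filtering is usually unstated; downstream tolerances absorb
the difference. Both channel ends are odd-reflection padded by six cutoff
periods before filtering because a plain forward-backward pass initialises
the filter state at zero and would otherwise corrupt several hundred edge
samples.

**Peak detection.** Peak criteria are rarely reported in field studies, so
the defaults here are chosen to be scale-free: a minimum separation of
0.15 s between same-side peaks (a 200 strokes/min ceiling, comfortably
above any sprint stroke rate) and a minimum topographic prominence of 25%
of the channel's 95th force percentile, which rejects filtered noise
ripples without assuming a stroke rate or absolute force level. Both are
configurable. Prominence is computed with the standard walk-to-higher-ground
rule; ties on flat tops take the plateau centre; when two candidates are
closer than the minimum separation the taller one wins.

**Segmentation and normalization.** Cycles run from one left-side peak to
the next, so 0% (and 100%) of the cycle is a left peak by construction.
Each cycle is linearly interpolated onto a fixed 101-point percent grid
(0, 1, …, 100 — the convention in cycle-normalized biomechanics) and the
profile is the pointwise mean ± SD over the averaged cycles.

**Which 15 cycles.** Ensemble profiles conventionally average 15 cycles,
but *which* 15 is a genuine choice: a bout with a rolling start still
accelerates early on. The default takes the **last** 15 complete cycles —
the steadiest regime — with `selection = "first"` available. Published
descriptive values that included the acceleration phase will therefore sit
slightly below what this default produces on an otherwise identical
recording.

**The 10-s window.** The impulse-over-10-s characteristic (and by default
stroke rate, mean force and velocity) is computed over the last 10 s of the
bout, consistent with the cycle selection; `first-10s` and explicit windows
are available. A 10-s window generally contains a non-integer number of
cycles, so window statistics differ from per-cycle truths by up to half a
cycle's worth of signal — about 0.4% at 125 strokes/min — which is why the
feature-recovery tests use 0.5% tolerances rather than exact equality.

## Feature conventions

* **Mean force** is the time-average of $(L + R)/2$ over the analysis
  window, troughs included. Under this convention
  $2 \times \text{mean force} \times \text{cycle duration} \approx
  \text{impulse per cycle}$, which is consistent with published
  maximal-effort values ($2 \times 289.5 \times 0.96 \approx 556 \approx
  554.8$). No single convention reproduces every published bout row, and
  the per-bout windowing behind such tables is not recoverable, so the
  package documents its convention rather than forcing agreement.
* **Peak force** is the mean over analysed cycles of each cycle's per-side
  maxima, both sides pooled.
* **Impulses** use the trapezoid rule on each channel and sum left + right;
  the per-cycle impulse is averaged over the analysed cycles so each bout
  yields one value.
* **Stroke rate** counts peaks on *both* sides in the window
  ($\times 60 /$ duration): one cycle is two strokes. A 10-s window makes
  the counting granularity 6 strokes/min, another reason recovery
  tolerances are ±2 strokes/min rather than exact.

## Statistical models

**Prediction.** `fit_ols()` wraps ordinary least squares and reports
normal-theory CIs, $R^2$, adjusted $R^2$, $F$, residuals and Cook's
distances, plus a Gaussian-likelihood BIC, $n \ln(\mathrm{RSS}/n) +
p \ln n$ with $p$ counting intercept and slopes. Any monotone-equivalent
BIC variant selects the same subset; a test verifies rank agreement with
`stats::BIC`. `select_model_bic()` searches all non-empty predictor subsets
exhaustively (capped at 15 candidates), breaking BIC ties toward fewer
predictors and then lexicographically. A constant response gets $R^2 = 0$
by convention. The package ships a fixed published coefficient set for
maximal velocity,

$$V_{max} = 0.0045\,F_{peak} + 0.0017\,J_{10s} + 0.05\,SR + 7.62,$$

as `vmax_published()`; `predict_vmax()` evaluates it (or any fitted model)
on a feature table.

**Cross-validation.** The phrase "leave-one-out five-fold cross-validation"
occasionally seen in applied work is contradictory; following its usual
elaboration this package implements 5-fold CV over seeded random folds of
equal size (±1), reporting the SD of held-out prediction errors, and offers
a true leave-one-out mode behind `method = "loo"`. On cohorts generated
with known residual SD the CV error SD estimates that SD, which is the
recovery property the tests assert.

**Explanatory models.** `explanatory_fit()` regresses a force
characteristic on velocity. "Mutually adjusted" is read as adjustment for
paddler group (age/sex level) entered as a categorical covariate — the
default — because group is the only level variable available in a feature
table; an alternative reading, adjusting jointly for the other force
characteristics, is available via `joint = TRUE`. No claim is made about
which reading any particular publication used.

**Bootstrap.** `bootstrap_ci()` does case resampling with percentile
intervals (1000 replications by default): it is the sensitivity check on
normal-theory CIs under possibly non-normal residuals, so a residual
bootstrap (which assumes the model) would defeat its purpose. Rank-deficient
resamples are redrawn, at most ten times.

**Multiple testing.** None is applied; p-values are reported raw, matching
standard practice in this literature for single-model analyses.

## Numerical choices and degenerate inputs

* Readers validate and refuse: missing columns, non-numeric cells,
  non-monotone time stamps and non-uniform sampling are errors, never
  silently repaired.
* A trace with no detectable strokes, or fewer than two left peaks, raises
  an insufficient-data error rather than returning zeros.
* Fewer cycles than requested for averaging produces a warning and a
  flagged profile, not a failure.
* Zero-variance variables in the correlation matrix are flagged and
  reported as `NA`, not as $r = 0$.
* All stochastic functions (generators, fold assignment, bootstrap) take
  explicit seeds; with equal seeds their output is bit-identical.

## Problem sizes in the test suite

The packaged tests run the full pipeline on 12–20 s sessions at 1000 Hz,
parameter-recovery fits on cohorts of $n = 10{,}000$, and the
calibration-style properties (CI coverage, BIC selection consistency, peak
count under noise) on 100 seeded replicates at moderate sizes
($n = 50$–200); these sizes give Monte-Carlo error comfortably below the
asserted tolerances while the whole suite completes in well under a minute
on a single core.

## Known limitations

The three bouts per paddler of a typical protocol form a correlated design;
like the analyses it mirrors, the package fits ordinary least squares and
exposes per-paddler residual grouping through `model_diagnostics()` rather
than fitting a mixed model. Leg-pull forces, seat and paddle forces, and
left/right asymmetry indices are out of scope. The synthetic cohort draws
predictors independently, so it does not reproduce the multicollinearity
structure of real feature tables (impulse per cycle and mean force are
strongly co-correlated in practice); correlation-matrix behaviour under
collinearity is exercised directly with constructed bivariate draws
instead.
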