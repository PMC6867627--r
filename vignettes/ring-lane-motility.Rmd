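---
title: "Run-and-rest motility analysis on ring micro-lanes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run-and-rest motility analysis on ring micro-lanes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringlane)
```

## The assay and the model

Single cells seeded on ring-shaped adhesive micro-lanes (fibronectin rings,
default radius 75 µm, surroundings passivated) migrate effectively in one
dimension. Their position is fully described by the unwrapped angle
$\varphi(t)$ on the ring; the arc-length coordinate is $r\varphi$ and the
tangential velocity is $v_\mathrm{tang} = r\,\dot\varphi$.

Confined cells alternate between two modes of motion:

* **run states** — persistent, ballistic translocation in one direction, and
* **rest states** — no net motion, only random wiggling around a fixed
  position.

`ringlane` segments each trajectory into these two states and summarizes a
population by a five-parameter motility fingerprint:

| parameter | meaning | uncertainty reported |
|---|---|---|
| $v_\mathrm{run}$ | mean of $|v_\mathrm{tang}|$ over run-state time points | standard error over cells |
| $\tau_\mathrm{run}$ | exponential lifetime of run states | 99% CI (bootstrap over cells) |
| $\tau_\mathrm{rest}$ | exponential lifetime of rest states | 99% CI (bootstrap over cells) |
| $P_\mathrm{run}$ | fraction of observation time spent running | standard error over cells |
| $q$ | persistence: positional range / path length | standard error over cells |

plus the *immobile fraction*: the share of cells that never leave the rest
state for the whole observation.

The state lifetimes are estimated from the dwell-time survival function
$S(t) = P(T > t)$, fitted on $\log S(t) = -t/\tau + c$ over $t \in [2, 16]$ h.
The lower cutoff excludes the short-time regime where empirical dwell
distributions deviate from an exponential; the intercept $c$ absorbs the
resulting offset, so the estimate of $\tau$ depends only on the slope of the
exponential tail. To keep the finite observation window from biasing the
sample, only states that *start* at least 16 h before the end of their track
enter the dwell sample; states still ongoing at track end are kept with
their observed duration (which then necessarily exceeds the 16 h fitting
horizon, leaving $S(t)$ on $[0,16]$ h unaffected).

## State classification

How exactly run and rest states are detected is the one methodological gap a
reader of the assay literature faces: published figures show the decomposed
trajectories but rarely the rule. `ringlane` uses a deliberately simple,
fully deterministic classifier whose every knob is exposed in
`segmentation_params()`:

1. compute the per-step velocity $r\,\Delta\varphi/\Delta t$ between
   consecutive frames (`step_velocity()`);
2. label a step RUN when its magnitude reaches `v_threshold`
   (default 6 µm/h), REST otherwise; a sign change of the velocity ends a
   run even without an intervening rest (`reversal_breaks_run`);
3. absorb segments shorter than `min_state_duration` into their longer
   neighbor, shortest first (ties go to the preceding segment), until all
   segments meet the minimum.

Two design choices deserve explanation, because the obvious alternatives
fail quantitatively against simulated ground truth:

* **Steps, not smoothed central differences.** A centered difference (and
  any symmetric smoothing window) mixes motion from both sides of a frame,
  so a rest lasting one or two frames between same-direction runs never
  shows a slow velocity sample and the two runs fuse; at realistic
  lifetimes this chaining visibly inflates $\hat\tau_\mathrm{run}$.
  Classifying the raw inter-frame steps resolves every rest at least
  one frame long. The smoothed central-difference series
  (`tangential_velocity()`, window `smooth_window` = 0.5 h) is still used
  to *measure* $v_\mathrm{run}$, where smoothing suppresses noise rather
  than destroying short features. `segment_states()` itself is agnostic and
  segments whichever velocity series it is given.
* **A one-frame minimum duration.** `min_state_duration` defaults to
  10 min, i.e. one frame at the default cadence: every resolvable state
  survives. Raising the minimum to 0.5 h looks like innocent denoising but
  absorbs a substantial share of genuine run states (for
  $\tau_\mathrm{run} = 2$ h, $P(T < 0.5\,\mathrm{h}) = 22\%$) and
  concatenates their neighboring rests, inflating
  $\hat\tau_\mathrm{rest}$ well beyond its sampling error. The default
  threshold of 6 µm/h sits more than 3 standard deviations above
  resting-state apparent speeds and far below typical run speeds, so
  frame-level noise creates almost no spurious states even without a
  duration filter.

The residual resolution limit is honest and documented: states shorter than
one frame (4% of rests at $\Delta t = 10$ min, $\tau_\mathrm{rest} = 4$ h)
are invisible at any threshold, and the resulting state-chaining leaves a
few-percent upward bias on the fitted lifetimes.

## Survival fitting: weights and confidence intervals

$S(t)$ is evaluated on the sampling grid $t = 0, \Delta t, \dots, 16$ h and
fitted by least squares on the log scale. Two numerical choices matter:

* **Inverse-variance weights.** By the delta method,
  $\mathrm{Var}[\log \hat S(t)] \approx (1-S)/(nS)$. An unweighted fit
  gives the handful of survivor-starved grid points in the far tail the
  same weight as the well-populated early points; worse, grid points whose
  empirical $S$ hits zero must be dropped from the log fit, and that
  selective removal of downward fluctuations biases the remaining tail
  upward while inflating the variance of the estimate. `fit_tau()`
  therefore weights each point by $nS/(1-S)$ by default;
  `weighting = "ols"` restores the plain fit. On exact exponential input
  both give $\tau$ to machine precision.
* **Bootstrap over cells for the CI.** The grid points of one empirical
  survival curve are strongly correlated, so the textbook regression
  interval of the slope dramatically understates the replicate-to-replicate
  variability of $\hat\tau$ and its nominal coverage is illusory.
  `fingerprint()` instead reports a percentile bootstrap over
  cells (default `ci_boot = 400` resamples, internally seeded so identical
  input yields identical output), which resamples the natural independence
  unit of the experiment; its 99% interval covers the true lifetime in at
  least 95% of replicate simulations at the validation scale, the
  property the test suite asserts. `fit_tau()` alone still reports the
  propagated slope interval, flagged as `ci_method = "slope_ci"`.

Cells that never leave the rest state are reported in the immobile fraction
and enter $P_\mathrm{run}$ as zeros, but are *excluded* from the dwell-time
sample: their single "rest duration" equals the observation window and
carries no information about rest-state turnover, while adding a constant
offset to the survival tail that a log-linear fit misreads as a longer
lifetime — an effect present even with perfect state labels.

## The trajectory simulator

`simulate_population()` generates the ground truth every stage is validated
against. Its model is intentionally the minimal one consistent with the
two-state description:

* exponential run and rest durations (`tau_run` = 2 h, `tau_rest` = 4 h by
  default) — memoryless states, matching the single-exponential survival
  the analysis fits; the first state is drawn with the stationary
  probability $\tau_\mathrm{run}/(\tau_\mathrm{run}+\tau_\mathrm{rest})$ so
  tracks start in equilibrium and $P_\mathrm{run}$ has no start-of-track
  bias;
* a per-cell run speed drawn from a lognormal (median 30 µm/h, log-sd 0.3),
  reproducing the broad, strictly positive spread of single-cell
  velocities; within a run the per-frame speed jitters by 2 µm/h;
* direction reversals with probability 0.5 at each new run;
* resting-state wiggle of 0.3 µm per frame (apparent speed ≈ 1.8 µm/h at
  the 10-min default cadence, well below the classification threshold);
* an immobile subpopulation (10% by default; 30% in the low-motility
  scenario) that rests for the entire track.

Defaults were fixed once, at values typical for single breast-cancer cells
on 1D lanes, before being used for validation. The two shipped scenarios —
`ctrl_like_params()` (30 µm/h, 4 h/2 h, 10% immobile) and
`induced_like_params()` (20 µm/h, 2 h/6 h, 30% immobile) — are plausible
test conditions for directional comparisons, not measurements of any real
cell line.

What the simulator does *not* emulate: gradual speed changes within a run,
dwell-time distributions with memory (refractory periods), cell divisions
and track fragmentation, lane-escape events, positional measurement noise
during runs, or any 2D structure. Passing the validation suite therefore
demonstrates correctness of the estimators under the stated two-state
model, not robustness to every artifact of real tracking data.

## Numerical choices and degenerate inputs

* Times are hours internally; input tables may declare minutes or frame
  counts. Sampling must be uniform to a relative 1e-6.
* Unwrapping flags a raw angular step of exactly π as ambiguous instead of
  guessing a direction; trajectories with any step ≥ π are rejected.
* Segment durations are exact multiples of Δt, so survival counts
  `duration > t` sit on a knife edge; a 1e-9 h guard makes the comparison
  immune to last-ulp arithmetic noise.
* Ties in short-segment absorption go to the preceding segment;
  equal-length neighbors are the only source of ambiguity and this rule
  makes segmentation fully deterministic.
* A cell whose path length is numerically zero has undefined $q$ and is
  excluded from the population mean with a logged count; a cell with no
  run frames has undefined $v_\mathrm{run}$ and counts toward the immobile
  fraction instead.
* A failed lifetime fit (too few usable grid points, or a non-negative
  log-survival slope) is reported as a missing value with a diagnostic
  message; the remaining parameters are unaffected.
* Feret diameters are measured on foreground-pixel centers of the convex
  hull, plus half a pixel to account for the pixel footprint; the minimum
  Feret search uses a 1° orientation grid. Off-grid orientations can add
  up to $w \sin(0.5°)$ to the minimum spread of very elongated objects.

## Validation scale

The test suite validates parameter recovery at the study scale of 300
cells × 48 h at Δt = 10 min (≈ 1500 dwell states per label), chosen so that
sampling error on $\hat\tau$ is ≈ 5% and systematic biases would be clearly
visible against the 15% recovery tolerance. Interval calibration uses 200
replicate simulations at that scale; the type-I error of the condition
comparison uses 200 replicate pairs of 100-cell conditions, matching the
per-condition n of a typical micro-lane experiment. Condition comparisons
(`compare_fingerprints()`) use Welch t-tests on per-cell values — the
safer default under unequal variances; `pooled_variance = TRUE` restores
the classical Student test — and non-overlap of the 99% lifetime CIs.

## Known limitations

* The classifier is a stand-in: it is deterministic, threshold-based and
  validated against the package's own simulator, not against any published
  reference classifier. A probabilistic (e.g. two-state HMM) segmenter can
  be swapped in: everything downstream consumes only the segment table.
* Lifetime estimates retain a small upward bias (a few percent at default
  conditions, well inside the 15% recovery tolerance the validation suite
  asserts) from sub-frame state chaining and from end-of-track censored
  states; both mechanisms are described above.
* The survival machinery implements exactly the horizon rule plus observed
  durations — it is not a general censoring framework (no Kaplan–Meier,
  no parametric alternatives to the exponential).
* Shape factors assume a single connected mask; segmentation of raw
  fluorescence images into masks is upstream of this package.
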