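---
title: "Quantifying free exploration from movement trajectories"
author: "exploretrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying free exploration from movement trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exploretrace)
```

## The problem

When people freely explore an unfamiliar environment — here, a bounded
virtual arena with landmarks, navigated for three minutes from a fixed
spawn point — their movement log (timestamped ground-plane positions at
roughly 15 Hz) carries far more information than "distance walked".
`exploretrace` turns such logs into a small set of interpretable
behavioral phenotypes and tests how they vary with sex and age.

The pipeline has four stages, each usable on its own:

1. **Measures** — thirteen trajectory-based exploration measures per
   participant.
2. **Variable clustering** — z-scoring, sign alignment, hierarchical
   clustering of the measures on a squared-correlation similarity, knee
   detection, and three compound dimensions: *exploratory activity*,
   *shape of exploration*, *exploratory efficiency*.
3. **Group statistics** — a 2 (sex) x 3 (exploration type) mixed
   repeated-measures ANCOVA with age as covariate, Greenhouse-Geisser
   correction, Bonferroni post-hoc t-tests, age correlations, and a
   BIC-approximated Bayes factor for the absence of a sex-by-age
   interaction.
4. **Simulation** — a correlated-random-walk agent with controllable
   demographic effects, so the full pipeline can be exercised and
   validated without human data.

## The thirteen measures and their estimators

The measures are defined by short operational glosses (total length,
time without movement, area covered, ...); turning each into a concrete
estimator requires choices. The choices here are deliberately
scale-relative so that the measures are comparable across environments
with different world units; every constant below lives in
`metric_config()` and can be overridden.

All metrics operate on a trajectory resampled to a uniform time base
(`dt` = 1/15 s, linear interpolation), because raw logs are only
*approximately* regular and step-sensitive measures (sinuosity,
turnarounds) are biased by timing jitter.

| measure | estimator |
|---|---|
| path length | sum of Euclidean step lengths |
| pausing | total time in maximal intervals with speed below `pause_speed` (default 5% of the participant's median moving speed) lasting at least `pause_min` = 1 s |
| area covered | occupied cells x cell area on a square grid (`cell_size` = 1/20 of the shorter arena edge; half-open cells, so an edge sample belongs to the higher-index cell) |
| roaming entropy | Shannon entropy of the cell occupancy distribution, normalized by `ln(K_total)` so 0 = one cell, 1 = uniform use of the arena |
| landmark visits | distinct landmarks with at least one visit event (entry into `landmark_radius` = 2 cell edges) |
| landmark revisits | surplus visit events beyond the first, summed over landmarks |
| revisiting | mean over occupied cells of (visit runs − 1) |
| turnarounds | events where unwrapped heading change within a `turn_window` = 3 s sliding window reaches pi; the accumulator resets after each event |
| flight turnarounds | direction reversals between consecutive *flights* (segments bounded by pauses and turnaround events; segments shorter than `flight_min_len` = 2 cell edges merged into neighbors) |
| fractal dimension | divider (Richardson) method: ruler walks at 8 geometric scales from twice the median step length to a quarter of the trajectory diameter; D = −slope of ln N(delta) on ln delta, clamped to [1, 2] |
| sinuosity | corrected estimator S = 2 [p (1+c)/(1−c) + b²]^(−1/2) with p the mean step length, c the mean turning-angle cosine, b the CV of step length, pauses removed first |
| area efficiency | area covered / path length |
| landmark efficiency | landmarks visited / path length |

Three of these deserve comment.

**"Turns greater than 180 degrees."** A single inter-step turning angle
can never exceed pi, so the only reading that produces non-trivial
counts is *cumulative* unwrapped turning within a time window. A
perfectly collinear reversal accumulates exactly pi, so the event
threshold is `|turn| >= pi − 1e-8`; without the tolerance, ideal
out-and-back paths — the canonical turnaround — would never count.

**Fractal dimension.** The divider method is the standard tortuosity
estimator for movement paths (box counting is a config alternative in
spirit but not implemented; the divider walk is exact on polylines and
is validated against a straight line, D = 1, and a Koch polyline,
D = ln 4 / ln 3). The ruler walk solves the circle-segment intersection
exactly rather than interpolating chord distances, and counts the
trailing remainder fractionally so N(delta) is smooth in delta.

**Sinuosity.** The corrected estimator is robust to step-length
variability, which matters because speed fluctuates; the naive
path/displacement ratio is confounded with whether the trajectory
happens to close on itself.

Degenerate inputs are flagged, not fudged: a stationary session has
pausing = duration, zero counts, one occupied cell — and *missing*
fractal dimension, sinuosity and efficiencies. Participants with
missing measures are dropped from clustering and statistics with a
logged reason.

## From thirteen measures to three dimensions

Measures are z-scored (n − 1 denominator) and four of them — pausing,
revisiting, landmark revisits, flight turnarounds — are negated so that
higher always means more exploration. Dissimilarity between measures is
`1 − r²` (pairwise-complete Pearson), which makes the clustering blind
to the sign convention; average linkage keeps aggregation heights
monotone and is simple enough to verify against a brute-force
agglomeration in the test suite.

The number of clusters is chosen with a kneedle-style knee detector on
the aggregation-height curve: normalize (merge index, height) to the
unit square, compute the difference curve `y_norm − x_norm`, and take
its maximum (sensitivity 1, no smoothing, first index on numerically
tied maxima). The knee lands on the first *expensive* merge; the
returned k is the number of clusters present just before that merge.
On a flat, structureless curve the convention degenerates to "accept no
merge"; knees at the very last merge are indistinguishable from that
case — a known boundary limitation of knee detection that does not
affect the three-of-thirteen regime this package targets.

Compound scores are per-participant means of the member z-columns. Two
details are decisions rather than forced moves:

* **The cut defaults to k = 3** (the kneedle selection is always
  reported next to it, and `strict = TRUE` errors on disagreement),
  because the downstream statistics are defined for exactly three
  within-subject levels.
* **`run_pipeline()` builds compounds from the reference membership by
  default** (activity: path length, pausing, area covered, roaming
  entropy, landmark visits; shape: fractal dimension, sinuosity;
  efficiency: the remaining six), treating the data-driven clustering
  as validation output. Measure-level correlation structure in any
  single finite sample — simulated or real — need not reproduce the
  reference partition exactly, and the compound definitions should not
  silently change meaning when it does not. `assignment = "fitted"`
  switches to the data-driven partition.

After compounding, a single-pass outlier screen removes participants
whose any compound deviates from its mean by more than 3 SD; the screen
is not iterated, and exclusions are logged with the offending
dimension.

## The statistical model

With scores in long format (one row per participant and exploration
type), the 2 x 3 mixed ANCOVA is computed through orthonormal
within-subject contrasts. Writing the per-participant score triple as a
row of Y, the between-subjects part projects Y on the unit contrast and
regresses it on `[1, sex, age, sex:age]` (sex effect-coded +-1/2, age
grand-mean centered); Type III sums of squares for these single-df
terms are `b_j² / (X'X)^{-1}_{jj}`, tested on N − 4 error df. The
within part projects Y on two orthonormal contrasts and tests each
design term across both contrast columns against the pooled within
error with 2(N − 4) df. Sphericity is handled by Greenhouse-Geisser:
epsilon = tr(S)² / ((k−1) tr(S²)) from the contrast-residual covariance
S, multiplying both within dfs; reported p-values for within effects
are always the corrected ones. Partial eta squared is
SS_effect / (SS_effect + SS_error). The implementation is validated
against `car::Anova(type = 3)` with an identical design in the test
suite, to eight decimals.

Post-hoc sex comparisons are pooled-variance Student t-tests per
exploration type (df = N − 2, matching the between-group design),
Bonferroni-corrected over the three contrasts; age relationships are
Pearson correlations with p from the exact t transform, likewise
Bonferroni-corrected. Calibration checks (type-I error, power) use each
test's raw p at alpha = .05: with m = 3 the Bonferroni-corrected
rejection rate under the null would sit near .017 by construction, and
corrected rejection of a d = 0.3 effect at N = 424 has power well below
the raw-alpha value (about .75 vs .87), so the corrected p is the
inference convention while the raw p is the calibration surface.

The Bayes factor for the *absence* of a sex-by-age interaction compares
the full fixed-effects model (type x sex x age, random participant
intercept, ML fit via `lme4`) with the model from which `sex:age` *and*
`type:sex:age` are removed — dropping a term while keeping its
higher-order relative would violate model hierarchy. BF01 =
exp((BIC_full − BIC_reduced)/2) is the Schwarz approximation; it is
documented as such and no claim is made that it reproduces
default-prior (JZS) Bayes factors, which weight parameters differently.

## What the simulator emulates — and what it does not

`simulate_study()` produces a complete synthetic study: a rectangular
arena (default 100 x 100 world units) with 20 landmarks placed on a
jittered node grid, a panel of 424 participants (218 male / 206 female,
ages drawn from a log-normal with mean about 24 and SD about 17 years,
truncated to 7-77), and one 180-second trajectory per participant at
15 Hz.

The agent is a correlated random walk with six behavioral parameters:
mean speed, pause initiation rate, mean pause duration, heading
diffusion (`turn_sd`, rad per square-root second), steering gain toward
the current goal landmark, and a revisit bias (the probability that the
next goal is an already-visited landmark). Each parameter has a
population base value and a between-subject SD; demographic effects are
additive on that standardized scale, so an effect coefficient of 0.5
means half a population SD between the sexes.

The shipped `demographic` profile makes males faster, less pausing,
more landmark-attracted, more revisit-biased, *and more erratic in
heading* (turn_sd sex coefficient +0.45), while turning noise declines
with age. The heading-noise sex effect is a modeling decision worth
being explicit about: speed and landmark attraction alone do not make
male trajectories more tortuous — faster straight-line progress, if
anything, lowers sinuosity — so an explicit complexity parameter is the
mechanism by which the male-more-complex-shape pattern arises. Age
enters only through turning concentration, so only the shape dimension
carries an age signal. No sex-by-age interaction terms exist in the
generator. Effect sizes were chosen once so the compound-score sex
differences land near Cohen's d of 0.3-0.5.

What the simulator does **not** emulate: path networks that constrain
movement (landmarks sit on a node grid but the agent roams freely),
timing jitter and dropped frames in the logger (timestamps are exactly
regular; the resampler is still exercised by io-level tests), learning
or memory dynamics within the session, and any cognitive realism in how
humans choose where to go. Passing end-to-end tests therefore shows
that the pipeline recovers *planted* structure of the kind described —
not that real human data have that structure.

## Numerical and validation choices

* Determinism: `simulate_study()` seeds a single RNG stream once;
  results are a pure function of the configuration, and identical
  config + seed reproduce feature tables and results JSON bit for bit.
* Validation problem sizes: metric oracles run on 50 random 200-sample
  trajectories (equality to 1e-9, counts exact); cluster recovery on
  100 block-correlated 424 x 13 tables (within-block r = 0.6, between
  0.1) with exact-partition and k = 3 in at least 95; type-I error of
  the sex tests from 2000 null replicates at N = 120 (accepted band
  0.035-0.065); power from 1000 replicates of a planted d = 0.3 effect
  at N = 424 (required > 0.8); qualitative sign reproduction of the
  full pipeline on 100 simulated studies at N = 424 (required in at
  least 90).
* The feature CSV writer prints 15 significant digits so read-back
  equals written values to at least 12 significant digits; missing
  values are empty fields.
* Out-of-bounds samples are clamped into boundary cells with a logged
  warning; the simulator itself reflects at walls so clamping is a
  data-quality signal, not a normal path.

## Limitations

* The measure estimators involve free constants (grid size, radii,
  windows); other implementations with other constants will produce
  numerically different raw measures. The scale-relative defaults make
  ranks and compounds stable, not raw values.
* The BIC Bayes factor is an approximation with a unit-information
  implied prior; treat its magnitude as an order-of-magnitude
  statement.
* The kneedle convention cannot flag a knee at the final merge
  (k = 2 structures) — by design of the normalization, not a bug.
* Compound scores average z-columns without reweighting; a measure
  that is noisy in a given dataset dilutes its dimension.
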