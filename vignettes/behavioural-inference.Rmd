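---
title: "Behavioural inference from multi-sensor logger records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural inference from multi-sensor logger records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diveseg)
```

# The problem

Animal-borne loggers combining a tri-axial accelerometer, a tri-axial
gyroscope and a time-depth recorder can monitor a sea turtle for days
with minimal disturbance, but the signals they deliver are only an
indirect view of behaviour. Head-mounted sensors see feeding directly;
carapace-mounted ones, which the animal tolerates far better, see it
only as faint pitch oscillations of the shell when the turtle pulls on
seagrass. `diveseg` turns such multi-rate records (20 Hz inertial
channels, 1 Hz depth) into behavioural bouts, bout categories and
activity budgets, and quantifies how well that inference works when the
truth is known.

The package follows a deliberately mixed strategy: behaviours that are
cheap to read off a single channel are classified by explicit rules
(surface behaviours from depth alone), and supervised learning is
reserved for the diving behaviours whose signatures overlap. Between the
two sits an adaptive segmentation that cuts each dive into homogeneous
bouts before any classifier sees it, avoiding the fixed-window
compromise (long windows smear short behaviours; short windows cannot
carry low-frequency structure).

# Signal model and preprocessing

All acceleration is handled in units of g (1 g = 9.81 m s⁻²), angular
velocity in rad s⁻¹, depth in metres positive downward.

**Tilt.** The logger sits on the carapace pitched about the sway axis so
its camera faces forward. For a pitch-only mounting the gravity
direction in device coordinates gives the angle directly:
θ = atan2(mean ā_x, mean ā_z). `estimate_tilt()` uses caller-supplied
flat intervals when available and the whole record otherwise — over a
record containing symmetric descents and ascents the body-pitch
contributions largely cancel, and on simulated records the estimate is
within half a degree of truth. `correct_tilt()` rotates both the
accelerometer and the gyroscope surge/heave pairs by −θ; per-sample
norms are preserved exactly, which the tests assert at 1e-9.

**Static/dynamic decomposition.** The static (gravity) vector is a
centred running mean over Δt = 2 s per axis, the smallest window whose
norm stays at 1 g on gravity-dominated data; at the record edges the
window shrinks symmetrically rather than padding (no data are
invented). The dynamic residual **d** = **a** − **ā** gives
DBA = ‖**d**‖, and RA = ‖**g**‖ summarizes rotation. A useful
calibration check, asserted in the tests: on a noiseless stationary
record ‖**ā**‖ = 1 g at every sample where the full window fits.

**Resampling.** 50 Hz records are linearly interpolated onto the 20 Hz
grid spanning the same range; the operation is exact on linear signals,
idempotent at 20 Hz, and its worst-case error on band-limited signals is
the standard (2πf)²h²/8 interpolation bound.

# Segmentation

Dives are maximal runs of depth strictly above 0.3 m lasting at least
5 s (the threshold is strict, the duration inclusive); everything else
is surface, split at 6 s into Breathing (≤ 6 s, boundary included) and
Staying at the surface. Surface behaviour is therefore never passed to a
classifier.

Within a dive, three chained stages of exact penalized changepoint
detection produce the bouts. The changepoint engine is PELT with
Gaussian per-segment costs:

* change in mean (unit variance): C = Σ(y − ȳ)²;
* change in variance (mean fixed at the series mean): C = m·log σ̂²;
* change in mean and variance: C = m·(log 2π + log σ̂² + 1);

each penalized by a constant per additional changepoint, variances
floored at 1e-12 so constant segments stay finite, minimum segment
length 2 samples, and ties resolved toward fewer changepoints and then
the earliest final changepoint so results are deterministic. Pruning is
lossless for these costs; with a minimum segment length the candidate
dominated by time *t* may only be discarded once *t* itself is old
enough to act as a split point, a detail the implementation handles by
deferring removals. The suite verifies PELT against an independent
brute-force optimal-partitioning oracle — identical changepoints on
hundreds of randomized series across all three costs and penalties
0.1–50 — plus penalty monotonicity, translation invariance of the mean
cost and scale equivariance of the variance cost.

The three stages:

1. **Depth stage, penalty 5.** The changepoint runs on the dive's 3 s
   vertical-speed series (central difference of 1 Hz depth),
   standardized within the dive. Running on depth *changes* rather than
   depth *levels* matters: a steady descent is a constant change value,
   so all changepoint evidence concentrates at the true phase switches
   instead of accumulating along the ramp, and standardization makes a
   fixed penalty mean the same thing for a 2 m and a 20 m dive. With
   this formulation the planted descent→bottom and bottom→ascent
   switches in the simulator are recovered within ±3 s in 100% of
   replicates; on raw metre-scale levels the corner localization
   degrades to roughly ±5 s because the last ramp piece's mean drags
   the boundary. Pieces are tagged descending (v > +0.1 m s⁻¹),
   ascending (v < −0.1 m s⁻¹) or flat, with depth positive down; a
   configuration switch flips the convention if a record uses the
   opposite sign.
2. **DBA stage, penalty 50.** Ascending and descending pieces are
   re-segmented on 20 Hz DBA for changes in mean and variance,
   separating powered swimming from gliding.
3. **Pitch-rate stage, penalty 20.** Flat pieces are re-segmented on the
   variance of g_y, isolating the high-frequency sagittal-plane
   oscillation bursts characteristic of feeding.

Sub-bouts shorter than 1 s (the feature-smoothing window) are merged
into their longer neighbour to avoid degenerate feature windows. The
emitted segments tile the record exactly — asserted to within one IMU
sample on every randomized run.

**Labelling.** A segment takes the category covering at least 3/5 of its
duration (half-open interval arithmetic; exactly 3/5 counts, since the
rule is "at least"); otherwise it is `Transition`. Annotation gaps count
as `Other`.

# Features

Each bout yields exactly 42 variables in a frozen, versioned order:
mean, minimum, maximum and variance of the eight 20 Hz channels (a_x,
a_y, a_z, g_x, g_y, g_z, DBA, RA); the last-minus-first depth; the
duration; and for g_x, g_y, a_x, a_y the oscillation pair — the raw
channel is smoothed by a 1 s centred running mean, the deviation d from
the smooth is centred by its segment mean m(d), and the mean and maximum
of (d − m(d))² are reported. Variances use the population (n)
denominator throughout; the choice is arbitrary but recorded so that
retraining is reproducible. The tilt-corrected channels feed the
oscillation features. The oscillation computation is verified against a
naive four-step reimplementation at 1e-10, and one analytic case is
pinned down in the tests: a 5 Hz sine sampled at 20 Hz has a 21-sample
running mean equal to −x/21 in the interior, so its osc_mean is
(22/21)²/2.

# Classification

Five base learners are trained on the labelled bouts of the training
individuals: CART (complexity 0.01, minsplit 20), random forest (300
trees, 14 candidate variables per split), extreme gradient boosting
(softmax over the present classes, learning rate 0.3, depth 3, 50
rounds), an RBF SVM (cost 1, γ = 1/42, standardized inputs) and LDA
(standardized inputs, constant columns dropped). Hyper-parameters not
fixed by the workflow's definition take the defaults of the
corresponding reference implementations. All stochastic fits are seeded
via documented per-component offsets from one master seed, and the
determinism is tested.

Class imbalance is handled by capping every class at 1000 training
segments (uniform subsampling without replacement, never upsampling);
`Transition` and `Other` are capped like the named behaviours.

Two ensembles combine the members: the **Voting Ensemble** keeps the
modal member prediction; the **Weighted Sum** scores each class by the
summed precision of the members voting for it, with per-member,
per-class precision estimated by 5-fold out-of-fold prediction *within
the training rows* — the test individuals are never touched, because
estimating weights on test data would leak. Ties in either ensemble go
to the tied class with the highest mean member precision, then to the
fixed alphabetical class order. With uniform weights the weighted sum
provably reduces to voting, which the suite checks on random prediction
matrices.

# Validation protocol

Individuals — not segments — are the sampling unit: all C(n, 4) splits
of the individuals into training and test sets are enumerated (715 for
13 animals), and splits in which the training side holds at most 60% of
all Feeding or Scratching segments are discarded, since a learner cannot
be fair to a behaviour it has barely seen. Per retained split the
workflow balances, trains the five members and both ensembles, and
scores the test individuals' bouts. Metrics follow the one-vs-rest
confusion-matrix formulas — sensitivity TP/(TP+FN), precision
TP/(TP+FP), specificity TN/(TN+FP), with TN = total − TP − FN − FP per
class (the standard multi-class lift of the binary definitions) and
global accuracy = trace/total. Ratios with zero denominators are
reported as NaN and excluded from averages, never silently zeroed.
Split-level metrics are aggregated by unweighted mean ± sd across
splits; formal inferential comparison of classifiers is out of scope —
the per-split table is returned so users can run whatever test suits
their design.

Activity budgets sum bout durations per category over the nine reporting
categories, surface categories always from the depth rules and dive
categories from either predictions or ground truth — the same code path
with a different label source, so predicted and observed budgets are
comparable by construction. Fractions sum to one by conservation, which
is asserted on every randomized run.

# The simulator

`make_dataset()` generates labelled records so that every stage of the
pipeline can be exercised and measured without field data. Per
individual it draws a semi-Markov behaviour sequence organised in dive
cycles — a surface bout (Breathing or Staying at the surface), a descent
(swimming or gliding), a sequence of bottom bouts (Resting, Feeding,
Scratching, Swimming, Other; log-normal durations; no immediate
self-repeats), an ascent — and renders 20 Hz IMU and 1 Hz depth signals:
gravity oriented by body pitch on ramps, flipper-beat surge oscillation
at 0.7 Hz for swimming, 3 Hz pitch-rate bursts with a ~50% duty cycle
for feeding (with a reduced-amplitude residual between grabs, as
handling movement does not stop dead), broadband accelerometer/gyroscope
noise bursts for scratching, a slow roll signature for Other, and
channel noise (accelerometer 0.01 g, gyroscope 0.02 rad s⁻¹). Depth is
sampled at 1 Hz and quantized to the sensor's 0.2 m resolution. The
device tilt (uniform within ±35°) is applied to the synthetic signals so
preprocessing must genuinely undo it.

Three design choices deserve comment:

* **Regime overlap is moderate on purpose.** Gliding and resting share
  low DBA but differ in vertical speed — exactly the contrast stages 1–2
  must resolve; Swimming and Other share the same pitch-rate variance,
  so the variance-only flat stage cannot separate them and adjacent
  bouts merge, which (through the 3/5 rule) is the honest source of
  `Transition` segments. A fraction of bottom time consists of rapid
  Swimming/Other alternation blocks for the same reason — real
  behaviour switches faster than any segmentation can follow, and the
  workflow must label such bouts Transition rather than guess.
* **Prevalence is heterogeneous across individuals**: log-normal jitter
  on the bottom-behaviour weights, one scratching specialist (an order
  of magnitude more and three-fold longer scratching bouts) and a couple
  of feeding-heavy animals, so the split-representation filter actually
  filters.
* **What the simulator does not model**: hydrodynamics, tides,
  temperature, sensor drift, attachment wobble, and the long-tailed
  messiness of real ethograms. Passing the synthetic benchmark shows the
  machinery is implemented correctly and the workflow's assumptions are
  sufficient for signals of this structure; it does not certify
  performance on real turtles, for which the original validation against
  video annotation remains the standard.

# Numerical choices and degenerate inputs

* Variance floor 1e-12 in the log-likelihood costs; population-variance
  denominators; running means with symmetric edge truncation.
* Exactly-6 s surface intervals are Breathing; exactly-3/5 overlap takes
  the category; dive rule: depth strictly greater than 0.3 m, duration
  at least 5 s.
* Dives shorter than twice the minimum segment length become a single
  flat bout; channels clipped to fewer than two samples are an error
  naming the segment.
* A constant series standardizes to zeros (no division by a ~0 standard
  deviation) and yields no changepoints under any positive penalty.
* Zero-denominator metrics are NaN, excluded from means.

# Problem sizes

The shipped tests and the acceptance script run the synthetic benchmark
at 13 individuals with a mean duration of 3600 s, evaluating a
deterministic subsample of 5–6 retained splits; oracle-equivalence
suites use series up to length 120–200 and boundary-recovery suites
40–100 replicates. These sizes keep a full run on a single CPU in the
minutes range while leaving each check statistically meaningful; all of
them scale up by changing one argument.

# Known limitations

* Tilt correction models a pitch-only mounting; roll misalignment is not
  estimated (a magnetometer-free 3-D orientation filter is out of
  scope).
* PELT's pruning gives linear time only when changepoints are plentiful;
  on long changepoint-free stretches it degrades toward quadratic —
  irrelevant at bout scale but worth knowing before feeding it hours of
  unsegmented signal.
* The precision-weight estimation refits every member k times per split;
  the validation loop is consequently the most expensive stage of the
  package.
* Penalties 5/50/20 are tuned for this workflow's signal conventions;
  records in other units, or species with different movement scales,
  need re-tuning (exposed in `diveseg_config()`).
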