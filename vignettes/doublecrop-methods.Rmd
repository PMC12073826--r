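---
title: "Methods: detecting double-cropping from field-scale NDVI series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting double-cropping from field-scale NDVI series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures behind `doublecrop`,
the assumptions they rest on, the numerical choices made where the
design was genuinely open, and what the synthetic test batteries do and
do not demonstrate.

## The signal and its confounders

A field's NDVI year is treated as a one-dimensional phenology signal:
greenness rises after planting, plateaus at full canopy, and falls to a
harvest trough. One harvested crop produces one rise–fall cycle; a
double-cropped field produces two, separated by a mid-summer trough
(harvest of the first crop, planting of the second). The classification
task is binary — single versus double — because in the target setting
intensities above two are essentially absent; the cycle count is still
reported.

Three families of confounders motivate the design:

* **Atmospheric contamination.** Clouds, haze and snow depress NDVI,
  sometimes drastically (a single observation can drop below −0.5).
  Contamination is almost always *downward*, which the denoising chain
  exploits twice (jump repair and maximum-value compositing).
* **Perennial canopies.** Orchards, vineyards and berries hold a
  moderate, flat NDVI all season. After min–max normalization a flat
  series is pure amplified noise, so a dedicated rule intercepts it.
* **Late plantings.** Cover crops and fall-planted winter crops add a
  genuine second greenness bump that is not a second harvested crop.
  The labelling semantics used throughout the package: a second
  planting must start by early August (day-of-year 219) to count as
  double-cropping; anything later is a cover crop or next year's crop,
  i.e. single-cropping.

## Denoising chain

`preprocess()` applies four steps in a fixed order; the composition is
deterministic.

1. **Jump repair** (`correct_jumps`, threshold 0.018 NDVI/day). Canopy
   growth is bounded: a rise faster than 0.018/day between adjacent
   acquisitions implies the *earlier* point was depressed, so that
   point is replaced by linear interpolation between its neighbours
   (the first point, lacking a left neighbour, is raised to its right
   neighbour). The threshold means climbing the full NDVI amplitude of
   a vigorous crop (≈0.7) takes at least ~39 days — planting to peak
   canopy in about six weeks. One repair can expose another violation
   upstream, so passes repeat to convergence with a limit of 20; if
   the limit is hit the series is returned as-is with a warning.
   Decreases are never modified. On realistic noisy series repairs
   converge in a few passes; only adversarial inputs (sustained
   super-threshold ramps, e.g. unbounded random walks) can exhaust the
   limit, which is why the limit-with-warning contract exists.
2. **Negative clipping** (`clip_negatives`). Negative NDVI means "no
   vegetation"; its magnitude is irrelevant but poisonous: one −0.9
   spike inflates the annual min–max denominator and lifts the
   normalized harvest trough, hiding the second cycle. Clipping to
   zero is idempotent and order-preserving.
3. **Compositing** (`regularize`). The year is divided into 36 fixed
   windows starting at day-of-year 1, 11, …, 351 (the last window
   absorbs the year-end remainder), and each window takes the
   *maximum* observed NDVI — the standard dekadal-style composite,
   justified by the downward bias of contamination. The grid is
   anchored at January 1 rather than first acquisition so every field
   shares one grid, which the fixed-length classifiers require. Empty
   windows are filled by linear interpolation between the nearest
   non-empty windows (ends held constant); interpolation is the least
   structured fill and a sparse-coverage warning fires below 25
   non-empty windows. A fully empty year is an error, not a guess.
4. **Savitzky–Golay smoothing** (`savitzky_golay`, window 7, order 3),
   via `signal::sgolayfilt`. The filter is a moving local
   least-squares cubic: it reproduces any cubic exactly (the test
   suite asserts 1e-9 agreement on random cubics) and damps isolated
   spikes. Edges are handled by evaluating the terminal polynomial
   fits, not by reflective padding, because reflection fabricates
   spurious season starts at year boundaries. Smoothed values may
   slightly over/undershoot [0, 1]; they are deliberately *not*
   re-clipped, since re-clipping would distort the normalization
   denominator that the ratio method depends on.

## The NDVI-ratio method

`classify_ratio()` implements the rule-based cycle counter.

* **Normalization.** `r(t) = (v(t) − min v) / (max v − min v)` over
  the whole smoothed year (not just the growing season), so `r`
  always attains 0 and 1. A constant series makes the transform
  undefined; the classifier maps that degenerate case to `single`
  with an explicit trace entry.
* **Rule 1 (flat series).** If the range of smoothed NDVI over
  windows starting May 1–October 31 (day-of-year 121–304) is ≤ 0.3,
  the field is single-cropped; this intercepts orchard-like canopies
  before normalization can amplify their wiggles. The rule
  short-circuits everything else, and uses the *smoothed* series (the
  raw range would be noise-inflated).
* **Rule 2 (crossings).** Starts of season are upward crossings of
  τ = 0.5 by `r`, ends of season downward crossings; the crossing
  date is linearly interpolated between the bracketing grid points.
  A point exactly at τ counts as crossed only when the next point is
  strictly on the other side, so plateaus at exactly 0.5 are not
  double-counted.
* **Rule 3 (unpaired events).** An SOS with no subsequent EOS in the
  year is nullified (a crop still growing at year end — a fall
  planting for next season). A *leading* EOS with no preceding SOS is
  a crop planted the previous fall and harvested mid-year; it is kept
  as a cycle anchored at day-of-year 1. Consequently a lone EOS
  followed by a later full cycle yields *two* cycles — the
  wheat-then-buckwheat succession. The alternative reading (count the
  lone EOS only when no other cycle exists) would silently erase that
  succession, which is a real double-cropping system; the trace flags
  `rule3b` whenever this path fires so users can audit it.
* **Rule 4 (minimum length).** Cycles shorter than 40 days are
  discarded: no crop is planted, grown and harvested in under 40
  days, but a narrow cover-crop bump can cross τ for less than that.

Two or more retained cycles ⇒ `double`; otherwise `single`. Every
decision path is recorded in `rule_trace`.

## Trained classifiers

`train_classifier()` fits a radial-kernel SVM (e1071), a random forest
(ranger), or kNN with a dynamic-time-warping distance computed in C.
Features are simply the 36 smoothed NDVI values in window order — no
rescaling, since NDVI is already a bounded physical index and the
models should see the amplitude differences between crops.

* **DTW.** Classic dynamic programming with absolute-difference local
  cost and unit steps, unconstrained by default (an optional
  Sakoe–Chiba band is available). DTW absorbs planting-date shifts
  that would dominate a lockstep (Euclidean-style) distance. The
  implementation is verified against an exhaustive recursive
  alignment oracle on short sequences.
* **Splitting.** Train/test splits are stratified by crop:
  `round(0.2·n)` of each crop's fields go to test (singleton strata
  stay in training). Stratification guarantees rare crops appear in
  training, mirroring how ground-truth samples are drawn in practice.
* **Oversampling.** Double-cropped fields are a small minority.
  The minority class is resampled with replacement to 50% of the
  majority size; originals are always retained and the majority is
  untouched. Ratios much above 50% push duplicated minority records
  into the majority's feature space and hurt validation accuracy.
  Oversampling is applied *inside each CV training fold only* — never
  to validation folds, where duplicates of training records would
  leak and inflate CV accuracy — and once more for the final refit.
* **Tuning.** Hyperparameters are chosen by mean overall accuracy
  over 5 class-stratified folds (stratified so no fold misses the
  minority class). Default grids: SVM cost {0.1, 1, 10, 100} ×
  gamma {1/(p·var x), 0.01, 0.1}; forest {100, 300} trees ×
  max depth {unlimited, 10}; kNN k {1, 3, 5, 7}. Ties in CV accuracy
  resolve to the first grid row, making selection deterministic. For
  kNN the train×train DTW matrix is computed once and sliced per fold
  and per k, so tuning cost is independent of the k grid.
* **Determinism.** Every random draw (folds, oversampling, tree
  seeds) derives from the user seed through a fixed integer-hash
  scheme, and the caller's RNG state is restored afterwards.

`render_series_image()` rasterizes a smoothed year onto a fixed
[0, 1] × year canvas as a deterministic 0/1 matrix. It is the input
adapter for external image classifiers (e.g. transfer-learned CNNs);
training such a model is out of scope and the package neither needs
nor loads any deep-learning dependency.

## Accuracy assessment

Count-based OA/UA/PA come straight from the 2×2 confusion matrix; a
zero denominator (e.g. no predicted doubles) yields `NA`, never a
silent 0. Standard errors treat the evaluation sample as a stratified
random sample with crops as strata: overall accuracy is the weighted
mean of within-stratum proportions with variance
`Σ W_h² (1 − n_h/N_h) s_h² / n_h`, and UA/PA are combined ratio
estimators with Taylor-linearized variance. With one stratum these
collapse exactly to the simple-random-sampling closed forms
(`SE(OA) = sqrt(p(1−p)/(n−1))`), which the tests assert. Population
stratum sizes are optional; without them weights default to sample
proportions and no finite-population correction is applied. Strata
with fewer than two samples contribute zero variance with a warning.
The estimator is the design-stratified (not poststratified) variant;
with self-weighting samples the two differ negligibly, and the choice
is documented here precisely because it is not externally forced.

The area-proportional confusion matrix divides each cell's acreage by
total acreage. No standard errors are produced for it: there is no
established design-based variance methodology for object-based
(per-field) classifications, and fabricating one would be worse than
omitting it.

## The synthetic generator

`generate_dataset()` simulates field-years from five scenario kinds:
`single`, `double`, `orchard_flat`, `single_plus_cover`, and
`single_plus_fall_planting`. Each harvested cycle is a normalized
product-of-logistics double-logistic curve — the standard phenology
shape — with green-up steepness 0.08/day (planting to peak in about
six weeks, consistent with the 0.018/day repair threshold), faster
senescence (0.25/day), peak NDVI ~0.75–0.88 for row crops, and a
background of ~0.1–0.18 (orchards: flat curves with base ~0.24–0.29
and amplitude ≤ ~0.24, under the 0.3 flat-rule threshold). Doubles
use two 85–95-day cycles with the first start around day 90–105 and a
10–18-day harvest-replant gap, keeping the second start at or before
day 218; cover-crop bumps start after day 245; fall plantings rise
from day 280–300 without senescing in-year. Cycle lengths for doubles
are chosen so that, after compositing and smoothing, detected cycles
clear the 40-day floor with margin — that is what makes the CLEAN
battery a *construction* on which rule-based counting must be exact.

Sampling emulates the combined two-mission cadence: nominal 8-day
revisit, ±2-day jitter, 8% dropouts; noise adds Gaussian jitter
(sd 0.02) and, with probability 0.08 per observation, a downward
cloud spike of depth 0.25–1.0 (values floored at −1). Truth labels are
a pure function of the cycle structure — at least two harvested
cycles with the second starting by day 219 — and never of the noise
draws. Areas are log-uniform on [5, 500] acres so the 10-acre filter
is exercised; crops are drawn from scenario-conditional tables
(orchard scenarios are always apple/blueberry, doubles mostly
buckwheat) so per-crop summaries are meaningful.

`default_battery()` fixes four study conditions: CLEAN (300 fields,
no noise, no confusers), NOISY (400, full noise, all scenarios),
CONFUSER (400, rich in cover/fall scenarios), and IMBALANCED (400,
doubles at ~12% — the realistic regional prevalence). These sizes keep
the full test suite under a minute on one CPU while leaving binomial
fluctuation small enough for the batteries' intended contrasts.

What passing tests on these batteries shows: the pipeline's logic is
correct under the stated noise model, the rule-based method fails in
the *direction* real crop-diverse regions make it fail (cover-crop
bumps counted as second crops — on the CONFUSER battery its
false-double count strictly exceeds every trained model's), and the
trained models can exploit bump *timing* that threshold rules cannot.
What it does not show: real-data accuracy. The generator's curves are
smoother than real phenology; it has no mixed pixels, no
mid-season hay cuttings (alfalfa's multi-cut sawtooth), no
multi-year context, and its class boundary is exactly the day-219
rule that the labels themselves encode. Real deployments need real
labelled fields.

## Numerical conventions

* Label factor order is (`single`, `double`) everywhere.
* The jump-repair comparison uses a 1e-12 slack so floating-point
  equality at the cap never triggers a repair loop.
* Degenerate inputs fail loudly: constant series (normalization),
  empty years (compositing), single-class training sets, zero
  `nir + red`. The one deliberate soft failure is the repair pass
  limit (warn and return).
* Percentages are computed at full precision and rounded only in
  presentation-layer output; report files print fixed-format numbers
  so byte-identical reproduction is meaningful.
* `run_end_to_end()` writes no timestamps or absolute paths into its
  artifacts; two runs with the same configuration are byte-identical.

## Known limitations

* The 36-window grid assumes the Northern-Hemisphere calendar year is
  the cropping year; winter-straddling seasons are only represented
  through the rule-3 conventions.
* The flat-series rule's May–October window is hemisphere- and
  latitude-specific.
* kNN-DTW prediction is O(train size) per field; for mapping millions
  of fields the SVM/forest models are the practical choices.
* The day-219 cutoff is a regional convention (second plantings by
  early August); transferring the labelling semantics to another
  climate requires changing that single constant in the generator and
  in any retraining labels.
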