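# doublecrop

Field-scale detection of double-cropping from NDVI time series.

## The problem

Whether a field grows one crop per year or two (its *cropping
intensity*) matters for food-supply accounting, irrigation-water
demand, and land-use policy — but it is rarely surveyed, because it
requires revisiting every field within a season. Satellite greenness
time series offer a scalable alternative: the Normalized Difference
Vegetation Index,

```
NDVI = (NIR − R) / (NIR + R),
```

rises after planting, peaks at full canopy, and falls through
senescence to harvest, so a double-cropped field traces two greenness
cycles within one year. In regions with high crop diversity this
signal is confounded by orchards (flat, elevated NDVI all season),
cover crops and fall plantings (a second greenness bump that is *not*
a second harvested crop), clouds (downward NDVI spikes), and the
irregular ~8-day cadence of combined Landsat 7/8 acquisitions.

`doublecrop` implements a complete, testable pipeline for this
problem at the field (object) scale, for users working with per-field
NDVI series exported from any image platform:

1. **Denoising** — `preprocess()`: repair of implausibly fast NDVI
   rises (a cap of 0.018/day; faster growth means the earlier point
   was cloud-depressed and is re-interpolated), clipping of negative
   NDVI, 10-day maximum-value compositing onto a fixed 36-point annual
   grid, and Savitzky–Golay smoothing (window 7, order 3).
2. **Rule-based classification** — `classify_ratio()`: the NDVI-ratio
   method. The smoothed year is min–max normalized,
   `r(t) = (v(t) − min) / (max − min)`; upward/downward crossings of
   τ = 0.5 mark starts/ends of season; fields whose May–October range
   is ≤ 0.3 are single-cropped (orchard rule); cycles shorter than 40
   days are discarded; two retained cycles ⇒ double-cropped.
3. **Trained classifiers** — `train_classifier()`: radial SVM, random
   forest, and k-nearest-neighbours with a dynamic-time-warping
   distance (so shifted planting dates still match), trained with
   crop-stratified 80/20 splits, 5-fold cross-validation, and
   oversampling of the minority (double-cropped) class to 50% of the
   majority inside training folds.
4. **Accuracy assessment** — `accuracy_metrics()`,
   `stratified_standard_errors()`, `area_matrix()`: count-based
   overall, user's and producer's accuracies with design-based
   standard errors under stratified (by-crop) sampling, plus the
   area-proportional confusion matrix and per-crop / per-county
   double-cropped acreage summaries.

A synthetic crop-phenology generator (`generate_dataset()`,
`default_battery()`) simulates field-years with known labels —
including the labelling semantics that a second planting after early
August (day-of-year 219) is a cover crop or fall planting and counts
as single-cropping — so the entire pipeline is testable offline.

## Worked example

```r
library(doublecrop)

sim <- generate_dataset(6, seed = 42)          # six simulated field-years
sim$truth[, c("field_id", "label", "scenario", "crop")]
#>   field_id  label                  scenario       crop
#> 1   F00001 single         single_plus_cover sweet_corn
#> 2   F00002 single single_plus_fall_planting      wheat
#> 3   F00003 single                    single    alfalfa
#> 4   F00004 single         single_plus_cover     potato
#> 5   F00005 double                    double  buckwheat
#> 6   F00006 double                    double       peas

classify_ratio(preprocess(sim$series[["F00005"]]))   # a true double
#> <intensity_result> double (2 cycle(s))
#>        sos      eos   length
#> 1 113.2272 168.1381 54.91087
#> 2 218.5361 272.4524 53.91630
#> trace: rule1:pass -> rule2:4-events
```

The buckwheat field crosses the 0.5 ratio upward on day 113, downward
on day 168, and again on days 219/272: two cycles longer than 40 days,
hence `double`. A fall-planted wheat field instead shows a start of
season with no end of season before the year closes, which rule 3
nullifies:

```r
classify_ratio(preprocess(sim$series[["F00002"]]))
#> <intensity_result> single (1 cycle(s))
#>        sos      eos   length
#> 1 144.4327 209.7687 65.33603
#> trace: rule1:pass -> rule2:3-events -> rule3a:sos-without-eos-nullified
```

For a full comparison of the rule-based method against the trained
models on one simulated region:

```r
run_end_to_end("run1", seed = 1, n_fields = 400)
```

which writes `report.csv` / `report.txt` (per-method OA, UA, PA and
standard errors on the held-out test split) and `per_crop.csv` (the
double-cropped share of each crop's acreage). A command-line front end
with `simulate`, `preprocess`, `classify-ratio`, `train`, `predict`,
`evaluate` and `end-to-end` subcommands is installed at
`inst/cli/doublecrop.R`.

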