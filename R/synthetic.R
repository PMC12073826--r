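#' Specification of one crop growth cycle
#'
#' Cycles are modelled with a normalized product-of-logistics
#' double-logistic curve, the standard phenology shape: a logistic
#' green-up centred about four weeks after the start of season, a
#' plateau, and a faster logistic senescence ending at
#' `sos_doy + length`. The curve is rescaled so its maximum equals
#' `peak_ndvi` exactly and it decays to `base_ndvi` away from the cycle.
#' The default rise steepness keeps green-up below the 0.018 NDVI/day
#' cap used by the denoising stage, i.e. planting-to-peak takes about
#' six weeks, which is agronomically typical.
#'
#' @param sos_doy Start-of-season day of year.
#' @param length Cycle length in days (`sos_doy + length <= 366`).
#' @param peak_ndvi Peak NDVI in (0.2, 1].
#' @param base_ndvi Off-season background NDVI in \[0, 0.3).
#' @param rise_rate,fall_rate Logistic steepness per day.
#' @return A `cycle_spec` list.
#' @export
cycle_spec <- function(sos_doy, length, peak_ndvi, base_ndvi = 0.12,
                       rise_rate = 0.08, fall_rate = 0.25) {
  stopifnot(peak_ndvi > base_ndvi, peak_ndvi > 0.2, peak_ndvi <= 1,
            base_ndvi >= 0, base_ndvi < 0.3, length > 0, sos_doy >= 1,
            sos_doy <= 366)
  # a cycle may run past day 366: that is a fall planting for the next
  # year, never a harvested in-year cycle (see harvested_cycles)
  structure(list(sos_doy = sos_doy, length = length,
                 peak_ndvi = peak_ndvi, base_ndvi = base_ndvi,
                 rise_rate = rise_rate, fall_rate = fall_rate),
            class = "cycle_spec")
}

cycle_shape_raw <- function(spec, doys) {
  m_r <- spec$sos_doy + 28
  m_f <- spec$sos_doy + spec$length - 12
  stats::plogis(spec$rise_rate * (doys - m_r)) *
    stats::plogis(-spec$fall_rate * (doys - m_f))
}

#' Evaluate a cycle curve at given days of year
#'
#' @param spec A [cycle_spec].
#' @param doys Numeric days of year.
#' @return NDVI values: `base_ndvi` far from the cycle, `peak_ndvi` at
#'   its maximum.
#' @export
cycle_curve <- function(spec, doys) {
  dense <- seq(spec$sos_doy, spec$sos_doy + spec$length, by = 0.25)
  gmax <- max(cycle_shape_raw(spec, dense))
  spec$base_ndvi + (spec$peak_ndvi - spec$base_ndvi) *
    cycle_shape_raw(spec, doys) / gmax
}

# Sum-of-cycles annual curve over a shared background.
field_curve <- function(cycles, doys) {
  base <- min(vapply(cycles, function(cs) cs$base_ndvi, numeric(1)))
  amp <- rep(0, length(doys))
  for (cs in cycles) {
    amp <- amp + (cycle_curve(cs, doys) - cs$base_ndvi)
  }
  pmin(base + amp, 1)
}

scenario_kinds <- function() {
  c("single", "double", "orchard_flat", "single_plus_cover",
    "single_plus_fall_planting")
}

# DOY 219 = August 7: a second planting after early August is a
# fall-planted crop or a cover crop, i.e. single-cropping.
second_planting_cutoff <- function() 219

harvested_cycles <- function(cycles) {
  Filter(function(cs) {
    cs$sos_doy <= second_planting_cutoff() &&
      cs$sos_doy + cs$length <= 366
  }, cycles)
}

#' Specification of a simulated field-year scenario
#'
#' @param kind Scenario kind: `"single"`, `"double"`, `"orchard_flat"`,
#'   `"single_plus_cover"` (late cover-crop bump, still single by the
#'   labelling semantics), or `"single_plus_fall_planting"` (greenness
#'   rising into winter for next year's crop).
#' @param cycles List of [cycle_spec]s; consistency with `kind` is
#'   checked (a double needs two harvested cycles with the second
#'   starting by day 219; a cover bump must start after day 219).
#' @param acquisition List: `start` (first DOY), `revisit` (mean days
#'   between acquisitions, default 8), `jitter` (uniform +/- days),
#'   `dropout` (probability an acquisition is lost).
#' @param noise List: `cloud_prob` (per-observation probability of a
#'   cloud spike), `spike_min`/`spike_max` (uniform spike depth, always
#'   subtracted — contamination biases NDVI down and can drive it
#'   negative), `sd` (Gaussian measurement noise).
#' @param seed Integer seed; the scenario is deterministic given it.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(kind, cycles,
                          acquisition = list(start = 4, revisit = 8,
                                             jitter = 0, dropout = 0),
                          noise = list(cloud_prob = 0, spike_min = 0.25,
                                       spike_max = 1, sd = 0),
                          seed = 1) {
  kind <- match.arg(kind, scenario_kinds())
  nh <- length(harvested_cycles(cycles))
  if (kind == "double" && nh < 2) {
    stop("scenario_spec: a double scenario needs two harvested cycles ",
         "with the second starting by DOY ", second_planting_cutoff())
  }
  if (kind != "double" && nh >= 2) {
    stop("scenario_spec: kind '", kind, "' but cycle structure implies double")
  }
  if (kind %in% c("single_plus_cover", "single_plus_fall_planting") &&
      length(cycles) < 2) {
    stop("scenario_spec: '", kind, "' needs a main cycle plus a late bump")
  }
  structure(list(kind = kind, cycles = cycles, acquisition = acquisition,
                 noise = noise, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Simulate one field-year of NDVI observations
#'
#' Samples the sum-of-cycles curve at jittered ~8-day acquisition dates,
#' applies Gaussian noise and downward cloud spikes (floored at -1), and
#' derives the truth label from the cycle structure alone: double iff at
#' least two harvested cycles exist, the second starting by day 219.
#' Noise never influences the label.
#'
#' @param spec A [scenario_spec].
#' @param field_id Identifier for the simulated field.
#' @param year Calendar year (default 2017).
#' @param meta Extra metadata list (crop, area, county, irrigation).
#' @return List with `series` (a [field_series]) and `truth` (one-row
#'   data frame: field_id, label, cycle_count, scenario, crop, area).
#' @export
generate_field <- function(spec, field_id = "F1", year = 2017,
                           meta = list()) {
  stopifnot(inherits(spec, "scenario_spec"))
  acq <- spec$acquisition
  nz <- spec$noise
  obs <- with_seed(spec$seed, {
    doys <- seq(acq$start, 365, by = acq$revisit)
    if ((acq$jitter %||% 0) > 0) {
      doys <- doys + sample(seq(-acq$jitter, acq$jitter),
                            length(doys), replace = TRUE)
    }
    doys <- sort(unique(pmin(pmax(doys, 1), 365)))
    if ((acq$dropout %||% 0) > 0) {
      doys <- doys[stats::runif(length(doys)) >= acq$dropout]
    }
    v <- field_curve(spec$cycles, doys)
    if ((nz$sd %||% 0) > 0) v <- v + stats::rnorm(length(v), sd = nz$sd)
    if ((nz$cloud_prob %||% 0) > 0) {
      hit <- stats::runif(length(v)) < nz$cloud_prob
      depth <- stats::runif(sum(hit), nz$spike_min, nz$spike_max)
      v[hit] <- v[hit] - depth
    }
    list(doys = doys, v = pmin(pmax(v, -1), 1))
  })
  series <- field_series(field_id, year,
                         dates = as.Date(obs$doys - 1,
                                         origin = sprintf("%d-01-01", year)),
                         ndvi = obs$v, meta = meta)
  nh <- length(harvested_cycles(spec$cycles))
  truth <- data.frame(
    field_id = field_id,
    label = if (nh >= 2) "double" else "single",
    cycle_count = max(nh, 1L),
    scenario = spec$kind,
    crop = as.character(meta$crop %||% NA),
    area = as.numeric(meta$area %||% NA),
    county = as.character(meta$county %||% NA),
    stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

# Random cycle structure for a scenario kind; called under a fixed seed.
random_cycles <- function(kind) {
  main_base <- runif1(0.10, 0.18)
  switch(kind,
    single = list(cycle_spec(runif1(95, 135), runif1(100, 140),
                             runif1(0.75, 0.88), main_base)),
    double = {
      sos1 <- runif1(90, 105)
      len1 <- runif1(85, 95)
      gap <- runif1(10, 18)
      sos2 <- sos1 + len1 + gap   # at most DOY 218, before early August
      list(cycle_spec(sos1, len1, runif1(0.75, 0.88), main_base),
           cycle_spec(sos2, runif1(85, 95), runif1(0.72, 0.85), main_base))
    },
    orchard_flat = {
      base <- runif1(0.24, 0.29)
      list(cycle_spec(runif1(80, 100), runif1(200, 230),
                      base + runif1(0.14, 0.24), base))
    },
    single_plus_cover = list(
      cycle_spec(runif1(100, 125), runif1(80, 100),
                 runif1(0.75, 0.88), main_base),
      cycle_spec(runif1(245, 262), runif1(80, 95),
                 runif1(0.55, 0.70), main_base)),
    single_plus_fall_planting = list(
      cycle_spec(runif1(100, 130), runif1(95, 120),
                 runif1(0.75, 0.88), main_base),
      # fall planting for next year: rises late, no in-year senescence
      cycle_spec(runif1(280, 300), 130, runif1(0.55, 0.70), main_base,
                 fall_rate = 0.08))
  )
}

default_crop_catalog <- function() {
  list(
    single = c(wheat = 0.30, potato = 0.25, alfalfa = 0.25,
               sweet_corn = 0.10, peas = 0.10),
    double = c(buckwheat = 0.50, sweet_corn = 0.30, peas = 0.20),
    orchard_flat = c(apple = 0.70, blueberry = 0.30),
    single_plus_cover = c(potato = 0.60, sweet_corn = 0.40),
    single_plus_fall_planting = c(wheat = 1.0)
  )
}

noise_profile <- function(name = c("none", "landsat")) {
  name <- match.arg(name)
  if (name == "none") {
    list(acquisition = list(start = 4, revisit = 8, jitter = 0,
                            dropout = 0),
         noise = list(cloud_prob = 0, spike_min = 0.25, spike_max = 1,
                      sd = 0))
  } else {
    # combined Landsat 7/8 cadence: ~8-day revisit, +/-2 d jitter,
    # occasional lost acquisitions and cloud-depressed values
    list(acquisition = list(start = 4, revisit = 8, jitter = 2,
                            dropout = 0.08),
         noise = list(cloud_prob = 0.08, spike_min = 0.25, spike_max = 1,
                      sd = 0.02))
  }
}

#' Simulate a dataset of field-years with known labels
#'
#' Draws scenario kinds from `class_mix`, assigns crops from a
#' kind-conditional catalog (orchard-like crops are never double-cropped,
#' buckwheat-like crops mostly are, so per-crop summaries are
#' exercised), areas log-uniform in \[5, 500\] acres (so the 10-acre
#' filter bites), and counties/irrigation at random.
#'
#' @param n_fields Number of field-years.
#' @param class_mix Named probabilities over scenario kinds, summing
#'   to 1.
#' @param noise `"none"` or `"landsat"` (see the noise profile), or a
#'   list with `acquisition` and `noise` entries.
#' @param crop_catalog Kind-conditional crop probability tables.
#' @param seed Integer seed; the dataset is a pure function of it.
#' @param year Calendar year.
#' @return List with `series` (named list of [field_series]) and
#'   `truth` (data frame with field_id, label, cycle_count, scenario,
#'   crop, area, county).
#' @export
generate_dataset <- function(n_fields,
                             class_mix = c(single = 0.40, double = 0.25,
                                           orchard_flat = 0.15,
                                           single_plus_cover = 0.12,
                                           single_plus_fall_planting = 0.08),
                             noise = "landsat",
                             crop_catalog = default_crop_catalog(),
                             seed = 1, year = 2017) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8,
            all(names(class_mix) %in% scenario_kinds()))
  prof <- if (is.character(noise)) noise_profile(noise) else noise
  counties <- c("Adams", "Benton", "Franklin", "Grant", "Yakima")
  irrig <- c("center_pivot", "drip", "rill", "flood")

  plan <- with_seed(seed, {
    data.frame(
      kind = sample(names(class_mix), n_fields, replace = TRUE,
                    prob = class_mix),
      crop = NA_character_,
      area = exp(stats::runif(n_fields, log(5), log(500))),
      county = sample(counties, n_fields, replace = TRUE),
      irrigation = sample(irrig, n_fields, replace = TRUE),
      sub_seed = sample.int(2147483646L, n_fields),
      stringsAsFactors = FALSE)
  })
  plan$crop <- vapply(seq_len(n_fields), function(i) {
    tab <- crop_catalog[[plan$kind[i]]]
    with_seed(derive_seed(plan$sub_seed[i], 1),
              sample(names(tab), 1, prob = tab))
  }, character(1))

  out <- vector("list", n_fields)
  for (i in seq_len(n_fields)) {
    cyc <- with_seed(derive_seed(plan$sub_seed[i], 2),
                     random_cycles(plan$kind[i]))
    spec <- scenario_spec(plan$kind[i], cyc,
                          acquisition = prof$acquisition,
                          noise = prof$noise,
                          seed = derive_seed(plan$sub_seed[i], 3))
    out[[i]] <- generate_field(
      spec, field_id = sprintf("F%05d", i), year = year,
      meta = list(crop = plan$crop[i], area = plan$area[i],
                  county = plan$county[i],
                  irrigation = plan$irrigation[i], survey_year = year))
  }
  series <- lapply(out, `[[`, "series")
  names(series) <- vapply(series, function(s) s$field_id, character(1))
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  list(series = series, truth = truth)
}

#' Standard synthetic test batteries
#'
#' A fixed catalog of datasets regenerated bit-identically from `seed`:
#' \describe{
#'   \item{CLEAN}{300 fields, no noise, no confuser scenarios — every
#'     cycle is long and well separated, so rule-based cycle counting
#'     should be exact.}
#'   \item{NOISY}{400 fields with cloud spikes, jitter and dropouts,
#'     including cover-crop and fall-planting scenarios.}
#'   \item{CONFUSER}{400 fields rich in late-bump scenarios that fool
#'     threshold-based cycle counting but are single-cropped by the
#'     labelling semantics.}
#'   \item{IMBALANCED}{400 fields with double-cropping at ~12\% —
#'     the realistic regional prevalence.}
#' }
#'
#' @param seed Integer seed.
#' @return Named list of datasets as returned by [generate_dataset()].
#' @export
default_battery <- function(seed = 1) {
  list(
    CLEAN = generate_dataset(
      300, class_mix = c(single = 0.55, double = 0.30,
                         orchard_flat = 0.15),
      noise = "none", seed = derive_seed(seed, 101)),
    NOISY = generate_dataset(
      400, class_mix = c(single = 0.40, double = 0.25,
                         orchard_flat = 0.15, single_plus_cover = 0.12,
                         single_plus_fall_planting = 0.08),
      noise = "landsat", seed = derive_seed(seed, 202)),
    CONFUSER = generate_dataset(
      400, class_mix = c(single = 0.20, double = 0.25,
                         single_plus_cover = 0.35,
                         single_plus_fall_planting = 0.20),
      noise = "landsat", seed = derive_seed(seed, 303)),
    IMBALANCED = generate_dataset(
      400, class_mix = c(single = 0.55, double = 0.12,
                         orchard_flat = 0.18, single_plus_cover = 0.10,
                         single_plus_fall_planting = 0.05),
      noise = "landsat", seed = derive_seed(seed, 404))
  )
}
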