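#' Evaluate predictions against truth labels
#'
#' Builds the confusion summary and the full accuracy report: count-based
#' OA/UA/PA with design-based standard errors (crops as strata) and the
#' area-proportional confusion matrix when areas are available.
#'
#' @param truth,predicted Label vectors.
#' @param strata Optional crop strata.
#' @param areas Optional acreages.
#' @param pop_sizes Optional population stratum sizes for the
#'   finite-population correction.
#' @return List with `summary` (`confusion_summary`), `metrics` (count
#'   point estimates), `stratified` (estimates + SEs), `area_matrix`
#'   (or NULL).
#' @export
evaluate_predictions <- function(truth, predicted, strata = NULL,
                                 areas = NULL, pop_sizes = NULL) {
  cs <- confusion(truth, predicted, strata = strata, areas = areas)
  list(summary = cs,
       metrics = accuracy_metrics(cs),
       stratified = stratified_standard_errors(cs, pop_sizes = pop_sizes),
       area_matrix = if (!is.null(areas) && !anyNA(areas))
         area_matrix(cs))
}

format_pct <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.1f", 100 * x))
}

#' Run the full synthetic workflow end to end
#'
#' Simulates a labelled dataset, denoises every field-year, classifies
#' the held-out test split with the rule-based NDVI-ratio method and
#' with each trained model, and writes a comparison report. All
#' randomness is controlled by `seed`; two runs with the same
#' configuration produce byte-identical reports.
#'
#' Artifacts written to `out_dir`: `report.csv` (one row per method with
#' OA/UA/PA and SEs), `report.txt` (human-readable), `per_crop.csv`,
#' `config.yaml` (the effective configuration and package version).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_fields Number of simulated field-years (default 400).
#' @param class_mix Scenario mix passed to [generate_dataset()].
#' @param noise Noise profile name (default "landsat").
#' @param models Character vector of model kinds to train.
#' @param test_fraction Held-out fraction per crop stratum.
#' @param oversample_ratio Minority oversampling target.
#' @param min_area Area filter in acres.
#' @param cv_folds Cross-validation folds.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the report data frame, the per-method
#'   evaluation objects, and the trained models.
#' @export
run_end_to_end <- function(out_dir, seed = 1, n_fields = 400,
                           class_mix = c(single = 0.40, double = 0.25,
                                         orchard_flat = 0.15,
                                         single_plus_cover = 0.12,
                                         single_plus_fall_planting = 0.08),
                           noise = "landsat",
                           models = c("svm", "rf", "knn_dtw"),
                           test_fraction = 0.2, oversample_ratio = 0.5,
                           min_area = 10, cv_folds = 5, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: ", n_fields, " field-years")
  sim <- generate_dataset(n_fields, class_mix = class_mix, noise = noise,
                          seed = derive_seed(seed, 1))
  series <- suppressMessages(filter_fields(sim$series, min_area = min_area))
  truth <- sim$truth[sim$truth$field_id %in% names(series), , drop = FALSE]
  say("filter: ", length(series), " of ", n_fields, " fields >= ",
      min_area, " acres")

  say("preprocess: denoising ", length(series), " series")
  smooths <- suppressWarnings(preprocess_all(series))
  ds <- build_dataset(smooths, truth)
  split <- stratified_split(ds, test_fraction = test_fraction,
                            seed = derive_seed(seed, 2))
  test <- split$test
  say("split: ", nrow(split$train$x), " train / ", nrow(test$x), " test")

  test_smooths <- smooths[match(test$field_id, names(smooths))]
  ratio_pred <- classify_ratio_all(test_smooths)$label

  evals <- list()
  fits <- list()
  evals$ndvi_ratio <- evaluate_predictions(
    as.character(test$y), ratio_pred, strata = test$strata,
    areas = test$area)

  for (kind in models) {
    say("train: ", kind)
    fit <- train_classifier(kind, split$train, cv_folds = cv_folds,
                            oversample_ratio = oversample_ratio,
                            seed = derive_seed(seed, 3))
    pred <- predict(fit, test)
    evals[[kind]] <- evaluate_predictions(
      as.character(test$y), as.character(pred), strata = test$strata,
      areas = test$area)
    fits[[kind]] <- fit
  }

  report <- do.call(rbind, lapply(names(evals), function(m) {
    st <- evals[[m]]$stratified
    data.frame(method = m,
               oa = st$oa, se_oa = st$se_oa,
               ua_double = st$ua_double, se_ua = st$se_ua,
               pa_double = st$pa_double, se_pa = st$se_pa,
               stringsAsFactors = FALSE)
  }))

  best <- report$method[which.max(report$oa)]
  best_pred <- if (best == "ndvi_ratio") {
    ratio_pred
  } else {
    as.character(predict(fits[[best]], test))
  }
  meta <- data.frame(crop = test$strata, area = test$area,
                     county = test$county, stringsAsFactors = FALSE)
  per_crop <- per_crop_double_fraction(best_pred, meta)
  regional <- regional_summary(best_pred, meta)

  # ---- artifacts (no timestamps or absolute paths: reports must be
  # byte-identical across reruns of the same configuration) ----
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  rep_out <- report
  for (cc in setdiff(names(rep_out), "method")) rep_out[[cc]] <- num(rep_out[[cc]])
  utils::write.csv(rep_out, file.path(out_dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  pc_out <- per_crop
  pc_out$acres <- sprintf("%.3f", pc_out$acres)
  pc_out$pct_double <- sprintf("%.3f", pc_out$pct_double)
  utils::write.csv(pc_out, file.path(out_dir, "per_crop.csv"),
                   row.names = FALSE, quote = FALSE)

  txt <- c("Cropping-intensity classification report",
           sprintf("fields: %d simulated, %d after %s-acre filter, %d test",
                   n_fields, length(series), format(min_area), nrow(test$x)),
           "",
           sprintf("%-12s %8s %8s %8s %8s %8s %8s", "method", "OA%",
                   "seOA%", "UA2%", "seUA%", "PA2%", "sePA%"),
           vapply(seq_len(nrow(report)), function(i) {
             r <- report[i, ]
             sprintf("%-12s %8s %8s %8s %8s %8s %8s", r$method,
                     format_pct(r$oa), format_pct(r$se_oa),
                     format_pct(r$ua_double), format_pct(r$se_ua),
                     format_pct(r$pa_double), format_pct(r$se_pa))
           }, character(1)),
           "",
           sprintf("best method: %s", best),
           "double-cropped share of test acreage by crop (best method):",
           vapply(seq_len(nrow(per_crop)), function(i) {
             sprintf("  %-12s %7.1f acres %6.1f%%", per_crop$crop[i],
                     per_crop$acres[i], per_crop$pct_double[i])
           }, character(1)))
  writeLines(txt, file.path(out_dir, "report.txt"))

  config <- list(package = "doublecrop",
                 version = as.character(utils::packageVersion("doublecrop")),
                 seed = seed, n_fields = n_fields,
                 class_mix = as.list(class_mix), noise = noise,
                 models = as.list(models), test_fraction = test_fraction,
                 oversample_ratio = oversample_ratio, min_area = min_area,
                 cv_folds = cv_folds,
                 tau = 0.5, range_threshold = 0.3, min_cycle_days = 40,
                 max_daily_increase = 0.018, window_days = 10,
                 sg_window = 7, sg_polyorder = 3)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))

  invisible(list(report = report, evals = evals, models = fits,
                 per_crop = per_crop, regional = regional,
                 split = split, smooths = smooths, truth = truth))
}
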