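#' Confusion summary for binary cropping-intensity labels
#'
#' Tallies a 2x2 confusion matrix (rows = truth, columns = predicted,
#' in the order single, double), overall and per stratum, and keeps the
#' record-level table for design-based variance estimation.
#'
#' @param truth,predicted Label vectors ("single"/"double"), equal length.
#' @param strata Optional stratum (crop) per record.
#' @param areas Optional area in acres per record.
#' @return A `confusion_summary`: list with `counts`, `by_stratum`
#'   (named list of 2x2 matrices), and `records` (data frame).
#' @export
confusion <- function(truth, predicted, strata = NULL, areas = NULL) {
  if (length(truth) != length(predicted)) {
    stop("confusion: truth and predicted lengths differ")
  }
  truth <- as_label_factor(truth)
  predicted <- as_label_factor(predicted)
  n <- length(truth)
  strata <- if (is.null(strata)) rep("all", n) else as.character(strata)
  if (length(strata) != n) stop("confusion: strata length mismatch")
  if (!is.null(areas) && length(areas) != n) {
    stop("confusion: areas length mismatch")
  }
  counts <- table(truth = truth, predicted = predicted)
  by_stratum <- lapply(split(seq_len(n), strata), function(idx) {
    table(truth = truth[idx], predicted = predicted[idx])
  })
  records <- data.frame(truth = truth, predicted = predicted,
                        stratum = strata,
                        area = if (is.null(areas)) NA_real_ else
                          as.numeric(areas))
  structure(list(counts = counts, by_stratum = by_stratum,
                 records = records),
            class = "confusion_summary")
}

#' Count-based accuracy point estimates
#'
#' Overall accuracy (OA) is the fraction of records on the confusion
#' matrix diagonal. Producer's accuracy of the double class (PA) is the
#' fraction of truly double-cropped records predicted double (recall);
#' user's accuracy (UA) is the fraction of predicted-double records that
#' are truly double (precision). Undefined metrics (zero denominators)
#' are reported as `NA`, never silently as 0.
#'
#' @param summary A `confusion_summary`.
#' @return List with `oa`, `ua_double`, `pa_double`.
#' @export
accuracy_metrics <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  m <- summary$counts
  n <- sum(m)
  if (n == 0) stop("accuracy_metrics: empty confusion matrix")
  n22 <- m["double", "double"]
  pred2 <- sum(m[, "double"])
  truth2 <- sum(m["double", ])
  list(oa = sum(diag(m)) / n,
       ua_double = if (pred2 > 0) n22 / pred2 else NA_real_,
       pa_double = if (truth2 > 0) n22 / truth2 else NA_real_)
}

# Within-stratum variance helper: sample variance of an indicator,
# zero (with warning) for strata that cannot support a variance.
.strat_var <- function(v) {
  if (length(v) < 2) {
    warning("stratified SE: stratum with fewer than 2 samples ",
            "contributes zero variance")
    return(0)
  }
  stats::var(v)
}

#' Design-based accuracies and standard errors under stratified sampling
#'
#' Treats the evaluation sample as a stratified random sample (strata =
#' crops, matching the sampling design). Overall accuracy is the
#' weighted mean of within-stratum proportions with weight
#' \eqn{W_h = N_h / N} (population stratum sizes if supplied, otherwise
#' sample proportions, i.e. self-weighting); its variance is
#' \eqn{\sum_h W_h^2 (1 - n_h/N_h) s_h^2 / n_h} with \eqn{s_h^2} the
#' sample variance of the correctness indicator. User's and producer's
#' accuracies are combined ratio estimators across strata with variance
#' by Taylor linearization of the ratio. With a single stratum the
#' formulas collapse to the simple-random-sampling forms, e.g.
#' \eqn{SE(OA) = \sqrt{p(1-p)/(n-1)}}. The finite-population correction
#' is applied only when population sizes are supplied.
#'
#' @param summary A `confusion_summary` built with strata.
#' @param pop_sizes Optional named vector of population stratum sizes.
#' @return List with stratified point estimates and standard errors:
#'   `oa`, `se_oa`, `ua_double`, `se_ua`, `pa_double`, `se_pa`.
#' @export
stratified_standard_errors <- function(summary, pop_sizes = NULL) {
  stopifnot(inherits(summary, "confusion_summary"))
  rec <- summary$records
  hs <- sort(unique(rec$stratum))
  n_h <- vapply(hs, function(h) sum(rec$stratum == h), numeric(1))
  if (!is.null(pop_sizes)) {
    if (!all(hs %in% names(pop_sizes))) {
      stop("stratified_standard_errors: pop_sizes missing strata")
    }
    N_h <- as.numeric(pop_sizes[hs])
    fpc <- pmax(0, 1 - n_h / N_h)
  } else {
    N_h <- n_h
    fpc <- rep(1, length(hs))
  }
  W <- N_h / sum(N_h)

  mean_h <- function(v) {
    vapply(hs, function(h) mean(v[rec$stratum == h]), numeric(1))
  }
  var_h <- function(v) {
    vapply(hs, function(h) .strat_var(v[rec$stratum == h]), numeric(1))
  }

  # overall accuracy: stratified mean of the correctness indicator
  correct <- as.numeric(rec$truth == rec$predicted)
  oa <- sum(W * mean_h(correct))
  se_oa <- sqrt(sum(W^2 * fpc * var_h(correct) / n_h))

  # combined ratio estimator for UA/PA of the double class
  ratio_est <- function(num, den) {
    xbar <- sum(W * mean_h(den))
    if (xbar == 0) return(list(est = NA_real_, se = NA_real_))
    r <- sum(W * mean_h(num)) / xbar
    d <- num - r * den
    se <- sqrt(sum(W^2 * fpc * var_h(d) / n_h)) / xbar
    list(est = r, se = se)
  }
  is2t <- as.numeric(rec$truth == "double")
  is2p <- as.numeric(rec$predicted == "double")
  both <- is2t * is2p
  ua <- ratio_est(both, is2p)
  pa <- ratio_est(both, is2t)

  list(oa = oa, se_oa = se_oa,
       ua_double = ua$est, se_ua = ua$se,
       pa_double = pa$est, se_pa = pa$se)
}

#' Area-proportional confusion matrix
#'
#' Each cell is the summed acreage of its records divided by the total
#' acreage, so the matrix sums to 1. Standard errors are intentionally
#' not produced: no established design-based methodology exists for
#' object-based (per-field) classifications.
#'
#' @param summary A `confusion_summary` built with `areas`.
#' @return 2x2 numeric matrix of area proportions.
#' @export
area_matrix <- function(summary) {
  stopifnot(inherits(summary, "confusion_summary"))
  rec <- summary$records
  if (anyNA(rec$area)) stop("area_matrix: missing areas")
  total <- sum(rec$area)
  m <- matrix(0, 2, 2, dimnames = list(truth = crop_labels(),
                                       predicted = crop_labels()))
  for (tl in crop_labels()) {
    for (pl in crop_labels()) {
      m[tl, pl] <- sum(rec$area[rec$truth == tl & rec$predicted == pl]) /
        total
    }
  }
  m
}

#' Percentage of each crop's acreage classified double-cropped
#'
#' @param predictions Label vector ("single"/"double") per field.
#' @param metadata Data frame aligned with `predictions`, with columns
#'   `crop` and `area`.
#' @return Data frame `crop`, `acres`, `pct_double` (acre-weighted,
#'   full precision; round only for presentation).
#' @export
per_crop_double_fraction <- function(predictions, metadata) {
  predictions <- as_label_factor(predictions)
  stopifnot(length(predictions) == nrow(metadata))
  rows <- lapply(split(seq_along(predictions), metadata$crop), function(i) {
    acres <- sum(metadata$area[i])
    dbl <- sum(metadata$area[i][predictions[i] == "double"])
    data.frame(crop = metadata$crop[i][1], acres = acres,
               pct_double = 100 * dbl / acres, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$pct_double), , drop = FALSE]
}

#' Percentage of each region's acreage classified double-cropped
#'
#' @param predictions Label vector per field.
#' @param metadata Aligned data frame containing `area` and the region
#'   column.
#' @param region_key Name of the region column (default "county").
#' @return Data frame `region`, `acres`, `pct_double`.
#' @export
regional_summary <- function(predictions, metadata, region_key = "county") {
  predictions <- as_label_factor(predictions)
  stopifnot(length(predictions) == nrow(metadata))
  region <- metadata[[region_key]]
  if (is.null(region)) stop("regional_summary: no column ", region_key)
  rows <- lapply(split(seq_along(predictions), region), function(i) {
    acres <- sum(metadata$area[i])
    dbl <- sum(metadata$area[i][predictions[i] == "double"])
    data.frame(region = region[i][1], acres = acres,
               pct_double = 100 * dbl / acres, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
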