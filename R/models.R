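#' Feature vector of a smoothed series
#'
#' The classifiers take the smoothed, equal-length NDVI year directly as
#' the feature vector, in window order and without rescaling (values are
#' already in NDVI units).
#'
#' @param smooth A smoothed `smooth_series`.
#' @param expected_length Contract on the grid length (default 36).
#' @return Numeric vector of length `expected_length`.
#' @export
to_feature_vector <- function(smooth, expected_length = 36) {
  stopifnot(inherits(smooth, "smooth_series"))
  if (length(smooth$values) != expected_length) {
    stop("to_feature_vector: series has length ", length(smooth$values),
         ", expected ", expected_length)
  }
  v <- smooth$values[order(smooth$window_starts[seq_along(smooth$values)])]
  if (!all(is.finite(v))) stop("to_feature_vector: non-finite values")
  v
}

#' Assemble a labelled dataset from smoothed series and a truth table
#'
#' @param smooths Named list of smoothed `smooth_series`.
#' @param truth Data frame with `field_id`, `label` ("single"/"double"),
#'   and optionally `crop` (stratum), `area`, `county`. Fields absent
#'   from `truth` get `NA` labels (prediction-only records are allowed
#'   via `require_labels = FALSE`).
#' @param require_labels Error if any field lacks a label (default TRUE).
#' @return A `labeled_dataset`: list with matrix `x` (fields x windows),
#'   factor `y`, character `strata`, `field_id`, numeric `area`,
#'   character `county`.
#' @export
build_dataset <- function(smooths, truth = NULL, require_labels = TRUE) {
  x <- do.call(rbind, lapply(smooths, to_feature_vector))
  field_id <- vapply(smooths, function(s) s$field_id, character(1))
  rownames(x) <- field_id
  crop_meta <- vapply(smooths, function(s) {
    as.character(s$meta$crop %||% "unknown")
  }, character(1))
  y <- rep(NA_character_, nrow(x))
  strata <- crop_meta
  area <- rep(NA_real_, nrow(x))
  county <- rep(NA_character_, nrow(x))
  if (!is.null(truth)) {
    m <- match(field_id, truth$field_id)
    if (require_labels && anyNA(m)) {
      stop("build_dataset: fields without truth labels: ",
           paste(utils::head(field_id[is.na(m)], 5), collapse = ", "))
    }
    y <- as.character(truth$label[m])
    if (!is.null(truth$crop)) strata <- as.character(truth$crop[m])
    if (!is.null(truth$area)) area <- as.numeric(truth$area[m])
    if (!is.null(truth$county)) county <- as.character(truth$county[m])
  }
  structure(
    list(x = x, y = if (all(is.na(y))) NULL else as_label_factor(y),
         strata = strata, field_id = field_id, area = area,
         county = county),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d records, %d features, %d strata\n",
              nrow(x$x), ncol(x$x), length(unique(x$strata))))
  if (!is.null(x$y)) print(table(x$y))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(
    list(x = ds$x[idx, , drop = FALSE],
         y = if (is.null(ds$y)) NULL else ds$y[idx],
         strata = ds$strata[idx], field_id = ds$field_id[idx],
         area = ds$area[idx], county = ds$county[idx]),
    class = "labeled_dataset")
}

#' Dynamic time warping distance
#'
#' Classic DTW with absolute-difference local cost and unit steps
#' (match, insert, delete), computed in C. DTW aligns shifted peaks and
#' valleys, so fields with different planting dates but the same cycle
#' structure score as similar. Unconstrained by default; `window` adds a
#' Sakoe-Chiba band of that half-width around the (scaled) diagonal.
#'
#' @param a,b Numeric sequences (non-empty).
#' @param window Optional nonnegative band half-width; `NULL` for
#'   unconstrained warping.
#' @return Nonnegative distance; 0 iff the sequences are equal up to
#'   repetition-collapse.
#' @export
dtw_distance <- function(a, b, window = NULL) {
  band <- if (is.null(window)) -1L else as.integer(window)
  if (band >= 0 && band < abs(length(a) - length(b))) {
    stop("dtw_distance: band narrower than the length difference")
  }
  .dtw_dist_cpp(as.numeric(a), as.numeric(b), band)
}

#' Pairwise DTW distances between rows of two matrices
#'
#' @param x,y Numeric matrices whose rows are sequences.
#' @param window Optional Sakoe-Chiba band half-width.
#' @return `nrow(x)` x `nrow(y)` distance matrix.
#' @export
dtw_cross <- function(x, y, window = NULL) {
  band <- if (is.null(window)) -1L else as.integer(window)
  .dtw_cross_cpp(as.matrix(x), as.matrix(y), band)
}

#' Crop-stratified train/test split
#'
#' Within each stratum (crop), `round(test_fraction * n)` records go to
#' the test set; strata of size 1 go entirely to training. The split is
#' disjoint, exhaustive, and deterministic given `seed`.
#'
#' @param ds A `labeled_dataset`.
#' @param test_fraction Fraction of each stratum held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` (`labeled_dataset`s); the chosen
#'   test indices are attached as `attr(, "test_idx")`.
#' @export
stratified_split <- function(ds, test_fraction = 0.2, seed = 1) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (anyNA(ds$strata)) stop("stratified_split: missing stratum labels")
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(ds$strata), ds$strata), function(idx) {
      n_test <- round(test_fraction * length(idx))
      if (length(idx) < 2 || n_test == 0) return(integer(0))
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(ds$strata), test_idx)
  out <- list(train = subset_dataset(ds, train_idx),
              test = subset_dataset(ds, test_idx))
  attr(out, "test_idx") <- test_idx
  out
}

# Indices realizing oversampling of the minority class to
# ceiling(target_ratio * majority size); originals always retained.
oversample_indices <- function(y, target_ratio = 0.5, seed = 1) {
  tab <- table(y)
  tab <- tab[tab > 0]
  if (length(tab) < 2) {
    stop("oversampling requires both classes in the training data")
  }
  minority <- names(tab)[which.min(tab)]
  target <- ceiling(target_ratio * max(tab))
  n_min <- min(tab)
  idx <- seq_along(y)
  if (n_min >= target) return(idx)
  min_idx <- which(y == minority)
  extra <- with_seed(seed, sample(min_idx, target - n_min, replace = TRUE))
  c(idx, extra)
}

#' Oversample the minority class of a training set
#'
#' Resamples the minority class with replacement until its size reaches
#' `ceiling(target_ratio * majority size)`. The majority class is never
#' touched, all original records are retained, and every added record is
#' a duplicate of an existing minority record. Deterministic given
#' `seed`. Oversampling counteracts class imbalance (double-cropped
#' fields are a small minority); ratios above ~50% tend to let the
#' minority invade the majority's feature space.
#'
#' @param train A `labeled_dataset` with labels for both classes.
#' @param target_ratio Target minority/majority size ratio (default 0.5).
#' @param seed Integer seed.
#' @return The augmented `labeled_dataset`.
#' @export
oversample_minority <- function(train, target_ratio = 0.5, seed = 1) {
  stopifnot(inherits(train, "labeled_dataset"))
  if (is.null(train$y)) stop("oversample_minority: unlabelled dataset")
  subset_dataset(train, oversample_indices(train$y, target_ratio, seed))
}

default_grid <- function(kind) {
  switch(kind,
    svm = expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c(NA, 0.01, 0.1)),   # NA = "scale"
    rf = expand.grid(num_trees = c(100, 300), max_depth = c(0, 10)),
    knn_dtw = data.frame(k = c(1, 3, 5, 7)),
    stop("unknown model kind: ", kind)
  )
}

# Stratified fold assignment by class so no fold misses a class.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

fit_one <- function(kind, x, y, params, seed) {
  if (kind == "svm") {
    gamma <- params$gamma
    if (is.na(gamma)) gamma <- 1 / (ncol(x) * stats::var(as.vector(x)))
    e1071::svm(x, y, kernel = "radial", cost = params$cost, gamma = gamma,
               scale = FALSE)
  } else if (kind == "rf") {
    ranger::ranger(x = as.data.frame(x), y = y,
                   num.trees = params$num_trees,
                   max.depth = params$max_depth,
                   seed = seed, num.threads = 1)
  } else {
    # kNN keeps its (oversampled) training set; distances computed lazily
    list(x = x, y = y, k = params$k)
  }
}

predict_one <- function(kind, fit, newx, dtw_window = NULL, d = NULL) {
  if (kind == "svm") {
    stats::predict(fit, newx)
  } else if (kind == "rf") {
    stats::predict(fit, data = as.data.frame(newx),
                   num.threads = 1)$predictions
  } else {
    if (is.null(d)) d <- dtw_cross(newx, fit$x, window = dtw_window)
    k <- min(fit$k, ncol(d))
    lev <- levels(fit$y)
    lab <- apply(d, 1, function(row) {
      nb <- fit$y[order(row)[seq_len(k)]]
      votes <- table(nb)
      lev[which.max(votes)]
    })
    factor(lab, levels = lev)
  }
}

#' Train a cropping-intensity classifier with cross-validated tuning
#'
#' Fits one of three model kinds on a labelled training set:
#' \describe{
#'   \item{`"svm"`}{radial-kernel support vector machine (e1071),
#'     tuned over cost and gamma (`NA` gamma means 1/(p * var(x))).}
#'   \item{`"rf"`}{random forest (ranger), tuned over tree count and
#'     maximum depth (0 = unlimited).}
#'   \item{`"knn_dtw"`}{k-nearest-neighbours with dynamic time warping
#'     distance, tuned over k.}
#' }
#' Hyperparameters are selected by mean overall accuracy over
#' class-stratified cross-validation folds. Minority oversampling (to
#' `oversample_ratio` of the majority) is applied inside each CV
#' training fold only — never to validation folds, where duplicated
#' records would leak and inflate CV accuracy — and again to the full
#' training set for the final refit.
#'
#' For `knn_dtw` the train-by-train DTW matrix is computed once and
#' sliced per fold and per k, so tuning cost is independent of the size
#' of the k grid.
#'
#' @param kind One of `"svm"`, `"rf"`, `"knn_dtw"`.
#' @param train A `labeled_dataset` containing both classes.
#' @param cv_folds Number of cross-validation folds (default 5).
#' @param grid Hyperparameter data frame; `NULL` for the built-in grid.
#' @param oversample_ratio Minority/majority target ratio (default 0.5).
#' @param seed Integer seed controlling folds, oversampling draws and
#'   (for rf) tree growing.
#' @param dtw_window Optional Sakoe-Chiba band for `knn_dtw`.
#' @return A `dblcrop_model`: list with the fitted state, chosen
#'   hyperparameters, the CV table, and the training configuration.
#' @export
train_classifier <- function(kind = c("svm", "rf", "knn_dtw"), train,
                             cv_folds = 5, grid = NULL,
                             oversample_ratio = 0.5, seed = 1,
                             dtw_window = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(train, "labeled_dataset"))
  if (is.null(train$y)) stop("train_classifier: unlabelled dataset")
  if (nlevels(droplevels(train$y)) < 2) {
    stop("train_classifier: training data must contain both classes")
  }
  if (is.null(grid)) grid <- default_grid(kind)
  if (nrow(grid) == 0) stop("train_classifier: empty hyperparameter grid")

  y <- train$y
  x <- train$x
  folds <- stratified_folds(y, cv_folds, derive_seed(seed, 11))
  dmat <- if (kind == "knn_dtw") dtw_cross(x, x, window = dtw_window)

  cv <- grid
  cv$mean_cv_accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- which(folds != f)
      va <- which(folds == f)
      os <- tr[oversample_indices(y[tr], oversample_ratio,
                                  derive_seed(seed, 100 + f))]
      fit <- fit_one(kind, x[os, , drop = FALSE], y[os],
                     grid[g, , drop = FALSE], derive_seed(seed, 200 + f))
      dsub <- if (!is.null(dmat)) dmat[va, os, drop = FALSE]
      pred <- predict_one(kind, fit, x[va, , drop = FALSE],
                          dtw_window = dtw_window, d = dsub)
      accs[f] <- mean(pred == y[va])
    }
    cv$mean_cv_accuracy[g] <- mean(accs)
  }
  best <- which.max(cv$mean_cv_accuracy)  # ties: first row, deterministic

  os_full <- oversample_indices(y, oversample_ratio, derive_seed(seed, 300))
  fit <- fit_one(kind, x[os_full, , drop = FALSE], y[os_full],
                 grid[best, , drop = FALSE], derive_seed(seed, 400))

  structure(
    list(kind = kind, fit = fit,
         best_params = grid[best, , drop = FALSE],
         cv_table = cv, n_features = ncol(x),
         classes = levels(y), dtw_window = dtw_window,
         config = list(cv_folds = cv_folds,
                       oversample_ratio = oversample_ratio, seed = seed),
         version = as.character(utils::packageVersion("doublecrop"))),
    class = "dblcrop_model")
}

#' @export
print.dblcrop_model <- function(x, ...) {
  cat(sprintf("<dblcrop_model> %s (best CV accuracy %.3f)\n", x$kind,
              max(x$cv_table$mean_cv_accuracy)))
  print(x$best_params)
  invisible(x)
}

#' Predict cropping-intensity labels
#'
#' Pure function of the model and the input: one label per row,
#' invariant under row permutation, identical after serialization and
#' reload of the model.
#'
#' @param object A `dblcrop_model`.
#' @param newdata Numeric matrix (rows = fields, 36 columns), a single
#'   vector, or a `labeled_dataset`.
#' @param ... Unused.
#' @return Factor of labels (`single`/`double`).
#' @export
predict.dblcrop_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features) {
    stop("predict: expected ", object$n_features, " columns, got ",
         ncol(newdata))
  }
  p <- predict_one(object$kind, object$fit, newdata,
                   dtw_window = object$dtw_window)
  factor(as.character(p), levels = object$classes)
}

#' Save / load a trained model
#'
#' Thin wrappers around [saveRDS()]/[readRDS()]; the model object embeds
#' its configuration, seed and package version, and reloaded models give
#' bit-identical predictions.
#'
#' @param model A `dblcrop_model`.
#' @param path File path.
#' @return `load_model` returns the model; `save_model` its path,
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dblcrop_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "dblcrop_model")) stop("load_model: not a dblcrop_model")
  m
}

#' Render a smoothed series as a binary image matrix
#'
#' Deterministic line plot of the series on a fixed \[0, 1\] x year
#' canvas: a matrix with `height` rows and `width` columns, 1 where the
#' polyline passes, 0 elsewhere. Row 1 is the top of the canvas, so a
#' higher NDVI puts ink at a smaller row index. Intended as the input
#' adapter for external image classifiers; no axes and no antialiasing.
#'
#' @param smooth A smoothed `smooth_series`.
#' @param width,height Canvas size in pixels (positive).
#' @return `height` x `width` matrix of 0/1.
#' @export
render_series_image <- function(smooth, width = 64, height = 64) {
  stopifnot(inherits(smooth, "smooth_series"))
  if (width < 2 || height < 2) {
    stop("render_series_image: canvas must be at least 2x2")
  }
  v <- pmin(pmax(smooth$values, 0), 1)
  n <- length(v)
  px <- round(seq(1, width, length.out = n))
  py <- height - round(v * (height - 1))
  img <- matrix(0L, nrow = height, ncol = width)
  for (i in seq_len(n - 1)) {
    steps <- max(abs(px[i + 1] - px[i]), abs(py[i + 1] - py[i])) + 1
    cx <- round(seq(px[i], px[i + 1], length.out = steps))
    cy <- round(seq(py[i], py[i + 1], length.out = steps))
    img[cbind(cy, cx)] <- 1L
  }
  img
}
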