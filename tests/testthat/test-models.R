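test_that("DTW matches the exhaustive alignment oracle on short pairs", {
  expect_equal(dtw_distance(c(0, 1, 0), c(0, 0, 1, 0)), 0)
  set.seed(21)
  for (i in 1:150) {
    a <- runif(sample(1:6, 1))
    b <- runif(sample(1:6, 1))
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_oracle(a, b), tolerance = 1e-12)
    expect_equal(d, dtw_distance(b, a), tolerance = 1e-12)
    expect_gte(d, 0)
  }
  expect_error(dtw_distance(numeric(0), 1:3), "empty")
})

test_that("DTW self-distance is zero and warping never beats lockstep", {
  set.seed(22)
  for (i in 1:50) {
    x <- runif(36)
    y <- runif(36)
    expect_equal(dtw_distance(x, x), 0)
    expect_lte(dtw_distance(x, y), sum(abs(x - y)) + 1e-12)
  }
  # Sakoe-Chiba band: wide band equals unconstrained; band 0 is lockstep
  x <- runif(12); y <- runif(12)
  expect_equal(dtw_distance(x, y, window = 12), dtw_distance(x, y))
  expect_equal(dtw_distance(x, y, window = 0), sum(abs(x - y)))
})

test_that("stratified split is exact per stratum, disjoint, seeded", {
  set.seed(23)
  x <- matrix(runif(70 * 36), 70)
  y <- rep(c("single", "double"), c(50, 20))
  strata <- rep(c("wheat", "corn", "rare"), c(50, 19, 1))
  ds <- structure(list(x = x, y = doublecrop:::as_label_factor(y),
                       strata = strata, field_id = paste0("F", 1:70),
                       area = runif(70, 5, 50),
                       county = rep("Grant", 70)),
                  class = "labeled_dataset")
  sp <- stratified_split(ds, 0.2, seed = 5)
  expect_equal(nrow(sp$test$x), round(0.2 * 50) + round(0.2 * 19))
  expect_equal(sum(sp$test$strata == "wheat"), 10)
  expect_equal(sum(sp$test$strata == "rare"), 0)  # singleton goes to train
  expect_setequal(c(sp$train$field_id, sp$test$field_id), ds$field_id)
  expect_length(intersect(sp$train$field_id, sp$test$field_id), 0)
  sp2 <- stratified_split(ds, 0.2, seed = 5)
  expect_identical(sp$test$field_id, sp2$test$field_id)
  sp3 <- stratified_split(ds, 0.2, seed = 6)
  expect_false(identical(sp$test$field_id, sp3$test$field_id))
})

test_that("minority oversampling reaches the target with duplicates only", {
  set.seed(24)
  x <- matrix(runif(120 * 36), 120)
  y <- rep(c("single", "double"), c(100, 20))
  ds <- structure(list(x = x, y = doublecrop:::as_label_factor(y),
                       strata = rep("wheat", 120),
                       field_id = paste0("F", 1:120), area = rep(10, 120),
                       county = rep("Grant", 120)),
                  class = "labeled_dataset")
  os <- oversample_minority(ds, 0.5, seed = 3)
  expect_equal(as.vector(table(os$y)), c(100, 50))
  # originals retained, majority untouched
  expect_true(all(ds$field_id %in% os$field_id))
  expect_equal(sum(os$y == "single"), 100)
  # every added record duplicates an existing minority record
  added <- setdiff(which(duplicated(os$field_id)), seq_len(120))
  expect_true(all(os$y[added] == "double"))
  expect_true(all(os$field_id[added] %in% ds$field_id[ds$y == "double"]))
  expect_identical(oversample_minority(ds, 0.5, seed = 3)$field_id,
                   os$field_id)
  # minority already at target: unchanged
  expect_equal(nrow(oversample_minority(ds, 0.1, seed = 3)$x), 120)
  ds1 <- doublecrop:::subset_dataset(ds, 1:100)
  expect_error(oversample_minority(ds1), "both classes")
})

test_that("feature vectors follow the window grid contract", {
  sm <- preprocess(clean_scenario_series("single", seed = 1))
  v <- to_feature_vector(sm)
  expect_length(v, 36)
  expect_identical(v, sm$values[order(sm$window_starts)])
  expect_error(to_feature_vector(ss(runif(10))), "length")
})

test_that("training is deterministic, serializable, and self-consistent", {
  ny <- generate_dataset(120, seed = 55)
  sm <- suppressWarnings(preprocess_all(ny$series))
  ds <- build_dataset(sm, ny$truth)
  sp <- stratified_split(ds, 0.2, seed = 2)

  # grid of size 1 returns that configuration
  m_rf <- train_classifier("rf", sp$train,
                           grid = data.frame(num_trees = 100, max_depth = 0),
                           seed = 9)
  expect_equal(m_rf$best_params$num_trees, 100)

  m1 <- train_classifier("svm", sp$train, seed = 9)
  m2 <- train_classifier("svm", sp$train, seed = 9)
  expect_identical(m1$best_params, m2$best_params)
  expect_identical(as.character(predict(m1, sp$test)),
                   as.character(predict(m2, sp$test)))

  # 1-NN DTW predicts a training record's own label
  m_knn <- train_classifier("knn_dtw", sp$train,
                            grid = data.frame(k = 1), seed = 9)
  i <- c(1, 10, 25)
  expect_identical(as.character(predict(m_knn, sp$train$x[i, ])),
                   as.character(sp$train$y[i]))

  # permutation equivariance of prediction
  p <- predict(m_rf, sp$test$x)
  perm <- rev(seq_len(nrow(sp$test$x)))
  expect_identical(as.character(predict(m_rf, sp$test$x[perm, ])),
                   as.character(p)[perm])

  # serialization round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m_knn, f)
  m_back <- load_model(f)
  expect_identical(as.character(predict(m_back, sp$test)),
                   as.character(predict(m_knn, sp$test)))
  expect_error(predict(m_rf, matrix(0, 2, 12)), "columns")
})

test_that("series images are deterministic with the right orientation", {
  sm <- preprocess(clean_scenario_series("single", seed = 13))
  img1 <- render_series_image(sm, 64, 64)
  img2 <- render_series_image(sm, 64, 64)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(64, 64))
  expect_true(all(img1 %in% c(0L, 1L)))

  flat <- render_series_image(ss(rep(0.5, 36)), 32, 32)
  expect_equal(length(unique(which(flat == 1, arr.ind = TRUE)[, "row"])), 1)

  # a higher peak puts ink at a smaller row index
  lo <- render_series_image(ss(rep(0.2, 36)), 32, 32)
  hi <- render_series_image(ss(rep(0.8, 36)), 32, 32)
  expect_lt(min(which(hi == 1, arr.ind = TRUE)[, "row"]),
            min(which(lo == 1, arr.ind = TRUE)[, "row"]))
  expect_error(render_series_image(sm, 1, 64), "at least")
})
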