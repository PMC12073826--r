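mk_labels <- function(n11, n12, n21, n22) {
  list(truth = rep(c("single", "single", "double", "double"),
                   c(n11, n12, n21, n22)),
       pred = rep(c("single", "double", "single", "double"),
                  c(n11, n12, n21, n22)))
}

test_that("confusion tallies counts overall and per stratum", {
  cs <- confusion(c("single", "single", "double", "double"),
                  c("single", "double", "double", "double"),
                  strata = c("a", "a", "b", "b"))
  expect_equal(as.vector(cs$counts), c(1, 0, 1, 2))  # column-major
  expect_equal(sum(cs$counts), 4)
  expect_equal(as.vector(cs$by_stratum$a), c(1, 0, 1, 0))
  # permutation invariance
  o <- c(3, 1, 4, 2)
  cs2 <- confusion(c("single", "single", "double", "double")[o],
                   c("single", "double", "double", "double")[o])
  expect_equal(cs2$counts, cs$counts)
  expect_error(confusion("single", c("single", "double")), "lengths")
  expect_error(confusion("maybe", "single"), "unknown")
})

test_that("OA/UA/PA arithmetic matches hand computation", {
  l <- mk_labels(90, 10, 5, 45)
  m <- accuracy_metrics(confusion(l$truth, l$pred))
  expect_equal(m$oa, 0.9)
  expect_equal(m$ua_double, 45 / 55)
  expect_equal(m$pa_double, 0.9)

  perfect <- accuracy_metrics(confusion(l$truth, l$truth))
  expect_equal(unlist(perfect), c(oa = 1, ua_double = 1, pa_double = 1))

  # no predicted doubles: UA undefined (NA, not 0), PA 0
  l2 <- mk_labels(95, 0, 5, 0)
  m2 <- accuracy_metrics(confusion(l2$truth, l2$pred))
  expect_true(is.na(m2$ua_double))
  expect_equal(m2$pa_double, 0)
})

test_that("one-stratum standard errors collapse to the SRS closed form", {
  truth <- rep(c("double", "single"), c(40, 61))  # n = 101
  pred <- truth
  pred[1:5] <- "single"      # 5 doubles missed
  pred[60:64] <- "double"    # 5 singles overcalled -> 91 of 101 correct
  cs <- confusion(truth, pred)
  st <- stratified_standard_errors(cs)
  p <- mean(truth == pred)
  n <- length(truth)
  expect_equal(st$oa, p)
  expect_equal(st$se_oa, sqrt(p * (1 - p) / (n - 1)))
  # UA: ratio-estimator linearized SE, computed directly
  y <- as.numeric(truth == "double" & pred == "double")
  x <- as.numeric(pred == "double")
  r <- sum(y) / sum(x)
  d <- y - r * x
  expect_equal(st$ua_double, r)
  expect_equal(st$se_ua, sqrt(var(d) / n) / mean(x))

  # exact textbook case: n = 101, 91 correct
  cs2 <- confusion(rep(c("single", "double"), c(91, 10)),
                   rep("single", 101))
  st2 <- stratified_standard_errors(cs2)
  expect_equal(st2$se_oa, sqrt((91 / 101) * (10 / 101) / 100))
})

test_that("duplicating every record roughly halves the variance", {
  l <- mk_labels(50, 8, 6, 36)
  st1 <- stratified_standard_errors(confusion(l$truth, l$pred))
  st2 <- stratified_standard_errors(confusion(rep(l$truth, 2),
                                              rep(l$pred, 2)))
  expect_equal(st2$se_oa^2 / st1$se_oa^2, 0.5, tolerance = 0.02)
})

test_that("two identical strata match the pooled estimate", {
  l <- mk_labels(40, 5, 5, 20)
  pooled <- stratified_standard_errors(confusion(l$truth, l$pred))
  split2 <- stratified_standard_errors(
    confusion(rep(l$truth, 2), rep(l$pred, 2),
              strata = rep(c("a", "b"), each = length(l$truth))))
  expect_equal(split2$oa, pooled$oa)
  expect_equal(split2$ua_double, pooled$ua_double)
  expect_equal(split2$pa_double, pooled$pa_double)
})

test_that("strata too small for a variance warn and contribute zero", {
  cs <- confusion(c("single", "single", "double"),
                  c("single", "double", "double"),
                  strata = c("a", "a", "lone"))
  w <- capture_warnings(st <- stratified_standard_errors(cs))
  expect_true(any(grepl("fewer than 2", w)))
  expect_true(is.finite(st$se_oa))
})

test_that("area matrix is a proper proportion table", {
  cs <- confusion(c("single", "double"), c("single", "double"),
                  areas = c(10, 30))
  am <- area_matrix(cs)
  expect_equal(am["single", "single"], 0.25)
  expect_equal(am["double", "double"], 0.75)
  expect_equal(sum(am), 1, tolerance = 1e-12)

  # equal areas: area matrix equals count matrix / n; OA agrees exactly
  l <- mk_labels(12, 3, 2, 8)
  n <- length(l$truth)
  cs2 <- confusion(l$truth, l$pred, areas = rep(7, n))
  expect_equal(area_matrix(cs2), unclass(cs2$counts) / n,
               ignore_attr = TRUE)
  expect_equal(sum(diag(area_matrix(cs2))),
               accuracy_metrics(cs2)$oa)
  expect_error(area_matrix(confusion("single", "single")), "missing areas")
})

test_that("per-crop and regional summaries are acre-weighted", {
  meta <- data.frame(crop = rep(c("buckwheat", "apple"), c(10, 2)),
                     area = c(90, rep(1, 9), 50, 50),
                     county = rep(c("Grant", "Yakima"), 6))
  pred <- rep(c("double", "single"), c(1, 11))
  pc <- per_crop_double_fraction(pred, meta)
  expect_equal(pc$pct_double[pc$crop == "buckwheat"], 100 * 90 / 99)
  expect_equal(pc$pct_double[pc$crop == "apple"], 0)

  # acreage-weighted mean of regional percentages equals the overall one
  rs <- regional_summary(pred, meta)
  overall <- 100 * sum(meta$area[pred == "double"]) / sum(meta$area)
  expect_equal(sum(rs$pct_double * rs$acres) / sum(rs$acres), overall)
})
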