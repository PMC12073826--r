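test_that("annual min-max normalization attains 0 and 1", {
  v <- 0.1 + 0.8 * plogis(seq(-4, 4, length.out = 36))
  r <- ndvi_ratio(ss(v))
  expect_equal(min(r$ratios), 0)
  expect_equal(max(r$ratios), 1)
  # direct substitution: min 0.1, max 0.9, v = 0.5 -> 0.5
  v2 <- c(0.1, 0.9, 0.5, runif(33, 0.1, 0.9))
  r2 <- ndvi_ratio(ss(v2))
  expect_equal(r2$ratios[3], 0.5)
  expect_error(ndvi_ratio(ss(rep(0.4, 36))), "constant")
})

test_that("flat-series rule fires at a May-October range of exactly 0.3", {
  base <- rep(0.2, 36)
  may_oct <- which(seq(1, 351, 10) >= 121 & seq(1, 351, 10) <= 304)
  mk <- function(range) { v <- base; v[may_oct] <- 0.2 + seq(0, range, length.out = length(may_oct)); ss(v) }
  expect_identical(flat_series_rule(mk(0.25)), "single")
  expect_identical(flat_series_rule(mk(0.30)), "single")
  expect_null(flat_series_rule(mk(0.31)))
  # winter variation outside May-Oct does not count
  v <- base; v[1:3] <- 0.9
  expect_identical(flat_series_rule(ss(v)), "single")
})

test_that("crossings are interpolated and alternate along the year", {
  # 0.4 at DOY 121 and 0.6 at DOY 131 cross 0.5 at DOY 126
  v <- rep(0, 36)
  v[13:17] <- c(0.4, 0.6, 1.0, 0.6, 0.4)
  ev <- detect_events(ndvi_ratio(ss(v)))
  expect_equal(ev$kind[1], "SOS")
  expect_equal(ev$doy[1], 126)

  # a single maximum yields exactly one SOS and one EOS around it
  v2 <- rep(0.1, 36); v2[20] <- 0.9
  ev2 <- detect_events(ndvi_ratio(ss(v2)))
  expect_equal(ev2$kind, c("SOS", "EOS"))
  expect_true(ev2$doy[1] < 191 && ev2$doy[2] > 191)

  # two-cycle series: events alternate SOS, EOS, SOS, EOS in doy order
  sm <- preprocess(clean_scenario_series("double", seed = 2))
  ev3 <- detect_events(ndvi_ratio(sm))
  expect_equal(ev3$kind, c("SOS", "EOS", "SOS", "EOS"))
  expect_false(is.unsorted(ev3$doy))
})

test_that("event pairing applies the 40-day rule and nullifies lone events", {
  ev <- data.frame(kind = c("SOS", "EOS", "SOS", "EOS"),
                   doy = c(110, 190, 210, 290))
  pf <- pair_and_filter(ev)
  expect_equal(nrow(pf$cycles), 2)
  expect_equal(pf$cycles$length, c(80, 80))

  # a 30-day cycle is discarded
  pf2 <- pair_and_filter(data.frame(kind = c("SOS", "EOS"),
                                    doy = c(250, 280)))
  expect_equal(nrow(pf2$cycles), 0)
  expect_true(any(grepl("rule4", pf2$trace)))

  # SOS with no EOS contributes nothing
  pf3 <- pair_and_filter(data.frame(kind = "SOS", doy = 300))
  expect_equal(nrow(pf3$cycles), 0)
  expect_true(any(grepl("rule3a", pf3$trace)))

  # leading EOS is a cycle anchored at DOY 1; with a later full cycle
  # it makes two (fall-planted wheat followed by a second crop)
  pf4 <- pair_and_filter(data.frame(kind = c("EOS", "SOS", "EOS"),
                                    doy = c(150, 200, 280)))
  expect_equal(nrow(pf4$cycles), 2)
  expect_equal(pf4$cycles$sos[1], 1)
  expect_true(any(grepl("rule3b", pf4$trace)))

  # raising the minimum cycle length never increases the cycle count
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:4, 1) * 2
    doys <- sort(runif(n, 1, 365))
    ev <- data.frame(kind = rep(c("SOS", "EOS"), n / 2), doy = doys)
    counts <- vapply(c(10, 40, 80, 120), function(mcd) {
      nrow(pair_and_filter(ev, min_cycle_days = mcd)$cycles)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("ratio classification recovers generator labels by scenario", {
  expect_equal(classify_ratio(preprocess(
    clean_scenario_series("double", seed = 3)))$label, "double")
  expect_equal(classify_ratio(preprocess(
    clean_scenario_series("single", seed = 3)))$label, "single")
  orc <- classify_ratio(preprocess(
    clean_scenario_series("orchard_flat", seed = 3)))
  expect_equal(orc$label, "single")
  expect_true(any(grepl("rule1:flat", orc$rule_trace)))

  # a late bump that stays above tau for under 40 days is single
  v <- rep(0.1, 36)
  v[11:19] <- c(0.3, 0.6, 0.85, 0.85, 0.6, 0.3, 0.15, 0.1, 0.1)  # main crop
  v[26:28] <- c(0.2, 0.8, 0.2)                # narrow bump near DOY 250
  res <- classify_ratio(ss(v))
  expect_equal(res$label, "single")
  expect_true(any(grepl("rule4", res$rule_trace)))
  expect_true(all(res$cycles$length >= 40))
})

test_that("raising tau delays SOS and advances EOS for a single cycle", {
  sm <- preprocess(clean_scenario_series("single", seed = 9))
  r <- ndvi_ratio(sm)
  sos <- eos <- numeric(0)
  for (tau in c(0.3, 0.5, 0.7)) {
    ev <- detect_events(r, tau = tau)
    sos <- c(sos, ev$doy[ev$kind == "SOS"][1])
    eos <- c(eos, rev(ev$doy[ev$kind == "EOS"])[1])
  }
  expect_true(all(diff(sos) > 0))
  expect_true(all(diff(eos) < 0))
})
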