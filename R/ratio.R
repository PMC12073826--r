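#' Annual min-max normalization of a smoothed NDVI series
#'
#' The NDVI-ratio transform rescales the smoothed year by its annual
#' minimum and maximum, \eqn{r(t) = (v(t) - min) / (max - min)}, so one
#' season-start/season-end threshold can serve crops with very different
#' peak greenness. The result always attains both 0 and 1.
#'
#' @param smooth A smoothed `smooth_series` (see [preprocess()]).
#' @return A `ratio_series`: list with `window_starts` and `ratios`.
#' @export
ndvi_ratio <- function(smooth) {
  stopifnot(inherits(smooth, "smooth_series"))
  v <- smooth$values
  rng <- max(v) - min(v)
  if (rng < 1e-12) {
    stop("ndvi_ratio: constant series; min-max normalization undefined")
  }
  structure(list(window_starts = smooth$window_starts,
                 ratios = (v - min(v)) / rng),
            class = "ratio_series")
}

#' Flat-series rule (orchards and other evergreen-like canopies)
#'
#' Orchards, vineyards and similar canopies hold a low-amplitude NDVI
#' plateau through the growing season; min-max normalization would still
#' magnify their wiggles into apparent seasons. If the range of the
#' smoothed series over windows starting in May through October
#' (inclusive) is at most `range_threshold`, the field is declared
#' single-cropped outright.
#'
#' @param smooth A smoothed `smooth_series`.
#' @param range_threshold Maximum May-October range for the rule to fire
#'   (default 0.3).
#' @return `"single"` if the rule fires, otherwise `NULL` (no decision).
#' @export
flat_series_rule <- function(smooth, range_threshold = 0.3) {
  stopifnot(inherits(smooth, "smooth_series"))
  in_season <- smooth$window_starts >= 121 & smooth$window_starts <= 304
  v <- smooth$values[in_season]
  if (length(v) == 0) stop("flat_series_rule: series does not cover May-October")
  if (max(v) - min(v) <= range_threshold) "single" else NULL
}

#' Detect start- and end-of-season threshold crossings
#'
#' A start of season (SOS) is an upward crossing of `tau` by the NDVI
#' ratio; an end of season (EOS) is a downward crossing. Crossing dates
#' are interpolated linearly between the two bracketing grid points. A
#' point lying exactly at `tau` counts as crossed only when the next
#' point is strictly on the other side, so plateaus at exactly `tau` are
#' not double-counted.
#'
#' @param ratio A `ratio_series` from [ndvi_ratio()].
#' @param tau Crossing threshold (default 0.5).
#' @return Data frame with columns `kind` ("SOS"/"EOS") and `doy`
#'   (fractional day of year), ordered by `doy`; possibly zero rows.
#' @export
detect_events <- function(ratio, tau = 0.5) {
  stopifnot(inherits(ratio, "ratio_series"))
  r <- ratio$ratios
  x <- as.numeric(ratio$window_starts)
  kind <- character(0)
  doy <- numeric(0)
  for (i in seq_len(length(r) - 1)) {
    up <- r[i] <= tau && r[i + 1] > tau
    down <- r[i] >= tau && r[i + 1] < tau
    if (up || down) {
      kind <- c(kind, if (up) "SOS" else "EOS")
      doy <- c(doy, x[i] + (tau - r[i]) / (r[i + 1] - r[i]) * (x[i + 1] - x[i]))
    }
  }
  data.frame(kind = kind, doy = doy)
}

#' Pair season events into growth cycles and filter them
#'
#' Scans the events left to right, pairing each SOS with the next EOS.
#' An SOS with no following EOS in the year is nullified (a crop still
#' growing at year end, e.g. newly planted winter wheat). A leading EOS
#' with no preceding SOS marks a crop planted the previous fall; it is
#' kept as a cycle whose start is anchored at day-of-year 1, so a lone
#' EOS followed by a later full cycle yields two cycles (fall wheat
#' harvested mid-year plus a second crop). Cycles shorter than
#' `min_cycle_days` are discarded: a growing cycle cannot be shorter
#' than 40 days.
#'
#' @param events Event data frame from [detect_events()], sorted by doy.
#' @param min_cycle_days Minimum credible cycle length in days.
#' @return List with `cycles` (data frame `sos`, `eos`, `length`) and
#'   `trace` (character vector of rule identifiers fired).
#' @export
pair_and_filter <- function(events, min_cycle_days = 40) {
  trace <- character(0)
  cycles <- data.frame(sos = numeric(0), eos = numeric(0),
                       length = numeric(0))
  if (nrow(events) > 0 && is.unsorted(events$doy)) {
    events <- events[order(events$doy), , drop = FALSE]
  }
  i <- 1
  n <- nrow(events)
  if (n > 0 && events$kind[1] == "EOS") {
    # fall-planted crop harvested mid-year: cycle measured from DOY 1
    cycles <- rbind(cycles, data.frame(sos = 1, eos = events$doy[1],
                                       length = events$doy[1] - 1))
    trace <- c(trace, "rule3b:leading-eos-kept-from-doy1")
    i <- 2
  }
  while (i <= n) {
    if (events$kind[i] == "SOS") {
      if (i + 1 <= n && events$kind[i + 1] == "EOS") {
        cycles <- rbind(cycles, data.frame(
          sos = events$doy[i], eos = events$doy[i + 1],
          length = events$doy[i + 1] - events$doy[i]))
        i <- i + 2
      } else {
        trace <- c(trace, "rule3a:sos-without-eos-nullified")
        i <- i + 1
      }
    } else {
      # an interior EOS without a preceding SOS cannot arise from
      # threshold crossings, but tolerate malformed input
      trace <- c(trace, "rule3:unpaired-eos-dropped")
      i <- i + 1
    }
  }
  short <- cycles$length < min_cycle_days
  if (any(short)) {
    trace <- c(trace, sprintf("rule4:discarded-%.0fd-cycle",
                              cycles$length[short]))
    cycles <- cycles[!short, , drop = FALSE]
  }
  rownames(cycles) <- NULL
  list(cycles = cycles, trace = trace)
}

#' Rule-based cropping-intensity classification (NDVI-ratio method)
#'
#' Applies, in order: the flat-series rule; the annual min-max
#' normalization; SOS/EOS detection at `tau`; and event pairing with the
#' minimum-cycle-length filter. One retained (SOS, EOS) pair indicates
#' single-cropping, two or more indicate double-cropping. A constant
#' (degenerate) series is labelled single. No training data are
#' involved; each field is classified independently.
#'
#' @param smooth A smoothed `smooth_series`.
#' @param tau Crossing threshold (default 0.5).
#' @param range_threshold Flat-rule May-October range cutoff (default 0.3).
#' @param min_cycle_days Minimum cycle length in days (default 40).
#' @return An `intensity_result`: list with `label` ("single"/"double"),
#'   `cycles` (data frame), and `rule_trace` (character).
#' @export
classify_ratio <- function(smooth, tau = 0.5, range_threshold = 0.3,
                           min_cycle_days = 40) {
  stopifnot(inherits(smooth, "smooth_series"))
  empty <- data.frame(sos = numeric(0), eos = numeric(0), length = numeric(0))
  res <- function(label, cycles, trace) {
    structure(list(label = label, cycles = cycles, rule_trace = trace),
              class = "intensity_result")
  }
  if (identical(flat_series_rule(smooth, range_threshold), "single")) {
    return(res("single", empty, "rule1:flat-may-oct"))
  }
  trace <- "rule1:pass"
  if (max(smooth$values) - min(smooth$values) < 1e-12) {
    return(res("single", empty, c(trace, "degenerate:constant-series")))
  }
  events <- detect_events(ndvi_ratio(smooth), tau = tau)
  trace <- c(trace, sprintf("rule2:%d-events", nrow(events)))
  pf <- pair_and_filter(events, min_cycle_days = min_cycle_days)
  trace <- c(trace, pf$trace)
  label <- if (nrow(pf$cycles) >= 2) "double" else "single"
  res(label, pf$cycles, trace)
}

#' @export
print.intensity_result <- function(x, ...) {
  cat(sprintf("<intensity_result> %s (%d cycle(s))\n",
              x$label, nrow(x$cycles)))
  if (nrow(x$cycles) > 0) print(x$cycles)
  cat("trace:", paste(x$rule_trace, collapse = " -> "), "\n")
  invisible(x)
}

#' Classify a collection of smoothed series with the ratio method
#'
#' @param smooths Named list of smoothed `smooth_series`.
#' @param ... Passed to [classify_ratio()].
#' @return Data frame with `field_id`, `label`, `n_cycles`, `rule_trace`.
#' @export
classify_ratio_all <- function(smooths, ...) {
  rows <- lapply(smooths, function(s) {
    r <- classify_ratio(s, ...)
    data.frame(field_id = s$field_id, label = r$label,
               n_cycles = nrow(r$cycles),
               rule_trace = paste(r$rule_trace, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
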