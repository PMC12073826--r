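#' Repair cloud-depressed observations via a maximum-growth rule
#'
#' Canopy greenness cannot rise arbitrarily fast: when NDVI grows from one
#' acquisition to the next at more than `max_daily_increase` per day, the
#' earlier observation is assumed to have been depressed (clouds, haze,
#' snow) and is replaced by linear interpolation between its temporal
#' neighbours. The first observation, having no left neighbour, is raised
#' to the value of its right neighbour. Repairs can expose new violations
#' upstream, so passes repeat until no violation remains or `max_passes`
#' is reached (with a warning).
#'
#' The default threshold of 0.018/day ensures planting-to-peak canopy
#' takes at least about a month. Decreases are never modified.
#'
#' @param series A [field_series] with at least 3 observations.
#' @param max_daily_increase Maximum allowed NDVI increase per day.
#' @param max_passes Repair-pass limit.
#' @return The repaired [field_series].
#' @export
correct_jumps <- function(series, max_daily_increase = 0.018,
                          max_passes = 20) {
  stopifnot(inherits(series, "field_series"))
  n <- length(series$ndvi)
  if (n < 3) stop("correct_jumps: need at least 3 observations")
  d <- as.numeric(series$dates)
  v <- series$ndvi
  eps <- 1e-12
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (t in seq_len(n - 1)) {
      slope <- (v[t + 1] - v[t]) / (d[t + 1] - d[t])
      if (slope > max_daily_increase + eps) {
        newv <- if (t == 1) {
          v[2]
        } else {
          v[t - 1] + (v[t + 1] - v[t - 1]) * (d[t] - d[t - 1]) /
            (d[t + 1] - d[t - 1])
        }
        if (abs(newv - v[t]) > eps) {
          v[t] <- newv
          changed <- TRUE
        }
      }
    }
    ok <- !any(diff(v) / diff(d) > max_daily_increase + eps)
    if (ok) break
    if (!changed || pass == max_passes) {
      warning("correct_jumps: pass limit reached with violations remaining")
      break
    }
  }
  series$ndvi <- v
  series
}

#' Set negative NDVI values to zero
#'
#' Negative NDVI indicates absence of vegetation; its magnitude is
#' irrelevant here but a single large negative spike inflates the
#' denominator of the annual min-max normalization and can mask the
#' harvest trough, so negatives are clipped to zero before compositing.
#'
#' @param series A [field_series].
#' @return The series with `ndvi = pmax(ndvi, 0)`; dates untouched.
#' @export
clip_negatives <- function(series) {
  stopifnot(inherits(series, "field_series"))
  series$ndvi <- pmax(series$ndvi, 0)
  series
}

# fixed annual grid: the last window absorbs the year-end remainder
n_windows_for <- function(window_days) as.integer(floor(365 / window_days))

new_smooth_series <- function(field_id, year, window_starts, values, meta,
                              smoothed = FALSE) {
  structure(
    list(field_id = field_id, year = year,
         window_starts = as.integer(window_starts),
         values = as.numeric(values), meta = meta, smoothed = smoothed),
    class = "smooth_series"
  )
}

#' @export
print.smooth_series <- function(x, ...) {
  cat(sprintf("<smooth_series> %s, year %d, %d windows%s\n",
              x$field_id, x$year, length(x$values),
              if (x$smoothed) ", smoothed" else ""))
  invisible(x)
}

#' Composite an irregular series onto a fixed 10-day grid
#'
#' Divides the year into fixed windows starting at day-of-year 1, 11,
#' ..., 351 (the last window absorbs days 351-365/366) and takes the
#' maximum NDVI within each window; the maximum is used because
#' atmospheric contamination biases NDVI downward. Empty windows are
#' filled by linear interpolation between the nearest non-empty windows,
#' with end windows held constant.
#'
#' @param series A [field_series] covering the target year.
#' @param window_days Compositing window length in days (default 10,
#'   giving 36 windows).
#' @param min_windows Fewer non-empty windows than this triggers a
#'   sparse-coverage warning (default 25).
#' @return A `smooth_series` (not yet Savitzky-Golay smoothed).
#' @export
regularize <- function(series, window_days = 10, min_windows = 25) {
  if (!inherits(series, "field_series")) {
    stop("regularize: input must be a field_series (re-compositing a ",
         "smooth_series is not meaningful)")
  }
  nw <- n_windows_for(window_days)
  doy <- doy_of(series$dates)
  idx <- pmin((doy - 1L) %/% as.integer(window_days) + 1L, nw)
  vals <- rep(NA_real_, nw)
  mx <- tapply(series$ndvi, idx, max)
  vals[as.integer(names(mx))] <- mx
  filled_n <- sum(!is.na(vals))
  if (filled_n == 0) {
    stop("regularize: every compositing window is empty; series unusable")
  }
  if (filled_n < min_windows) {
    warning(sprintf(
      "regularize: only %d of %d windows have observations (field %s)",
      filled_n, nw, series$field_id))
  }
  values <- if (filled_n == nw) {
    vals
  } else if (filled_n == 1) {
    rep(vals[!is.na(vals)], nw)
  } else {
    stats::approx(x = which(!is.na(vals)), y = vals[!is.na(vals)],
                  xout = seq_len(nw), rule = 2)$y
  }
  new_smooth_series(series$field_id, series$year,
                    window_starts = seq(1L, by = as.integer(window_days),
                                        length.out = nw),
                    values = values, meta = series$meta, smoothed = FALSE)
}

#' Savitzky-Golay smoothing of a composited series
#'
#' Local least-squares polynomial smoothing via [signal::sgolayfilt()].
#' Edges are handled by evaluating the terminal polynomial fits rather
#' than by reflective padding, so no spurious season starts are
#' fabricated at year boundaries; a polynomial of degree `polyorder` or
#' lower is reproduced exactly. Values may slightly over/undershoot
#' \[0, 1\] and are deliberately not re-clipped, as re-clipping would
#' distort the annual min-max normalization downstream.
#'
#' @param regular A `smooth_series` from [regularize()].
#' @param window Odd moving-window length (default 7).
#' @param polyorder Polynomial degree, less than `window` (default 3).
#' @return The smoothed `smooth_series`.
#' @export
savitzky_golay <- function(regular, window = 7, polyorder = 3) {
  if (!inherits(regular, "smooth_series")) {
    stop("savitzky_golay: input must be a smooth_series from regularize()")
  }
  if (window %% 2 != 1) stop("savitzky_golay: window must be odd")
  if (polyorder >= window) {
    stop("savitzky_golay: polyorder must be smaller than window")
  }
  if (length(regular$values) < window) {
    stop("savitzky_golay: series shorter than the smoothing window")
  }
  regular$values <- as.numeric(
    signal::sgolayfilt(regular$values, p = polyorder, n = window))
  regular$smoothed <- TRUE
  regular
}

#' Full denoising chain for one field-year
#'
#' Applies, in order: [correct_jumps()], [clip_negatives()],
#' [regularize()], [savitzky_golay()]. Deterministic: identical input
#' yields bit-identical output.
#'
#' @param series A [field_series].
#' @param max_daily_increase Jump-repair threshold (NDVI/day).
#' @param window_days Compositing window (days).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @return A smoothed `smooth_series` of fixed length (36 for 10-day
#'   windows).
#' @export
preprocess <- function(series, max_daily_increase = 0.018, window_days = 10,
                       sg_window = 7, sg_polyorder = 3) {
  series |>
    correct_jumps(max_daily_increase = max_daily_increase) |>
    clip_negatives() |>
    regularize(window_days = window_days) |>
    savitzky_golay(window = sg_window, polyorder = sg_polyorder)
}

#' Preprocess a whole collection
#'
#' @param collection Named list of [field_series].
#' @param ... Passed to [preprocess()].
#' @return Named list of smoothed `smooth_series`.
#' @export
preprocess_all <- function(collection, ...) {
  lapply(collection, preprocess, ...)
}
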