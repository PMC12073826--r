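# Small builders shared across test files. Everything is generated in
# code; no fixture files.

# A field_series from day-of-year/value pairs.
fs <- function(doys, ndvi, field_id = "T1", year = 2017, meta = list()) {
  field_series(field_id, year,
               dates = as.Date(doys - 1, origin = "2017-01-01"),
               ndvi = ndvi, meta = meta)
}

# A smooth_series directly from values on the standard 36-window grid.
ss <- function(values, field_id = "T1", smoothed = TRUE, meta = list()) {
  structure(list(field_id = field_id, year = 2017L,
                 window_starts = seq(1L, 351L, by = 10L),
                 values = as.numeric(values), meta = meta,
                 smoothed = smoothed),
            class = "smooth_series")
}

# Dense noise-free sampling of a scenario, as a field_series.
clean_scenario_series <- function(kind, seed = 1) {
  cyc <- doublecrop:::with_seed(seed, doublecrop:::random_cycles(kind))
  spec <- scenario_spec(kind, cyc, seed = seed)
  generate_field(spec, field_id = paste0(kind, seed))$series
}

# Exhaustive recursive DTW oracle (exponential; lengths <= 6 only).
dtw_oracle <- function(a, b) {
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(abs(a[1] - b[1]))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    abs(a[i] - b[j]) + best
  }
  rec(length(a), length(b))
}

# Brute-force 10-day window maximum on the 36-window grid.
window_max_oracle <- function(doys, vals) {
  idx <- pmin((doys - 1) %/% 10 + 1, 36)
  out <- rep(NA_real_, 36)
  for (w in unique(idx)) out[w] <- max(vals[idx == w])
  out
}
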