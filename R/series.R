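#' NDVI from red and near-infrared reflectance
#'
#' Computes the Normalized Difference Vegetation Index,
#' \eqn{(NIR - R) / (NIR + R)}, from atmospherically corrected surface
#' reflectances. Vectorized over both arguments.
#'
#' @param nir Near-infrared reflectance, nonnegative.
#' @param red Red reflectance, nonnegative.
#' @return NDVI values in \[-1, 1\].
#' @examples
#' compute_ndvi(0.5, 0.1)
#' @export
compute_ndvi <- function(nir, red) {
  if (any(nir < 0, na.rm = TRUE) || any(red < 0, na.rm = TRUE)) {
    stop("compute_ndvi: reflectances must be nonnegative")
  }
  s <- nir + red
  if (any(s == 0, na.rm = TRUE)) {
    stop("compute_ndvi: nir + red is zero; NDVI undefined")
  }
  (nir - red) / s
}

#' Construct a field-year NDVI series
#'
#' A `field_series` holds one field-year of dated NDVI observations plus
#' field metadata (crop, irrigation system, county, area in acres).
#' Observations are sorted and must have strictly increasing dates.
#'
#' @param field_id Field identifier (scalar).
#' @param year Calendar year of the series.
#' @param dates `Date` vector of acquisition dates.
#' @param ndvi Numeric NDVI values in \[-1, 1\], same length as `dates`.
#' @param meta Named list of field metadata; recognised entries are
#'   `crop`, `irrigation`, `county`, `area` (acres, > 0), `survey_year`.
#' @return An object of class `field_series`.
#' @export
field_series <- function(field_id, year, dates, ndvi, meta = list()) {
  dates <- as.Date(dates)
  ndvi <- as.numeric(ndvi)
  if (length(dates) != length(ndvi)) {
    stop("field_series: dates and ndvi lengths differ")
  }
  if (anyNA(dates) || anyNA(ndvi)) {
    stop("field_series: missing dates or NDVI values")
  }
  o <- order(dates)
  dates <- dates[o]
  ndvi <- ndvi[o]
  if (any(duplicated(dates))) {
    stop("field_series: duplicate observation dates (collapse them first)")
  }
  if (any(ndvi < -1 - 1e-9) || any(ndvi > 1 + 1e-9)) {
    stop("field_series: NDVI outside [-1, 1]")
  }
  if (!is.null(meta$area) && !is.na(meta$area) && meta$area <= 0) {
    stop("field_series: area must be positive")
  }
  structure(
    list(field_id = as.character(field_id), year = as.integer(year),
         dates = dates, ndvi = ndvi, meta = meta),
    class = "field_series"
  )
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %s, year %d, %d observations\n",
              x$field_id, x$year, length(x$ndvi)))
  invisible(x)
}

doy_of <- function(dates) as.POSIXlt(dates)$yday + 1L

#' Read field-scale NDVI series from a long-format CSV
#'
#' Expects columns `field_id`, `date`, `ndvi` (names configurable). One
#' `field_series` is built per (field_id, year). Duplicate (field, date)
#' rows are collapsed to their mean with a warning; Landsat 7/8 same-day
#' overlaps make such duplicates plausible rather than fatal.
#'
#' @param path Path to the series CSV.
#' @param meta_path Optional path to a metadata CSV keyed by `field_id`
#'   with columns among `crop`, `irrigation`, `county`, `area`,
#'   `survey_year`.
#' @param date_format Date format string (default ISO-8601).
#' @param cols Named list mapping the roles `field_id`, `date`, `ndvi` to
#'   column names in the file.
#' @return A named list of [field_series] objects (names `fieldid_year`).
#' @export
read_series_table <- function(path, meta_path = NULL,
                              date_format = "%Y-%m-%d",
                              cols = list(field_id = "field_id",
                                          date = "date", ndvi = "ndvi")) {
  if (!file.exists(path)) stop("read_series_table: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- unlist(cols[c("field_id", "date", "ndvi")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("read_series_table: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) return(structure(list(), names = character()))

  dates <- as.Date(raw[[cols$date]], format = date_format)
  vals <- suppressWarnings(as.numeric(raw[[cols$ndvi]]))
  bad <- which(is.na(dates) | is.na(vals))
  if (length(bad) > 0) {
    stop("read_series_table: unparseable date/value in row(s): ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  df <- data.frame(field_id = raw[[cols$field_id]], date = dates,
                   ndvi = vals, stringsAsFactors = FALSE)

  dup <- duplicated(df[, c("field_id", "date")])
  if (any(dup)) {
    warning(sprintf(
      "read_series_table: %d duplicate (field, date) row(s) averaged",
      sum(dup)))
    df <- stats::aggregate(ndvi ~ field_id + date, data = df, FUN = mean)
  }

  meta_tab <- NULL
  if (!is.null(meta_path)) {
    meta_tab <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (!"field_id" %in% names(meta_tab)) {
      stop("read_series_table: metadata file lacks field_id column")
    }
    meta_tab$field_id <- as.character(meta_tab$field_id)
  }

  df$year <- as.integer(format(df$date, "%Y"))
  key <- paste(df$field_id, df$year, sep = "_")
  out <- lapply(split(df, key), function(d) {
    meta <- list()
    if (!is.null(meta_tab)) {
      row <- meta_tab[match(d$field_id[1], meta_tab$field_id), , drop = FALSE]
      if (nrow(row) == 1 && !is.na(row$field_id)) {
        meta <- as.list(row[, setdiff(names(row), "field_id"), drop = FALSE])
      }
    }
    field_series(d$field_id[1], d$year[1], d$date, d$ndvi, meta = meta)
  })
  out[order(names(out))]
}

#' Write a collection of field series to a long-format CSV
#'
#' Inverse of [read_series_table()]: round-tripping preserves values to
#' better than 1e-9. NDVI values are written verbatim (negative values
#' included; clipping is the preprocessing stage's job).
#'
#' @param collection Named list of [field_series].
#' @param path Output CSV path for the observations.
#' @param meta_path Optional output CSV path for the per-field metadata.
#' @return Invisibly, the observation data frame written.
#' @export
write_series_table <- function(collection, path, meta_path = NULL) {
  rows <- lapply(collection, function(s) {
    data.frame(field_id = s$field_id,
               date = format(s$dates, "%Y-%m-%d"),
               ndvi = sprintf("%.12g", s$ndvi),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(field_id = character(), date = character(),
               ndvi = character(), stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    utils::write.csv(series_metadata(collection), meta_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}

#' Per-field metadata of a series collection as a data frame
#'
#' @param collection Named list of [field_series] or smooth series.
#' @return Data frame with one row per unique field.
#' @export
series_metadata <- function(collection) {
  grab <- function(s, k) {
    v <- s$meta[[k]]
    if (is.null(v) || length(v) == 0) NA else v
  }
  df <- do.call(rbind, lapply(collection, function(s) {
    data.frame(field_id = s$field_id,
               crop = as.character(grab(s, "crop")),
               irrigation = as.character(grab(s, "irrigation")),
               county = as.character(grab(s, "county")),
               area = as.numeric(grab(s, "area")),
               survey_year = as.integer(grab(s, "survey_year") %||% s$year),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(field_id = character(), crop = character(),
                     irrigation = character(), county = character(),
                     area = numeric(), survey_year = integer())
  }
  rownames(df) <- NULL
  df[!duplicated(df$field_id), , drop = FALSE]
}

#' Drop fields below a minimum area
#'
#' Small fields average few satellite pixels and give noisy field-scale
#' NDVI, so fields strictly smaller than `min_area` acres are removed
#' (fields of exactly `min_area` acres are retained).
#'
#' @param collection Named list of [field_series]; every element must
#'   carry an `area` entry in its metadata.
#' @param min_area Minimum area in acres (default 10).
#' @return The filtered collection; a message reports the count and
#'   acreage removed.
#' @export
filter_fields <- function(collection, min_area = 10) {
  areas <- vapply(collection, function(s) {
    a <- s$meta$area
    if (is.null(a) || is.na(a)) {
      stop("filter_fields: field ", s$field_id, " has no area metadata")
    }
    as.numeric(a)
  }, numeric(1))
  keep <- areas >= min_area
  removed <- sum(!keep)
  message(sprintf(
    "filter_fields: removed %d field-series (%.1f acres) below %.4g acres",
    removed, sum(areas[!keep]), min_area))
  if (all(!keep)) warning("filter_fields: no fields retained")
  collection[keep]
}
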