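#' Read an hourly GPS fix table
#'
#' Parses the canonical fix CSV (one row per device transmission) into a
#' typed, per-individual time-sorted tibble. The dialect carries the ten
#' device variables plus the individual identifier: `individual_id`,
#' `time` (ISO-8601 UTC), `longitude`, `latitude`, `speed` (m/s),
#' `heading` (deg), `altitude` (m), `exercise_volume` (counts/h),
#' `device_temp` (degC), `voltage` (V), `accuracy` (A-E or `invalid`).
#' Duplicate timestamps within an individual are collapsed keeping the
#' best accuracy class (then first occurrence).
#'
#' @param path CSV file path.
#' @return A tibble of fixes.
#' @export
read_fixes <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  for (v in c("individual_id", "accuracy"))
    if (v %in% names(raw)) raw[[v]] <- as.character(raw[[v]])
  if ("time" %in% names(raw) && !inherits(raw$time, "POSIXct"))
    raw$time <- as.character(raw$time)
  validate_fixes(tidy_fixes(raw))
}

tidy_fixes <- function(raw) {
  need <- fix_columns()
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("fix table is missing required column(s): ",
         paste(missing, collapse = ", "))
  raw$time <- parse_utc_time(raw$time, "fix")
  raw <- raw[, need]
  raw$exercise_volume <- as.integer(raw$exercise_volume)
  # best accuracy wins on duplicated hours; ties keep ingestion order
  rank <- match(raw$accuracy, c("A", "B", "C", "D", "E", "invalid"))
  ord <- order(raw$individual_id, raw$time, rank)
  raw <- raw[ord, ]
  dup <- duplicated(raw[, c("individual_id", "time")])
  tibble::as_tibble(raw[!dup, ])
}

parse_utc_time <- function(x, what) {
  if (inherits(x, "POSIXct")) return(lubridate_free_utc(x))
  formats <- c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
               "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")
  t <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                  tz = "UTC")
  for (fmt in formats) {
    idx <- which(is.na(t) & !is.na(x))
    if (!length(idx)) break
    t[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  bad <- which(is.na(t) & !is.na(x))
  if (length(bad))
    stop("unparseable ", what, " timestamp at row ", bad[1], ": ", x[bad[1]])
  t
}

lubridate_free_utc <- function(x) {
  attr(x, "tzone") <- "UTC"
  x
}

validate_fixes <- function(fx) {
  ok_lat <- is.na(fx$latitude) | abs(fx$latitude) <= 90
  ok_lon <- is.na(fx$longitude) | (fx$longitude >= -180 & fx$longitude <= 180)
  if (!all(ok_lat)) stop("latitude outside [-90, 90] at row ", which(!ok_lat)[1])
  if (!all(ok_lon)) stop("longitude outside [-180, 180] at row ", which(!ok_lon)[1])
  if (any(fx$exercise_volume < 0, na.rm = TRUE))
    stop("negative exercise_volume")
  bad_acc <- !fx$accuracy %in% c("A", "B", "C", "D", "E", "invalid")
  if (any(bad_acc))
    stop("unknown accuracy class at row ", which(bad_acc)[1], ": ",
         fx$accuracy[which(bad_acc)[1]])
  fx
}

#' Write a fix table in the canonical CSV dialect
#' @param fixes Fix tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- fixes
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Keep only fixes with positioning accuracy A, B or C
#'
#' The analysis uses positions only from the three best accuracy classes
#' (nominal error at most +/-20 m); D, E and invalid fixes are discarded.
#'
#' @param fixes Fix tibble with an `accuracy` column.
#' @param quiet Suppress the retention message.
#' @return The retained fixes; a warning is raised if nothing survives.
#' @export
filter_accuracy <- function(fixes, quiet = TRUE) {
  keep <- fixes$accuracy %in% c("A", "B", "C")
  out <- fixes[keep, ]
  if (!quiet)
    message(sum(keep), "/", length(keep), " fixes retained (classes A-C)")
  if (nrow(fixes) > 0 && nrow(out) == 0)
    warning("no fixes with accuracy A-C remain")
  out
}

#' Read a daily station weather table
#'
#' Expects one row per calendar date with the ten station variables (TEMP,
#' DEWP, SLP, STP, VISIB, WDSP, MXSPD, MAX, MIN, PRCP). Station-format
#' sentinel codes for missing data are mapped to `NA` according to a
#' declared dialect; gap dates (absent rows inside the covered span) are
#' recorded in the `gap_dates` attribute. Duplicate dates are a hard
#' error.
#'
#' @param path CSV file path.
#' @param sentinels Named list mapping variable name to its missing-data
#'   sentinel value(s); defaults to the GSOD family (9999.9 for
#'   temperatures and pressures, 999.9 for VISIB/WDSP/MXSPD, 99.99 for
#'   PRCP).
#' @return A date-sorted weather tibble.
#' @export
read_weather <- function(path, sentinels = gsod_sentinels()) {
  w <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("date", weather_vars())
  missing <- setdiff(need, names(w))
  if (length(missing))
    stop("weather table is missing column(s): ",
         paste(missing, collapse = ", "))
  w$date <- as.Date(w$date)
  if (anyNA(w$date)) stop("unparseable weather date")
  if (anyDuplicated(w$date))
    stop("duplicate weather date: ", w$date[anyDuplicated(w$date)])
  w <- w[order(w$date), need]
  for (v in weather_vars()) {
    sent <- sentinels[[v]]
    if (!is.null(sent)) w[[v]][w[[v]] %in% sent] <- NA_real_
  }
  full <- seq(min(w$date), max(w$date), by = "day")
  attr(w, "gap_dates") <- as.Date(setdiff(full, w$date), origin = "1970-01-01")
  tibble::as_tibble(w)
}

weather_vars <- function() {
  c("TEMP", "DEWP", "SLP", "STP", "VISIB", "WDSP", "MXSPD", "MAX", "MIN",
    "PRCP")
}

#' GSOD-style missing-value sentinel dialect
#' @return Named list of sentinel codes per weather variable.
#' @export
gsod_sentinels <- function() {
  list(TEMP = 9999.9, DEWP = 9999.9, SLP = 9999.9, STP = 9999.9,
       VISIB = 999.9, WDSP = 999.9, MXSPD = 999.9, MAX = 9999.9,
       MIN = 9999.9, PRCP = 99.99)
}

#' Write a weather table in the canonical CSV dialect
#' @param weather Weather tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(weather, path) {
  readr::write_csv(weather, path)
  invisible(path)
}

#' Read the individual release metadata table
#'
#' One row per goose: `individual_id`, `species`, `release_site`,
#' `source` (capture/rescue), `tracker` (neck/backpack), `release_year`,
#' `release_time` (ISO-8601 UTC), `weight` (kg > 0).
#'
#' @param path CSV file path.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_guess()))
  if ("individual_id" %in% names(m))
    m$individual_id <- as.character(m$individual_id)
  if ("release_time" %in% names(m) && !inherits(m$release_time, "POSIXct"))
    m$release_time <- as.character(m$release_time)
  need <- c("individual_id", "species", "release_site", "source", "tracker",
            "release_year", "release_time", "weight")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("metadata table is missing column(s): ",
         paste(missing, collapse = ", "))
  m$release_time <- parse_utc_time(m$release_time, "release")
  if (any(m$weight <= 0)) stop("non-positive weight")
  tibble::as_tibble(m[, need])
}
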