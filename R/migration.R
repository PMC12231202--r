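#' Detect the first northward migration departure
#'
#' A departure is called on the first date at which the bird's
#' great-circle displacement from the release-region centroid exceeds
#' `min_displacement_km` with net northward movement, and the excursion is
#' sustained for at least `min_sustain_h` without returning inside the
#' region. The release-region centroid is the median location over the
#' first `ref_days` tracked days (a robust anchor for the wintering site).
#'
#' @param fixes Accuracy-filtered fix tibble for one individual (any
#'   ordering; sorted internally).
#' @param min_displacement_km Displacement threshold (km).
#' @param min_sustain_h Minimum time the bird must stay beyond the
#'   threshold (h).
#' @param ref_days Days of early data defining the release-region centroid.
#' @return A list (`DepartureCall`): `individual_id`, `departure_date`
#'   (Date or `NA`), `method_flags` (character diagnostics), `window_end`
#'   (the departure date when present, otherwise `NA`; the pipeline
#'   substitutes the fate end for non-migrants).
#' @export
detect_departure <- function(fixes, min_displacement_km = 50,
                             min_sustain_h = 48, ref_days = 14) {
  id <- if (nrow(fixes)) fixes$individual_id[1] else NA_character_
  fx <- fixes[!is.na(fixes$longitude) & !is.na(fixes$latitude), ]
  fx <- fx[order(fx$time), ]
  flags <- character()
  if (nrow(fx) < 2 ||
      diff(range(fx$time)) < as.difftime(24, units = "hours")) {
    return(list(individual_id = id, departure_date = as.Date(NA),
                method_flags = "insufficient_data",
                window_end = as.Date(NA)))
  }
  t0 <- min(fx$time)
  ref <- fx[fx$time <= t0 + ref_days * 86400, ]
  c_lon <- stats::median(ref$longitude)
  c_lat <- stats::median(ref$latitude)
  disp <- gc_distance_m(fx$longitude, fx$latitude, c_lon, c_lat) / 1000
  away <- disp > min_displacement_km
  if (!any(away)) {
    return(list(individual_id = id, departure_date = as.Date(NA),
                method_flags = "never_exceeded_threshold",
                window_end = as.Date(NA)))
  }
  # runs of consecutive beyond-threshold fixes; a run qualifies if it spans
  # min_sustain_h and moves net northward over that span
  r <- rle(away)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in which(r$values)) {
    i <- starts[k]; j <- ends[k]
    span_h <- as.numeric(difftime(fx$time[j], fx$time[i], units = "hours"))
    if (span_h < min_sustain_h) next          # returned too soon
    # net northward over the sustained window: north of the wintering
    # centroid and latitude increasing across the first sustain window
    jw <- max(which(fx$time <= fx$time[i] + min_sustain_h * 3600))
    northward <- fx$latitude[jw] > fx$latitude[i] &&
      fx$latitude[jw] > c_lat
    if (northward) {
      dep_date <- local_date(fx$time[i])
      return(list(individual_id = id, departure_date = dep_date,
                  method_flags = "sustained_northward",
                  window_end = dep_date))
    }
  }
  list(individual_id = id, departure_date = as.Date(NA),
       method_flags = "excursions_not_sustained_northward",
       window_end = as.Date(NA))
}

#' Days between release and migration onset (StayDur)
#'
#' Whole days between the release date and the departure date. For birds
#' that never departed (death, loss or censoring first), the duration runs
#' to the fate end date and is flagged as a non-migrant value.
#'
#' @param release_time Release POSIXct (UTC).
#' @param departure_call Output of [detect_departure()].
#' @param fate_end_date Date ending the record for non-migrants.
#' @param tz_offset_h Civil-day offset.
#' @return List with `stay_days` and `migrant` (logical flag).
#' @export
stay_duration <- function(release_time, departure_call,
                          fate_end_date = NULL, tz_offset_h = 8) {
  rel_date <- local_date(release_time, tz_offset_h)
  dep <- departure_call$departure_date
  if (!is.na(dep)) {
    days <- as.integer(dep - rel_date)
    if (days < 0) stop("departure precedes release")
    return(list(stay_days = days, migrant = TRUE))
  }
  if (is.null(fate_end_date) || is.na(fate_end_date))
    stop("non-migrant requires a fate end date")
  days <- as.integer(as.Date(fate_end_date) - rel_date)
  if (days < 0) stop("fate end precedes release")
  list(stay_days = days, migrant = FALSE)
}

#' Mean weather exposure over the 14 days before migration
#'
#' Per-variable arithmetic means over the half-open window
#' `[window_end - span_days, window_end)`; days with a missing value are
#' skipped variable by variable, and a variable missing on every day of
#' the window yields `NA` with a flag.
#'
#' @param weather Daily weather tibble.
#' @param window_end Date ending the window (the departure date for
#'   migrants, the fate end for others).
#' @param span_days Window length in days (default 14).
#' @return List with `means` (named numeric over the ten variables) and
#'   `missing_vars` (character).
#' @export
premigration_weather <- function(weather, window_end, span_days = 14) {
  window_end <- as.Date(window_end)
  w <- weather[weather$date >= window_end - span_days &
                 weather$date < window_end, ]
  vars <- weather_vars()
  means <- vapply(vars, function(v) {
    x <- w[[v]]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  list(means = means, missing_vars = vars[is.na(means)])
}
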