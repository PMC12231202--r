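#' Overall dynamic body acceleration
#'
#' ODBA of a triaxial dynamic-acceleration sample is the sum of the
#' absolute values across the three axes, `|ax| + |ay| + |az|`, in G. The
#' static (gravitational) component must already have been removed; this is
#' what the tag firmware computes before thresholding movement counts.
#'
#' @param accel A numeric matrix or data frame with three columns
#'   (ax, ay, az) in G, one row per sample.
#' @return Numeric vector of ODBA values (G).
#' @export
odba <- function(accel) {
  a <- as.matrix(accel)
  if (ncol(a) != 3) stop("accel must have three columns (ax, ay, az)")
  if (!all(is.finite(a))) stop("non-finite acceleration input")
  rowSums(abs(a))
}

#' Count threshold-exceeding movements per collection cycle
#'
#' Replicates the tag's movement counter: within each collection cycle
#' (1 h by default) the counter increments for every sample whose ODBA
#' strictly exceeds the threshold (0.15 G by default). A sample exactly at
#' the threshold does not count.
#'
#' @param odba_series Numeric ODBA values (G).
#' @param cycle_id Factor/vector assigning each sample to a cycle; a single
#'   cycle is assumed if omitted.
#' @param threshold Exceedance threshold in G (> 0).
#' @return Tibble with `cycle` and `count` (samples above threshold); an
#'   empty cycle contributes a zero count.
#' @export
count_movements <- function(odba_series, cycle_id = NULL, threshold = 0.15) {
  if (threshold <= 0) stop("threshold must be positive")
  if (is.null(cycle_id)) cycle_id <- rep(1L, length(odba_series))
  cyc <- if (is.factor(cycle_id)) cycle_id else factor(cycle_id)
  cnt <- tapply(odba_series > threshold, cyc, sum, default = 0L)
  tibble::tibble(cycle = names(cnt), count = as.integer(cnt))
}

#' Daily activity totals from hourly fixes
#'
#' Sums the hourly movement counts (`exercise_volume`) within each local
#' civil date; the number of distinct hours observed that day is kept so
#' that partial days can be screened later.
#'
#' @param fixes Fix tibble (any accuracy class; the accelerometer channel
#'   is valid regardless of GPS fix quality).
#' @param tz_offset_h Civil-day offset in hours (UTC+8 by default).
#' @return Tibble `individual_id`, `date`, `activity`, `hours_observed`.
#'   Dates with no fixes are simply absent.
#' @export
daily_activity <- function(fixes, tz_offset_h = 8) {
  if (nrow(fixes) == 0)
    return(tibble::tibble(individual_id = character(),
                          date = as.Date(character()),
                          activity = numeric(), hours_observed = integer()))
  d <- fixes
  d$date <- local_date(d$time, tz_offset_h)
  d |>
    dplyr::group_by(individual_id, date) |>
    dplyr::summarise(activity = sum(exercise_volume, na.rm = TRUE),
                     hours_observed = dplyr::n_distinct(
                       format(time, "%Y-%m-%d %H")),
                     .groups = "drop")
}

#' Average daily activity over a window (ActAvg)
#'
#' Arithmetic mean of daily activity totals over dates inside
#' `[window_start, window_end]`, keeping only days with at least
#' `min_hours` observed hours so partial days do not bias the mean
#' downward.
#'
#' @param daily Output of [daily_activity()] for one individual.
#' @param window_start,window_end Dates bounding the window (inclusive).
#' @param min_hours Minimum observed hours for a day to qualify
#'   (default 20).
#' @return The mean daily activity (counts/day).
#' @export
activity_average <- function(daily, window_start, window_end,
                             min_hours = 20) {
  if (as.Date(window_end) < as.Date(window_start))
    stop("empty activity window")
  keep <- daily$date >= as.Date(window_start) &
    daily$date <= as.Date(window_end) &
    daily$hours_observed >= min_hours
  if (!any(keep))
    stop("no qualifying days in activity window",
         if (nrow(daily)) paste0(" for ", daily$individual_id[1]) else "")
  mean(daily$activity[keep])
}
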