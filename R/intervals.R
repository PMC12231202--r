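# Interval finders for the three mortality criteria. Convention: an hourly
# record covers the hour starting at its timestamp, so a run of k
# consecutive satisfying records spans k hours; intervals are reported as
# [start, end) with end = last timestamp + 1 h. A gap longer than
# `max_gap_h` between consecutive records breaks continuity for the sensor
# criteria (thermal, quiescence); positional gaps do not break confinement
# because an unlocated bird gives no evidence of leaving the circle.

interval_tibble <- function(start = as.POSIXct(character(), tz = "UTC"),
                            end = as.POSIXct(character(), tz = "UTC")) {
  tibble::tibble(start = start, end = end,
                 duration_h = as.numeric(difftime(end, start, units = "hours")))
}

# maximal runs of ok == TRUE over an (almost) hourly timeline
runs_to_intervals <- function(times, ok, dur_h, max_gap_h = 1) {
  stopifnot(length(times) == length(ok))
  if (length(times) == 0) return(interval_tibble())
  o <- order(times)
  times <- times[o]; ok <- ok[o]
  gap_break <- c(FALSE, diff(as.numeric(times)) / 3600 > max_gap_h)
  grp <- cumsum(!ok | gap_break)
  keep <- which(ok)
  if (!length(keep)) return(interval_tibble())
  spl <- split(keep, grp[keep])
  starts <- as.POSIXct(vapply(spl, function(ix) as.numeric(times[ix[1]]),
                              numeric(1)), origin = "1970-01-01", tz = "UTC")
  ends <- as.POSIXct(vapply(spl, function(ix) as.numeric(times[ix[length(ix)]]) + 3600,
                            numeric(1)), origin = "1970-01-01", tz = "UTC")
  iv <- interval_tibble(starts, ends)
  iv[iv$duration_h >= dur_h, ]
}

#' Thermal-equilibration intervals
#'
#' Maximal continuous intervals during which the device temperature stays
#' within `tol` degC of ambient (inclusive bound) for at least `dur_h`
#' hours. Ambient is the station daily mean interpolated to hourly (see
#' [ambient_hourly()]); hours with missing ambient are excluded and
#' flagged.
#'
#' @param device_temp Hourly device temperatures (degC).
#' @param ambient Hourly ambient temperatures aligned with `device_temp`.
#' @param times POSIXct timestamps of the hourly series.
#' @param tol Tolerance in degC (default 2, inclusive).
#' @param dur_h Minimum duration in hours (default 72).
#' @return Interval tibble (`start`, `end`, `duration_h`).
#' @export
thermal_equilibration <- function(device_temp, ambient, times, tol = 2,
                                  dur_h = 72) {
  ok <- !is.na(device_temp) & !is.na(ambient) &
    abs(device_temp - ambient) <= tol
  runs_to_intervals(times, ok, dur_h)
}

#' Behavioural-quiescence intervals
#'
#' Maximal intervals with hourly movement counts strictly below
#' `max_count` for at least `dur_h` consecutive hours.
#'
#' @param counts Hourly movement counts.
#' @param times POSIXct timestamps of the hourly series.
#' @param max_count Strict upper bound (default 10: a count of exactly 10
#'   breaks the run).
#' @param dur_h Minimum duration in hours (default 24).
#' @return Interval tibble.
#' @export
quiescence <- function(counts, times, max_count = 10, dur_h = 24) {
  ok <- !is.na(counts) & counts < max_count
  runs_to_intervals(times, ok, dur_h)
}

#' Spatial-confinement intervals
#'
#' Maximal intervals during which every located fix lies within `radius_m`
#' (great-circle) of some anchor fix in the interval — the interval's
#' medoid in the minimax sense — lasting at least `dur_h` hours. Intervals
#' with fewer than three fixes are not evaluable.
#'
#' The search anchors each fix in turn and extends the contiguous run of
#' fixes within `radius_m` of it in both directions; maximal satisfied
#' intervals are the non-nested such runs. This agrees with an exhaustive
#' scan over all start/end pairs (checked in the test suite by brute
#' force).
#'
#' @param fixes Accuracy-filtered fix tibble (positions present).
#' @param radius_m Confinement radius in metres (default 200).
#' @param dur_h Minimum duration in hours (default 72).
#' @return Interval tibble.
#' @export
confinement <- function(fixes, radius_m = 200, dur_h = 72) {
  fx <- fixes[!is.na(fixes$longitude) & !is.na(fixes$latitude), ]
  fx <- fx[order(fx$time), ]
  n <- nrow(fx)
  if (n < 3) return(interval_tibble())
  pr <- project_aeqd(fx$longitude, fx$latitude)
  x <- pr$x; y <- pr$y
  r2 <- radius_m^2
  # candidate prefilter: an anchor can only seed a long run if its close
  # neighbourhood is non-trivial; cheap check on immediate neighbours
  L <- integer(n); R <- integer(n)
  for (a in seq_len(n)) {
    i <- a
    while (i > 1 && (x[i - 1] - x[a])^2 + (y[i - 1] - y[a])^2 <= r2) i <- i - 1
    j <- a
    while (j < n && (x[j + 1] - x[a])^2 + (y[j + 1] - y[a])^2 <= r2) j <- j + 1
    L[a] <- i; R[a] <- j
  }
  span_h <- as.numeric(difftime(fx$time[R], fx$time[L], units = "hours")) + 1
  cand <- which(span_h >= dur_h & (R - L + 1) >= 3)
  if (!length(cand)) return(interval_tibble())
  # drop runs nested inside another run
  iv <- unique(data.frame(L = L[cand], R = R[cand]))
  keep <- rep(TRUE, nrow(iv))
  ord <- order(iv$L, -iv$R)
  iv <- iv[ord, ]
  best_r <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv$R[k] <= best_r) keep[k] <- FALSE else best_r <- iv$R[k]
  }
  iv <- iv[keep, ]
  out <- interval_tibble(fx$time[iv$L], fx$time[iv$R] + 3600)
  out[out$duration_h >= dur_h, ]
}

# pairwise intersection of two interval sets
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(interval_tibble())
  res <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a$start[i], b$start)
    e <- pmin(a$end[i], b$end)
    ok <- which(e > s)
    if (length(ok)) res[[length(res) + 1]] <- interval_tibble(s[ok], e[ok])
  }
  if (!length(res)) return(interval_tibble())
  out <- dplyr::bind_rows(res)
  out[order(out$start), ]
}
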