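#' Default thresholds for mortality determination
#'
#' The three simultaneous criteria for biologically confirmed mortality
#' (thermal equilibration within +/-2 degC for >= 72 h, behavioural
#' quiescence < 10 counts/h for >= 24 h, spatial confinement within 200 m
#' for >= 72 h), the hunting/abrupt-loss gap, and the 365-day
#' right-censoring horizon.
#'
#' @return Named list of thresholds.
#' @export
mortality_params <- function() {
  list(thermal_tol_c = 2, thermal_dur_h = 72,
       quiesc_max_count = 10, quiesc_dur_h = 24,
       conf_radius_m = 200, conf_dur_h = 72,
       abrupt_gap_h = 72, decline_window_h = 72,
       horizon_days = 365)
}

#' Joint decline trend in activity, altitude and speed
#'
#' TRUE when all three series (hourly movement counts, altitude, movement
#' speed) show a robust negative linear trend over the `window_h` hours
#' before `eval_time`: Theil-Sen slope < 0 together with a one-sided
#' Mann-Kendall test at `alpha`. The conjunction keeps the false-positive
#' rate on flat series negligible.
#'
#' @param fixes Hourly fix tibble for one individual.
#' @param eval_time Evaluation instant (default: last fix).
#' @param window_h Trend window in hours (default 72).
#' @param alpha Significance level per series.
#' @return List with `decline` (logical) and `flags`.
#' @export
decline_trend <- function(fixes, eval_time = NULL, window_h = 72,
                          alpha = 0.05) {
  if (is.null(eval_time)) eval_time <- max(fixes$time)
  w <- fixes[fixes$time >= eval_time - window_h * 3600 &
               fixes$time < eval_time, ]
  if (nrow(w) < 12)
    return(list(decline = FALSE, flags = "insufficient_data"))
  tnum <- as.numeric(w$time) / 3600
  neg <- vapply(list(w$exercise_volume, w$altitude, w$speed), function(yy) {
    ok <- is.finite(yy)
    if (sum(ok) < 12) return(FALSE)
    theil_sen_slope(tnum[ok], yy[ok]) < 0 &&
      kendall_trend_p(tnum[ok], yy[ok]) < alpha
  }, logical(1))
  list(decline = all(neg), flags = character())
}

theil_sen_slope <- function(t, y) {
  n <- length(t)
  # subsample pair slopes for long windows; exact below 200 points
  if (n > 200) {
    i <- sample.int(n, 200)
    t <- t[i]; y <- y[i]; n <- 200
  }
  dt <- outer(t, t, "-")
  dy <- outer(y, y, "-")
  sel <- upper.tri(dt) & dt != 0
  stats::median(dy[sel] / dt[sel])
}

kendall_trend_p <- function(t, y) {
  suppressWarnings(
    stats::cor.test(t, y, method = "kendall", alternative = "less",
                    exact = FALSE)$p.value)
}

#' Detect hunting-like abrupt signal loss
#'
#' TRUE when the transmission stream terminates (or leaves a gap of at
#' least `gap_h` hours against the monitoring end) from a state with no
#' preceding joint decline trend. The death-signature check (triple
#' criterion overlap) is left to [classify_mortality()], which gives
#' precedence to the earlier event when both fire.
#'
#' @param fixes Hourly fix tibble for one individual.
#' @param monitor_end Expected end of monitoring (release + horizon).
#' @param gap_h Terminal gap defining abrupt loss (default 72).
#' @return List with `abrupt` (logical), `last_time`, `flags`.
#' @export
detect_abrupt_loss <- function(fixes, monitor_end, gap_h = 72) {
  if (nrow(fixes) == 0)
    return(list(abrupt = FALSE, last_time = as.POSIXct(NA, tz = "UTC"),
                flags = "no_data"))
  last_t <- max(fixes$time)
  truncated <- as.numeric(difftime(monitor_end, last_t, units = "hours")) >= gap_h
  if (!truncated)
    return(list(abrupt = FALSE, last_time = last_t, flags = character()))
  dec <- decline_trend(fixes, eval_time = last_t + 3600)
  list(abrupt = !dec$decline, last_time = last_t,
       flags = if (dec$decline) "terminal_decline_present" else character())
}

#' Classify an individual's fate from its telemetry
#'
#' Applies the rule-based mortality determination: biologically confirmed
#' death requires the thermal-equilibration, quiescence and
#' spatial-confinement intervals to overlap, with the death time taken as
#' the start of the earliest triple overlap; an abrupt terminal signal
#' loss without a death signature is classed as hunting or tag loss (and
#' right-censored at the last valid fix); everything else is censored at
#' the last fix or the horizon. Survival time runs from release to the
#' death time (or censoring point) in days, truncated at the horizon.
#'
#' Sensor criteria (thermal, quiescence) use the full hourly record; the
#' confinement criterion uses accuracy-filtered (A-C) positions.
#'
#' @param fixes Hourly fix tibble for one individual (all accuracy
#'   classes).
#' @param weather Daily weather tibble (ambient source).
#' @param release_time Release POSIXct (UTC).
#' @param params Thresholds, see [mortality_params()].
#' @return A `FateRecord` list: `individual_id`, `fate`
#'   (`dead_confirmed`/`hunting_or_loss`/`censored`), `survival_days`,
#'   `event`, `death_time`, `criteria` (interval tibbles), `flags`.
#' @export
classify_mortality <- function(fixes, weather, release_time,
                               params = mortality_params()) {
  id <- if (nrow(fixes)) fixes$individual_id[1] else NA_character_
  fixes <- fixes[order(fixes$time), ]
  monitor_end <- release_time + params$horizon_days * 86400
  amb <- ambient_hourly(weather, fixes$time)
  th <- thermal_equilibration(fixes$device_temp, amb, fixes$time,
                              tol = params$thermal_tol_c,
                              dur_h = params$thermal_dur_h)
  qu <- quiescence(fixes$exercise_volume, fixes$time,
                   max_count = params$quiesc_max_count,
                   dur_h = params$quiesc_dur_h)
  cf <- confinement(filter_accuracy(fixes),
                    radius_m = params$conf_radius_m,
                    dur_h = params$conf_dur_h)
  triple <- intersect_intervals(intersect_intervals(th, qu), cf)
  loss <- detect_abrupt_loss(fixes, monitor_end,
                             gap_h = params$abrupt_gap_h)
  flags <- character()

  death_time <- as.POSIXct(NA, tz = "UTC")
  if (nrow(triple) > 0) death_time <- min(triple$start)

  fate <- "censored"
  if (!is.na(death_time) &&
      death_time <= max(fixes$time) + 3600) {        # precedes termination
    fate <- "dead_confirmed"
    if (loss$abrupt && loss$last_time < death_time) {
      # contradictory: earlier abrupt loss wins
      fate <- "hunting_or_loss"
      flags <- c(flags, "overlap_after_abrupt_loss")
      death_time <- as.POSIXct(NA, tz = "UTC")
    }
  } else if (loss$abrupt) {
    fate <- "hunting_or_loss"
  } else {
    miss <- c("thermal", "quiescence", "confinement")[
      c(nrow(th) == 0, nrow(qu) == 0, nrow(cf) == 0)]
    if (length(miss))
      flags <- c(flags, paste0("criteria_unmet:",
                               paste(miss, collapse = "+")))
  }

  end_point <- switch(fate,
                      dead_confirmed = death_time,
                      hunting_or_loss = loss$last_time,
                      censored = max(fixes$time))
  surv <- as.numeric(difftime(end_point, release_time, units = "days"))
  surv <- min(surv, params$horizon_days)
  if (fate != "dead_confirmed" && surv >= params$horizon_days)
    surv <- params$horizon_days
  list(individual_id = id, fate = fate,
       survival_days = surv,
       event = as.integer(fate == "dead_confirmed"),
       death_time = death_time,
       criteria = list(thermal = th, quiescence = qu, confinement = cf,
                       triple_overlap = triple),
       flags = flags)
}
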