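#' Simulate a GPS-tracked goose cohort with known ground truth
#'
#' Generates hourly multi-sensor telemetry, daily station weather and
#' release metadata for a cohort whose true fates are known, so every
#' downstream stage (activity, departure detection, mortality
#' classification, home ranges, survival models) can be validated against
#' truth.
#'
#' Fate signatures follow the field patterns the classifier looks for:
#' natural deaths are preceded by a 72-h monotone decline in hourly
#' movement counts, altitude and speed (linear-in-mean with multiplicative
#' noise), then a post-mortem phase in which the device temperature tracks
#' ambient within a fraction of a degree, counts drop to near zero and
#' positions stay within tens of metres, lasting 120 h before the
#' transmitter falls silent. Hunting or tag loss truncates the stream
#' abruptly from a normal-activity state. Surviving migrants show a
#' sustained northward displacement starting at their true departure date;
#' censored residents transmit for the full horizon.
#'
#' @param config A [scenario_config()].
#' @return A list with `fixes` (one tibble of hourly fixes for the whole
#'   cohort), `weather` (daily station table), `meta` (release metadata)
#'   and `truth` (a list: `individuals` tibble with true fate, death time,
#'   departure date and latent covariates; `daily_activity` tibble;
#'   `hazard` — the generating coefficients).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  weather <- simulate_weather(config)

  n <- config$n_individuals
  if (n == 0) {
    return(list(fixes = empty_fix_table(), weather = weather,
                meta = empty_meta_table(),
                truth = list(individuals = tibble::tibble(
                  individual_id = character(), fate = character(),
                  death_time = as.POSIXct(character(), tz = "UTC"),
                  departure_date = as.Date(character()),
                  z_act = numeric(), z_wdsp = numeric()),
                  daily_activity = tibble::tibble(
                    individual_id = character(), date = as.Date(character()),
                    activity = numeric()),
                  hazard = config$hazard_spec)))
  }

  ids <- sprintf("G%03d", seq_len(n))
  counts <- apportion(n, config$fate_mix)
  fate <- sample(rep(names(counts), counts))

  sites <- list(Duchang = c(lon = 116.18, lat = 29.27),
                Nanjishan = c(lon = 116.37, lat = 28.87))
  meta <- tibble::tibble(
    individual_id = ids,
    species = sample(c("A. serrirostris serrirostris", "A. albifrons"), n,
                     replace = TRUE, prob = c(25, 12)),
    release_site = sample(names(sites), n, replace = TRUE, prob = c(20, 17)),
    source = sample(c("capture", "rescue"), n, replace = TRUE,
                    prob = c(30, 7)),
    tracker = sample(c("neck", "backpack"), n, replace = TRUE,
                     prob = c(17, 20)),
    release_year = as.integer(format(config$start_date, "%Y")),
    release_time = as.POSIXct(paste(config$start_date, "02:00:00"),
                              tz = "UTC") +
      3600 * sample(0:47, n, replace = TRUE),
    weight = round(pmax(2.0, stats::rnorm(n, 3.0, 0.35)), 2)
  )

  hz <- config$hazard_spec
  z_act <- stats::rnorm(n)
  z_wdsp <- stats::rnorm(n)
  lambda <- hz$baseline * exp(hz$beta_actavg * z_act + hz$beta_wdsp * z_wdsp)

  horizon <- config$horizon_days
  death_time <- rep(as.POSIXct(NA, tz = "UTC"), n)
  departure_date <- rep(as.Date(NA), n)
  end_time <- meta$release_time + horizon * 86400

  fix_list <- vector("list", n)
  truth_act <- vector("list", n)
  for (i in seq_len(n)) {
    rel <- meta$release_time[i]
    site <- sites[[meta$release_site[i]]]
    if (fate[i] == "natural_death") {
      # conditional exponential death time in [7, horizon] days
      lo <- 7; hi <- horizon
      u <- stats::runif(1)
      Flo <- 1 - exp(-lambda[i] * lo); Fhi <- 1 - exp(-lambda[i] * hi)
      td <- -log(1 - (Flo + u * (Fhi - Flo))) / lambda[i]
      death_time[i] <- rel + round(td * 24) * 3600
      end_time[i] <- death_time[i] + 120 * 3600
    } else if (fate[i] == "hunting_loss") {
      tl <- stats::runif(1, 10, 0.9 * horizon)
      end_time[i] <- rel + round(tl * 24) * 3600
    } else if (fate[i] == "survivor_migrant") {
      dep_days <- round(stats::runif(1, 45, 90))
      departure_date[i] <- as.Date(rel) + dep_days
      end_time[i] <- rel + horizon * 86400
    }
    sim <- simulate_track(rel, end_time[i], site, fate[i], death_time[i],
                          departure_date[i], z_act[i], config, weather)
    sim$fixes$individual_id <- ids[i]
    fix_list[[i]] <- sim$fixes
    truth_act[[i]] <- tibble::tibble(individual_id = ids[i],
                                     date = sim$daily$date,
                                     activity = sim$daily$activity)
  }

  fixes <- dplyr::bind_rows(fix_list)
  fixes <- inject_accuracy_noise(fixes, config$noise_spec$acc_mix,
                                 config$noise_spec$jitter_sd_m)
  fixes <- fixes[, fix_columns()]

  truth <- list(
    individuals = tibble::tibble(individual_id = ids, fate = fate,
                                 death_time = death_time,
                                 departure_date = departure_date,
                                 z_act = z_act, z_wdsp = z_wdsp),
    daily_activity = dplyr::bind_rows(truth_act),
    hazard = hz)
  list(fixes = fixes, weather = weather, meta = meta, truth = truth)
}

fix_columns <- function() {
  c("individual_id", "time", "longitude", "latitude", "speed", "heading",
    "altitude", "exercise_volume", "device_temp", "voltage", "accuracy")
}

empty_fix_table <- function() {
  tibble::tibble(individual_id = character(),
                 time = as.POSIXct(character(), tz = "UTC"),
                 longitude = numeric(), latitude = numeric(),
                 speed = numeric(), heading = numeric(),
                 altitude = numeric(), exercise_volume = integer(),
                 device_temp = numeric(), voltage = numeric(),
                 accuracy = character())
}

empty_meta_table <- function() {
  tibble::tibble(individual_id = character(), species = character(),
                 release_site = character(), source = character(),
                 tracker = character(), release_year = integer(),
                 release_time = as.POSIXct(character(), tz = "UTC"),
                 weight = numeric())
}

# One individual's hourly series. Phases: resident (OU walk around the
# release site), decline (last 72 h before a natural death), dead (post-
# mortem transmission), migrating (10-day northward push), settled
# (breeding-area residency).
simulate_track <- function(release_time, end_time, site, fate, death_time,
                           departure_date, z_act, config, weather) {
  times <- seq(release_time, end_time, by = 3600)
  nh <- length(times)
  act <- config$activity_spec

  phase <- rep("resident", nh)
  if (fate == "natural_death") {
    phase[times >= death_time] <- "dead"
    phase[times >= death_time - 72 * 3600 & times < death_time] <- "decline"
  } else if (fate == "survivor_migrant") {
    dep_t <- as.POSIXct(paste(departure_date, "00:00:00"), tz = "UTC")
    phase[times >= dep_t & times < dep_t + 10 * 86400] <- "migrating"
    phase[times >= dep_t + 10 * 86400] <- "settled"
  }

  # hourly movement counts: diurnal foraging/roosting, individual
  # propensity exp(propensity_log_sd * z_act), linear-in-mean decline with
  # multiplicative noise, near-zero post-mortem
  hr_local <- as.integer(format(times + 8 * 3600, "%H", tz = "UTC"))
  day <- hr_local >= 7 & hr_local <= 18
  mu <- ifelse(day, act$day_mean, act$night_mean) *
    exp(act$propensity_log_sd * z_act)
  sdv <- ifelse(day, act$day_sd, act$night_sd)
  counts <- pmax(0, round(stats::rnorm(nh, mu, sdv)))
  dec <- phase == "decline"
  if (any(dec)) {
    frac <- 1 - (cumsum(dec)[dec] / (sum(dec) + 1))   # 1 -> ~0 across window
    counts[dec] <- pmax(0, round(mu[dec] * frac * exp(stats::rnorm(sum(dec), 0, 0.3))))
  }
  counts[phase == "dead"] <- stats::rpois(sum(phase == "dead"), 0.3)

  # positions
  lon <- numeric(nh); lat <- numeric(nh)
  x <- numeric(nh); y <- numeric(nh)   # metres relative to site centre
  resident_like <- phase %in% c("resident", "settled")
  step_sd <- 600
  xx <- 0; yy <- 0
  dead_xy <- NULL
  mig_rate_lat <- 2.0 / 24   # degrees north per hour while migrating
  lat0 <- site["lat"]; lon0 <- site["lon"]
  cur_lat <- lat0; cur_lon <- lon0
  settled_anchor <- NULL
  dec_idx <- which(dec)
  for (t in seq_len(nh)) {
    ph <- phase[t]
    if (ph == "resident") {
      xx <- 0.85 * xx + stats::rnorm(1, 0, step_sd)
      yy <- 0.85 * yy + stats::rnorm(1, 0, step_sd)
      cur_lon <- lon0 + xx / (111320 * cos(lat0 * pi / 180))
      cur_lat <- lat0 + yy / 111320
    } else if (ph == "decline") {
      if (is.null(dead_xy)) dead_xy <- c(xx, yy)
      k <- match(t, dec_idx)
      r <- 800 * (1 - k / length(dec_idx)) + 30
      cur_lon <- lon0 + (dead_xy[1] + stats::rnorm(1, 0, r)) /
        (111320 * cos(lat0 * pi / 180))
      cur_lat <- lat0 + (dead_xy[2] + stats::rnorm(1, 0, r)) / 111320
    } else if (ph == "dead") {
      if (is.null(dead_xy)) dead_xy <- c(xx, yy)
      cur_lon <- lon0 + (dead_xy[1] + stats::rnorm(1, 0, 15)) /
        (111320 * cos(lat0 * pi / 180))
      cur_lat <- lat0 + (dead_xy[2] + stats::rnorm(1, 0, 15)) / 111320
    } else if (ph == "migrating") {
      cur_lat <- cur_lat + mig_rate_lat + stats::rnorm(1, 0, 0.01)
      cur_lon <- cur_lon + 0.3 / 24 + stats::rnorm(1, 0, 0.01)
    } else { # settled
      if (is.null(settled_anchor)) { settled_anchor <- c(cur_lon, cur_lat); xx <- 0; yy <- 0 }
      xx <- 0.85 * xx + stats::rnorm(1, 0, step_sd)
      yy <- 0.85 * yy + stats::rnorm(1, 0, step_sd)
      cur_lon <- settled_anchor[1] + xx / (111320 * cos(settled_anchor[2] * pi / 180))
      cur_lat <- settled_anchor[2] + yy / 111320
    }
    lon[t] <- cur_lon; lat[t] <- cur_lat
  }

  altitude <- stats::rnorm(nh, 20, 8)
  altitude[phase == "migrating"] <- stats::rnorm(sum(phase == "migrating"), 500, 150)
  if (any(dec)) {
    frac <- 1 - (cumsum(dec)[dec] / (sum(dec) + 1))
    altitude[dec] <- pmax(0.5, 20 * frac * exp(stats::rnorm(sum(dec), 0, 0.2)))
  }
  altitude[phase == "dead"] <- abs(stats::rnorm(sum(phase == "dead"), 1, 0.5))
  altitude <- pmax(0, altitude)

  speed <- abs(ifelse(day, stats::rnorm(nh, 1.2, 0.8), stats::rnorm(nh, 0.3, 0.2)))
  speed[phase == "migrating"] <- abs(stats::rnorm(sum(phase == "migrating"), 16, 3))
  if (any(dec)) {
    frac <- 1 - (cumsum(dec)[dec] / (sum(dec) + 1))
    speed[dec] <- pmax(0.01, 1.2 * frac * exp(stats::rnorm(sum(dec), 0, 0.3)))
  }
  speed[phase == "dead"] <- abs(stats::rnorm(sum(phase == "dead"), 0.02, 0.02))

  amb <- ambient_hourly(weather, times)
  device_temp <- stats::rnorm(nh, 40.5, 0.4)
  idx_dead <- phase == "dead"
  device_temp[idx_dead] <- amb[idx_dead] + stats::rnorm(sum(idx_dead), 0, 0.5)

  voltage <- round(4.15 - 0.0004 * (seq_len(nh) / 24) + stats::rnorm(nh, 0, 0.03), 3)
  heading <- stats::runif(nh, 0, 360)

  fixes <- tibble::tibble(time = times, longitude = lon, latitude = lat,
                          speed = round(speed, 3),
                          heading = round(heading, 1),
                          altitude = round(altitude, 1),
                          exercise_volume = as.integer(counts),
                          device_temp = round(device_temp, 2),
                          voltage = voltage)
  d <- local_date(times)
  daily <- tibble::tibble(date = d, counts = counts) |>
    dplyr::group_by(date) |>
    dplyr::summarise(activity = sum(counts), .groups = "drop")
  list(fixes = fixes, daily = daily)
}

#' Assign GPS accuracy classes and positional error to fixes
#'
#' Each fix draws an accuracy class from `mixture`; its coordinates are
#' jittered with a Gaussian of the class's nominal error SD, and `invalid`
#' fixes (no position obtained) get missing coordinates. Sensor channels
#' (counts, temperature, voltage) are untouched: the accelerometer and
#' thermometer record regardless of GPS fix quality.
#'
#' @param fixes Fix tibble with `longitude`, `latitude`.
#' @param mixture Named probabilities over `A,B,C,D,E,invalid`; must sum
#'   to 1.
#' @param jitter_sd_m Named per-class jitter SD in metres (classes A-E).
#' @return The fixes with `accuracy` set and positions perturbed.
#' @export
inject_accuracy_noise <- function(fixes,
                                  mixture = c(A = 0.45, B = 0.30, C = 0.15,
                                              D = 0.06, E = 0.03,
                                              invalid = 0.01),
                                  jitter_sd_m = c(A = 5, B = 10, C = 20,
                                                  D = 100, E = 2000)) {
  classes <- c("A", "B", "C", "D", "E", "invalid")
  if (!setequal(names(mixture), classes))
    stop("mixture must be named over classes A, B, C, D, E, invalid")
  mixture <- mixture[classes]
  if (abs(sum(mixture) - 1) > 1e-8) stop("accuracy mixture must sum to 1")
  n <- nrow(fixes)
  cls <- sample(classes, n, replace = TRUE, prob = mixture)
  sd_m <- unname(jitter_sd_m[cls])
  sd_m[cls == "invalid"] <- NA_real_
  m_per_deg_lat <- 111320
  m_per_deg_lon <- 111320 * cos(fixes$latitude * pi / 180)
  jx <- stats::rnorm(n, 0, 1) * sd_m
  jy <- stats::rnorm(n, 0, 1) * sd_m
  out <- fixes
  out$longitude <- fixes$longitude + jx / m_per_deg_lon
  out$latitude <- fixes$latitude + jy / m_per_deg_lat
  out$longitude[cls == "invalid"] <- NA_real_
  out$latitude[cls == "invalid"] <- NA_real_
  out$accuracy <- cls
  out
}

#' Simulate a daily station weather table
#'
#' Annual-sinusoid seasonal means with day-to-day Gaussian noise for the
#' ten station variables, spanning 20 days before release to 40 days past
#' the horizon so 14-day windows and hourly interpolation never run off the
#' table.
#'
#' @param config A [scenario_config()].
#' @return A daily weather tibble (`date`, TEMP, DEWP, SLP, STP, VISIB,
#'   WDSP, MXSPD, MAX, MIN, PRCP), metric units.
#' @export
simulate_weather <- function(config) {
  ws <- config$weather_spec
  dates <- seq(config$start_date - 20,
               config$start_date + config$horizon_days + 40, by = "day")
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- cos(2 * pi * (doy - ws$peak_doy) / 365.25)
  TEMP <- ws$TEMP$mean + ws$TEMP$amp * seasonal + stats::rnorm(nd, 0, ws$TEMP$sd)
  DEWP <- TEMP + ws$DEWP_offset$mean + stats::rnorm(nd, 0, ws$DEWP_offset$sd)
  MAX <- TEMP + abs(stats::rnorm(nd, ws$MAXMIN_spread$up, ws$MAXMIN_spread$sd))
  MIN <- TEMP - abs(stats::rnorm(nd, ws$MAXMIN_spread$down, ws$MAXMIN_spread$sd))
  SLP <- ws$SLP$mean + ws$SLP$amp * seasonal + stats::rnorm(nd, 0, ws$SLP$sd)
  STP <- SLP + ws$STP_offset$mean + stats::rnorm(nd, 0, ws$STP_offset$sd)
  VISIB <- pmax(ws$VISIB$min, stats::rnorm(nd, ws$VISIB$mean, ws$VISIB$sd))
  WDSP <- pmax(ws$WDSP$min, stats::rnorm(nd, ws$WDSP$mean, ws$WDSP$sd))
  MXSPD <- WDSP + abs(stats::rnorm(nd, ws$MXSPD_gap$mean, ws$MXSPD_gap$sd))
  wet <- stats::runif(nd) > ws$PRCP$p_dry
  PRCP <- ifelse(wet, stats::rexp(nd, 1 / ws$PRCP$mean_wet), 0)
  tibble::tibble(date = dates,
                 TEMP = round(TEMP, 1), DEWP = round(DEWP, 1),
                 SLP = round(SLP, 1), STP = round(STP, 1),
                 VISIB = round(VISIB, 1), WDSP = round(WDSP, 1),
                 MXSPD = round(MXSPD, 1), MAX = round(MAX, 1),
                 MIN = round(MIN, 1), PRCP = round(PRCP, 2))
}

#' Hourly ambient temperature interpolated from daily station means
#'
#' Linear interpolation of the daily TEMP series, anchoring each daily mean
#' at local noon (UTC+8). The mortality classifier uses the same
#' convention, so a post-mortem device temperature that tracks ambient
#' stays within the +/-2 degC criterion.
#'
#' @param weather Daily weather tibble with `date` and `TEMP`.
#' @param times POSIXct (UTC) instants to interpolate at.
#' @param tz_offset_h Civil-day offset defining local noon.
#' @return Numeric ambient temperature at `times` (degC).
#' @export
ambient_hourly <- function(weather, times, tz_offset_h = 8) {
  anchor <- as.POSIXct(paste(weather$date, "12:00:00"), tz = "UTC") -
    tz_offset_h * 3600
  stats::approx(as.numeric(anchor), weather$TEMP, xout = as.numeric(times),
                rule = 2)$y
}

#' Draw per-individual survival rows from the covariate-hazard link
#'
#' The covariate-level generator behind the cohort's natural-death times:
#' standardized activity (ActAvg) and wind-speed (WDSP) covariates drawn
#' iid N(0,1), an exponential baseline hazard scaled by
#' `exp(beta_actavg * ActAvg + beta_wdsp * WDSP)`, and right-censoring at
#' `horizon` days. Used to study recovery of the generating hazard ratios
#' by the native Cox fitter without simulating terabytes of telemetry.
#'
#' @param n Number of individuals.
#' @param beta Length-2 log-hazard coefficients (ActAvg, WDSP).
#' @param baseline Baseline hazard, events/day.
#' @param horizon Censoring horizon in days.
#' @param seed Optional integer seed.
#' @return Tibble with `individual_id`, `ActAvg`, `WDSP`, `survival_days`,
#'   `event`.
#' @export
simulate_hazard_rows <- function(n, beta = c(log(0.461), log(2.311)),
                                 baseline = 0.002, horizon = 365,
                                 seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
  }
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  lambda <- baseline * exp(beta[1] * z1 + beta[2] * z2)
  t_death <- stats::rexp(n, lambda)
  event <- as.integer(t_death <= horizon)
  tibble::tibble(individual_id = sprintf("S%04d", seq_len(n)),
                 ActAvg = z1, WDSP = z2,
                 survival_days = pmin(t_death, horizon),
                 event = event)
}
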