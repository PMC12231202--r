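#' Pipeline configuration
#'
#' Collects every analysis threshold in one validated place so each run
#' can carry its full provenance: accuracy filter classes, the mortality
#' criteria, the censoring horizon, the departure rule, activity
#' screening, home-range estimation, the Moran's I weight scheme and the
#' model-selection controls. Unknown keys are rejected up front.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    accuracy_classes = c("A", "B", "C"),
    mortality = mortality_params(),
    departure_min_km = 50,
    departure_sustain_h = 48,
    activity_min_hours = 20,
    kde_bandwidth_m = "silverman",
    moran_scheme = "inverse_distance",
    moran_n_perm = 999,
    vif_threshold = 5,
    aic_delta = 2,
    tz_offset_h = 8,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown pipeline_config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  num_keys <- c("departure_min_km", "departure_sustain_h",
                "activity_min_hours", "vif_threshold", "aic_delta")
  for (kk in num_keys) if (cfg[[kk]] <= 0) stop(kk, " must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Run the full survival pipeline
#'
#' From raw tables to the report bundle: accuracy filtering, daily
#' activity and ActAvg, departure detection and StayDur, 14-day
#' pre-migration weather exposure, fate classification with hunting
#' exclusion and 365-day censoring, per-individual home ranges, spatial
#' clustering and Moran's I on survival times, Kaplan-Meier curves with
#' log-rank tests for each study-design factor, and VIF-screened
#' all-subsets Cox model selection.
#'
#' @param fixes Cohort fix tibble (all accuracy classes).
#' @param weather Daily weather tibble.
#' @param meta Release metadata tibble.
#' @param config A [pipeline_config()].
#' @return A list: `covariates` (per-individual analysis rows), `fates`,
#'   `km` (per-factor curves and log-rank results), `spatial` (home
#'   ranges, clustering, Moran's I), `cox` (VIF screen, model table,
#'   final fit, Schoenfeld tests), `config`.
#' @export
run_pipeline <- function(fixes, weather, meta, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- meta$individual_id
  tz <- config$tz_offset_h
  rows <- vector("list", length(ids))
  fates <- vector("list", length(ids))
  hr_list <- vector("list", length(ids))
  pre_fixes <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    id <- ids[i]
    fx <- fixes[fixes$individual_id == id, ]
    fx <- fx[order(fx$time), ]
    if (nrow(fx) == 0)
      stop("pipeline stage 'ingest' failed: no fixes for individual ", id)
    rel_t <- meta$release_time[i]
    rel_date <- local_date(rel_t, tz)
    fxf <- filter_accuracy(fx)

    fr <- tryCatch(
      classify_mortality(fx, weather, rel_t, config$mortality),
      error = function(e) stop("pipeline stage 'mortality' failed for ",
                               id, ": ", conditionMessage(e)))
    dep <- detect_departure(fxf, min_displacement_km = config$departure_min_km,
                            min_sustain_h = config$departure_sustain_h)
    fate_end <- local_date(max(fx$time), tz)
    if (fr$fate == "dead_confirmed") fate_end <- local_date(fr$death_time, tz)
    stay <- stay_duration(rel_t, dep, fate_end_date = fate_end, tz_offset_h = tz)
    window_end <- if (stay$migrant) dep$departure_date else fate_end

    act_daily <- daily_activity(fx, tz)
    act_avg <- tryCatch(
      activity_average(act_daily, rel_date, window_end - 1,
                       min_hours = config$activity_min_hours),
      error = function(e) NA_real_)

    wx <- premigration_weather(weather, window_end)

    pre <- fxf[local_date(fxf$time, tz) < window_end, ]
    pre_fixes[[i]] <- pre
    hr <- tryCatch(home_range(pre, config$kde_bandwidth_m),
                   error = function(e) NULL)
    hr_list[[i]] <- hr

    fates[[i]] <- tibble::tibble(
      individual_id = id, fate = fr$fate,
      survival_days = fr$survival_days, event = fr$event,
      death_time = fr$death_time,
      flags = paste(fr$flags, collapse = ";"))
    rows[[i]] <- tibble::tibble(
      individual_id = id,
      Releasetime = as.numeric(format(rel_date, "%j")),
      StayDur = stay$stay_days,
      migrant = stay$migrant,
      departure_date = dep$departure_date,
      ActAvg = act_avg,
      KDE = if (is.null(hr)) NA_real_ else hr$kde95_area_km2,
      kde50_km2 = if (is.null(hr)) NA_real_ else hr$kde50_area_km2,
      kde50_lon = if (is.null(hr)) NA_real_ else unname(hr$kde50_centroid["lon"]),
      kde50_lat = if (is.null(hr)) NA_real_ else unname(hr$kde50_centroid["lat"]),
      Weight = meta$weight[i],
      VISIB = unname(wx$means["VISIB"]), WDSP = unname(wx$means["WDSP"]),
      TEMP = unname(wx$means["TEMP"]), PRCP = unname(wx$means["PRCP"]),
      survival_days = fr$survival_days, event = fr$event)
  }
  fates <- dplyr::bind_rows(fates)
  covariates <- dplyr::bind_rows(rows)

  # Kaplan-Meier + log-rank per study-design factor
  km <- list()
  for (fac in c("species", "release_site", "source", "tracker",
                "release_year")) {
    g <- as.character(meta[[fac]])[match(covariates$individual_id,
                                         meta$individual_id)]
    km[[fac]] <- list(
      curve = km_fit(covariates$survival_days, covariates$event, g),
      logrank = tryCatch(
        logrank_test(covariates$survival_days, covariates$event, g),
        error = function(e) NULL))
  }

  # spatial structure
  spatial <- list(home_ranges = tibble::tibble(
    individual_id = covariates$individual_id,
    kde95_km2 = covariates$KDE, kde50_km2 = covariates$kde50_km2,
    kde50_lon = covariates$kde50_lon, kde50_lat = covariates$kde50_lat))
  pre_all <- dplyr::bind_rows(pre_fixes)
  spatial$distance_km <- tryCatch(individual_distance_matrix(pre_all),
                                  error = function(e) NULL)
  if (!is.null(spatial$distance_km) && nrow(spatial$distance_km) >= 3) {
    spatial$clusters <- hierarchical_clusters(spatial$distance_km)
  }
  cen_ok <- is.finite(covariates$kde50_lon) & is.finite(covariates$kde50_lat)
  if (sum(cen_ok) >= 4 &&
      stats::sd(covariates$survival_days[cen_ok]) > 0) {
    n_c <- sum(cen_ok)
    Dc <- matrix(0, n_c, n_c)
    lonc <- covariates$kde50_lon[cen_ok]; latc <- covariates$kde50_lat[cen_ok]
    for (i in seq_len(n_c))
      Dc[i, ] <- gc_distance_m(lonc[i], latc[i], lonc, latc) / 1000
    wgt <- inverse_distance_weights(Dc)
    spatial$moran <- morans_i(covariates$survival_days[cen_ok], wgt,
                              n_perm = config$moran_n_perm,
                              seed = config$seed + 7L)
  }

  # Cox layer: screen, all-subsets, diagnostics
  candidates <- c("Releasetime", "StayDur", "ActAvg", "KDE", "Weight",
                  "VISIB", "WDSP", "TEMP", "PRCP")
  cc <- stats::complete.cases(covariates[, candidates])
  cox_rows <- covariates[cc, c(candidates, "survival_days", "event")]
  cox <- list(n_rows = nrow(cox_rows))
  if (nrow(cox_rows) >= 10 && sum(cox_rows$event) >= 3) {
    usable <- candidates[vapply(candidates, function(v)
      stats::sd(cox_rows[[v]]) > 0, logical(1))]
    screen <- vif_screen(cox_rows, usable, threshold = config$vif_threshold)
    sel <- model_select(cox_rows, screen$retained, delta = config$aic_delta)
    cox$vif <- screen
    cox$selection <- sel
    cox$final <- sel$final
    cox$schoenfeld <- tryCatch(schoenfeld_test(sel$final),
                               error = function(e) NULL)
  }
  list(covariates = covariates, fates = fates, km = km, spatial = spatial,
       cox = cox, config = config)
}

#' Simulate a cohort and validate the pipeline against ground truth
#'
#' Runs [simulate_cohort()] and [run_pipeline()] and compares: the fate
#' confusion matrix (true fate class vs recovered class), the death-time
#' error for recovered deaths, and the departure-date error for true
#' migrants, against the recovery thresholds (all fates correct, death
#' times within `death_tol_h`, departures within `departure_tol_d`).
#'
#' @param config A [scenario_config()].
#' @param pipe_config A [pipeline_config()].
#' @param death_tol_h Death-time tolerance in hours (default 24).
#' @param departure_tol_d Departure-date tolerance in days (default 1).
#' @return List: `report` (the pipeline bundle), `confusion`,
#'   `fate_accuracy`, `death_errors_h`, `departure_errors_d`, `pass`.
#' @export
simulate_and_validate <- function(config = scenario_config(),
                                  pipe_config = pipeline_config(),
                                  death_tol_h = 24, departure_tol_d = 1) {
  cohort <- simulate_cohort(config)
  if (config$n_individuals == 0) {
    return(list(report = NULL,
                confusion = table(character(), character()),
                fate_accuracy = NA_real_, death_errors_h = numeric(),
                departure_errors_d = numeric(), pass = TRUE))
  }
  report <- run_pipeline(cohort$fixes, cohort$weather, cohort$meta,
                         pipe_config)
  truth <- cohort$truth$individuals
  called <- report$fates
  m <- match(truth$individual_id, called$individual_id)
  true_class <- c(survivor_migrant = "censored",
                  censored_resident = "censored",
                  natural_death = "dead_confirmed",
                  hunting_loss = "hunting_or_loss")[truth$fate]
  confusion <- table(truth = true_class, called = called$fate[m])
  fate_ok <- true_class == called$fate[m]
  dead <- which(truth$fate == "natural_death" & fate_ok)
  death_err <- as.numeric(difftime(called$death_time[m][dead],
                                   truth$death_time[dead], units = "hours"))
  mig <- which(truth$fate == "survivor_migrant")
  dep_called <- report$covariates$departure_date[
    match(truth$individual_id[mig], report$covariates$individual_id)]
  dep_err <- as.numeric(dep_called - truth$departure_date[mig])
  pass <- all(fate_ok) && all(abs(death_err) <= death_tol_h) &&
    all(is.finite(dep_err)) && all(abs(dep_err) <= departure_tol_d)
  list(report = report, confusion = confusion,
       fate_accuracy = mean(fate_ok),
       death_errors_h = death_err, departure_errors_d = dep_err,
       pass = pass)
}
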