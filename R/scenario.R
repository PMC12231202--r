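#' Scenario configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic telemetry generator: cohort size and
#' calendar, the mixture of true fates, the covariate-to-hazard link used to
#' draw natural death times, the behavioural activity model, the seasonal
#' weather model for the ten station variables, and the GPS error model.
#' Defaults describe a winter release of wild-caught geese at Poyang Lake
#' with hourly fixes and a 365-day monitoring horizon.
#'
#' @param n_individuals Number of geese in the cohort.
#' @param start_date Release date (Date or parseable string); individuals
#'   are released within 48 h of it.
#' @param horizon_days Monitoring horizon in days (right-censoring bound).
#' @param fate_mix Named proportions over the four true fates
#'   `survivor_migrant`, `natural_death`, `hunting_loss`,
#'   `censored_resident`; must sum to 1.
#' @param hazard_spec List with `baseline` (events/day for an average bird),
#'   `beta_actavg` and `beta_wdsp` (log-hazard per 1 SD of the standardized
#'   covariate). Defaults are the hazard ratios 0.461 and 2.311 on the log
#'   scale with a baseline of 0.002/day.
#' @param activity_spec Hourly movement-count model by behavioural state:
#'   means and SDs for daytime foraging and nocturnal roosting, plus the
#'   per-SD multiplicative effect of the individual activity propensity.
#' @param weather_spec Seasonal mean, seasonal amplitude and day-to-day SD
#'   for the station variables (annual sinusoid peaking in mid-July).
#' @param noise_spec GPS error model: per-class jitter SD in metres for
#'   accuracy classes A-E and the class mixture (including `invalid`, for
#'   which no position is reported).
#' @param seed Integer seed; the generator is byte-reproducible given the
#'   full configuration.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_individuals = 40,
                            start_date = as.Date("2022-01-05"),
                            horizon_days = 365,
                            fate_mix = c(survivor_migrant = 0.40,
                                         natural_death = 0.25,
                                         hunting_loss = 0.15,
                                         censored_resident = 0.20),
                            hazard_spec = list(baseline = 0.002,
                                               beta_actavg = log(0.461),
                                               beta_wdsp = log(2.311)),
                            activity_spec = list(day_mean = 45, day_sd = 10,
                                                 night_mean = 20, night_sd = 6,
                                                 propensity_log_sd = 0.25),
                            weather_spec = NULL,
                            noise_spec = list(
                              jitter_sd_m = c(A = 5, B = 10, C = 20,
                                              D = 100, E = 2000),
                              acc_mix = c(A = 0.45, B = 0.30, C = 0.15,
                                          D = 0.06, E = 0.03,
                                          invalid = 0.01)),
                            seed = 1L) {
  start_date <- as.Date(start_date)
  if (length(n_individuals) != 1 || is.na(n_individuals) || n_individuals < 0)
    stop("n_individuals must be a single non-negative count")
  if (horizon_days < 1) stop("horizon_days must be >= 1")
  fates <- c("survivor_migrant", "natural_death", "hunting_loss",
             "censored_resident")
  if (!setequal(names(fate_mix), fates))
    stop("fate_mix must be named over the four fate classes")
  fate_mix <- fate_mix[fates]
  if (abs(sum(fate_mix) - 1) > 1e-8) stop("fate_mix must sum to 1")
  if (any(fate_mix < 0)) stop("fate_mix proportions must be non-negative")
  if (is.null(weather_spec)) weather_spec <- default_weather_spec()
  mix <- noise_spec$acc_mix
  if (abs(sum(mix) - 1) > 1e-8)
    stop("accuracy-class mixture must sum to 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 start_date = start_date,
                 horizon_days = as.integer(horizon_days),
                 fate_mix = fate_mix,
                 hazard_spec = hazard_spec,
                 activity_spec = activity_spec,
                 weather_spec = weather_spec,
                 noise_spec = noise_spec,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Seasonal climate for the Poyang Lake / Nanchang station: annual sinusoid
# peaking around mid-July (day 196), plus day-to-day noise.
default_weather_spec <- function() {
  list(
    TEMP = list(mean = 17.5, amp = 11.5, sd = 2.5),
    DEWP_offset = list(mean = -4, sd = 1.5),
    MAXMIN_spread = list(up = 5, down = 5, sd = 1.2),
    SLP = list(mean = 1016, amp = -8, sd = 3),
    STP_offset = list(mean = -3, sd = 0.5),
    VISIB = list(mean = 14, sd = 4, min = 1),
    WDSP = list(mean = 3, sd = 1.4, min = 0.3),
    MXSPD_gap = list(mean = 2.5, sd = 1),
    PRCP = list(p_dry = 0.6, mean_wet = 8),
    peak_doy = 196
  )
}

# Largest-remainder apportionment of n among proportions p (named).
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}
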