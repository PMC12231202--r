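test_that("thermal equilibration honours the inclusive 2-degree bound", {
  t0 <- as.POSIXct("2022-03-01 00:00:00", tz = "UTC")
  times <- t0 + 3600 * (0:99)
  amb <- rep(10, 100)
  # device identically ambient for 100 h: one interval covering it all
  iv <- thermal_equilibration(rep(10, 100), amb, times)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$duration_h, 100)
  # |diff| exactly 2.0 satisfies the criterion (inclusive bound)
  iv2 <- thermal_equilibration(rep(12, 100), amb, times)
  expect_equal(nrow(iv2), 1)
  # 71 within-tolerance hours then an excursion: no interval
  dev <- c(rep(10, 71), 20, rep(10, 28))
  iv3 <- thermal_equilibration(dev, amb, times)
  expect_equal(nrow(iv3), 0)
  # 2.1 degrees off throughout: nothing
  expect_equal(nrow(thermal_equilibration(rep(12.1, 100), amb, times)), 0)
})

test_that("quiescence needs strictly fewer than 10 counts for 24 h running", {
  t0 <- as.POSIXct("2022-03-01 00:00:00", tz = "UTC")
  times <- t0 + 3600 * (0:47)
  iv <- quiescence(rep(0, 30), times[1:30])
  expect_equal(nrow(iv), 1)
  expect_equal(iv$duration_h, 30)
  # exactly 10 counts breaks the criterion (strict bound)
  expect_equal(nrow(quiescence(rep(10, 48), times)), 0)
  # 23 quiet hours then one loud hour: consecutiveness broken
  expect_equal(nrow(quiescence(c(rep(3, 23), 12), times[1:24])), 0)
  # but a fresh 24-h quiet run after the interruption does qualify
  expect_equal(nrow(quiescence(c(rep(3, 24), 12, rep(3, 23)), times)), 1)
})

test_that("confinement detects tight clusters and breaks on displacement", {
  fx <- make_fixes(n_h = 80)
  iv <- confinement(fx)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$duration_h, 80)
  # a bounded random walk stays confined
  set.seed(31)
  n <- 80
  ang <- runif(n, 0, 2 * pi); r <- runif(n, 0, 140)
  fx2 <- make_fixes(n_h = n)
  fx2$longitude <- fx2$longitude + (r * cos(ang)) / (111320 * cos(29.1 * pi / 180))
  fx2$latitude <- fx2$latitude + (r * sin(ang)) / 111320
  expect_gte(nrow(confinement(fx2)), 1)
  # one 500 m displacement at hour 40 splits the window below 72 h
  fx3 <- make_fixes(n_h = 80)
  fx3$latitude[40] <- fx3$latitude[40] + 500 / 111320
  expect_equal(nrow(confinement(fx3)), 0)
  # < 3 located fixes is not evaluable
  expect_equal(nrow(confinement(make_fixes(n_h = 2))), 0)
})

test_that("interval finders agree with exhaustive scans", {
  t0 <- as.POSIXct("2022-03-01 00:00:00", tz = "UTC")
  set.seed(77)
  for (rep_i in 1:3) {
    nh <- 500
    times <- t0 + 3600 * (0:(nh - 1))
    # blocky series so long satisfied runs actually occur
    state <- rep(rbinom(25, 1, 0.5), each = 20)
    amb <- rep(10, nh)
    dev <- ifelse(state == 1, 10 + rnorm(nh, 0, 0.5), 25)
    got <- thermal_equilibration(dev, amb, times, tol = 2, dur_h = 72)
    want <- brute_intervals_1d(times, abs(dev - amb) <= 2, 72)
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)

    cts <- ifelse(state == 1, rpois(nh, 2), rpois(nh, 40))
    got_q <- quiescence(cts, times, max_count = 10, dur_h = 24)
    want_q <- brute_intervals_1d(times, cts < 10, 24)
    expect_equal(as.numeric(got_q$start), want_q$start)
    expect_equal(as.numeric(got_q$end), want_q$end)
  }

  # confinement against the all-pairs/all-anchors oracle on mixed motion
  set.seed(13)
  nh <- 140
  fx <- make_fixes(n_h = nh)
  drift <- cumsum(c(0, rnorm(nh - 1, 0, 60)))
  wobble <- rnorm(nh, 0, 40)
  fx$longitude <- fx$longitude +
    (drift + wobble) / (111320 * cos(29.1 * pi / 180))
  fx$latitude <- fx$latitude + rnorm(nh, 0, 40) / 111320
  got_c <- confinement(fx, radius_m = 200, dur_h = 24)
  want_c <- brute_confinement(fx, 200, 24)
  expect_equal(as.numeric(got_c$start), want_c$start)
  expect_equal(as.numeric(got_c$end), want_c$end)
})

test_that("decline trend requires all three series to fall", {
  fx <- make_fixes(n_h = 80)
  set.seed(5)
  down <- function(n, from, to) seq(from, to, length.out = n) *
    exp(rnorm(n, 0, 0.1))
  n <- nrow(fx)
  fx$exercise_volume <- as.integer(round(down(n, 40, 1)))
  fx$altitude <- down(n, 20, 1)
  fx$speed <- down(n, 1.5, 0.05)
  expect_true(decline_trend(fx)$decline)

  flat <- make_fixes(n_h = 80)
  flat$exercise_volume <- as.integer(rpois(n, 30))
  flat$altitude <- rnorm(n, 20, 3)
  flat$speed <- abs(rnorm(n, 1, 0.3))
  expect_false(decline_trend(flat)$decline)

  # conjunction: two falling series and one flat are not a decline
  mixed <- fx
  mixed$altitude <- rnorm(n, 20, 3)
  expect_false(decline_trend(mixed)$decline)

  short <- make_fixes(n_h = 6)
  out <- decline_trend(short)
  expect_false(out$decline)
  expect_equal(out$flags, "insufficient_data")
})

test_that("abrupt loss distinguishes hunting from natural death tracks", {
  co <- shared_cohort()
  tr <- co$truth$individuals
  horizon <- 365
  for (i in seq_len(nrow(tr))) {
    id <- tr$individual_id[i]
    fx <- co$fixes[co$fixes$individual_id == id, ]
    rel <- co$meta$release_time[co$meta$individual_id == id]
    loss <- detect_abrupt_loss(fx, rel + horizon * 86400)
    if (tr$fate[i] == "hunting_loss") {
      expect_true(loss$abrupt)
    } else if (tr$fate[i] %in% c("survivor_migrant", "censored_resident")) {
      expect_false(loss$abrupt)
    }
    # natural deaths terminate early but with a decline/death signature;
    # classification (not the raw loss flag) decides those, tested below
  }
})

test_that("fate classification round-trips the generator's ground truth", {
  co <- shared_cohort()
  tr <- co$truth$individuals
  map <- c(survivor_migrant = "censored", censored_resident = "censored",
           natural_death = "dead_confirmed", hunting_loss = "hunting_or_loss")
  for (i in seq_len(nrow(tr))) {
    id <- tr$individual_id[i]
    fx <- co$fixes[co$fixes$individual_id == id, ]
    rel <- co$meta$release_time[co$meta$individual_id == id]
    fr <- classify_mortality(fx, co$weather, rel)
    expect_equal(fr$fate, unname(map[tr$fate[i]]),
                 label = paste("fate for", id))
    if (tr$fate[i] == "natural_death") {
      expect_lte(abs(as.numeric(difftime(fr$death_time, tr$death_time[i],
                                         units = "hours"))), 24)
      expect_equal(fr$event, 1L)
    } else {
      expect_equal(fr$event, 0L)
    }
    expect_lte(fr$survival_days, 365)
  }
})

test_that("survivors beyond the horizon are right-censored at 365 days", {
  fx <- make_fixes(n_h = 24 * 400)
  set.seed(6)
  fx$longitude <- fx$longitude + rnorm(nrow(fx), 0, 0.02)
  fx$latitude <- fx$latitude + rnorm(nrow(fx), 0, 0.02)
  fx$exercise_volume <- as.integer(rpois(nrow(fx), 30))
  w <- tibble::tibble(date = seq(as.Date("2022-01-01"), by = "day",
                                 length.out = 430),
                      TEMP = 15, DEWP = 10, SLP = 1015, STP = 1012,
                      VISIB = 10, WDSP = 3, MXSPD = 6, MAX = 20, MIN = 10,
                      PRCP = 0)
  fr <- classify_mortality(fx, w, fx$time[1])
  expect_equal(fr$fate, "censored")
  expect_equal(fr$survival_days, 365)
  expect_equal(fr$event, 0L)
})

test_that("two criteria without the third yield censoring with diagnostics", {
  # stationary, quiet, but body temperature never equilibrates
  fx <- make_fixes(n_h = 24 * 30, counts = 0, device_temp = 40.5)
  w <- tibble::tibble(date = seq(as.Date("2022-01-01"), by = "day",
                                 length.out = 60),
                      TEMP = 10, DEWP = 5, SLP = 1015, STP = 1012,
                      VISIB = 10, WDSP = 3, MXSPD = 6, MAX = 15, MIN = 5,
                      PRCP = 0)
  params <- mortality_params()
  params$horizon_days <- 30          # monitored to the end of the track
  fr <- classify_mortality(fx, w, fx$time[1], params)
  expect_equal(fr$fate, "censored")
  expect_gte(nrow(fr$criteria$quiescence), 1)
  expect_gte(nrow(fr$criteria$confinement), 1)
  expect_equal(nrow(fr$criteria$thermal), 0)
  expect_match(paste(fr$flags, collapse = ";"), "thermal")
})

test_that("relaxing thresholds never turns a confirmed death into censoring", {
  co <- shared_cohort()
  tr <- co$truth$individuals
  dead_ids <- tr$individual_id[tr$fate == "natural_death"]
  relaxed <- mortality_params()
  relaxed$thermal_tol_c <- 4
  relaxed$thermal_dur_h <- 48
  relaxed$quiesc_dur_h <- 12
  relaxed$conf_radius_m <- 400
  relaxed$conf_dur_h <- 48
  for (id in dead_ids) {
    fx <- co$fixes[co$fixes$individual_id == id, ]
    rel <- co$meta$release_time[co$meta$individual_id == id]
    strict <- classify_mortality(fx, co$weather, rel)
    loose <- classify_mortality(fx, co$weather, rel, relaxed)
    expect_equal(strict$fate, "dead_confirmed")
    expect_equal(loose$fate, "dead_confirmed")
    expect_lte(loose$death_time, strict$death_time)
  }
})
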