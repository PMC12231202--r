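# Shared fixtures and independent brute-force oracles.

# small hourly fix table builder (positions optional)
make_fixes <- function(id = "X1", t0 = as.POSIXct("2022-01-10 00:00:00",
                                                  tz = "UTC"),
                       n_h = 48, lon = 116.2, lat = 29.1, counts = 30,
                       speed = 1, altitude = 20, device_temp = 40.5,
                       accuracy = "A") {
  tibble::tibble(
    individual_id = id,
    time = t0 + 3600 * (seq_len(n_h) - 1),
    longitude = rep_len(lon, n_h), latitude = rep_len(lat, n_h),
    speed = rep_len(speed, n_h), heading = 0,
    altitude = rep_len(altitude, n_h),
    exercise_volume = as.integer(rep_len(counts, n_h)),
    device_temp = rep_len(device_temp, n_h),
    voltage = 4.1, accuracy = rep_len(accuracy, n_h))
}

# cached small cohort reused across test files
shared_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value))
      value <<- gooseSurv::simulate_cohort(
        gooseSurv::scenario_config(n_individuals = 8, seed = 101))
    value
  }
})

# exhaustive 1-d interval oracle: all (i,j) index pairs, cumulative-sum
# feasibility, then maximal pairs; independent of the run-length path
brute_intervals_1d <- function(times, ok, dur_h) {
  n <- length(times)
  cs <- cumsum(ok)
  sat <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      all_ok <- (cs[j] - if (i > 1) cs[i - 1] else 0) == (j - i + 1)
      contiguous <- as.numeric(difftime(times[j], times[i],
                                        units = "hours")) == (j - i)
      span <- j - i + 1
      if (all_ok && contiguous && span >= dur_h)
        sat[[length(sat) + 1]] <- c(i, j)
    }
  }
  if (!length(sat)) return(data.frame(start = numeric(), end = numeric()))
  m <- do.call(rbind, sat)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
           (m[, 1] != m[r, 1] | m[, 2] != m[r, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  data.frame(start = as.numeric(times[m[, 1]]),
             end = as.numeric(times[m[, 2]]) + 3600)
}

# exhaustive confinement oracle: for every (i,j) check every anchor
brute_confinement <- function(fx, radius_m, dur_h) {
  fx <- fx[order(fx$time), ]
  n <- nrow(fx)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    D[i, ] <- gooseSurv::gc_distance_m(fx$longitude[i], fx$latitude[i],
                                       fx$longitude, fx$latitude)
  sat <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < 3) next
      span <- as.numeric(difftime(fx$time[j], fx$time[i],
                                  units = "hours")) + 1
      if (span < dur_h) next
      feasible <- FALSE
      for (a in i:j) {
        if (max(D[a, i:j]) <= radius_m) { feasible <- TRUE; break }
      }
      if (feasible) sat[[length(sat) + 1]] <- c(i, j)
    }
  }
  if (!length(sat)) return(data.frame(start = numeric(), end = numeric()))
  m <- do.call(rbind, sat)
  keep <- vapply(seq_len(nrow(m)), function(r) {
    !any(m[, 1] <= m[r, 1] & m[, 2] >= m[r, 2] &
           (m[, 1] != m[r, 1] | m[, 2] != m[r, 2]))
  }, logical(1))
  m <- m[keep, , drop = FALSE]
  data.frame(start = as.numeric(fx$time[m[, 1]]),
             end = as.numeric(fx$time[m[, 2]]) + 3600)
}

# permutation reference for the two-group log-rank p-value
perm_logrank_p <- function(time, event, group, n_perm = 2000, seed = 1) {
  obs <- gooseSurv::logrank_test(time, event, group)$chisq
  set.seed(seed)
  perm <- replicate(n_perm, {
    g <- sample(group)
    tryCatch(gooseSurv::logrank_test(time, event, g)$chisq,
             error = function(e) NA_real_)
  })
  mean(perm >= obs, na.rm = TRUE)
}

# double-loop Moran's I, straight from the definition
brute_morans_i <- function(values, W) {
  n <- length(values)
  xbar <- mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (values[i] - xbar) * (values[j] - xbar)
  (n / sum(W)) * num / sum((values - xbar)^2)
}
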