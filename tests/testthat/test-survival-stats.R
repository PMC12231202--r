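test_that("Kaplan-Meier equals the closed-form product limit", {
  # three deaths, no censoring: S = 2/3, 1/3, 0
  k <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(unname(attr(k, "medians")["all"]), 2)   # first S <= 0.5

  # all censored: flat at 1, no median
  k2 <- km_fit(c(5, 8, 9), c(0, 0, 0))
  expect_true(all(k2$survival == 1))
  expect_true(is.na(attr(k2, "medians")["all"]))

  # single event at t=5 among five subjects
  k3 <- km_fit(c(5, 6, 7, 8, 9), c(1, 0, 0, 0, 0))
  expect_equal(k3$survival[1], 0.8)

  # mixed fixture against the hand product over event times, kept
  # rational: distinct times 2, 3 (1 death + 1 censor), 5, 7 (censor), 8
  t <- c(2, 3, 3, 5, 7, 8)
  e <- c(1, 1, 0, 1, 0, 1)
  k4 <- km_fit(t, e)
  hand <- c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3,
            5 / 6 * 4 / 5 * 2 / 3, 0)
  expect_equal(k4$survival, hand)
  expect_error(km_fit(numeric(0), numeric(0)), "empty")
  expect_error(km_fit(c(0, 1), c(1, 1)), "positive")
})

test_that("Kaplan-Meier matches the reference implementation per group", {
  skip_if_not_installed("survival")
  set.seed(10)
  d <- simulate_hazard_rows(80, seed = 44)
  d$survival_days <- ceiling(d$survival_days)   # create ties
  g <- rep(c("a", "b"), 40)
  ours <- km_fit(d$survival_days, d$event, g)
  for (gg in c("a", "b")) {
    sf <- survival::survfit(
      survival::Surv(survival_days, event) ~ 1,
      data = d[g == gg, ])
    o <- ours[ours$group == gg, ]
    expect_equal(o$survival, sf$surv, tolerance = 1e-12)
    expect_equal(o$n_risk, sf$n.risk)
  }
})

test_that("log-rank reproduces a hand-computed two-group table", {
  # 6 subjects: group A times 1,3,5 (all deaths), group B 2,4,6 (death,
  # death, censored). Hand O-E for A: at t=1 e=3/6, t=2 e=2/5, t=3 e=2/4,
  # t=4 e=1/3, t=5 e=1/2 -> E_A = 2.2333...; O_A = 3.
  t <- c(1, 3, 5, 2, 4, 6)
  e <- c(1, 1, 1, 1, 1, 0)
  g <- c("A", "A", "A", "B", "B", "B")
  lr <- logrank_test(t, e, g)
  EA <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 1 / 2
  expect_equal(lr$table$expected[lr$table$group == "A"], EA)
  expect_equal(lr$table$observed[lr$table$group == "A"], 3)
  VA <- (3 / 6) * (3 / 6) + (2 / 5) * (3 / 5) + (2 / 4) * (2 / 4) +
    (1 / 3) * (2 / 3) + (1 / 2) * (1 / 2)
  expect_equal(lr$chisq, (3 - EA)^2 / VA)
  expect_equal(lr$df, 1)

  # duplicated data in both arms: no difference at all
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(1, 6); g2 <- rep(c("x", "y"), each = 3)
  expect_equal(logrank_test(t2, e2, g2)$chisq, 0)
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "zero events")
})

test_that("log-rank agrees with survdiff and a permutation reference", {
  skip_if_not_installed("survival")
  set.seed(15)
  n <- 30
  g <- rep(c("a", "b"), n / 2)
  t <- rexp(n, ifelse(g == "a", 1 / 50, 1 / 18))
  e <- as.integer(t < 60); t <- pmin(t, 60)
  lr <- logrank_test(t, e, g)
  sd_ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chisq, sd_ref$chisq, tolerance = 1e-10)
  p_perm <- perm_logrank_p(t, e, g, n_perm = 2000, seed = 2)
  mc <- 3 * sqrt(max(p_perm, 1e-4) * (1 - p_perm) / 2000)
  expect_lt(abs(lr$p_value - p_perm), mc + 0.02)

  # strongly separated exponentials are decisive
  set.seed(16)
  g2 <- rep(c("a", "b"), 100)
  t2 <- rexp(200, ifelse(g2 == "a", 1, 4))
  lr2 <- logrank_test(t2, rep(1, 200), g2)
  expect_lt(lr2$p_value, 0.001)
})

test_that("the native Cox fitter matches the reference on tied data", {
  skip_if_not_installed("survival")
  set.seed(20)
  d <- simulate_hazard_rows(150, beta = c(log(0.5), log(2)),
                            baseline = 0.004, seed = 77)
  d$survival_days <- ceiling(d$survival_days / 10)  # heavy ties
  d$extra <- rnorm(150)
  f <- cox_fit(d, c("ActAvg", "WDSP", "extra"), standardize = FALSE)
  r <- survival::coxph(survival::Surv(survival_days, event) ~
                         ActAvg + WDSP + extra, data = d, ties = "efron")
  expect_equal(f$coef$beta, unname(coef(r)), tolerance = 1e-7)
  expect_equal(f$coef$se, unname(sqrt(diag(vcov(r)))), tolerance = 1e-7)
  expect_equal(unname(f$loglik["model"]), r$loglik[2], tolerance = 1e-8)
  expect_equal(f$AIC, stats::AIC(r), tolerance = 1e-7)
  expect_equal(f$concordance, unname(r$concordance["concordance"]),
               tolerance = 1e-10)
  expect_equal(f$score_chisq, unname(r$score), tolerance = 1e-7)
  # the partial-likelihood gradient vanishes at the optimum
  g <- gooseSurv:::cox_pll(f$beta, f$time, f$event, f$X)
  expect_lt(sqrt(sum(g$grad^2)), 1e-6)
  expect_equal(f$AIC, -2 * unname(f$loglik["model"]) + 2 * 3)
})

test_that("Cox estimation recovers generating effects and respects nulls", {
  # a generating log-hazard of log(2) sits inside its Wald CI
  d <- simulate_hazard_rows(500, beta = c(log(2), 0), baseline = 0.003,
                            seed = 91)
  f <- cox_fit(d, c("ActAvg", "WDSP"), standardize = FALSE)
  ci <- c(f$coef$beta[1] - 1.96 * f$coef$se[1],
          f$coef$beta[1] + 1.96 * f$coef$se[1])
  expect_gt(log(2), ci[1]); expect_lt(log(2), ci[2])

  # pure-noise covariate: CI covers zero in about 95% of replicates
  cover <- vapply(1:60, function(b) {
    dd <- simulate_hazard_rows(200, beta = c(0, 0), baseline = 0.004,
                               seed = 400 + b)
    ff <- cox_fit(dd, "ActAvg", standardize = FALSE)
    abs(ff$coef$beta[1]) < 1.96 * ff$coef$se[1]
  }, logical(1))
  expect_gte(mean(cover), 0.85)

  # duplicating the dataset leaves beta fixed and shrinks SEs by sqrt(2)
  # (exact under Breslow ties; Efron's tie correction perturbs the
  # duplicated fit at the third decimal)
  d2 <- rbind(d, d)
  f2 <- cox_fit(d2, c("ActAvg", "WDSP"), standardize = FALSE)
  expect_equal(f2$coef$beta, f$coef$beta, tolerance = 0.01)
  expect_equal(f2$coef$se, f$coef$se / sqrt(2), tolerance = 0.02)

  expect_error(cox_fit(within(d, ActAvg <- 1), "ActAvg"), "constant")
})

test_that("concordance is 1 on perfectly ranked data and 0 when inverted", {
  t <- c(1, 2, 3, 4, 5); e <- rep(1, 5)
  eta_good <- c(5, 4, 3, 2, 1)    # highest risk dies first
  expect_equal(cox_concordance(t, e, eta_good), 1)
  expect_equal(cox_concordance(t, e, rev(eta_good)), 0)
  expect_equal(cox_concordance(t, e, rep(0, 5)), 0.5)
})

test_that("Schoenfeld test keeps level under PH and detects violations", {
  # null model gives an empty table
  d0 <- simulate_hazard_rows(60, seed = 5)
  f0 <- cox_fit(d0, character())
  expect_equal(nrow(schoenfeld_test(f0)), 0)

  # under proportional hazards the rejection rate is near alpha
  set.seed(30)
  rej <- vapply(1:60, function(b) {
    d <- simulate_hazard_rows(120, beta = c(log(2), 0), baseline = 0.004,
                              seed = 600 + b)
    f <- cox_fit(d, c("ActAvg", "WDSP"), standardize = FALSE)
    any(schoenfeld_test(f)$p < 0.05)
  }, logical(1))
  expect_lt(mean(rej), 0.25)   # two covariates, nominal ~0.10 joint

  # a strongly time-varying effect is caught with high power
  set.seed(31)
  pow <- vapply(1:30, function(b) {
    n <- 300
    x <- rnorm(n)
    # effect reverses over time: early hazard up, late hazard down
    t1 <- rexp(n, 0.02 * exp(1.5 * x))
    t_obs <- ifelse(t1 < 30, t1, 30 + rexp(n, 0.02 * exp(-1.5 * x)))
    d <- tibble::tibble(survival_days = pmin(t_obs, 150),
                        event = as.integer(t_obs < 150), x = x)
    f <- cox_fit(d, "x", standardize = FALSE)
    schoenfeld_test(f)$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(pow), 0.8)
})

test_that("VIF equals 1/(1-R^2) and the screen drops collinear terms", {
  set.seed(40)
  n <- 100
  d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d$d <- d$a + rnorm(n, 0, 0.05)        # near-duplicate of a
  v <- vif(d, c("a", "b", "c", "d"))
  for (nm in names(v)) {
    r2 <- summary(lm(reformulate(setdiff(c("a", "b", "c", "d"), nm),
                                 response = nm), data = d))$r.squared
    expect_equal(unname(v[nm]), 1 / (1 - r2), tolerance = 1e-10)
  }
  sc <- vif_screen(d, c("a", "b", "c", "d"), threshold = 5)
  expect_true(all(sc$vif <= 5))
  expect_equal(length(sc$dropped), 1)
  expect_true(sc$dropped %in% c("a", "d"))

  # orthogonal design: nothing dropped, VIFs unity
  d2 <- tibble::tibble(a = rep(c(-1, 1), 20), b = rep(c(-1, -1, 1, 1), 10))
  sc2 <- vif_screen(d2, c("a", "b"))
  expect_equal(unname(sc2$vif), c(1, 1), tolerance = 1e-10)
  expect_length(sc2$dropped, 0)

  # perfect collinearity resolves deterministically (alphabetical)
  d3 <- tibble::tibble(a = rnorm(20), z = rnorm(20))
  d3$b <- d3$a
  sc3 <- vif_screen(d3, c("a", "b", "z"))
  expect_equal(sc3$dropped, "b")
})

test_that("all-subsets AIC selection is exhaustive and parsimonious", {
  # k = 2 enumerates exactly 4 models including the null
  d <- simulate_hazard_rows(80, beta = c(log(2), 0), baseline = 0.005,
                            seed = 50)
  sel <- model_select(d, c("ActAvg", "WDSP"))
  expect_equal(nrow(sel$table), 4)
  expect_true("(null)" %in% sel$table$terms)
  expect_true(all(diff(sel$table$AIC) >= 0))
  expect_true(all(sel$retained_set$delta_AIC < 2))

  # one predictive covariate among noise is found in most cohorts
  hits <- vapply(1:10, function(b) {
    dd <- simulate_hazard_rows(300, beta = c(log(2.5), 0), baseline = 0.004,
                               seed = 700 + b)
    dd$n1 <- rnorm(300); dd$n2 <- rnorm(300); dd$n3 <- rnorm(300)
    s <- model_select(dd, c("ActAvg", "WDSP", "n1", "n2", "n3"))
    "ActAvg" %in% s$final_terms
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # all-noise candidates collapse to the null model most of the time
  nulls <- vapply(1:10, function(b) {
    dd <- simulate_hazard_rows(150, beta = c(0, 0), baseline = 0.004,
                               seed = 800 + b)
    dd$n1 <- rnorm(150)
    s <- model_select(dd, c("ActAvg", "WDSP", "n1"))
    length(s$final_terms)
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.6)

  # forward stepwise includes the strong covariate first
  dd <- simulate_hazard_rows(300, beta = c(log(3), 0), baseline = 0.004,
                             seed = 60)
  fs <- forward_stepwise(dd, c("ActAvg", "WDSP"))
  expect_equal(fs$terms[1], "ActAvg")
})
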