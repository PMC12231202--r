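#' Kaplan-Meier product-limit estimator
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), where d_i is
#' the number of deaths at t_i and n_i the number at risk just before t_i;
#' right-censored individuals leave the risk set without contributing an
#' event. The median survival time is the first time at which S(t) falls
#' to 0.5 or below (absent if the curve never does).
#'
#' @param time Survival times in days (> 0).
#' @param event Event indicator (1 = death observed, 0 = censored).
#' @param group Optional grouping factor; one curve per level.
#' @return A tibble with one row per distinct event/censoring time and
#'   columns `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`; the per-group medians are in the `medians` attribute.
#' @export
km_fit <- function(time, event, group = NULL) {
  if (length(time) == 0) stop("empty survival data")
  if (any(time <= 0)) stop("survival times must be positive")
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  out <- list(); med <- list()
  for (g in unique(group)) {
    tt <- time[group == g]; ee <- event[group == g]
    if (!length(tt)) stop("empty group: ", g)
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ee == 1), numeric(1))
    n_cens <- vapply(ut, function(u) sum(tt == u & ee == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    out[[g]] <- tibble::tibble(group = g, time = ut, n_risk = n_risk,
                               n_event = n_event, n_censor = n_cens,
                               survival = surv)
    below <- which(surv <= 0.5)
    med[[g]] <- if (length(below)) ut[below[1]] else NA_real_
  }
  res <- dplyr::bind_rows(out)
  attr(res, "medians") <- unlist(med)
  res
}

#' Log-rank test for equality of survival curves
#'
#' The standard (Mantel-Haenszel) log-rank statistic: at every distinct
#' event time the observed deaths per group are compared against their
#' hypergeometric expectation given the risk sets, and the summed
#' differences are combined through the estimated covariance matrix. The
#' statistic is chi-squared with (groups - 1) degrees of freedom.
#'
#' @param time Survival times in days.
#' @param event Event indicator (1 = death).
#' @param group Grouping factor (>= 2 levels).
#' @return List with `chisq`, `df`, `p_value`, and the per-group
#'   observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  G <- nlevels(group)
  if (G < 2) stop("log-rank test needs at least 2 groups")
  if (sum(event) == 0) stop("log-rank undefined with zero events")
  ut <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(G), levels(group))
  V <- matrix(0, G, G)
  for (u in ut) {
    at_risk <- time >= u
    N <- sum(at_risk)
    d <- sum(event == 1 & time == u)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g),
                 numeric(1))
    dg <- vapply(levels(group), function(g)
      sum(event == 1 & time == u & group == g), numeric(1))
    eg <- d * ng / N
    O <- O + dg
    E <- E + eg
    if (N > 1) {
      fac <- d * (N - d) / (N - 1)
      V <- V + fac * (diag(ng / N, G) - (ng / N) %o% (ng / N))
    }
  }
  U <- (O - E)[-G]
  Vm <- V[-G, -G, drop = FALSE]
  chisq <- as.numeric(t(U) %*% solve(Vm, U))
  df <- G - 1
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
       table = tibble::tibble(group = levels(group), observed = unname(O),
                              expected = unname(E)))
}
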