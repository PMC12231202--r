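#' Cox proportional-hazards regression (native fitter)
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with Efron's
#' approximation for tied event times, h(t|X) = h0(t) exp(X beta).
#' Reports per-covariate hazard ratios with Wald 95% confidence intervals
#' and p-values, the model AIC (-2 logPL + 2k), Harrell's concordance
#' index and the global score (log-rank) test. Covariates are z-score
#' standardized internally by default, with coefficients reported on both
#' scales.
#'
#' @param data Data frame with `survival_days`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate names (may be empty:
#'   the null model).
#' @param standardize Z-score the covariates before fitting (default
#'   TRUE).
#' @param max_iter,tol Newton-Raphson controls.
#' @return A `cox_fit` list: `coef` tibble (term, beta, se, z, p, HR,
#'   HR_lower, HR_upper, beta_raw, se_raw), `loglik` (null and fitted),
#'   `AIC`, `concordance`, `score_chisq`, `score_df`, `score_p`,
#'   `n`, `n_event`, `iter`, `converged`, plus fitting internals used by
#'   the Schoenfeld test.
#' @export
cox_fit <- function(data, covariates, standardize = TRUE,
                    max_iter = 50, tol = 1e-9) {
  time <- data$survival_days
  event <- data$event
  n <- length(time)
  k <- length(covariates)
  if (any(time <= 0)) stop("survival times must be positive")

  X_raw <- as.matrix(data[, covariates, drop = FALSE])
  if (k > 0) {
    if (any(apply(X_raw, 2, stats::sd) == 0))
      stop("constant covariate: ",
           paste(covariates[apply(X_raw, 2, stats::sd) == 0], collapse = ", "))
    ctr <- colMeans(X_raw)
    scl <- if (standardize) apply(X_raw, 2, stats::sd) else rep(1, k)
    X <- sweep(sweep(X_raw, 2, ctr), 2, scl, "/")
  } else {
    X <- matrix(nrow = n, ncol = 0)
    ctr <- scl <- numeric(0)
  }

  pll <- function(beta) cox_pll(beta, time, event, X)
  ll0 <- pll(numeric(k))$ll

  beta <- numeric(k)
  converged <- k == 0
  iter <- 0
  if (k > 0) {
    cur <- pll(beta)
    for (iter in seq_len(max_iter)) {
      step <- tryCatch(solve(cur$info, cur$grad),
                       error = function(e) stop("singular information ",
                                                "matrix (separation?)"))
      new_beta <- beta + step
      new <- pll(new_beta)
      halvings <- 0
      while ((!is.finite(new$ll) || new$ll < cur$ll - 1e-12) &&
             halvings < 20) {
        step <- step / 2
        new_beta <- beta + step
        new <- pll(new_beta)
        halvings <- halvings + 1
      }
      beta <- new_beta
      done <- sqrt(sum(new$grad^2)) < tol ||
        abs(new$ll - cur$ll) < 1e-12 * (abs(cur$ll) + 1e-12)
      cur <- new
      if (done) { converged <- TRUE; break }
    }
    if (!converged)
      stop("Cox Newton-Raphson failed to converge in ", max_iter,
           " iterations (last |grad| = ",
           format(sqrt(sum(cur$grad^2))), ")")
    info <- cur$info
    ll1 <- cur$ll
    se <- sqrt(diag(solve(info)))
  } else {
    ll1 <- ll0
    info <- matrix(nrow = 0, ncol = 0)
    se <- numeric(0)
  }

  # global score (log-rank) test at beta = 0
  if (k > 0) {
    null_fit <- pll(numeric(k))
    score_chisq <- as.numeric(t(null_fit$grad) %*%
                                solve(null_fit$info, null_fit$grad))
    score_p <- stats::pchisq(score_chisq, k, lower.tail = FALSE)
  } else {
    score_chisq <- 0; score_p <- NA_real_
  }

  eta <- as.numeric(X %*% beta)
  zstat <- beta / se
  coef_tbl <- tibble::tibble(
    term = covariates,
    beta = unname(beta), se = unname(se), z = unname(zstat),
    p = 2 * stats::pnorm(-abs(zstat)),
    HR = exp(unname(beta)),
    HR_lower = exp(unname(beta - stats::qnorm(0.975) * se)),
    HR_upper = exp(unname(beta + stats::qnorm(0.975) * se)),
    beta_raw = unname(if (k) beta / scl else numeric(0)),
    se_raw = unname(if (k) se / scl else numeric(0)))

  structure(list(coef = coef_tbl,
                 loglik = c(null = ll0, model = ll1),
                 AIC = -2 * ll1 + 2 * k,
                 concordance = cox_concordance(time, event, eta),
                 score_chisq = score_chisq, score_df = k,
                 score_p = score_p,
                 n = n, n_event = sum(event),
                 iter = iter, converged = converged,
                 beta = beta, X = X, time = time, event = event,
                 covariates = covariates, center = ctr, scale = scl,
                 info = info),
            class = "cox_fit")
}

# Efron partial log-likelihood, gradient and information
cox_pll <- function(beta, time, event, X) {
  n <- length(time)
  k <- length(beta)
  eta <- if (k) as.numeric(X %*% beta) else numeric(n)
  w <- exp(eta)
  ut <- sort(unique(time[event == 1]))
  ll <- 0
  grad <- numeric(k)
  info <- matrix(0, k, k)
  for (u in ut) {
    R <- time >= u
    D <- event == 1 & time == u
    d <- sum(D)
    S0 <- sum(w[R])
    s0 <- sum(w[D])
    if (k) {
      XR <- X[R, , drop = FALSE]; XD <- X[D, , drop = FALSE]
      S1 <- colSums(XR * w[R])
      s1 <- colSums(XD * w[D])
      S2 <- crossprod(XR * sqrt(w[R]))
      s2 <- crossprod(XD * sqrt(w[D]))
      grad <- grad + colSums(XD)
    }
    ll <- ll + sum(eta[D])
    for (j in seq_len(d) - 1) {
      f <- j / d
      phi <- S0 - f * s0
      ll <- ll - log(phi)
      if (k) {
        v <- (S1 - f * s1) / phi
        grad <- grad - v
        info <- info + (S2 - f * s2) / phi - tcrossprod(v)
      }
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs (an observed event earlier than the other
#' subject's time) in which the higher-risk subject fails first; ties in
#' the linear predictor count one half.
#'
#' @param time Survival times.
#' @param event Event indicators.
#' @param eta Linear predictor (risk score).
#' @return Concordance in [0, 1]; NA when no pair is usable.
#' @export
cox_concordance <- function(time, event, eta) {
  n <- length(time)
  conc <- 0; ties <- 0; usable <- 0
  for (i in which(event == 1)) {
    later <- which(time[i] < time |
                     (time == time[i] & event == 0 & seq_len(n) != i))
    if (!length(later)) next
    usable <- usable + length(later)
    conc <- conc + sum(eta[i] > eta[later])
    ties <- ties + sum(eta[i] == eta[later])
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * ties) / usable
}

#' Proportional-hazards test on scaled Schoenfeld residuals
#'
#' For each covariate, the scaled Schoenfeld residuals are correlated
#' against a transform of event time (by default the Kaplan-Meier scaled
#' time, 1 - S(t)); a significant correlation indicates a time-varying
#' effect, violating proportional hazards.
#'
#' @param fit A [cox_fit()] object.
#' @param transform `"km"` (default), `"rank"` or `"identity"`.
#' @return Tibble `term`, `rho`, `p`; empty for a null model. Requires at
#'   least 3 events.
#' @export
schoenfeld_test <- function(fit, transform = "km") {
  k <- length(fit$beta)
  if (k == 0) return(tibble::tibble(term = character(), rho = numeric(),
                                    p = numeric()))
  time <- fit$time; event <- fit$event; X <- fit$X
  if (sum(event) < 3) stop("Schoenfeld test needs at least 3 events")
  w <- exp(as.numeric(X %*% fit$beta))
  ev_idx <- which(event == 1)
  ev_idx <- ev_idx[order(time[ev_idx])]
  resid <- matrix(0, length(ev_idx), k)
  for (r in seq_along(ev_idx)) {
    i <- ev_idx[r]
    R <- time >= time[i]
    S0 <- sum(w[R])
    xbar <- colSums(X[R, , drop = FALSE] * w[R]) / S0
    resid[r, ] <- X[i, ] - xbar
  }
  # Grambsch-Therneau scaling: r* = d * I(beta)^-1 r + beta
  d <- length(ev_idx)
  Iinv <- solve_or_ginv(fit$info)
  scaled <- d * resid %*% Iinv +
    matrix(fit$beta, d, k, byrow = TRUE)
  g <- switch(transform,
              km = {
                km <- km_fit(time, event)
                sf <- stats::stepfun(km$time, c(1, km$survival))
                1 - sf(time[ev_idx])
              },
              rank = rank(time[ev_idx]),
              identity = time[ev_idx],
              stop("unknown transform"))
  res <- lapply(seq_len(k), function(j) {
    ct <- suppressWarnings(stats::cor.test(g, scaled[, j]))
    tibble::tibble(term = fit$covariates[j],
                   rho = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_rows(res)
}

solve_or_ginv <- function(M) {
  tryCatch(solve(M), error = function(e) {
    s <- svd(M)
    pos <- s$d > max(s$d) * 1e-10
    s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
      t(s$u[, pos, drop = FALSE])
  })
}
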