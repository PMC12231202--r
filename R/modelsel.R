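#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary least-squares
#' regression of covariate j on all the others (plus an intercept).
#'
#' @param data Data frame holding the covariates.
#' @param covariates Character vector of covariate names (>= 2).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(data, covariates) {
  if (length(covariates) < 2)
    return(stats::setNames(rep(1, length(covariates)), covariates))
  X <- as.data.frame(data[, covariates, drop = FALSE])
  vapply(covariates, function(v) {
    fml <- stats::reformulate(setdiff(covariates, v), response = v)
    fit <- stats::lm(fml, data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits allowed
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF screen for multicollinearity
#'
#' Repeatedly drops the covariate with the largest VIF until all remaining
#' VIFs are at or below `threshold` (default 5). Perfectly collinear pairs
#' give infinite VIFs; ties are broken alphabetically (the later name is
#' dropped) so the screen is deterministic.
#'
#' @param data Data frame holding the covariates.
#' @param covariates Candidate covariate names.
#' @param threshold VIF cutoff (default 5).
#' @return List: `retained`, `dropped` (in drop order), `vif` (final
#'   values).
#' @export
vif_screen <- function(data, covariates, threshold = 5) {
  if (nrow(data) <= length(covariates))
    warning("fewer observations than covariates; VIFs may be unstable")
  keep <- covariates
  dropped <- character()
  repeat {
    v <- vif(data, keep)
    if (all(v <= threshold) || length(keep) < 2) break
    worst <- max(v)
    cand <- sort(names(v)[v >= worst - 1e-12])
    drop_one <- cand[length(cand)]   # alphabetical tie-break: later name
    dropped <- c(dropped, drop_one)
    keep <- setdiff(keep, drop_one)
  }
  list(retained = keep, dropped = dropped, vif = vif(data, keep))
}

#' All-subsets Cox model selection by AIC
#'
#' Enumerates every subset of the candidate covariates (including the null
#' model), fits each by [cox_fit()], ranks by AIC, retains the competing
#' set with delta-AIC < `delta` (default 2) and picks the most
#' parsimonious member (fewest covariates; ties broken by lower AIC). A
#' forward-stepwise path (likelihood-ratio entry at p < 0.05) is returned
#' as a diagnostic alongside.
#'
#' @param data Data frame with `survival_days`, `event` and covariates.
#' @param candidates Candidate covariate names (at most 15).
#' @param delta AIC window for the competing set.
#' @param standardize Passed to [cox_fit()].
#' @return List: `final` (a `cox_fit`), `final_terms`, `table` (all
#'   subsets with AIC and delta-AIC, ranked), `retained_set` (delta-AIC <
#'   `delta`), `stepwise` (forward path).
#' @export
model_select <- function(data, candidates, delta = 2, standardize = TRUE) {
  k <- length(candidates)
  if (k > 15) stop("all-subsets enumeration capped at 15 candidates")
  subsets <- lapply(0:(2^k - 1), function(m) candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  fits <- vector("list", length(subsets))
  aic <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(cox_fit(data, subsets[[i]],
                                  standardize = standardize),
                          error = function(e) NULL)
    if (!is.null(fits[[i]])) aic[i] <- fits[[i]]$AIC
  }
  if (all(is.na(aic))) stop("no candidate subset could be fitted")
  tab <- tibble::tibble(
    model_id = seq_along(subsets),
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(null)", character(1)),
    n_terms = lengths(subsets),
    AIC = aic)
  tab <- tab[order(tab$AIC), ]
  tab$delta_AIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  retained <- tab[!is.na(tab$delta_AIC) & tab$delta_AIC < delta, ]
  pick <- retained[order(retained$n_terms, retained$AIC), ][1, ]
  final_terms <- subsets[[pick$model_id]]
  list(final = fits[[pick$model_id]], final_terms = final_terms,
       table = tab, retained_set = retained,
       stepwise = forward_stepwise(data, candidates,
                                   standardize = standardize))
}

#' Forward stepwise Cox selection (likelihood-ratio entry)
#'
#' Starting from the null model, repeatedly adds the covariate with the
#' smallest likelihood-ratio p-value while that p-value is below
#' `p_enter`.
#'
#' @param data Data frame with `survival_days`, `event` and covariates.
#' @param candidates Candidate covariate names.
#' @param p_enter Entry threshold (default 0.05).
#' @param standardize Passed to [cox_fit()].
#' @return List: `terms` (selection order), `path` (tibble of steps with
#'   LR statistics).
#' @export
forward_stepwise <- function(data, candidates, p_enter = 0.05,
                             standardize = TRUE) {
  selected <- character()
  path <- list()
  ll_cur <- cox_fit(data, character(), standardize = standardize)$loglik["model"]
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- lapply(remaining, function(v)
      tryCatch(cox_fit(data, c(selected, v), standardize = standardize),
               error = function(e) NULL))
    ok <- !vapply(trial, is.null, logical(1))
    if (!any(ok)) break
    lr <- vapply(trial[ok], function(f)
      2 * (f$loglik["model"] - ll_cur), numeric(1))
    p <- stats::pchisq(lr, 1, lower.tail = FALSE)
    best <- which.min(p)
    if (p[best] >= p_enter) break
    v <- remaining[ok][best]
    selected <- c(selected, v)
    ll_cur <- trial[ok][[best]]$loglik["model"]
    path[[length(path) + 1]] <- tibble::tibble(step = length(selected),
                                               added = v,
                                               lr_chisq = lr[best],
                                               p = p[best])
  }
  list(terms = selected,
       path = if (length(path)) dplyr::bind_rows(path)
       else tibble::tibble(step = integer(), added = character(),
                           lr_chisq = numeric(), p = numeric()))
}
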