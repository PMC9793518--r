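# Weighted Cox proportional-hazards model fitted from first principles:
# Breslow tie handling, Newton-Raphson with step-halving on the weighted
# log partial likelihood, model-based and robust (sandwich) variance from
# weighted score residuals, Breslow baseline cumulative hazard, and scaled
# Schoenfeld residual diagnostics.
#
# Notation (weights w_i, risk score r_i = exp(x_i' beta), risk set at t =
# {j : t_j >= t}, weighted event mass at t_k: dtilde_k = sum_{i in D_k} w_i):
#   S0(t) = sum_risk w_j r_j
#   S1(t) = sum_risk w_j r_j x_j
#   S2(t) = sum_risk w_j r_j x_j x_j'
#   loglik = sum_k [ sum_{i in D_k} w_i x_i'beta - dtilde_k log S0(t_k) ]

cox_sums <- function(time, event, X, w, beta) {
  # returns loglik, score U, information I, and per-event-time pieces
  o <- order(time)                  # ascending
  t_s <- time[o]; e_s <- event[o]; X_s <- X[o, , drop = FALSE]; w_s <- w[o]
  n <- length(t_s); p <- ncol(X)
  eta <- drop(X_s %*% beta)
  r <- w_s * exp(eta)
  # reverse cumulative risk-set sums at each sorted position
  S0_at <- rev(cumsum(rev(r)))                       # S0 over {j >= i}
  S1_at <- apply(X_s * r, 2, function(col) rev(cumsum(rev(col))))
  S1_at <- matrix(S1_at, nrow = n)
  # unique event times -> first index with t_j >= t_k
  ev_idx <- which(e_s)
  if (!length(ev_idx)) stop("no events: Cox model undefined")
  ut <- unique(t_s[ev_idx])
  first_idx <- match(ut, t_s)       # t_s sorted, so first occurrence works
  S0_k <- S0_at[first_idx]
  S1_k <- S1_at[first_idx, , drop = FALSE]
  dtilde <- vapply(ut, function(tk) sum(w_s[e_s & t_s == tk]), numeric(1))
  sum_wx <- t(vapply(ut, function(tk) {
    sel <- e_s & t_s == tk
    colSums(X_s[sel, , drop = FALSE] * w_s[sel])
  }, numeric(p)))
  sum_wx <- matrix(sum_wx, ncol = p)
  sum_weta <- vapply(ut, function(tk) {
    sel <- e_s & t_s == tk
    sum(w_s[sel] * eta[sel])
  }, numeric(1))
  loglik <- sum(sum_weta) - sum(dtilde * log(S0_k))
  xbar <- S1_k / S0_k
  U <- colSums(sum_wx - dtilde * xbar)
  info <- matrix(0, p, p)
  for (k in seq_along(ut)) {
    risk <- first_idx[k]:n
    rk <- r[risk]
    Xk <- X_s[risk, , drop = FALSE]
    S2k <- crossprod(Xk * sqrt(rk))
    info <- info + dtilde[k] * (S2k / S0_k[k] - tcrossprod(xbar[k, ]))
  }
  list(loglik = loglik, U = U, info = info,
       ord = o, t_s = t_s, e_s = e_s, X_s = X_s, w_s = w_s, r = r,
       ut = ut, first_idx = first_idx, S0_k = S0_k, xbar = xbar,
       dtilde = dtilde)
}

#' Fit a weighted Cox proportional-hazards model
#'
#' Maximizes the weighted Breslow log partial likelihood by Newton-Raphson
#' with step-halving. Case-control reweighting enters through `weights`
#' (see [control_weight()]). The model-based variance is the inverse
#' information; the robust variance is the sandwich estimator from
#' weighted per-subject score residuals (dfbeta), which is what the
#' reported confidence intervals use.
#'
#' @param time positive follow-up times.
#' @param event logical (or 0/1) event indicators; at least one event.
#' @param X numeric covariate matrix (one column per covariate; column
#'   names become coefficient names).
#' @param weights positive case weights (default all 1).
#' @param tol convergence threshold on the max absolute score
#'   (default 1e-7).
#' @param max_iter Newton iteration cap (default 100).
#' @return object of class `cox_fit`: `coefficients`, `var` (model-based),
#'   `robust_var`, `hazard_ratios` (HR, 95% CI from robust SEs, z, p),
#'   `loglik`, `n`, `n_events`, `converged`, `baseline` (event times,
#'   weighted Breslow cumulative hazard increments), plus the sorted data
#'   needed by [baseline_survival()] and [ph_assumption_check()].
#' @export
fit_weighted_cox <- function(time, event, X, weights = NULL,
                             tol = 1e-7, max_iter = 100L) {
  X <- as.matrix(X)
  event <- as.logical(event)
  n <- length(time)
  stopifnot(length(event) == n, nrow(X) == n, all(time > 0))
  if (!any(event)) stop("no events: Cox model undefined")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  beta <- rep(0, p)
  cs <- cox_sums(time, event, X, weights, beta)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    if (max(abs(cs$U)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(cs$info, cs$U), error = function(e)
      stop("singular information matrix; check covariate ",
           colnames(X)[which.max(diag(cs$info) == min(diag(cs$info)))],
           " for collinearity or separation"))
    # step-halving: never accept a decrease in the partial likelihood
    for (h in 0:30) {
      beta_new <- beta + step / 2^h
      cs_new <- cox_sums(time, event, X, weights, beta_new)
      if (cs_new$loglik >= cs$loglik - 1e-12) break
    }
    beta <- beta_new
    cs <- cs_new
  }
  if (!converged && max(abs(cs$U)) < tol) converged <- TRUE
  vcov_model <- solve(cs$info)
  # weighted score residuals -> dfbeta -> sandwich
  resid_score <- cox_score_residuals(cs, beta)
  dfbeta <- (cs$w_s * resid_score) %*% vcov_model
  robust_var <- crossprod(dfbeta)
  se_r <- sqrt(diag(robust_var))
  hr <- data.frame(covariate = colnames(X),
                   coef = beta,
                   hr = exp(beta),
                   se_robust = se_r,
                   hr_lo = exp(beta - 1.96 * se_r),
                   hr_hi = exp(beta + 1.96 * se_r),
                   z = beta / se_r,
                   p = 2 * pnorm(-abs(beta / se_r)),
                   stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = setNames(beta, colnames(X)),
                 var = vcov_model, robust_var = robust_var,
                 hazard_ratios = hr,
                 loglik = cs$loglik, n = n, n_events = sum(event),
                 converged = converged, iterations = iter,
                 baseline = data.frame(time = cs$ut,
                                       dH0 = cs$dtilde / cs$S0_k),
                 sums = cs, X = X, time = time, event = event,
                 weights = weights),
            class = "cox_fit")
}

# per-subject (unweighted) score residuals at beta, using the sorted
# pieces in cs; row order matches cs$ord (sorted by time)
cox_score_residuals <- function(cs, beta) {
  n <- length(cs$t_s); p <- ncol(cs$X_s)
  A_k <- cs$dtilde / cs$S0_k                       # dH0 increments
  B_k <- cs$xbar * A_k                             # xbar * dH0
  cumA <- cumsum(A_k)
  cumB <- apply(B_k, 2, cumsum)
  cumB <- matrix(cumB, ncol = p)
  # index of last event time <= t_i for each subject
  ki <- findInterval(cs$t_s, cs$ut)
  r_unw <- exp(drop(cs$X_s %*% beta))
  res <- matrix(0, n, p)
  ev_k <- match(cs$t_s, cs$ut)                     # event-time index (NA ok)
  for (i in seq_len(n)) {
    xi <- cs$X_s[i, ]
    if (cs$e_s[i]) res[i, ] <- xi - cs$xbar[ev_k[i], ]
    if (ki[i] >= 1)
      res[i, ] <- res[i, ] - r_unw[i] * (xi * cumA[ki[i]] - cumB[ki[i], ])
  }
  res
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("weighted Cox fit: n = %d, events = %d, %s in %d iteration(s)\n",
              x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$hazard_ratios, digits = 3)
  invisible(x)
}

#' Baseline and profile survival curves from a weighted Cox fit
#'
#' The weighted Breslow cumulative baseline hazard is
#' `H0(t) = sum over event times t_k <= t of dtilde_k / S0(t_k)`; the
#' survival of a covariate profile x is
#' `S(t | x) = exp(-H0(t))^(exp(beta' x))`.
#'
#' @param fit a converged [fit_weighted_cox()] object.
#' @param covariate_profile numeric vector (or matrix, one profile per
#'   row) in the fit's covariate space; default the weighted cohort means.
#' @return data.frame with `time`, `H0` and one survival column per
#'   profile.
#' @export
baseline_survival <- function(fit, covariate_profile = NULL) {
  if (!fit$converged) stop("baseline_survival requires a converged fit")
  if (is.null(covariate_profile))
    covariate_profile <- colSums(fit$X * fit$weights) / sum(fit$weights)
  prof <- if (is.matrix(covariate_profile)) covariate_profile else
    matrix(covariate_profile, nrow = 1)
  H0 <- cumsum(fit$baseline$dH0)
  out <- data.frame(time = fit$baseline$time, H0 = H0)
  for (i in seq_len(nrow(prof))) {
    risk <- exp(sum(fit$coefficients * prof[i, ]))
    out[[paste0("S_profile", i)]] <- exp(-H0 * risk)
  }
  out
}

#' PRS-percentile survival curves
#'
#' Sweeps one covariate (the PRS) over cohort quantiles while holding all
#' other covariates at their weighted cohort means, and evaluates
#' [baseline_survival()] for each profile.
#'
#' @param fit a converged [fit_weighted_cox()] object.
#' @param prs_column name of the PRS column in the fit's covariate matrix.
#' @param percentiles probabilities to sweep (default deciles 0.1..0.9).
#' @return data.frame with `time`, `H0`, and one `S_p<percentile>` column
#'   per requested percentile.
#' @export
prs_percentile_curves <- function(fit, prs_column = "prs",
                                  percentiles = seq(0.1, 0.9, 0.1)) {
  stopifnot(prs_column %in% colnames(fit$X))
  base <- colSums(fit$X * fit$weights) / sum(fit$weights)
  qs <- quantile(fit$X[, prs_column], percentiles, names = FALSE)
  prof <- matrix(rep(base, each = length(qs)), nrow = length(qs),
                 dimnames = list(NULL, colnames(fit$X)))
  prof[, prs_column] <- qs
  out <- baseline_survival(fit, prof)
  names(out)[-(1:2)] <- sprintf("S_p%02d", round(100 * percentiles))
  out
}

#' Proportional-hazards assumption check via scaled Schoenfeld residuals
#'
#' Per covariate, the scaled Schoenfeld residuals (inverse-information
#' scaling, offset by the fitted coefficient) are correlated against the
#' rank of the event time; the two-sided p-value is the usual t-test on
#' the correlation with k - 2 degrees of freedom. Report only — no refit.
#'
#' @param fit a converged [fit_weighted_cox()] object.
#' @return data.frame with `covariate`, `rho`, `p`, plus the residual
#'   matrix as attribute `"schoenfeld"` (one row per event, sorted by
#'   event time).
#' @export
ph_assumption_check <- function(fit) {
  if (!fit$converged) stop("ph_assumption_check requires a converged fit")
  cs <- fit$sums
  if (sum(cs$e_s) < 2) stop("need at least 2 events for the PH check")
  ev <- which(cs$e_s)
  ev_k <- match(cs$t_s[ev], cs$ut)
  sch <- cs$X_s[ev, , drop = FALSE] - cs$xbar[ev_k, , drop = FALSE]
  d <- length(ev)
  scaled <- d * sch %*% fit$var +
    matrix(fit$coefficients, d, ncol(sch), byrow = TRUE)
  tr <- rank(cs$t_s[ev])
  res <- do.call(rbind, lapply(seq_len(ncol(sch)), function(j) {
    ct <- suppressWarnings(cor.test(scaled[, j], tr))
    data.frame(covariate = names(fit$coefficients)[j],
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  attr(res, "schoenfeld") <- sch
  res
}
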