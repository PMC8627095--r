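# Core Cox partial-likelihood machinery (Breslow tie handling) shared by the
# univariate and multivariable interfaces.
#
# Newton-Raphson from beta = 0 with step halving; a coefficient walking past
# +-15 on the log-hazard scale is treated as a monotone-likelihood /
# non-convergent fit and flagged rather than reported.
coxNR <- function(X, time, event, tol = 1e-8, maxIter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(time) != n || length(event) != n)
    stopf("time/event must align with the covariate rows")
  if (any(time <= 0)) stopf("survival times must be > 0")
  if (sum(event) < 1) stopf("no events: Cox model cannot be fit")

  ord <- order(time, -event)   # increasing time; events before censorings at ties
  X <- X[ord, , drop = FALSE]
  time <- time[ord]
  event <- event[ord]

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    ll <- 0
    # risk sums from the back (largest time first)
    S0 <- rev(cumsum(rev(w)))
    # Breslow: each event contributes eta_i - log S0(t_i) with S0 over {time >= t_i}
    riskStart <- match(time, time)  # first index with this time (times sorted)
    ev <- which(event == 1)
    sum(eta[ev] - log(S0[riskStart[ev]]))
  }

  scoreInfo <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    S0 <- rev(cumsum(rev(w)))
    S1 <- apply(X * w, 2L, function(col) rev(cumsum(rev(col))))
    S1 <- matrix(S1, n, p)
    riskStart <- match(time, time)
    ev <- which(event == 1)
    U <- colSums(X[ev, , drop = FALSE] - S1[riskStart[ev], , drop = FALSE] / S0[riskStart[ev]])
    I <- matrix(0, p, p)
    for (a in seq_len(p)) for (b in a:p) {
      S2ab <- rev(cumsum(rev(X[, a] * X[, b] * w)))
      s0 <- S0[riskStart[ev]]
      term <- sum(S2ab[riskStart[ev]] / s0 -
                  (S1[riskStart[ev], a] / s0) * (S1[riskStart[ev], b] / s0))
      I[a, b] <- term
      I[b, a] <- term
    }
    list(U = U, I = I)
  }

  beta <- rep(0, p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    si <- scoreInfo(beta)
    step <- tryCatch(solve(si$I, si$U), error = function(e) NULL)
    if (is.null(step)) break
    newBeta <- beta + step
    newLL <- loglik(newBeta)
    halvings <- 0L
    while ((!is.finite(newLL) || newLL < ll - 1e-12) && halvings < 20L) {
      step <- step / 2
      newBeta <- beta + step
      newLL <- loglik(newBeta)
      halvings <- halvings + 1L
    }
    deltaOk <- max(abs(step)) < tol
    beta <- newBeta
    ll <- newLL
    if (any(abs(beta) > 15)) {
      return(list(beta = sign(beta) * ifelse(abs(beta) > 15, Inf, abs(beta)),
                  se = rep(NA_real_, p), converged = FALSE, iterations = iter,
                  loglik = ll, info = si$I))
    }
    if (deltaOk) { converged <- TRUE; break }
  }
  si <- scoreInfo(beta)
  se <- sqrt(diag(solve(si$I)))
  list(beta = beta, se = se, converged = converged, iterations = iter,
       loglik = ll, info = si$I)
}

coxFitTable <- function(fit, terms, level = 0.95) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- fit$beta / fit$se
  data.frame(term = terms,
             beta = fit$beta,
             se = fit$se,
             z = z,
             p = 2 * stats::pnorm(-abs(z)),
             hr = exp(fit$beta),
             ciLow = exp(fit$beta - zq * fit$se),
             ciHigh = exp(fit$beta + zq * fit$se),
             converged = fit$converged,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Univariate Cox proportional-hazards fit
#'
#' Breslow tie handling, Newton-Raphson maximisation (tolerance 1e-8, at
#' most 50 iterations), Wald inference. Monotone-likelihood fits are flagged
#' (`converged = FALSE`, infinite coefficient sentinel) so callers can
#' exclude them.
#'
#' @param x Numeric covariate per sample.
#' @param time,event Overall survival time (> 0) and status (0/1).
#' @return One-row data frame: beta, se, z, p, hr, ciLow, ciHigh, converged.
#' @export
univariateCox <- function(x, time, event) {
  if (any(!is.finite(x))) stopf("covariate must be finite")
  fit <- coxNR(matrix(x, ncol = 1L), time, event)
  coxFitTable(fit, "x")
}

#' Multivariable Cox proportional-hazards fit
#'
#' Categorical covariates are one-hot encoded (first level as reference);
#' the design must be full rank and carry at least 10 events.
#'
#' @param covariates Data frame of covariates (numeric or categorical).
#' @param time,event Survival time and status.
#' @return Data frame with one row per model term.
#' @export
multivariableCox <- function(covariates, time, event) {
  if (sum(event) < 10) stopf("at least 10 events are required")
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1L, drop = FALSE]
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stopf("collinear design; aliased column(s): %s", paste(aliased, collapse = ", "))
  }
  fit <- coxNR(mm, time, event)
  coxFitTable(fit, colnames(mm))
}

#' Kaplan-Meier product-limit estimator
#'
#' Ties between events and censorings at the same time are resolved by
#' processing events first (censored subjects remain at risk for that
#' time's events).
#'
#' @param time,event Survival time (> 0) and status (0/1).
#' @return Data frame (time, nRisk, nEvent, nCensor, surv) over the distinct
#'   observed times; S(0) = 1 implicitly.
#' @export
kaplanMeier <- function(time, event) {
  if (!length(time)) stopf("empty survival input")
  if (any(time <= 0)) stopf("survival times must be > 0")
  ut <- sort(unique(time))
  nRisk <- vapply(ut, function(t) sum(time >= t), 0)
  nEvent <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  nCensor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - nEvent / nRisk)
  data.frame(time = ut, nRisk = nRisk, nEvent = nEvent,
             nCensor = nCensor, surv = surv, row.names = NULL)
}

#' Log-rank test across two or more groups
#'
#' Observed-minus-expected chi-square with hypergeometric variance at each
#' distinct event time, on k-1 degrees of freedom. For two groups, the
#' standardised statistic `z = (O1 - E1)/sqrt(V11)` is also returned (the
#' quantity maximised by the optimal-cutpoint search).
#'
#' @param groups Grouping vector (>= 2 non-empty groups).
#' @param time,event Survival time and status.
#' @return List: chi2, df, p, observed, expected, and z (two groups only).
#' @export
logrankTest <- function(groups, time, event) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) < 2L)
    stopf("at least two non-empty groups are required")
  if (sum(event) < 1) stopf("at least one event is required")
  k <- nlevels(groups)
  evTimes <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(rep(0, k), levels(groups))
  V <- matrix(0, k, k, dimnames = list(levels(groups), levels(groups)))
  for (t in evTimes) {
    atRisk <- time >= t
    nT <- sum(atRisk)
    dT <- sum(time == t & event == 1)
    nG <- vapply(levels(groups), function(g) sum(atRisk & groups == g), 0)
    dG <- vapply(levels(groups), function(g) sum(time == t & event == 1 & groups == g), 0)
    O <- O + dG
    E <- E + dT * nG / nT
    if (nT > 1) {
      mult <- dT * (nT - dT) / (nT - 1)
      pG <- nG / nT
      V <- V + mult * (diag(pG, k) - outer(pG, pG))
    }
  }
  OE <- (O - E)[-k]
  Vred <- V[-k, -k, drop = FALSE]
  chi2 <- if (max(abs(O - E)) < 1e-12) 0 else {
    sol <- tryCatch(solve(Vred, OE), error = function(e) NULL)
    if (is.null(sol)) 0 else drop(crossprod(OE, sol))
  }
  out <- list(chi2 = chi2, df = k - 1L,
              p = stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE),
              observed = O, expected = E, variance = V)
  if (k == 2L)
    out$z <- if (V[1L, 1L] > 0) unname(O[1L] - E[1L]) / sqrt(V[1L, 1L]) else 0
  out
}

# Log-rank (Peto) scores: a_i = status_i - cumulative hazard at the
# subject's time, with the Nelson-Aalen estimator over distinct event times.
logrankScores <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  d <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  nRisk <- vapply(ut, function(t) sum(time >= t), 0)
  cumHaz <- cumsum(d / nRisk)
  haz <- function(t) {
    idx <- findInterval(t, ut)
    ifelse(idx == 0, 0, cumHaz[pmax(idx, 1L)])
  }
  event - haz(time)
}

#' Optimal survival cutpoint by maximally selected rank statistics
#'
#' Computes per-subject log-rank scores once, then evaluates the
#' standardised between-group score sum at every admissible midpoint
#' between consecutive sorted unique score values (both resulting groups
#' must hold at least `minprop` of the samples):
#' `z = (S - n_high * mean(a)) / sqrt(n_high * n_low / (n (n-1)) * sum((a - mean(a))^2))`
#' where `S` is the sum of the log-rank scores `a` in the high group — the
#' permutation standardisation of the maximally selected rank statistic.
#' The cutoff maximising |z| is returned; ties go to the lower cutoff. The
#' maximum is not corrected for the multiplicity of candidate cutpoints;
#' downstream inference should use the log-rank test on the resulting
#' groups, as published, with that caveat in mind.
#'
#' @param score Numeric score per sample.
#' @param time,event Survival time and status.
#' @param minprop Minimum fraction of samples on each side (default 0.1).
#' @return List: cutoff, statistic (signed standardised statistic at the
#'   cutoff), nHigh, nLow, minprop, and the full candidate table.
#' @export
optimalCutpoint <- function(score, time, event, minprop = 0.1) {
  u <- sort(unique(score))
  if (length(u) < 2L) stopf("at least two distinct score values are required")
  if (sum(event) < 1) stopf("at least one event is required")
  mids <- (u[-length(u)] + u[-1L]) / 2
  n <- length(score)
  a <- logrankScores(time, event)
  abar <- mean(a)
  ssq <- sum((a - abar)^2)
  stats_ <- rep(NA_real_, length(mids))
  admissible <- logical(length(mids))
  for (i in seq_along(mids)) {
    hi <- score > mids[i]
    n1 <- sum(hi)
    if (min(n1, n - n1) / n < minprop) next
    admissible[i] <- TRUE
    v <- n1 * (n - n1) / (n * (n - 1)) * ssq
    stats_[i] <- if (v > 0) (sum(a[hi]) - n1 * abar) / sqrt(v) else 0
  }
  if (!any(admissible)) stopf("no admissible split satisfies minprop = %g", minprop)
  idx <- which(admissible)
  best <- idx[which.max(abs(stats_[idx]))]  # which.max takes the first (lower cutoff) on ties
  cutoff <- mids[best]
  list(cutoff = cutoff,
       statistic = stats_[best],
       nHigh = sum(score > cutoff),
       nLow = sum(score <= cutoff),
       minprop = minprop,
       candidates = data.frame(cutoff = mids, z = stats_, admissible = admissible))
}

#' Dichotomise a score at a cutoff
#'
#' Samples strictly above the cutoff are "high"; scores equal to the cutoff
#' fall in the "low" group.
#'
#' @param score Numeric scores.
#' @param cutoff Finite cutoff.
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize <- function(score, cutoff) {
  if (!is.finite(cutoff)) stopf("cutoff must be finite")
  factor(ifelse(score > cutoff, "high", "low"), levels = c("low", "high"))
}
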