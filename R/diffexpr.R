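#' Empirical-Bayes moderated two-group t-test
#'
#' Per feature, an ordinary two-group comparison on log2-scale data whose
#' residual variances are shrunk towards a common prior variance s0^2 with
#' prior degrees of freedom d0, estimated by method of moments on the
#' log residual variances: with d = n - 2 residual df per feature, the model
#' log s^2 = log s0^2 + log(chi^2_d/d) - log(chi^2_d0/d0) gives
#' Var(log s^2) = trigamma(d/2) + trigamma(d0/2), solved for d0 by inverting
#' the trigamma function. The moderated statistic is
#' t = log2FC / (s_tilde * sqrt(1/n1 + 1/n2)) with
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d) on d + d0 degrees of freedom.
#'
#' When the prior df is infinite (estimated, or forced through `dfPrior`),
#' every feature uses the common variance, taken as the df-weighted pooled
#' residual variance across features (the maximum-likelihood common-variance
#' estimate under the equal-variance model).
#'
#' The fold-change direction convention is group 2 minus group 1 (positive
#' log2FC = higher in the second group level).
#'
#' @param exprLog Feature-by-sample matrix on the log2 scale.
#' @param groups Two-level grouping vector aligned with columns; the sorted
#'   first level is "group 1".
#' @param dfPrior Optional prior df override (e.g. `Inf` to fully pool).
#' @return Data frame (feature, log2fc, s2, t, p, adj_p) with attributes
#'   `dfPrior`, `s02`, and `dfResidual`.
#' @export
moderatedTTest <- function(exprLog, groups, dfPrior = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups are required")
  if (length(groups) != ncol(exprLog))
    stopf("one group label per sample is required")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (min(n1, n2) < 2L) stopf("each group needs at least 2 samples")

  x1 <- exprLog[, groups == levels(groups)[1L], drop = FALSE]
  x2 <- exprLog[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  fc <- m2 - m1
  d <- n1 + n2 - 2L
  rss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- rss / d

  pos <- s2 > 0
  if (!any(pos)) {
    d0 <- Inf
    s02 <- 0
  } else {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- if (sum(pos) > 1L) stats::var(e) else 0
    excess <- evar - trigamma(d / 2)
    d0 <- if (excess > 0) 2 * trigammaInverse(excess) else Inf
    s02 <- if (is.finite(d0)) exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
           else sum(d * s2[pos]) / (d * sum(pos))
  }
  if (!is.null(dfPrior)) {
    d0 <- dfPrior
    if (!is.finite(d0)) {
      s02 <- if (any(pos)) sum(d * s2[pos]) / (d * sum(pos)) else 0
    } else if (any(pos)) {
      e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }

  stilde2 <- if (is.finite(d0)) (d0 * s02 + d * s2) / (d0 + d) else rep(s02, length(s2))
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, fc / se, ifelse(fc == 0, 0, sign(fc) * Inf))
  dfTotal <- if (is.finite(d0)) d + d0 else Inf
  p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  p[se == 0 & fc == 0] <- 1
  degenerate <- sum(se == 0 & fc == 0)
  if (degenerate > 0)
    mc5Log(degenerate, " feature(s) with zero residual variance and zero ",
           "fold change: t set to 0, p to 1")

  out <- data.frame(gene = rownames(exprLog),
                    log2fc = fc,
                    s2 = s2,
                    t = tstat,
                    p = p,
                    adj_p = bhAdjust(p),
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "dfPrior") <- d0
  attr(out, "s02") <- s02
  attr(out, "dfResidual") <- d
  attr(out, "direction") <- sprintf("log2fc = mean(%s) - mean(%s)",
                                    levels(groups)[2L], levels(groups)[1L])
  out
}

#' Select differentially expressed genes at the published thresholds
#'
#' Strict inequalities on both criteria: adjusted p below `adjPMax` (default
#' 0.001) and |log2FC| above `minAbsLog2FC` (default 1.5, log2 units).
#'
#' @param table Output of [moderatedTTest()].
#' @param adjPMax,minAbsLog2FC Selection thresholds.
#' @return Character vector of selected genes.
#' @export
selectDegs <- function(table, adjPMax = 0.001, minAbsLog2FC = 1.5) {
  table$gene[table$adj_p < adjPMax & abs(table$log2fc) > minAbsLog2FC]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement, via
#' [stats::p.adjust()]. Inputs outside \[0,1\] are rejected.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0,1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}
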