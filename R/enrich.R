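#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (average ranks on ties)
#' and walked in decreasing order; the enrichment score is the sum over the
#' ordered list of the difference between the weighted in-set empirical CDF
#' (weights = rank^alpha) and the uniform out-of-set CDF. Scores therefore
#' depend only on within-sample ranks and are invariant to monotone
#' transforms of the expression values. With `normalize = TRUE` the whole
#' score matrix is divided by its range (max - min).
#'
#' @param exprLog Gene-by-sample matrix (any monotone expression scale).
#' @param sets Gene-set collection as returned by [readGeneSets()].
#' @param alpha Rank-weight exponent (default 0.25).
#' @param normalize Divide all scores by the global score range.
#' @return Signature-by-sample matrix; sets with no overlap are skipped with
#'   a warning (absent from the output, not zero-filled).
#' @export
ssgsea <- function(exprLog, sets, alpha = 0.25, normalize = TRUE) {
  if (!length(sets)) stopf("empty gene-set collection")
  genes <- rownames(exprLog)
  N <- length(genes)
  keep <- vapply(sets, function(s) length(intersect(s$genes, genes)) > 0, TRUE)
  if (any(!keep)) {
    warning(sprintf("skipping %d gene set(s) with no overlap: %s", sum(!keep),
                    paste(names(sets)[!keep], collapse = ", ")), call. = FALSE)
    mc5Log("ssGSEA: skipped set(s) with zero overlap: ",
           paste(names(sets)[!keep], collapse = ", "))
    sets <- sets[keep]
  }
  if (!length(sets)) stopf("no gene set overlaps the expression matrix")

  ranks <- apply(exprLog, 2L, rank)          # average ranks on ties
  inset <- lapply(sets, function(s) genes %in% s$genes)
  ES <- matrix(0, length(sets), ncol(exprLog),
               dimnames = list(names(sets), colnames(exprLog)))
  for (j in seq_len(ncol(exprLog))) {
    r <- ranks[, j]
    ord <- order(r, decreasing = TRUE)       # ties resolved by gene order
    w <- r[ord]^alpha
    for (i in seq_along(sets)) {
      ins <- inset[[i]][ord]
      wIn <- w * ins
      sumIn <- sum(wIn)
      nOut <- N - sum(ins)
      pIn <- cumsum(wIn) / sumIn
      pOut <- if (nOut > 0) cumsum(!ins) / nOut else rep(0, N)
      ES[i, j] <- sum(pIn - pOut)
    }
  }
  if (normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
  }
  attr(ES, "alpha") <- alpha
  attr(ES, "normalized") <- normalize
  ES
}

#' T-cell-inflamed score (TIS)
#'
#' Weighted sum of log-scale expression over the 18 published
#' IFN-gamma-responsive genes: `TIS_j = sum_g beta_g * x_gj`. The
#' coefficients are supplied by the user (see [readTisWeights()]); genes
#' absent from the matrix contribute 0 with a warning.
#'
#' @param exprLog Gene-by-sample matrix on the log2 scale.
#' @param weights Named numeric coefficients.
#' @return Named numeric TIS per sample.
#' @export
tisScore <- function(exprLog, weights) {
  if (is.null(names(weights)) || any(!is.finite(weights)))
    stopf("weights must be a named, finite numeric vector")
  present <- intersect(names(weights), rownames(exprLog))
  if (!length(present)) stopf("none of the TIS genes are present in the matrix")
  if (length(present) < length(weights))
    warning(sprintf("%d TIS gene(s) absent; contribute 0",
                    length(weights) - length(present)), call. = FALSE)
  drop(crossprod(exprLog[present, , drop = FALSE], weights[present]))
}

#' Cancer-immunity-cycle step activities
#'
#' Each step is a signed gene set (directions +1/-1 from the signed-GMT
#' dialect); its activity per sample is the ssGSEA score of the
#' positive-direction genes minus the ssGSEA score of the negative-direction
#' genes (steps without negative genes reduce to plain ssGSEA). Subset
#' scores are computed unnormalised so the subtraction is on a common scale.
#'
#' @param exprLog Gene-by-sample matrix.
#' @param stepSets Gene-set collection with direction weights.
#' @param alpha ssGSEA exponent.
#' @return Step-by-sample activity matrix.
#' @export
immunityCycleActivity <- function(exprLog, stepSets, alpha = 0.25) {
  if (!length(stepSets)) stopf("empty step-set collection")
  out <- matrix(0, length(stepSets), ncol(exprLog),
                dimnames = list(names(stepSets), colnames(exprLog)))
  for (nm in names(stepSets)) {
    s <- stepSets[[nm]]
    posGenes <- s$genes[s$weights[s$genes] > 0]
    negGenes <- s$genes[s$weights[s$genes] < 0]
    act <- rep(0, ncol(exprLog))
    if (length(intersect(posGenes, rownames(exprLog))))
      act <- act + ssgsea(exprLog, list(step = list(genes = posGenes)),
                          alpha = alpha, normalize = FALSE)[1L, ]
    if (length(intersect(negGenes, rownames(exprLog))))
      act <- act - ssgsea(exprLog, list(step = list(genes = negGenes)),
                          alpha = alpha, normalize = FALSE)[1L, ]
    out[nm, ] <- act
  }
  out
}

#' Correlate a per-sample score with a feature matrix
#'
#' Spearman (default) or Pearson correlation per feature, with a
#' t-approximation p-value and BH adjustment across the non-degenerate
#' features. Constant features are emitted with a flag and excluded from
#' the adjustment.
#'
#' @param score Numeric score per sample.
#' @param features Feature-by-sample matrix.
#' @param method `"spearman"` or `"pearson"`.
#' @return Data frame (feature, coefficient, p, adj_p, constant).
#' @export
correlateScore <- function(score, features, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  features <- rbind(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("feature", seq_len(nrow(features)))
  if (ncol(features) != length(score)) stopf("features must align with the score samples")
  if (length(score) < 3L) stopf("at least 3 paired samples are required")
  res <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    if (stats::sd(f) == 0 || stats::sd(score) == 0)
      return(data.frame(coefficient = NA_real_, p = NA_real_, constant = TRUE))
    ct <- suppressWarnings(stats::cor.test(score, f, method = method, exact = FALSE))
    data.frame(coefficient = unname(ct$estimate), p = ct$p.value, constant = FALSE)
  })
  out <- do.call(rbind, res)
  out <- data.frame(feature = rownames(features), out,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- NA_real_
  ok <- !out$constant
  if (any(ok)) out$adj_p[ok] <- bhAdjust(out$p[ok])
  out
}

#' Compare features between two groups
#'
#' Continuous features: with `test = "auto"`, both groups are checked for
#' normality (Shapiro-Wilk at alpha 0.05) and compared by Welch t when both
#' pass, Mann-Whitney U otherwise (normal approximation, no continuity
#' correction). Binary 0/1 features use Fisher's exact test on the 2x2
#' counts. Effects are reported as group-2 minus group-1 (means for t,
#' rates for Fisher, rank-biserial-like median shift for MWU); BH adjustment
#' runs across all features.
#'
#' @param features Feature-by-sample matrix.
#' @param groups Two-level grouping vector.
#' @param test `"auto"`, `"t"`, `"mwu"`, or `"fisher"`.
#' @return Data frame (feature, test, effect, p, adj_p).
#' @export
compareGroups <- function(features, groups, test = c("auto", "t", "mwu", "fisher")) {
  test <- match.arg(test)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups are required")
  features <- rbind(features)
  if (is.null(rownames(features)))
    rownames(features) <- paste0("feature", seq_len(nrow(features)))
  g1 <- groups == levels(groups)[1L]
  g2 <- groups == levels(groups)[2L]
  if (test %in% c("auto", "t", "mwu") && min(sum(g1), sum(g2)) < 3L)
    stopf("each group needs at least 3 samples for continuous tests")

  oneFeature <- function(f) {
    isBinary <- all(f %in% c(0, 1))
    useTest <- test
    if (useTest == "auto") {
      if (isBinary) useTest <- "fisher"
      else {
        shOk <- function(v) {
          if (length(unique(v)) < 3L) return(FALSE)
          stats::shapiro.test(v)$p.value > 0.05
        }
        useTest <- if (shOk(f[g1]) && shOk(f[g2])) "t" else "mwu"
      }
    }
    if (useTest == "fisher") {
      tab <- rbind(c(sum(f[g1] == 1), sum(f[g1] == 0)),
                   c(sum(f[g2] == 1), sum(f[g2] == 0)))
      p <- stats::fisher.test(tab)$p.value
      eff <- mean(f[g2]) - mean(f[g1])
    } else if (useTest == "t") {
      ht <- stats::t.test(f[g2], f[g1])
      p <- ht$p.value
      eff <- mean(f[g2]) - mean(f[g1])
    } else {
      ht <- suppressWarnings(stats::wilcox.test(f[g2], f[g1], exact = FALSE,
                                                correct = FALSE))
      p <- ht$p.value
      eff <- stats::median(f[g2]) - stats::median(f[g1])
    }
    data.frame(test = useTest, effect = eff, p = p)
  }
  res <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) oneFeature(features[i, ])))
  out <- data.frame(feature = rownames(features), res,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- bhAdjust(out$p)
  out
}
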