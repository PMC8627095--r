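#' Filter differentially expressed genes for prognostic value
#'
#' Runs a univariate Cox model per gene on log2 expression and keeps genes
#' with Wald p strictly below `alpha` (default 0.05, the field-standard
#' threshold; the source analysis states no explicit value). Flagged
#' non-convergent fits are excluded with a log entry.
#'
#' @param degGenes Character vector of candidate genes.
#' @param exprLog Gene-by-sample matrix on the log2 scale.
#' @param clinical Data frame with `sample_id`, `os_time`, `os_event`
#'   aligned with (or matched to) the expression columns.
#' @param alpha Wald p-value threshold.
#' @return Character vector of prognostic genes.
#' @export
selectPrognostic <- function(degGenes, exprLog, clinical, alpha = 0.05) {
  if (!length(degGenes)) stopf("the DEG list is empty")
  clinical <- clinical[match(colnames(exprLog), clinical$sample_id), ]
  if (anyNA(clinical$sample_id))
    stopf("clinical table lacks some expression samples")
  genes <- intersect(degGenes, rownames(exprLog))
  keep <- character()
  dropped <- character()
  for (g in genes) {
    fit <- tryCatch(univariateCox(exprLog[g, ], clinical$os_time, clinical$os_event),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      dropped <- c(dropped, g)
      next
    }
    if (fit$p < alpha) keep <- c(keep, g)
  }
  if (length(dropped))
    mc5Log("excluded ", length(dropped),
           " gene(s) with non-convergent Cox fits: ",
           paste(utils::head(dropped, 5L), collapse = ", "))
  if (!length(keep))
    stopf("no prognostic genes at alpha = %g; consider relaxing the threshold", alpha)
  keep
}

#' Fit the 5mC score model
#'
#' Standardises each prognostic gene to a z-score, takes the leading
#' eigenvector of the gene-gene correlation matrix as the PC1 loadings
#' (unit norm), and orients the score so that cluster 1 carries the higher
#' mean (matching the published equivalence of cluster 1 with the high-score
#' group). Zero-variance genes are dropped with a warning.
#'
#' @param exprLog Gene-by-sample matrix on the log2 scale.
#' @param genes Prognostic gene list.
#' @param clusterLabels Cluster assignment (1/2) per sample, used only for
#'   orientation.
#' @return A [ScoreModel-class].
#' @export
fitScoreModel <- function(exprLog, genes, clusterLabels) {
  genes <- intersect(genes, rownames(exprLog))
  if (length(genes) < 2L) stopf("at least 2 model genes are required")
  if (ncol(exprLog) < 3L) stopf("at least 3 samples are required")
  X <- exprLog[genes, , drop = FALSE]
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(sds == 0)), call. = FALSE)
    X <- X[sds > 0, , drop = FALSE]
    genes <- rownames(X)
    sds <- sds[sds > 0]
    if (length(genes) < 2L) stopf("all but %d gene(s) dropped; cannot fit PC1", length(genes))
  }
  centers <- rowMeans(X)
  Z <- (X - centers) / sds
  R <- stats::cor(t(X))
  eig <- eigen(R, symmetric = TRUE)
  w <- eig$vectors[, 1L]
  w <- w / sqrt(sum(w^2))
  names(w) <- genes
  raw <- drop(crossprod(Z, w))
  m1 <- mean(raw[clusterLabels == 1])
  m2 <- mean(raw[clusterLabels == 2])
  s <- if (m1 >= m2) 1 else -1
  methods::new("ScoreModel",
               genes = genes,
               centers = stats::setNames(centers, genes),
               scales = stats::setNames(sds, genes),
               loadings = w,
               sign = s,
               varianceExplained = eig$values[1L] / sum(pmax(eig$values, 0)))
}

#' Apply a score model to an expression matrix
#'
#' The per-sample score is the oriented PC1 projection
#' `s * sum_g w_g (x_gj - mean_g) / sd_g`. By default the standardisation
#' constants are recomputed within the scored cohort, which makes scores
#' comparable across platforms; set `freezeStandardization = TRUE` to reuse
#' the training constants. Model genes missing from the matrix enter at
#' standardised 0 with a warning; below 50% overlap the call errors.
#'
#' @param model A [ScoreModel-class].
#' @param exprLog Gene-by-sample matrix on the log2 scale.
#' @param freezeStandardization Reuse training means/sds instead of
#'   recomputing them in this cohort.
#' @return Named numeric score per sample.
#' @export
applyScore <- function(model, exprLog, freezeStandardization = FALSE) {
  stopifnot(methods::is(model, "ScoreModel"))
  present <- intersect(model@genes, rownames(exprLog))
  missing <- setdiff(model@genes, present)
  if (length(present) < 0.5 * length(model@genes))
    stopf("fewer than half of the model genes are present; missing: %s",
          paste(missing, collapse = ", "))
  if (length(missing))
    warning(sprintf("%d model gene(s) absent; imputed at standardised 0: %s",
                    length(missing), paste(utils::head(missing, 5L), collapse = ", ")),
            call. = FALSE)
  X <- exprLog[present, , drop = FALSE]
  if (freezeStandardization) {
    ctr <- model@centers[present]
    scl <- model@scales[present]
  } else {
    ctr <- rowMeans(X)
    scl <- apply(X, 1L, stats::sd)
    if (any(scl == 0)) {
      warning(sprintf("%d model gene(s) constant in this cohort; contribute 0",
                      sum(scl == 0)), call. = FALSE)
      scl[scl == 0] <- Inf  # z-score 0
    }
  }
  Z <- (X - ctr) / scl
  drop(model@sign * crossprod(Z, model@loadings[present]))
}
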