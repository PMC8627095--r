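#' ROC curve and AUC for a score against binary labels
#'
#' AUC via the rank (Mann-Whitney) statistic with ties counted 0.5; the
#' operating points come from a threshold sweep over the distinct score
#' values (ties grouped), so the curve is monotone non-decreasing.
#'
#' @param score Numeric score per sample.
#' @param labels Binary labels (0/1, logical, or two-level factor); the
#'   positive class is 1 / `TRUE` / the second level.
#' @return List: `auc` and `curve` (data frame of fpr, tpr).
#' @export
rocAuc <- function(score, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("both classes must be present")
  r <- rank(score)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(score, decreasing = TRUE)
  sc <- score[ord]
  lb <- labels[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- cumsum(lb)
  fp <- cumsum(1L - lb)
  last <- !duplicated(grp, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1))
  list(auc = auc, curve = curve)
}

#' Agreement between two clusterings
#'
#' Contingency table plus the number of reclassified samples under the
#' label matching that maximises agreement (exhaustive over label
#' permutations, cheap for up to 6 clusters), so the result is invariant to
#' relabeling either input. An association p-value is attached: Fisher's
#' exact test for 2x2 tables, chi-square otherwise.
#'
#' @param labelsA,labelsB Cluster labels over the same samples.
#' @return List: `table`, `nReclassified`, `p`, `method`.
#' @export
crosstabAgreement <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stopf("label vectors must have the same length")
  tab <- table(labelsA, labelsB)
  nr <- nrow(tab)
  nc <- ncol(tab)
  k <- max(nr, nc)
  if (k > 6L) stopf("exhaustive label matching supports at most 6 clusters")
  sq <- matrix(0, k, k)
  sq[seq_len(nr), seq_len(nc)] <- tab
  perms <- permutations(k)
  agree <- apply(perms, 1L, function(pm) sum(sq[cbind(seq_len(k), pm)]))
  nReclassified <- length(labelsA) - max(agree)
  p <- if (nr == 2L && nc == 2L) stats::fisher.test(tab)$p.value
       else suppressWarnings(stats::chisq.test(tab)$p.value)
  list(table = tab, nReclassified = nReclassified, p = p,
       method = if (nr == 2L && nc == 2L) "fisher" else "chisq")
}

permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Compare mutation rates between two groups over a gene set
#'
#' Per-gene mutation rates per group with Fisher's exact p, plus the pooled
#' rate defined at the sample level (fraction of samples mutated in at
#' least one set gene) with its own Fisher test. Genes absent from the
#' table are skipped with a warning.
#'
#' @param mutations Sample-by-gene binary matrix.
#' @param groups Two-level grouping vector aligned with rows.
#' @param genes Gene set (non-empty).
#' @return List: `perGene` (gene, rate1, rate2, p) and `pooled`
#'   (rate1, rate2, p); group order follows the sorted factor levels.
#' @export
mutationRateCompare <- function(mutations, groups, genes) {
  if (!length(genes)) stopf("gene set must be non-empty")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stopf("exactly two groups are required")
  present <- intersect(genes, colnames(mutations))
  if (length(present) < length(genes))
    warning(sprintf("skipping %d gene(s) absent from the mutation table: %s",
                    length(genes) - length(present),
                    paste(setdiff(genes, present), collapse = ", ")), call. = FALSE)
  if (!length(present)) stopf("none of the genes are in the mutation table")
  g1 <- groups == levels(groups)[1L]
  fisherP <- function(x1, n1, x2, n2) {
    stats::fisher.test(rbind(c(x1, n1 - x1), c(x2, n2 - x2)))$p.value
  }
  perGene <- do.call(rbind, lapply(present, function(g) {
    x1 <- sum(mutations[g1, g])
    x2 <- sum(mutations[!g1, g])
    data.frame(gene = g,
               rate1 = x1 / sum(g1),
               rate2 = x2 / sum(!g1),
               p = fisherP(x1, sum(g1), x2, sum(!g1)),
               stringsAsFactors = FALSE)
  }))
  any1 <- as.integer(rowSums(mutations[, present, drop = FALSE]) > 0)
  pooled <- list(rate1 = mean(any1[g1]),
                 rate2 = mean(any1[!g1]),
                 p = fisherP(sum(any1[g1]), sum(g1), sum(any1[!g1]), sum(!g1)))
  list(perGene = perGene, pooled = pooled)
}

#' Run the full subtyping and scoring pipeline
#'
#' Orchestrates: consensus clustering on the regulator genes, relabeling so
#' cluster 1 is the regulator-high cluster, moderated-t DEG selection, the
#' univariate-Cox prognostic filter, the PC1 score, the maximally selected
#' survival cutpoint with log-rank and Cox summaries, ssGSEA of the
#' supplied (or cohort-derived marker) signatures with score correlations,
#' the DMP/DMG methylation stage when beta values are present, and the
#' evaluation stage (score-vs-truth AUC, cluster agreement, chemo-gene
#' mutation rates). Each stage failure aborts with the stage name; a
#' manifest records the configuration, seed, and stages run.
#'
#' @param cohort A [SyntheticCohort-class] (or a list with the same
#'   components: `expression`, `clinical`, optionally `methylation`,
#'   `probeAnnotation`, `mutations`, `trueLabels`, `geneRoles`).
#' @param config Run configuration, see [defaultConfig()].
#' @param geneSets Optional gene-set collection for the enrichment stage;
#'   defaults to marker-block sets derived from the cohort's gene roles.
#' @param chemoGenes Genes whose pooled mutation rate is compared between
#'   score groups (default the neoadjuvant-chemotherapy-related set).
#' @return List bundle with one element per stage plus `manifest`.
#' @export
runPipeline <- function(cohort, config = defaultConfig(), geneSets = NULL,
                        chemoGenes = c("RB1", "ATM", "ERBB2", "ERCC2", "FANCC")) {
  cfg <- defaultConfig()
  cfg[names(config)] <- config
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  getc <- function(what) {
    if (methods::is(cohort, "SyntheticCohort")) methods::slot(cohort, what)
    else cohort[[what]]
  }
  out <- list()
  stagesRun <- character()

  exprLog <- stage("expression", logTPM(getc("expression")))
  clinical <- getc("clinical")

  out$cluster <- stage("cluster", consensusCluster(exprLog, cfg))
  clusters <- clusterAssignments(out$cluster, k = 2L)
  ## anchor labels: cluster 1 = regulator-high cluster (orientation of the
  ## published system: regulator-high, luminal, high-score)
  regGenes <- intersect(regulatorCatalog()$gene, rownames(exprLog))
  regMeans <- tapply(colMeans(exprLog[regGenes, , drop = FALSE]), clusters, mean)
  if (which.max(regMeans) != 1L) clusters <- 3L - clusters
  out$clusters <- clusters
  stagesRun <- c(stagesRun, "cluster")

  out$deg <- stage("deg", moderatedTTest(exprLog, clusters))
  out$degGenes <- selectDegs(out$deg, cfg$degAdjPMax, cfg$degMinAbsLog2FC)
  stagesRun <- c(stagesRun, "deg")

  out$prognosticGenes <- stage("score",
    selectPrognostic(out$degGenes, exprLog, clinical, alpha = cfg$coxAlpha))
  out$scoreModel <- stage("score", fitScoreModel(exprLog, out$prognosticGenes, clusters))
  out$score <- stage("score", applyScore(out$scoreModel, exprLog))
  stagesRun <- c(stagesRun, "score")

  out$cutpoint <- stage("survival",
    optimalCutpoint(out$score, clinical$os_time, clinical$os_event,
                    minprop = cfg$cutpointMinprop))
  out$scoreGroup <- dichotomize(out$score, out$cutpoint$cutoff)
  out$survival <- stage("survival", list(
    logrank = logrankTest(out$scoreGroup, clinical$os_time, clinical$os_event),
    cox = univariateCox(as.integer(out$scoreGroup == "high"),
                        clinical$os_time, clinical$os_event),
    km = lapply(split(seq_along(out$score), out$scoreGroup), function(ix)
      kaplanMeier(clinical$os_time[ix], clinical$os_event[ix]))
  ))
  stagesRun <- c(stagesRun, "survival")

  roles <- tryCatch(getc("geneRoles"), error = function(e) NULL)
  if (is.null(geneSets) && !is.null(roles) && nrow(roles)) {
    mk <- function(role) {
      g <- roles$gene[roles$role == role]
      list(genes = g, weights = stats::setNames(rep(1, length(g)), g))
    }
    geneSets <- list(immune_block = mk("immune_marker"),
                     luminal_block = mk("luminal_marker"),
                     basal_block = mk("basal_marker"))
  }
  if (!is.null(geneSets)) {
    out$enrichment <- stage("enrich", ssgsea(exprLog, geneSets,
                                             alpha = cfg$ssgseaAlpha,
                                             normalize = cfg$ssgseaNormalize))
    out$scoreCorrelations <- stage("enrich",
      correlateScore(out$score, out$enrichment, method = "spearman"))
    stagesRun <- c(stagesRun, "enrich")
  }

  beta <- tryCatch(getc("methylation"), error = function(e) NULL)
  if (!is.null(beta) && nrow(beta)) {
    out$dmp <- stage("methyl", specificDmps(
      dmpTest(beta, clusters, adjPMax = cfg$dmpAdjPMax),
      lowThresh = cfg$betaLow, highThresh = cfg$betaHigh))
    anno <- getc("probeAnnotation")
    out$dmgGenes <- stage("methyl", mapDmpsToGenes(out$dmp, anno))
    stagesRun <- c(stagesRun, "methyl")
  } else {
    mc5Log("no methylation data: methyl stage skipped")
  }

  truth <- tryCatch(getc("trueLabels"), error = function(e) NULL)
  evalRes <- list()
  if (!is.null(truth) && length(truth)) {
    evalRes$scoreAuc <- stage("evaluate", rocAuc(out$score, truth == 1L))
    evalRes$clusterAgreement <- stage("evaluate", crosstabAgreement(clusters, truth))
  }
  mut <- tryCatch(getc("mutations"), error = function(e) NULL)
  if (!is.null(mut) && nrow(mut)) {
    present <- intersect(chemoGenes, colnames(mut))
    if (length(present))
      evalRes$chemoMutations <- stage("evaluate",
        mutationRateCompare(mut, out$scoreGroup, present))
  }
  out$evaluation <- evalRes
  stagesRun <- c(stagesRun, "evaluate")

  out$manifest <- list(
    package = "mc5score",
    version = as.character(utils::packageVersion("mc5score")),
    seed = cfg$seed,
    config = cfg,
    stages = stagesRun,
    skipped = setdiff(c("cluster", "deg", "score", "survival", "enrich",
                        "methyl", "evaluate"), stagesRun)
  )
  out
}
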