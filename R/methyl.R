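PROMOTER_REGIONS <- c("TSS1500", "TSS200", "5UTR", "1stExon")

#' Differential methylation probe (DMP) test
#'
#' Moderated t-test (the same empirical-Bayes engine as the expression
#' module) on beta values between two groups, with BH adjustment;
#' significance is adjusted p strictly below `adjPMax` (default 0.01).
#' Group means are always reported on the beta scale. With
#' `mValues = TRUE` the test statistic is computed on
#' M = log2(beta/(1-beta)) with beta clipped to \[0.001, 0.999\].
#'
#' @param beta Probe-by-sample beta matrix in \[0,1\].
#' @param groups Two-level grouping vector.
#' @param adjPMax Significance threshold on the adjusted p.
#' @param mValues Test on M-values instead of beta values.
#' @return Data frame (probe, meanGroup1, meanGroup2, deltaBeta, t, p,
#'   adj_p, significant).
#' @export
dmpTest <- function(beta, groups, adjPMax = 0.01, mValues = FALSE) {
  if (any(beta < 0 | beta > 1)) stopf("beta values must lie in [0,1]")
  groups <- as.factor(groups)
  x <- if (mValues) {
    b <- pmin(pmax(beta, 0.001), 0.999)
    log2(b / (1 - b))
  } else beta
  tt <- moderatedTTest(x, groups)
  g1 <- groups == levels(groups)[1L]
  out <- data.frame(probe = rownames(beta),
                    meanGroup1 = rowMeans(beta[, g1, drop = FALSE]),
                    meanGroup2 = rowMeans(beta[, !g1, drop = FALSE]),
                    t = tt$t,
                    p = tt$p,
                    adj_p = tt$adj_p,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  out$deltaBeta <- out$meanGroup2 - out$meanGroup1
  out$significant <- out$adj_p < adjPMax
  attr(out, "groups") <- levels(groups)
  out
}

#' Classify group-specific DMPs by the beta-threshold rule
#'
#' Applies the published specificity rule to significant probes, relative to
#' the second group (the "case": cancer in a cancer-vs-normal contrast,
#' cluster 2 in a cluster contrast): `hyper_specific` means unmethylated in
#' group 1 (mean beta < `lowThresh`) and highly methylated in group 2
#' (mean beta > `highThresh`); `hypo_specific` is the mirror image. All
#' inequalities, including significance, are strict; the classification is
#' antisymmetric under swapping the group labels.
#'
#' @param dmp Output of [dmpTest()].
#' @param lowThresh,highThresh Beta thresholds (defaults 0.2 and 0.5).
#' @return The input table with a `class` column in
#'   `{hyper_specific, hypo_specific, none}`.
#' @export
specificDmps <- function(dmp, lowThresh = 0.2, highThresh = 0.5) {
  class_ <- rep("none", nrow(dmp))
  hyper <- dmp$significant & dmp$meanGroup2 > highThresh & dmp$meanGroup1 < lowThresh
  hypo <- dmp$significant & dmp$meanGroup2 < lowThresh & dmp$meanGroup1 > highThresh
  class_[hyper] <- "hyper_specific"
  class_[hypo] <- "hypo_specific"
  dmp$class <- class_
  dmp
}

#' Map classified DMPs to differential methylation genes (DMGs)
#'
#' Genes linked to at least one classified probe through a promoter region
#' (TSS1500, TSS200, 5'UTR, 1stExon) when `promoterOnly`, or any region
#' otherwise. Probes annotated to several genes contribute to every gene
#' whose region passes the filter. The result is deduplicated and sorted,
#' so it does not depend on probe order.
#'
#' @param dmps Output of [specificDmps()].
#' @param annotation Long probe annotation (probe, gene, region).
#' @param promoterOnly Restrict links to promoter regions.
#' @param classes DMP classes that count (default both specific classes).
#' @return Character vector of gene symbols (possibly empty).
#' @export
mapDmpsToGenes <- function(dmps, annotation, promoterOnly = TRUE,
                           classes = c("hyper_specific", "hypo_specific")) {
  hits <- dmps$probe[dmps$class %in% classes]
  links <- annotation[annotation$probe %in% hits, , drop = FALSE]
  if (promoterOnly)
    links <- links[links$region %in% PROMOTER_REGIONS, , drop = FALSE]
  sort(unique(links$gene))
}

#' Consensus clustering on a methylation probe subset
#'
#' Delegates to [consensusCluster()] on the beta sub-matrix (beta values are
#' used directly, without transformation).
#'
#' @param beta Probe-by-sample beta matrix.
#' @param probes Probes to cluster on (at least 5 present).
#' @param config Run configuration.
#' @return A [ConsensusResult-class].
#' @export
dmpConsensusCluster <- function(beta, probes, config = defaultConfig()) {
  present <- intersect(probes, rownames(beta))
  if (length(present) < 5L) stopf("at least 5 probes are required")
  consensusCluster(beta[present, , drop = FALSE], config, features = NULL)
}

#' Correlate the 5mC score with promoter methylation of selected genes
#'
#' Spearman correlation of the score against every promoter-region probe of
#' the listed genes, BH-adjusted, with counts of significantly negative and
#' positive probes.
#'
#' @param score Per-sample score aligned with beta columns.
#' @param beta Probe-by-sample beta matrix.
#' @param annotation Long probe annotation.
#' @param genes Gene list (non-empty).
#' @param adjPMax Significance threshold for the counts.
#' @return List: `table` (per-probe correlation table),
#'   `nNegativeSignificant`, `nPositiveSignificant`.
#' @export
promoterMethylationCorrelation <- function(score, beta, annotation, genes,
                                           adjPMax = 0.05) {
  if (!length(genes)) stopf("gene list must be non-empty")
  links <- annotation[annotation$gene %in% genes &
                      annotation$region %in% PROMOTER_REGIONS, , drop = FALSE]
  probes <- intersect(unique(links$probe), rownames(beta))
  if (!length(probes)) stopf("no promoter probes found for the listed genes")
  tab <- correlateScore(score, beta[probes, , drop = FALSE], method = "spearman")
  names(tab)[names(tab) == "feature"] <- "probe"
  sig <- !is.na(tab$adj_p) & tab$adj_p < adjPMax
  list(table = tab,
       nNegativeSignificant = sum(sig & tab$coefficient < 0),
       nPositiveSignificant = sum(sig & tab$coefficient > 0))
}
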