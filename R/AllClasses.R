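#' Consensus clustering result
#'
#' Holds, for every evaluated cluster number k, the consensus matrix (fraction
#' of co-sampled resampling runs in which two samples co-clustered), the final
#' item assignments, and the k-selection diagnostics (PAC and delta-area of
#' the consensus CDF), together with the per-replicate resampling record used
#' by the bookkeeping oracle.
#'
#' @slot sampleIds Character vector of sample identifiers.
#' @slot consensusMatrices Named list ("2".."maxK") of sample-by-sample
#'   consensus matrices in \[0,1\], unit diagonal.
#' @slot assignments Named list of integer cluster assignments per k, derived
#'   by average-linkage hierarchical clustering of 1 - consensus.
#' @slot coSampleCounts Matrix N of times each sample pair was co-sampled.
#' @slot coClusterCounts Named list of matrices C of times each pair
#'   co-clustered; consensus = C/N with 0/0 defined as 0.
#' @slot pac Named numeric, proportion of ambiguous clustering per k.
#' @slot deltaArea Named numeric, relative increase in consensus-CDF area.
#' @slot chosenK Integer, k minimising PAC (ties to the smaller k).
#' @slot resamples List with one entry per replicate: sampled item indices,
#'   sampled feature indices, and per-k assignments on the subsample.
#' @slot params List of the resampling parameters used.
#' @export
setClass("ConsensusResult", representation(
  sampleIds = "character",
  consensusMatrices = "list",
  assignments = "list",
  coSampleCounts = "matrix",
  coClusterCounts = "list",
  pac = "numeric",
  deltaArea = "numeric",
  chosenK = "integer",
  resamples = "list",
  params = "list"
))

setValidity("ConsensusResult", function(object) {
  for (k in names(object@consensusMatrices)) {
    M <- object@consensusMatrices[[k]]
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-12)))
      return(sprintf("consensus matrix for k=%s is not symmetric", k))
    if (any(M < -1e-12) || any(M > 1 + 1e-12))
      return(sprintf("consensus matrix for k=%s has entries outside [0,1]", k))
    if (any(abs(diag(M) - 1) > 1e-12))
      return(sprintf("consensus matrix for k=%s diagonal is not 1", k))
  }
  TRUE
})

#' Prognostic 5mC score model
#'
#' The oriented first principal component over the prognostic
#' differentially-expressed genes: per-gene standardisation constants, PC1
#' loadings (unit norm), and the orientation sign chosen so that cluster 1
#' carries the higher mean score.
#'
#' @slot genes Character vector of model genes.
#' @slot centers,scales Per-gene mean and standard deviation used for
#'   standardisation at fit time.
#' @slot loadings Named numeric PC1 loadings, sum of squares 1.
#' @slot sign Orientation sign, +1 or -1.
#' @slot varianceExplained Fraction of variance explained by PC1.
#' @export
setClass("ScoreModel", representation(
  genes = "character",
  centers = "numeric",
  scales = "numeric",
  loadings = "numeric",
  sign = "numeric",
  varianceExplained = "numeric"
))

setValidity("ScoreModel", function(object) {
  if (abs(sum(object@loadings^2) - 1) > 1e-8)
    return("PC1 loadings must have unit sum of squares")
  if (!object@sign %in% c(-1, 1))
    return("orientation sign must be +1 or -1")
  if (any(object@scales <= 0))
    return("all model genes must have positive standard deviation")
  TRUE
})

#' Synthetic tumor cohort with planted two-subtype structure
#'
#' Expression (linear TPM), clinical survival data, methylation beta values
#' with probe annotation, binary mutation calls, and tumor purity, generated
#' from one seed with recorded ground-truth subtype labels and parameters.
#'
#' @slot expression Gene-by-sample linear-TPM matrix.
#' @slot clinical Data frame with sample_id, os_time (days), os_event,
#'   age, stage, grade, lvi, purity.
#' @slot methylation Probe-by-sample beta-value matrix.
#' @slot probeAnnotation Data frame (probe, gene, region), one row per
#'   probe-gene-region link.
#' @slot mutations Sample-by-gene binary matrix.
#' @slot trueLabels Integer subtype (1 or 2) per sample.
#' @slot geneRoles Data frame (gene, role) recording which genes are 5mC
#'   regulators, marker-block members, or background.
#' @slot config The simulation configuration the cohort was generated from.
#' @export
setClass("SyntheticCohort", representation(
  expression = "matrix",
  clinical = "data.frame",
  methylation = "matrix",
  probeAnnotation = "data.frame",
  mutations = "matrix",
  trueLabels = "integer",
  geneRoles = "data.frame",
  config = "list"
))

setValidity("SyntheticCohort", function(object) {
  ids <- colnames(object@expression)
  if (!identical(object@clinical$sample_id, ids))
    return("clinical sample ids do not match expression columns")
  if (ncol(object@methylation) > 0 && !identical(colnames(object@methylation), ids))
    return("methylation sample ids do not match expression columns")
  if (nrow(object@mutations) > 0 && !identical(rownames(object@mutations), ids))
    return("mutation sample ids do not match expression columns")
  if (length(object@trueLabels) != length(ids))
    return("one true label per sample required")
  if (!all(object@trueLabels %in% c(1L, 2L)))
    return("true labels must be 1 or 2")
  TRUE
})

## Accessors ------------------------------------------------------------

#' @describeIn ConsensusResult-class Consensus matrix for a given k.
#' @param object,x A `ConsensusResult`.
#' @param k Number of clusters (defaults to the chosen k).
#' @export
consensusMatrix <- function(x, k = chosenK(x)) {
  stopifnot(is(x, "ConsensusResult"))
  M <- x@consensusMatrices[[as.character(k)]]
  if (is.null(M)) stopf("no consensus matrix for k=%s", k)
  M
}

#' @describeIn ConsensusResult-class Final item assignments for a given k.
#' @export
clusterAssignments <- function(x, k = chosenK(x)) {
  stopifnot(is(x, "ConsensusResult"))
  a <- x@assignments[[as.character(k)]]
  if (is.null(a)) stopf("no assignments for k=%s", k)
  a
}

#' @describeIn ConsensusResult-class PAC (proportion of ambiguous clustering) per k.
#' @export
pacScores <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  x@pac
}

#' @describeIn ConsensusResult-class The selected number of clusters.
#' @export
chosenK <- function(x) {
  stopifnot(is(x, "ConsensusResult"))
  x@chosenK
}

#' @describeIn ScoreModel-class Genes in the score model.
#' @export
modelGenes <- function(x) {
  stopifnot(is(x, "ScoreModel"))
  x@genes
}

#' @describeIn ScoreModel-class PC1 loadings (unit norm).
#' @export
modelLoadings <- function(x) {
  stopifnot(is(x, "ScoreModel"))
  x@loadings
}

#' @describeIn ScoreModel-class Orientation sign (+1/-1).
#' @export
orientationSign <- function(x) {
  stopifnot(is(x, "ScoreModel"))
  x@sign
}

#' @describeIn SyntheticCohort-class Linear-TPM expression matrix.
#' @export
exprMatrix <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@expression
}

#' @describeIn SyntheticCohort-class Clinical table.
#' @export
clinicalTable <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@clinical
}

#' @describeIn SyntheticCohort-class Beta-value methylation matrix.
#' @export
betaMatrix <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@methylation
}

#' @describeIn SyntheticCohort-class Probe-to-gene/region annotation.
#' @export
probeAnno <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@probeAnnotation
}

#' @describeIn SyntheticCohort-class Binary sample-by-gene mutation matrix.
#' @export
mutationTable <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@mutations
}

#' @describeIn SyntheticCohort-class Planted subtype labels.
#' @export
trueLabels <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@trueLabels
}

#' @describeIn SyntheticCohort-class Gene role table (regulator/marker/background).
#' @export
geneRoles <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@geneRoles
}

#' @describeIn SyntheticCohort-class The simulation configuration used.
#' @export
simParams <- function(x) {
  stopifnot(is(x, "SyntheticCohort"))
  x@config
}

## show methods ---------------------------------------------------------

setMethod("show", "ConsensusResult", function(object) {
  ks <- names(object@consensusMatrices)
  cat("ConsensusResult:", length(object@sampleIds), "samples, k =",
      paste(range(as.integer(ks)), collapse = ".."),
      "(", length(object@resamples), "resamplings )\n")
  cat("  PAC:", paste(sprintf("k%s=%.3f", names(object@pac), object@pac),
                      collapse = " "), "\n")
  cat("  chosen k:", object@chosenK, "\n")
})

setMethod("show", "ScoreModel", function(object) {
  cat("ScoreModel:", length(object@genes), "prognostic genes; PC1 explains",
      sprintf("%.1f%%", 100 * object@varianceExplained),
      "of variance; orientation", ifelse(object@sign > 0, "+1", "-1"), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort:", ncol(object@expression), "samples,",
      nrow(object@expression), "genes,",
      nrow(object@methylation), "probes,",
      ncol(object@mutations), "mutation genes\n")
  cat("  subtype sizes:", sum(object@trueLabels == 1L), "/",
      sum(object@trueLabels == 2L), "(1/2)\n")
})
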