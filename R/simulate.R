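#' Simulation configuration for a synthetic two-subtype cohort
#'
#' Defines the planted structure every downstream stage is tested against:
#' two latent expression subtypes separated on the 21 regulator genes plus
#' luminal/basal/immune marker blocks, subtype-dependent exponential survival
#' with uniform censoring, subtype-specific methylation probes, group-wise
#' mutation rates, and optional linear tumor-purity confounding of
#' expression. Effects are on the log2 expression scale in units of the
#' within-group standard deviation (which is 1).
#'
#' @param nSamples Cohort size.
#' @param nBackgroundGenes Genes with no planted effect.
#' @param regulatorEffect Shift (sd units) added to the 21 regulator genes in
#'   subtype 1.
#' @param nMarkerGenes Genes per marker block (luminal, basal, immune).
#' @param markerEffect Shift (sd units) for the marker blocks: luminal up in
#'   subtype 1; basal and immune up in subtype 2.
#' @param subtype1Fraction Probability that a sample belongs to subtype 1,
#'   strictly inside (0,1).
#' @param baselineHazard Exponential hazard per day for subtype 1.
#' @param logHazardRatio Log hazard ratio of subtype 2 versus subtype 1.
#' @param censoringRate Target fraction of censored samples in \[0,1).
#' @param nProbes,nClusterSpecificProbes Methylation probes overall and with
#'   subtype-specific beta means.
#' @param betaConcentration Beta-distribution concentration (a+b) for probe
#'   draws; larger is less noisy.
#' @param cluster2SpecificFraction Fraction of the specific probes
#'   hypermethylated in subtype 2 (beta mean 0.6 vs 0.1); the remainder run
#'   in the opposite direction.
#' @param mutationRates Data frame (gene, rate1, rate2) of per-gene Bernoulli
#'   mutation probabilities per subtype.
#' @param purityMean,puritySd Tumor purity distribution (clipped to \[0,1\]).
#' @param purityConfounding Per-gene slope of log2 expression on purity; 0
#'   disables confounding.
#' @param seed Master seed; the cohort is fully reproducible from it.
#' @return Validated configuration list of class `mc5SimConfig`.
#' @export
simulationConfig <- function(nSamples = 400L,
                             nBackgroundGenes = 300L,
                             regulatorEffect = 2,
                             nMarkerGenes = 30L,
                             markerEffect = 2,
                             subtype1Fraction = 0.34,
                             baselineHazard = 1 / 1500,
                             logHazardRatio = 0.7,
                             censoringRate = 0.3,
                             nProbes = 200L,
                             nClusterSpecificProbes = 40L,
                             betaConcentration = 30,
                             cluster2SpecificFraction = 0.95,
                             mutationRates = NULL,
                             purityMean = 0.75,
                             puritySd = 0.10,
                             purityConfounding = 0,
                             seed = 1L) {
  if (is.null(mutationRates)) {
    mutationRates <- data.frame(
      gene = c("TP53", "RB1", "ATM", "ERBB2", "ERCC2", "FANCC"),
      rate1 = c(0.40, 0.09, 0.07, 0.07, 0.07, 0.07),
      rate2 = c(0.55, 0.27, 0.12, 0.12, 0.12, 0.12),
      stringsAsFactors = FALSE
    )
  }
  cfg <- list(nSamples = as.integer(nSamples),
              nBackgroundGenes = as.integer(nBackgroundGenes),
              regulatorEffect = regulatorEffect,
              nMarkerGenes = as.integer(nMarkerGenes),
              markerEffect = markerEffect,
              subtype1Fraction = subtype1Fraction,
              baselineHazard = baselineHazard,
              logHazardRatio = logHazardRatio,
              censoringRate = censoringRate,
              nProbes = as.integer(nProbes),
              nClusterSpecificProbes = as.integer(nClusterSpecificProbes),
              betaConcentration = betaConcentration,
              cluster2SpecificFraction = cluster2SpecificFraction,
              mutationRates = mutationRates,
              purityMean = purityMean,
              puritySd = puritySd,
              purityConfounding = purityConfounding,
              seed = as.integer(seed))
  if (cfg$subtype1Fraction <= 0 || cfg$subtype1Fraction >= 1)
    stopf("subtype1Fraction must lie strictly inside (0,1)")
  if (cfg$censoringRate < 0 || cfg$censoringRate >= 1)
    stopf("censoringRate must lie in [0,1)")
  if (cfg$nClusterSpecificProbes > cfg$nProbes)
    stopf("nClusterSpecificProbes cannot exceed nProbes")
  if (cfg$baselineHazard <= 0) stopf("baselineHazard must be positive")
  if (any(cfg$mutationRates$rate1 < 0 | cfg$mutationRates$rate1 > 1) ||
      any(cfg$mutationRates$rate2 < 0 | cfg$mutationRates$rate2 > 1))
    stopf("mutation rates must lie in [0,1]")
  class(cfg) <- c("mc5SimConfig", "list")
  cfg
}

# Uniform-censoring upper bound c solving
#   P(censored) = E_group[(1 - exp(-lambda c)) / (lambda c)] = target.
solveCensoringMax <- function(rates, fractions, target) {
  if (target <= 0) return(Inf)
  pcens <- function(cmax) {
    sum(fractions * (1 - exp(-rates * cmax)) / (rates * cmax))
  }
  f <- function(lc) pcens(exp(lc)) - target
  stats::uniroot(f, lower = log(1e-6 / max(rates)), upper = log(1e6 / min(rates)),
                 tol = 1e-10)$root |> exp()
}

#' Generate a synthetic cohort with planted two-subtype structure
#'
#' @param config A [simulationConfig()].
#' @return A [SyntheticCohort-class] object; identical config and seed give a
#'   byte-identical cohort.
#' @export
simulateCohort <- function(config = simulationConfig()) {
  if (!inherits(config, "mc5SimConfig")) config <- do.call(simulationConfig, config)
  set.seed(config$seed)
  n <- config$nSamples
  ids <- sprintf("S%04d", seq_len(n))

  labels <- 1L + stats::rbinom(n, 1L, 1 - config$subtype1Fraction)
  if (length(unique(labels)) < 2L)
    stopf("degenerate cohort: a subtype received no samples; increase nSamples")
  is2 <- labels == 2L

  ## purity (drawn before expression so the confounder is reproducible)
  purity <- pmin(pmax(stats::rnorm(n, config$purityMean, config$puritySd), 0), 1)

  ## expression on the log2 scale, then exponentiated to TPM-like values
  catalog <- regulatorCatalog()
  genes <- c(catalog$gene,
             sprintf("LUM%03d", seq_len(config$nMarkerGenes)),
             sprintf("BAS%03d", seq_len(config$nMarkerGenes)),
             sprintf("IMM%03d", seq_len(config$nMarkerGenes)),
             sprintf("BG%04d", seq_len(config$nBackgroundGenes)))
  roles <- data.frame(
    gene = genes,
    role = c(rep("regulator", nrow(catalog)),
             rep("luminal_marker", config$nMarkerGenes),
             rep("basal_marker", config$nMarkerGenes),
             rep("immune_marker", config$nMarkerGenes),
             rep("background", config$nBackgroundGenes)),
    stringsAsFactors = FALSE
  )
  g <- length(genes)
  base <- stats::runif(g, 2, 8)
  x <- matrix(stats::rnorm(g * n), g, n, dimnames = list(genes, ids)) + base
  shift <- matrix(0, g, n)
  ## Regulator separation is heterogeneous per gene (as in real subtype
  ## heatmaps, where regulators split in both directions): a fixed pattern
  ## with mean |shift| = regulatorEffect and a net positive component in
  ## subtype 1. A uniform shift would leave within-sample gene ranks -- and
  ## hence the 1-Spearman sample distances the clustering runs on --
  ## unchanged, making the planted structure unrecoverable by construction.
  nReg <- sum(roles$role == "regulator")
  regPattern <- seq(0.5, 1.5, length.out = nReg) * rep_len(c(1, 1, -1), nReg)
  shift[roles$role == "regulator", !is2] <- config$regulatorEffect * regPattern
  shift[roles$role == "luminal_marker", !is2] <- config$markerEffect
  shift[roles$role == "basal_marker", is2] <- config$markerEffect
  shift[roles$role == "immune_marker", is2] <- config$markerEffect
  x <- x + shift
  if (config$purityConfounding != 0)
    x <- x + config$purityConfounding * matrix(purity, g, n, byrow = TRUE)
  tpm <- pmax(2^x - 1, 0)
  attr(tpm, "scale") <- "linear_tpm"

  ## survival: exponential with subtype hazard ratio, independent uniform censoring
  rate <- config$baselineHazard * exp(config$logHazardRatio * is2)
  tEvent <- stats::rexp(n, rate)
  if (config$censoringRate > 0) {
    rates <- config$baselineHazard * exp(config$logHazardRatio * c(0, 1))
    fr <- c(config$subtype1Fraction, 1 - config$subtype1Fraction)
    cmax <- solveCensoringMax(rates, fr, config$censoringRate)
    cens <- stats::runif(n, 0, cmax)
    osTime <- pmin(tEvent, cens)
    osEvent <- as.integer(tEvent <= cens)
  } else {
    osTime <- tEvent
    osEvent <- rep(1L, n)
  }
  clinical <- data.frame(
    sample_id = ids,
    os_time = osTime,
    os_event = osEvent,
    age = round(stats::rnorm(n, 68, 10)),
    stage = sample(c("II", "III", "IV"), n, replace = TRUE),
    grade = sample(c("high", "low"), n, replace = TRUE, prob = c(0.8, 0.2)),
    lvi = stats::rbinom(n, 1L, 0.3),
    purity = purity,
    stringsAsFactors = FALSE
  )

  ## methylation: subtype-specific probes vs mean-matched background
  nP <- config$nProbes
  nCS <- config$nClusterSpecificProbes
  probes <- sprintf("cg%06d", seq_len(nP))
  conc <- config$betaConcentration
  beta <- matrix(0, nP, n, dimnames = list(probes, ids))
  hyper2 <- stats::rbinom(nCS, 1L, config$cluster2SpecificFraction) == 1L
  for (p in seq_len(nP)) {
    if (p <= nCS) {
      mHigh <- 0.6; mLow <- 0.1
      m <- if (hyper2[p]) ifelse(is2, mHigh, mLow) else ifelse(is2, mLow, mHigh)
    } else {
      m <- rep(stats::runif(1, 0.1, 0.9), n)
    }
    beta[p, ] <- stats::rbeta(n, m * conc, (1 - m) * conc)
  }
  regions <- c("TSS1500", "TSS200", "5UTR", "1stExon", "Body", "3UTR")
  anno <- data.frame(
    probe = probes,
    gene = c(sprintf("MGENE%03d", seq_len(nCS)),
             sample(genes, nP - nCS, replace = TRUE)),
    region = c(rep("TSS200", nCS),
               sample(regions, nP - nCS, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  ## mutations: Bernoulli per gene with subtype-dependent rates
  mr <- config$mutationRates
  mut <- vapply(seq_len(nrow(mr)), function(j) {
    stats::rbinom(n, 1L, ifelse(is2, mr$rate2[j], mr$rate1[j]))
  }, integer(n))
  mut <- matrix(as.double(mut), n, nrow(mr), dimnames = list(ids, mr$gene))

  methods::new("SyntheticCohort",
               expression = tpm,
               clinical = clinical,
               methylation = beta,
               probeAnnotation = anno,
               mutations = mut,
               trueLabels = labels,
               geneRoles = roles,
               config = unclass(config))
}

#' Compare planted simulation parameters with their realized values
#'
#' @param cohort A [SyntheticCohort-class].
#' @return Data frame with columns `parameter`, `planted`, `realized`.
#' @export
truthReport <- function(cohort) {
  stopifnot(methods::is(cohort, "SyntheticCohort"))
  cfg <- simParams(cohort)
  lab <- trueLabels(cohort)
  is2 <- lab == 2L
  xlog <- logTPM(exprMatrix(cohort))
  roles <- geneRoles(cohort)
  reg <- roles$gene[roles$role == "regulator"]
  regDelta <- mean(abs(rowMeans(xlog[reg, !is2, drop = FALSE]) -
                       rowMeans(xlog[reg, is2, drop = FALSE])))
  rows <- list(
    c("n_samples", cfg$nSamples, length(lab)),
    c("subtype1_fraction", cfg$subtype1Fraction, mean(!is2)),
    c("group_size_1", cfg$nSamples * cfg$subtype1Fraction, sum(!is2)),
    c("group_size_2", cfg$nSamples * (1 - cfg$subtype1Fraction), sum(is2)),
    c("censoring_rate", cfg$censoringRate, mean(clinicalTable(cohort)$os_event == 0)),
    c("regulator_effect", cfg$regulatorEffect, regDelta),
    c("event_time_log_hr", cfg$logHazardRatio,
      log(mean(clinicalTable(cohort)$os_time[!is2 & clinicalTable(cohort)$os_event == 1]) /
          mean(clinicalTable(cohort)$os_time[is2 & clinicalTable(cohort)$os_event == 1])))
  )
  mut <- mutationTable(cohort)
  mr <- cfg$mutationRates
  for (j in seq_len(nrow(mr))) {
    rows[[length(rows) + 1L]] <- c(paste0("mutation_rate1_", mr$gene[j]),
                                   mr$rate1[j], mean(mut[!is2, mr$gene[j]]))
    rows[[length(rows) + 1L]] <- c(paste0("mutation_rate2_", mr$gene[j]),
                                   mr$rate2[j], mean(mut[is2, mr$gene[j]]))
  }
  out <- data.frame(parameter = vapply(rows, `[[`, "", 1L),
                    planted = as.numeric(vapply(rows, `[[`, "", 2L)),
                    realized = as.numeric(vapply(rows, `[[`, "", 3L)),
                    stringsAsFactors = FALSE)
  out
}
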