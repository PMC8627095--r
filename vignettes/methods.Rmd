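---
title: "Methods: 5mC regulator subtyping and the 5mC score"
author: "mc5score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5mC regulator subtyping and the 5mC score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

DNA 5-methylcytosine homeostasis is maintained by three regulator classes:
writers (DNMT1, DNMT3A, DNMT3B), erasers (TET1, TET2, TET3, TDG), and
methyl-CpG readers. The package's premise is that the joint mRNA expression
of these 21 genes carries enough information to stratify bulk tumors into
molecular subtypes that track differentiation state, immune infiltration,
prognosis, and therapy response. Two quantities are produced:

* **5mC clusters** — discrete subtypes from consensus resampling
  clustering of samples on the regulator genes;
* **5mC score** — a continuous per-sample quantification: the oriented
  first principal component over the cluster-derived prognostic gene
  signature, `score_j = s · Σ_g w_g (x_gj − μ_g)/σ_g`.

Expression enters all statistics on the log2(TPM+1) scale; the linear TPM
scale is kept for reporting. This transform is the package's choice — the
clustering distance is rank-based and indifferent, but fold changes,
PCA loadings, and Cox coefficients are interpretable only on a log scale.

## The regulator catalog

The literature names the three writers, four erasers, and eleven readers
while describing the reader class as holding fourteen genes. The catalog
therefore ships the eleven named readers plus three explicit placeholder
slots (`READER12`–`READER14`) and accepts a user override
(`regulatorCatalog(readers = ...)`); inventing the missing symbols would
be worse than exposing the gap. Genes absent from a given matrix are
simply dropped, with a floor of five present genes for clustering.

## Consensus clustering

Each of `reps` replicates draws ⌈0.8·n⌉ samples and ⌈0.8·g⌉ genes without
replacement, computes 1−Spearman distances between samples (average ranks
on ties), and partitions the subsample by PAM k-medoids for every k in
2..6. The consensus matrix entry for a sample pair is the fraction of
co-sampled replicates in which the pair co-clustered (0/0 defined as 0,
unit diagonal). Final memberships come from average-linkage hierarchical
clustering of 1−consensus cut at k — the long-standing convention of
consensus-clustering implementations; nothing in the method itself forces
this choice, so it is stated rather than hidden.

k is selected by minimum PAC — the fraction of off-diagonal consensus
entries strictly inside (0.1, 0.9) — with ties to the smaller k; the
delta-area curve of the consensus CDF is reported alongside and the choice
can be overridden. Picking k "by inspection plus prognosis", as a human
analyst would, is not mechanizable; PAC is the standard automated
surrogate.

PAM uses BUILD initialisation and best-improvement SWAP with all cost ties
broken towards the lowest index, which makes every run deterministic
without random restarts. A consequence worth knowing: SWAP is a local
search, and an exact cost tie can lock it one swap away from the global
optimum on adversarial fixtures. Per-replicate RNG streams are derived
from the master seed by replicate index, so replicates are
order-independent and the bookkeeping (C and N counts, recorded per
replicate) can be re-verified exactly after the fact.

### Purity correction

Bulk expression mixes tumor and stroma, and tumor purity (e.g. the CPE
consensus estimate) can confound regulator expression. `purityAdjust()`
fits, per gene, the least-squares line of log expression on purity and
returns residual plus gene mean. With a constant purity vector the slope
is unidentifiable and the matrix is returned unchanged with a warning.
Note that the fitted slope is never exactly zero on finite data even when
no confounding was planted; the adjustment is a projection, not a no-op.

## Differential expression

The moderated t-statistic shrinks per-gene residual variances toward a
common prior: with d = n−2 residual df per gene, the prior df d₀ and prior
variance s₀² are estimated by method of moments on the log residual
variances (variance of log s² in excess of trigamma(d/2) is
trigamma(d₀/2), inverted by Newton iteration). The posterior variance is
the df-weighted blend and the statistic has d+d₀ df. When the estimated or
forced d₀ is infinite, the common variance is taken as the df-weighted
pooled residual variance — the maximum-likelihood common variance under
the equal-variance model, making the statistic exactly the pooled-variance
ordinary t in that limit. The moments estimator was chosen over iterative
ML because it is closed-form, testable, and indistinguishable at the
scales involved.

DEG selection uses strict inequalities: adjusted p < 0.001 (BH) and
|log2FC| > 1.5, with the positive direction meaning higher in cluster 2.
The fold-change unit is log2 on log2(TPM+1) data.

## The score

Signature genes are filtered by univariate Cox regression (Breslow ties,
Newton–Raphson to 1e-8 within 50 iterations, Wald p < 0.05 strict).
Monotone-likelihood fits — a coefficient walking past ±15 on the
log-hazard scale — are flagged and excluded rather than reported as
converged. The 0.05 threshold is the field default; the original analysis
states no explicit value, and the parameter is exposed.

PCA runs on the gene-standardized sub-matrix; the loadings are the leading
eigenvector of the gene–gene correlation matrix, normalised to unit sum of
squares. The score is the PC1 projection, i.e. the loading-weighted sum of
standardized expression — the convention of the antecedent gene-signature
score literature, not the sum of loadings alone. Orientation is anchored
to the cluster labels (cluster 1 high) rather than to survival, because
the subtype system defines cluster 1 as the high-score subtype; with the
synthetic generator's defaults the two anchorings agree.

When scoring an external cohort the standardization constants are
recomputed within that cohort by default (cross-platform comparability);
`freezeStandardization = TRUE` reuses the training constants. Model genes
missing from the target matrix are imputed at standardized zero with a
warning, and below 50% overlap the call refuses. Cohorts without survival
data can be scored from the unfiltered signature — the prognostic filter
is simply skipped by passing the full DEG list; whether loadings should be
refit per cohort is left to the caller, and both modes exist
(`fitScoreModel()` on the new cohort vs `applyScore()` with a frozen
model), since neither can be asserted as canonical.

## Survival machinery

Kaplan–Meier uses the product-limit estimator with events processed before
censorings at tied times. The log-rank test accumulates observed minus
expected counts with hypergeometric variance at each distinct event time
(χ² on k−1 df). The optimal score cutoff is the maximally selected rank
statistic: per-subject log-rank (Peto) scores aᵢ = δᵢ − Λ̂(tᵢ) are computed
once from the Nelson–Aalen cumulative hazard, and each admissible midpoint
between consecutive unique score values is standardized by the permutation
variance, z = (S − n₁ā)/√(n₁n₀/(n(n−1))·Σ(a−ā)²). Both resulting groups
must hold at least `minprop` = 0.1 of the samples (the referenced
function's default; not stated in the original analysis and flagged as an
assumption). Ties in |z| go to the lower cutoff. The maximum is *not*
corrected for the multiplicity of candidate cutpoints; downstream
inference runs the ordinary log-rank test on the resulting groups, as
published, and the raw maximum statistic is exposed so users can see what
was optimised. Breslow tie handling is used throughout (simpler than
Efron and adequate at these event-tie densities); samples are dichotomized
by strict `score > cutoff`.

## Enrichment

ssGSEA ranks genes within each sample (average ranks on ties), walks the
list in decreasing rank order, and sums the difference between the
weighted in-set ECDF (weights rank^α, α = 0.25) and the uniform out-of-set
ECDF. Scores depend only on within-sample ranks, hence are invariant to
monotone transforms of expression. With `normalize = TRUE` the score
matrix is divided by its global range — the common implementation's
default. Cancer-immunity-cycle steps are signed gene sets (GMT tokens
suffixed `|+1`/`|-1`): activity is the unnormalised ssGSEA of the positive
subset minus that of the negative subset, reducing to plain ssGSEA when no
negative genes exist. The 18 TIS coefficients are published supplementary
material and must be supplied by the user (`readTisWeights()` enforces
exactly 18 finite entries); the package does not invent them, and TIS is
computed on log2(TPM+1) since the source platform's normalisation is not
reproducible here.

Group comparisons follow the normality-conditional convention: Shapiro–
Wilk on both groups at α = 0.05 chooses Welch t versus Mann–Whitney U
(normal approximation, no continuity correction, so identical groups give
p = 1 exactly); binary features use Fisher's exact test; BH runs across
features.

## Methylation

DMP testing runs the same moderated-t engine directly on β values between
clusters with adjusted p < 0.01 (strict); an `mValues` flag tests on
log2(β/(1−β)) with β clipped to [0.001, 0.999] instead. The specificity
rule classifies a significant probe relative to the second group: mean β
> 0.5 there and < 0.2 in the first group is `hyper_specific`, the mirror
image `hypo_specific`; all thresholds strict, and the same rule serves the
cancer-vs-normal and cluster-vs-cluster contrasts (the source describes
one filter criterion for both). Swapping the group labels provably swaps
the two classes. DMP→gene mapping accepts promoter regions TSS1500,
TSS200, 5′UTR, 1stExon (any region with `promoterOnly = FALSE`);
multi-gene probes contribute to every annotated gene passing the filter,
and the gene list is deduplicated and sorted so probe order is
irrelevant.

# The synthetic cohort generator

`simulateCohort()` is the test harness: it plants exactly the structure
the analysis assumes and records the truth.

* **Expression.** Log2-scale Gaussian blocks (per-gene baselines uniform
  on [2, 8], unit noise) exponentiated to TPM. Luminal markers shift up in
  subtype 1; basal and immune markers in subtype 2 (default 2 sd).
  The regulator separation uses a fixed heterogeneous per-gene pattern —
  magnitudes spread over 0.5–1.5× the nominal effect, 14 of 21 genes
  positive in subtype 1 — rather than a uniform shift. This is deliberate:
  a shift common to all genes in the distance panel leaves within-sample
  gene ranks untouched and is therefore *invisible* to the 1−Spearman
  sample distance the clustering runs on; real subtype heatmaps likewise
  separate regulators in both directions with varying magnitude. The net
  positive component keeps "cluster 1 = regulator-high" well-defined for
  orientation anchoring.
* **Survival.** Exponential event times with baseline hazard 1/1500 per
  day for subtype 1 and log hazard ratio 0.7 for subtype 2 (subtype 2 =
  worse prognosis), censored by an independent Uniform(0, c_max) with
  c_max solved numerically so the expected censoring fraction equals the
  configured 30%.
* **Methylation.** Cluster-specific probes are Beta-distributed with mean
  0.6 in the hypermethylated group and 0.1 in the other (concentration 30,
  so the 0.2/0.5 rule is planted with margin); 95% of them run
  hypermethylated-in-subtype-2, mirroring the near-unanimous direction
  reported for the real cohort. Background probes are mean-matched across
  groups. Specific probes are annotated to promoter (TSS200) regions of
  dedicated genes so the DMG mapping has planted truth.
* **Mutations.** Per-gene Bernoulli rates per subtype; defaults plant
  TP53 0.40/0.55 and RB1 0.09/0.27 (the published rate contrast) plus
  four chemotherapy-response genes at 0.07/0.12, giving the low-score
  group the higher pooled rate.
* **Purity.** Normal(0.75, 0.10) clipped to [0, 1]; when the confounding
  slope is nonzero it adds linearly to every gene's log expression.
* **Sizes.** Defaults n = 400 with subtype-1 fraction 0.34 (the published
  cohort size and 135/265 split), 300 background genes, 30 genes per
  marker block, 200 probes of which 40 cluster-specific.

What the generator does **not** emulate: negative-binomial count noise and
library-size effects, gene–gene correlation beyond the block structure,
informative censoring, copy-number or fusion events, batch effects, and
probe-level 450k artifacts. Green tests therefore certify the statistical
machinery and its planted-effect recovery, not robustness to every failure
mode of real RNA-seq or array data.

# Numerical choices and degenerate inputs

* Cox: tolerance 1e-8, max 50 Newton steps with step-halving; |β| > 15 ⇒
  flagged non-convergent with an infinite sentinel.
* Moderated t: genes with zero residual variance and zero fold change get
  t = 0, p = 1 (logged); zero variance with nonzero fold change gives an
  infinite statistic and p → 0.
* Consensus: pairs never co-sampled have consensus 0 by definition;
  the diagonal is fixed at 1.
* PAC window (0.1, 0.9) open on both sides; k ties to the smaller value.
* Duplicate gene rows on input collapse by per-sample maximum (logged);
  duplicate sample ids, out-of-range β, non-positive survival times, and
  non-binary mutation entries are hard errors.
* Constant features in correlation tables are flagged and excluded from
  BH; constant purity skips adjustment with a warning.
* All selection thresholds (0.001/1.5, 0.05, 0.01, 0.2/0.5) are strict
  inequalities.

# Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on generated data:
clustering recovery at n = 200 with 100 resamplings, Cox calibration with
200 null replicates of n = 500 and 50 planted replicates of n = 1000, the
end-to-end pipeline at n = 200–400 with 60–100 resamplings, and
oracle-equality fixtures of 6–200 samples. These sizes make every
property decisive (planted effects are several standard errors wide)
while keeping the whole suite in well under a minute of compute per file.

# Known limitations

* The consensus-matrix memory footprint grows as O(n² · maxK); cohorts of
  tens of thousands of samples would need a slimmer record (the
  per-replicate resampling log can be disabled only by editing the code).
* The maximally selected cutpoint p-value is optimistically biased by
  construction; only the group-wise log-rank test should be quoted.
* ssGSEA normalisation by the global score range couples signatures
  scored together; score sets jointly or set `normalize = FALSE` when
  comparing across runs.
* The pipeline's cluster-1 anchoring assumes the regulator-high cluster
  is the luminal/high-score one, which holds for the planted generator
  and the published system but should be checked on new cohorts.
* Placeholder reader genes (`READER12`–`READER14`) exist only so the
  catalog's arity matches its description; they match nothing in real
  matrices and are silently absent from analyses.
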