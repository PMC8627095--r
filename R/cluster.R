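#' 1 - Spearman correlation distance between samples
#'
#' Columns (samples) are rank-transformed within sample using average ranks
#' for ties; the distance is one minus the Pearson correlation of the ranks,
#' so values lie in \[0,2\] with an exactly zero diagonal.
#'
#' @param expr Feature-by-sample numeric matrix with at least two features.
#' @return Symmetric sample-by-sample distance matrix.
#' @export
spearmanDistance <- function(expr) {
  if (nrow(expr) < 2L) stopf("at least 2 features are required")
  ranks <- apply(expr, 2L, rank)
  sds <- apply(ranks, 2L, stats::sd)
  if (any(sds == 0))
    stopf("sample '%s' has zero variance across the supplied features",
          colnames(expr)[which(sds == 0)[1L]])
  d <- 1 - stats::cor(ranks)
  diag(d) <- 0
  d[d < 0] <- 0  # clip numerical negatives from rho ~ 1
  dimnames(d) <- list(colnames(expr), colnames(expr))
  d
}

#' k-medoids (PAM) clustering on a precomputed distance matrix
#'
#' Classical partitioning around medoids: greedy BUILD initialisation
#' followed by exhaustive SWAP until no strictly improving swap exists.
#' Cost ties are always broken towards the lowest index, so the algorithm is
#' fully deterministic; the `seed` argument is accepted for interface
#' stability but does not influence the result.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @param k Number of clusters, 2..n.
#' @param seed Ignored (determinism comes from lowest-index tie-breaking).
#' @return Integer cluster assignments (1..k, numbered by medoid order),
#'   with the medoid indices in attribute `"medoids"`.
#' @export
kMedoids <- function(dist, k, seed = NULL) {
  n <- nrow(dist)
  if (k > n) stopf("k (%d) cannot exceed the number of items (%d)", k, n)
  if (k < 1L) stopf("k must be at least 1")

  ## BUILD: first medoid minimises total distance; then greedily add the
  ## point giving the largest cost reduction (ties -> lowest index).
  medoids <- unname(which.min(colSums(dist)))
  while (length(medoids) < k) {
    dmin <- apply(dist[, medoids, drop = FALSE], 1L, min)
    cand <- setdiff(seq_len(n), medoids)
    gain <- vapply(cand, function(h) sum(pmin(dmin, dist[, h])), 0)
    medoids <- c(medoids, cand[which.min(gain)])
  }

  ## SWAP: take the best strictly improving (medoid, candidate) swap.
  repeat {
    dm <- dist[, medoids, drop = FALSE]
    nearIdx <- max.col(-dm, ties.method = "first")
    d1 <- dm[cbind(seq_len(n), nearIdx)]
    d2 <- if (length(medoids) > 1L) {
      apply(dm, 1L, function(r) sort(r, partial = 2)[2L])
    } else rep(Inf, n)
    cost <- sum(d1)
    cand <- setdiff(seq_len(n), medoids)
    if (!length(cand)) break
    best <- list(delta = -1e-12, m = NA, h = NA)
    for (mi in seq_along(medoids)) {
      base <- ifelse(nearIdx == mi, d2, d1)
      ## new cost for swapping medoid mi with each candidate h, vectorised
      newCost <- colSums(pmin(dist[, cand, drop = FALSE], base))
      deltas <- newCost - cost
      j <- which.min(deltas)
      if (deltas[j] < best$delta) best <- list(delta = deltas[j], m = mi, h = cand[j])
    }
    if (is.na(best$m)) break
    medoids[best$m] <- best$h
  }

  medoids <- sort(unname(medoids))
  assign <- max.col(-dist[, medoids, drop = FALSE], ties.method = "first")
  names(assign) <- rownames(dist)
  attr(assign, "medoids") <- medoids
  assign
}

#' Consensus resampling clustering
#'
#' Repeatedly subsamples items and features without replacement, clusters
#' each subsample by k-medoids on 1-Spearman distances, and accumulates for
#' every sample pair the number of co-sampled runs (N) and co-clustered runs
#' (C); the consensus matrix is C/N (0/0 defined as 0, unit diagonal). Final
#' assignments come from average-linkage hierarchical clustering of
#' 1 - consensus cut at k, and k is selected by minimum PAC.
#'
#' Defaults follow the published analysis: 80% item resampling, 80% feature
#' resampling, 1000 replicates, maximum k of 6.
#'
#' @param expr Feature-by-sample matrix (log2 expression, or beta values for
#'   methylation-based clustering).
#' @param config Run configuration, see [defaultConfig()].
#' @param features Features to restrict to before clustering; defaults to
#'   the 21-gene regulator catalog. Use `NULL` to keep all rows. At least 5
#'   of the requested features must be present.
#' @return A [ConsensusResult-class].
#' @export
consensusCluster <- function(expr, config = defaultConfig(), features = regulatorCatalog()$gene) {
  cfg <- defaultConfig()
  cfg[names(config)] <- config
  if (!is.null(features)) {
    present <- intersect(features, rownames(expr))
    if (length(present) < 5L)
      stopf("fewer than 5 catalog features found in the matrix; missing: %s",
            paste(setdiff(features, rownames(expr)), collapse = ", "))
    expr <- expr[present, , drop = FALSE]
  }
  if (nrow(expr) < 5L) stopf("at least 5 features are required")
  n <- ncol(expr)
  g <- nrow(expr)
  ks <- 2:cfg$maxK
  nItem <- ceiling(cfg$pItem * n)
  nFeat <- ceiling(cfg$pFeature * g)

  N <- matrix(0, n, n)
  C <- stats::setNames(rep(list(matrix(0, n, n)), length(ks)), as.character(ks))
  resamples <- vector("list", cfg$reps)

  for (r in seq_len(cfg$reps)) {
    set.seed(derivedSeed(cfg$seed, r))
    items <- sort(sample.int(n, nItem))
    feats <- sort(sample.int(g, nFeat))
    d <- spearmanDistance(expr[feats, items, drop = FALSE])
    N[items, items] <- N[items, items] + 1
    repAssign <- list()
    for (k in ks) {
      a <- kMedoids(d, k)
      kc <- as.character(k)
      for (cl in seq_len(k)) {
        idx <- items[a == cl]
        C[[kc]][idx, idx] <- C[[kc]][idx, idx] + 1
      }
      repAssign[[kc]] <- a
    }
    resamples[[r]] <- list(items = items, features = feats, assignments = repAssign)
  }

  ids <- colnames(expr)
  M <- lapply(C, function(Ck) {
    Mk <- ifelse(N > 0, Ck / pmax(N, 1), 0)
    diag(Mk) <- 1
    dimnames(Mk) <- list(ids, ids)
    Mk
  })

  assignments <- stats::setNames(lapply(seq_along(ks), function(i) {
    hc <- stats::hclust(stats::as.dist(1 - M[[i]]), method = "average")
    a <- stats::cutree(hc, k = ks[i])
    names(a) <- ids
    a
  }), as.character(ks))

  up <- upper.tri(N)
  pac <- vapply(M, function(Mk) mean(Mk[up] > 0.1 & Mk[up] < 0.9), 0)
  area <- vapply(M, function(Mk) {
    v <- sort(Mk[up])
    ecdfv <- stats::ecdf(v)
    xs <- sort(unique(c(0, v, 1)))
    sum(diff(xs) * ecdfv(xs[-length(xs)]))
  }, 0)
  deltaArea <- c(area[1L], diff(area) / area[-length(area)])
  names(deltaArea) <- names(area)

  res <- methods::new("ConsensusResult",
                      sampleIds = ids,
                      consensusMatrices = M,
                      assignments = assignments,
                      coSampleCounts = N,
                      coClusterCounts = C,
                      pac = pac,
                      deltaArea = deltaArea,
                      chosenK = 0L,
                      resamples = resamples,
                      params = cfg[c("pItem", "pFeature", "maxK", "reps", "seed")])
  res@chosenK <- selectK(res)
  methods::validObject(res)
  res
}

#' Select the number of clusters by minimum PAC
#'
#' PAC (proportion of ambiguous clustering) is the fraction of off-diagonal
#' consensus entries strictly inside (0.1, 0.9); a low PAC indicates a
#' stable k. Ties are resolved towards the smaller k. The delta-area curve
#' is reported alongside for inspection, and the choice can be overridden
#' downstream.
#'
#' @param x A [ConsensusResult-class] or a named numeric vector of PAC
#'   values (names = k).
#' @return The chosen k (integer).
#' @export
selectK <- function(x) {
  pac <- if (methods::is(x, "ConsensusResult")) x@pac else x
  ks <- as.integer(names(pac))
  ord <- order(pac, ks)
  ks[ord[1L]]
}

#' Adjust expression for tumor purity
#'
#' Per gene, fits a least-squares line of log-scale expression on purity and
#' returns residual plus the gene grand mean, which removes the linear
#' purity component while keeping the scale interpretable. A constant purity
#' vector leaves the matrix unchanged (the slope is unidentifiable) with a
#' logged warning.
#'
#' @param expr Gene-by-sample matrix on the log2 scale.
#' @param purity Per-sample purity in \[0,1\], aligned with columns.
#' @return Adjusted matrix of the same shape.
#' @export
purityAdjust <- function(expr, purity) {
  if (length(purity) != ncol(expr))
    stopf("one purity value per sample is required")
  if (any(purity < 0 | purity > 1)) stopf("purity must lie in [0,1]")
  pc <- purity - mean(purity)
  vp <- sum(pc^2)
  if (vp == 0) {
    mc5Log("constant purity vector: returning mean-anchored expression unchanged")
    warning("constant purity vector; no adjustment possible", call. = FALSE)
    return(expr)
  }
  slopes <- (expr %*% pc) / vp
  adjusted <- expr - slopes %*% rbind(pc)
  attr(adjusted, "scale") <- attr(expr, "scale")
  adjusted
}
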