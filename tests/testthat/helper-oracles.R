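# Independent oracles and shared fixtures. Each oracle is a deliberately
# naive implementation (loops, enumeration, closed forms) kept free of the
# package's own code paths.

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sx <- sum(choose(rowSums(tab), 2))
  sy <- sum(choose(colSums(tab), 2))
  sxy <- sum(choose(tab, 2))
  e <- sx * sy / choose(n, 2)
  (sxy - e) / ((sx + sy) / 2 - e)
}

# Step-up Benjamini-Hochberg written from the definition.
bhBrute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities not exceeding the observed one.
fisherEnum <- function(tab) {
  x <- tab[1, 1]
  m <- sum(tab[1, ])
  k <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, k - (n - m)):min(m, k)
  probs <- stats::dhyper(support, m, n - m, k)
  pObs <- stats::dhyper(x, m, n - m, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# AUC by explicit concordant-pair counting (ties count 0.5).
aucPairs <- function(score, labels) {
  pos <- score[labels == 1]
  neg <- score[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# ssGSEA running sum computed with naive loops, directly from the
# definition: genes ordered by decreasing within-sample rank, in-set ECDF
# weighted by rank^alpha, uniform out-of-set ECDF.
ssgseaOracle <- function(exprLog, setGenes, alpha = 0.25) {
  out <- numeric(ncol(exprLog))
  genes <- rownames(exprLog)
  N <- length(genes)
  for (j in seq_len(ncol(exprLog))) {
    r <- rank(exprLog[, j])
    ord <- order(r, decreasing = TRUE)
    sumIn <- 0
    for (i in ord) if (genes[i] %in% setGenes) sumIn <- sumIn + r[i]^alpha
    nOut <- N - sum(genes %in% setGenes)
    runIn <- 0; runOut <- 0; es <- 0
    for (i in ord) {
      if (genes[i] %in% setGenes) runIn <- runIn + r[i]^alpha / sumIn
      else runOut <- runOut + 1 / nOut
      es <- es + (runIn - runOut)
    }
    out[j] <- es
  }
  out
}

# Leading eigenvector of a symmetric matrix by power iteration.
powerIterPC1 <- function(S, iters = 5000) {
  v <- rep(1, ncol(S)) / sqrt(ncol(S))
  for (i in seq_len(iters)) {
    v2 <- S %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(abs(v2) - abs(v))) < 1e-14) { v <- v2; break }
    v <- v2
  }
  drop(v)
}

# Small planted cohort shared across tests (memoised per parameter set).
.cohortCache <- new.env(parent = emptyenv())
testCohort <- function(nSamples = 200, seed = 7, ...) {
  key <- paste(nSamples, seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.cohortCache[[key]])) {
    .cohortCache[[key]] <- simulateCohort(simulationConfig(
      nSamples = nSamples, nBackgroundGenes = 100, nMarkerGenes = 15,
      nProbes = 80, nClusterSpecificProbes = 20, seed = seed, ...))
  }
  .cohortCache[[key]]
}

fastConfig <- function(reps = 50, seed = 11, ...) {
  c(list(reps = reps, seed = seed), list(...))
}

# Exhaustive maximally-selected-rank-statistic oracle, written from the
# definition with naive loops: Nelson-Aalen log-rank scores, permutation
# variance, all admissible midpoints.
cutpointOracle <- function(score, tm, ev, minprop) {
  n <- length(score)
  ut <- sort(unique(tm[ev == 1]))
  a <- numeric(n)
  for (i in seq_len(n)) {
    ch <- 0
    for (t in ut[ut <= tm[i]]) ch <- ch + sum(tm == t & ev == 1) / sum(tm >= t)
    a[i] <- ev[i] - ch
  }
  abar <- mean(a); ssq <- sum((a - abar)^2)
  u <- sort(unique(score))
  mids <- (u[-length(u)] + u[-1]) / 2
  best <- -Inf; bestCut <- NA
  for (m in mids) {
    hi <- score > m
    n1 <- sum(hi)
    if (min(n1, n - n1) / n < minprop) next
    z <- (sum(a[hi]) - n1 * abar) / sqrt(n1 * (n - n1) / (n * (n - 1)) * ssq)
    if (abs(z) > best + 1e-12) { best <- abs(z); bestCut <- m }
  }
  list(cutoff = bestCut, absZ = best)
}

# Build a beta fixture with planted hyper-specific, hypo-specific, and null
# probes (relative to group 2), using tight Beta draws so the 0.2/0.5 rule
# is planted exactly.
plantedBeta <- function(nHyper = 10, nHypo = 5, nNull = 85, n1 = 20, n2 = 20,
                        seed = 91) {
  set.seed(seed)
  nP <- nHyper + nHypo + nNull
  draw <- function(m, n) rbeta(n, m * 80, (1 - m) * 80)
  beta <- matrix(0, nP, n1 + n2,
                 dimnames = list(sprintf("cg%04d", seq_len(nP)),
                                 paste0("s", seq_len(n1 + n2))))
  for (p in seq_len(nP)) {
    if (p <= nHyper) { mA <- 0.1; mB <- 0.65 }           # hyper in group 2
    else if (p <= nHyper + nHypo) { mA <- 0.65; mB <- 0.1 }  # hypo in group 2
    else { m <- runif(1, 0.3, 0.7); mA <- m; mB <- m }
    beta[p, ] <- c(draw(mA, n1), draw(mB, n2))
  }
  list(beta = beta, groups = rep(1:2, c(n1, n2)),
       hyper = rownames(beta)[seq_len(nHyper)],
       hypo = rownames(beta)[nHyper + seq_len(nHypo)])
}
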