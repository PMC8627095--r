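test_that("spearman distance matches hand rank computation and flags degenerate samples", {
  x <- cbind(A = c(1, 2, 3), B = c(1, 2, 3))
  rownames(x) <- paste0("g", 1:3)
  expect_equal(spearmanDistance(x)["A", "B"], 0)

  x <- cbind(A = c(1, 2, 3), B = c(3, 2, 1)); rownames(x) <- paste0("g", 1:3)
  expect_equal(spearmanDistance(x)["A", "B"], 2)

  # average-rank ties: ranks of (1,2,2) are (1, 2.5, 2.5), of (1,2,3) are (1,2,3)
  x <- cbind(A = c(1, 2, 2), B = c(1, 2, 3)); rownames(x) <- paste0("g", 1:3)
  ra <- c(1, 2.5, 2.5); rb <- c(1, 2, 3)
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearmanDistance(x)["A", "B"], 1 - rho, tolerance = 1e-12)

  x <- cbind(A = c(1, 1, 1), B = c(1, 2, 3)); rownames(x) <- paste0("g", 1:3)
  expect_error(spearmanDistance(x), "sample 'A' has zero variance")
  expect_error(spearmanDistance(x[1, , drop = FALSE]), "at least 2 features")
})

test_that("k-medoids recovers well-separated pairs and attains the exhaustive optimum", {
  # two far pairs
  pts <- c(0, 0.1, 10, 10.1)
  d <- abs(outer(pts, pts, "-")); dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  a <- kMedoids(d, 2)
  expect_equal(unname(a[1]), unname(a[2]))
  expect_equal(unname(a[3]), unname(a[4]))
  expect_false(a[1] == a[3])

  # compare against the exhaustive optimum over all C(7,2) medoid pairs; the
  # SWAP neighbourhood guarantees local optimality (verified for every seed)
  # and reaches the global optimum whenever no cost tie locks the search
  for (seed in 1:5) {
    set.seed(seed)
    p <- matrix(rnorm(14), 7, 2)
    d <- as.matrix(dist(p)); dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
    a <- kMedoids(d, 2)
    med <- attr(a, "medoids")
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- Inf
    for (i in 1:6) for (j in (i + 1):7) {
      best <- min(best, sum(pmin(d[, i], d[, j])))
    }
    # local optimality: no single medoid swap improves the solution
    deltas <- c()
    for (m in med) for (h in setdiff(1:7, med)) {
      alt <- sum(pmin(d[, setdiff(med, m)], d[, h]))
      expect_gte(alt, cost - 1e-12)
      deltas <- c(deltas, alt - cost)
    }
    # global optimality holds unless an exact cost tie locked the search
    if (cost > best + 1e-12) expect_lt(min(abs(deltas)), 1e-9)
    else expect_equal(cost, best, tolerance = 1e-12)
  }

  # k = n: every point its own medoid, zero cost
  a <- kMedoids(d, 7)
  expect_equal(attr(a, "medoids"), 1:7)
  expect_equal(sum(apply(d[, attr(a, "medoids")], 1, min)), 0)
  expect_error(kMedoids(d, 8), "cannot exceed")
})

test_that("k-medoids agrees with an independent PAM implementation", {
  skip_if_not_installed("cluster")
  for (seed in 1:3) {
    set.seed(seed)
    p <- matrix(rnorm(60), 30, 2)
    d <- as.matrix(dist(p)); dimnames(d) <- list(paste0("s", 1:30), paste0("s", 1:30))
    for (k in c(2, 4)) {
      a <- kMedoids(d, k)
      ours <- sum(apply(d[, attr(a, "medoids"), drop = FALSE], 1, min))
      ref <- cluster::pam(as.dist(d), k = k)
      theirs <- sum(apply(d[, ref$id.med, drop = FALSE], 1, min))
      expect_lte(ours, theirs + 1e-9)
    }
  }
})

test_that("consensus matrix separates planted blobs and matches the bookkeeping oracle", {
  set.seed(4)
  n <- 40
  g <- 24
  grp <- rep(1:2, each = n / 2)
  # two blobs separated by 3 sd on a +/- gene pattern over a shared baseline
  base <- runif(g, 2, 8)
  pattern <- rep(c(1, -1), each = g / 2)
  x <- matrix(rnorm(g * n), g, n) + base +
    1.5 * outer(pattern, ifelse(grp == 2, 1, -1))
  dimnames(x) <- list(paste0("g", seq_len(g)), paste0("s", 1:n))
  res <- consensusCluster(x, config = list(reps = 50, maxK = 3, seed = 2),
                          features = NULL)
  M <- consensusMatrix(res, 2)
  within <- M[grp == 1, grp == 1][upper.tri(M[grp == 1, grp == 1])]
  cross <- M[grp == 1, grp == 2]
  expect_gte(min(within), 0.95)
  expect_lte(max(cross), 0.05)
  expect_gte(ari(clusterAssignments(res, 2), grp), 0.99)

  # bookkeeping oracle: recompute C and N from the per-rep record, exactly
  for (k in c("2", "3")) {
    C <- matrix(0, n, n); N <- matrix(0, n, n)
    for (r in res@resamples) {
      N[r$items, r$items] <- N[r$items, r$items] + 1
      a <- r$assignments[[k]]
      for (cl in unique(a)) {
        idx <- r$items[a == cl]
        C[idx, idx] <- C[idx, idx] + 1
      }
    }
    M2 <- ifelse(N > 0, C / pmax(N, 1), 0); diag(M2) <- 1
    expect_identical(unname(consensusMatrix(res, as.integer(k))), M2)
  }
  expect_identical(res@coSampleCounts, {
    N <- matrix(0, n, n)
    for (r in res@resamples) N[r$items, r$items] <- N[r$items, r$items] + 1
    N
  })
})

test_that("partial configs inherit the published resampling defaults", {
  co <- testCohort(nSamples = 60, seed = 2)
  xl <- logTPM(exprMatrix(co))
  res <- consensusCluster(xl, config = list(reps = 5L, maxK = 3L, seed = 1))
  expect_equal(res@params$pItem, 0.8)
  expect_equal(res@params$pFeature, 0.8)
  # the full defaults are the published parameters
  expect_equal(defaultConfig()[c("pItem", "pFeature", "maxK", "reps")],
               list(pItem = 0.8, pFeature = 0.8, maxK = 6L, reps = 1000L))
})

test_that("k selection minimises PAC with ties to the smaller k", {
  expect_equal(selectK(c(`2` = 0.02, `3` = 0.10, `4` = 0.15)), 2L)
  expect_equal(selectK(c(`2` = 0.10, `3` = 0.02, `4` = 0.15)), 3L)
  expect_equal(selectK(c(`2` = 0.05, `3` = 0.05, `4` = 0.15)), 2L)
})

test_that("consensus clustering requires at least 5 catalog features", {
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(c("DNMT1", "TET1", "MBD1", "UNG"), paste0("s", 1:10)))
  expect_error(consensusCluster(x, config = list(reps = 3)), "fewer than 5")
})

test_that("purity adjustment removes planted linear confounding", {
  set.seed(6)
  n <- 400
  purity <- pmin(pmax(rnorm(n, 0.7, 0.12), 0), 1)
  base <- matrix(rnorm(20 * n), 20, n,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))

  # expression exactly linear in purity: adjusted variance collapses
  lin <- outer(seq(1, 3, length.out = 20), purity)
  dimnames(lin) <- dimnames(base)
  adj <- purityAdjust(lin, purity)
  expect_lt(max(apply(adj, 1, var)), 1e-20)

  # zero planted slope: the fitted slope is only sampling noise, so the
  # adjustment equals subtracting the per-gene OLS slope times centred
  # purity (bookkeeping oracle) and is statistically negligible
  adj0 <- purityAdjust(base, purity)
  pc <- purity - mean(purity)
  for (i in c(1, 10, 20)) {
    bHat <- sum(base[i, ] * pc) / sum(pc^2)
    expect_equal(adj0[i, ], base[i, ] - bHat * pc, tolerance = 1e-12)
  }
  expect_lt(max(abs(adj0 - base)), 0.5)

  # planted slope 2: residual orthogonality per gene
  conf <- base + 2 * matrix(purity, 20, n, byrow = TRUE)
  adj2 <- purityAdjust(conf, purity)
  rs <- apply(adj2, 1, function(v) abs(cor(v, purity)))
  expect_lt(max(rs), 0.02)

  expect_warning(purityAdjust(base, rep(0.5, n)), "constant purity")
  expect_error(purityAdjust(base, purity[-1]), "one purity value per sample")
})

test_that("purity-adjusted clustering agrees with unadjusted at mild confounding", {
  co <- testCohort(nSamples = 150, seed = 13, purityConfounding = 0.5)
  xl <- logTPM(exprMatrix(co))
  cfg <- list(reps = 40, maxK = 3, seed = 5)
  raw <- clusterAssignments(consensusCluster(xl, cfg), 2)
  adj <- clusterAssignments(
    consensusCluster(purityAdjust(xl, clinicalTable(co)$purity), cfg), 2)
  agree <- max(mean(raw == adj), mean(raw == (3L - adj)))
  expect_gte(agree, 0.95)
})
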