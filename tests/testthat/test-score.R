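test_that("univariate Cox matches an independent implementation with Breslow ties", {
  skip_if_not_installed("survival")
  for (seed in 1:3) {
    set.seed(seed)
    n <- 80
    x <- rnorm(n)
    tm <- round(rexp(n, exp(0.4 * x) / 50), 0) + 1  # heavy ties
    ev <- rbinom(n, 1, 0.7)
    f <- univariateCox(x, tm, ev)
    ref <- survival::coxph(survival::Surv(tm, ev) ~ x, ties = "breslow")
    expect_equal(f$beta, unname(coef(ref)), tolerance = 1e-7)
    expect_equal(f$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-7)
  }
})

test_that("the Cox estimate maximises a brute-force partial likelihood", {
  # 4 subjects, all events at distinct times, binary covariate
  tm <- c(1, 2, 3, 4); ev <- rep(1, 4); x <- c(0, 1, 0, 1)
  f <- univariateCox(x, tm, ev)
  pl <- function(b) {
    eta <- b * x
    sum(vapply(which(ev == 1), function(i) {
      eta[i] - log(sum(exp(eta[tm >= tm[i]])))
    }, 0))
  }
  grid <- seq(-5, 5, by = 1e-4)
  bGrid <- grid[which.max(vapply(grid, pl, 0))]
  expect_equal(f$beta, bGrid, tolerance = 1e-3)
  expect_equal(f$beta, optimize(pl, c(-5, 5), maximum = TRUE)$maximum,
               tolerance = 1e-6)
})

test_that("monotone likelihood is flagged, not reported as converged", {
  # two subjects, both events: the partial likelihood is monotone in beta
  f <- univariateCox(c(0, 1), c(2, 1), c(1, 1))
  expect_false(f$converged)
  expect_true(is.infinite(f$beta))
  expect_error(univariateCox(c(0, 1), c(1, 2), c(0, 0)), "no events")
})

test_that("null covariates give calibrated Wald p-values", {
  set.seed(31)
  ps <- replicate(60, {
    n <- 120
    tm <- rexp(n, 1 / 100); ev <- rbinom(n, 1, 0.7)
    univariateCox(rnorm(n), tm, ev)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.07)
})

test_that("the prognostic filter keeps signal and excludes degenerate fits", {
  set.seed(41)
  n <- 300
  risk <- rnorm(n)
  tm <- rexp(n, exp(risk) / 300); ev <- rbinom(n, 1, 0.8)
  expr <- rbind(strong = risk + rnorm(n, sd = 0.2),
                noise1 = rnorm(n), noise2 = rnorm(n))
  colnames(expr) <- paste0("s", 1:n)
  clin <- data.frame(sample_id = colnames(expr), os_time = tm, os_event = ev)
  keep <- selectPrognostic(c("strong", "noise1", "noise2"), expr, clin)
  expect_true("strong" %in% keep)
  expect_error(selectPrognostic(character(), expr, clin), "empty")
  expect_error(selectPrognostic("noise1", expr, clin, alpha = 1e-12),
               "no prognostic genes")
})

test_that("PC1 loadings match a power-iteration oracle and have unit norm", {
  set.seed(51)
  n <- 20
  for (nGenes in c(3, 5, 10)) {
    x <- matrix(rnorm(nGenes * n), nGenes, n,
                dimnames = list(paste0("g", seq_len(nGenes)), paste0("s", 1:n)))
    x[1, ] <- x[2, ] * 0.8 + rnorm(n, sd = 0.3)  # induce structure
    labels <- rep(1:2, each = n / 2)
    m <- fitScoreModel(x, rownames(x), labels)
    expect_equal(sum(modelLoadings(m)^2), 1, tolerance = 1e-12)
    R <- cor(t(x))
    vOracle <- powerIterPC1(R)
    vOracle <- vOracle / sqrt(sum(vOracle^2))
    w <- unname(modelLoadings(m))
    expect_lt(min(max(abs(w - vOracle)), max(abs(w + vOracle))), 1e-8)
  }
})

test_that("two perfectly correlated genes load equally and PC1 explains everything", {
  n <- 30
  set.seed(52)
  g1 <- rnorm(n)
  x <- rbind(a = g1, b = 2 * g1 + 5)
  colnames(x) <- paste0("s", 1:n)
  m <- fitScoreModel(x, c("a", "b"), rep(1:2, each = 15))
  expect_equal(abs(unname(modelLoadings(m))), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(m@varianceExplained, 1, tolerance = 1e-10)
})

test_that("orientation puts cluster 1 on the high-score side", {
  for (seed in c(3, 17, 29)) {
    co <- testCohort(seed = seed)
    xl <- logTPM(exprMatrix(co))
    genes <- geneRoles(co)$gene[geneRoles(co)$role %in%
                                c("luminal_marker", "basal_marker")]
    m <- fitScoreModel(xl, genes, trueLabels(co))
    sc <- applyScore(m, xl)
    expect_gt(mean(sc[trueLabels(co) == 1]), mean(sc[trueLabels(co) == 2]))
  }
})

test_that("scoring reproduces fit-time projections and is affine-invariant", {
  set.seed(61)
  x <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:40)))
  labels <- rep(1:2, each = 20)
  m <- fitScoreModel(x, rownames(x), labels)
  sc <- applyScore(m, x)
  # direct formula
  Z <- (x - rowMeans(x)) / apply(x, 1, sd)
  direct <- drop(m@sign * crossprod(Z, modelLoadings(m)))
  expect_equal(sc, direct, tolerance = 1e-12)
  expect_equal(applyScore(m, x, freezeStandardization = TRUE), sc, tolerance = 1e-12)

  # gene-wise affine rescaling is absorbed by standardisation
  y <- x * seq(2, 9) + seq(-3, 4)
  expect_equal(applyScore(m, y), sc, tolerance = 1e-10)
})

test_that("missing model genes degrade gracefully until the 50% floor", {
  set.seed(62)
  x <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
  m <- fitScoreModel(x, rownames(x), rep(1:2, each = 15))
  expect_warning(sc <- applyScore(m, x[1:4, ]), "absent")
  expect_length(sc, 30L)
  expect_error(applyScore(m, x[1:2, ]), "fewer than half")
})

test_that("a single-gene model is a monotone map of that gene", {
  set.seed(63)
  x <- matrix(rnorm(2 * 30), 2, 30,
              dimnames = list(c("g1", "g2"), paste0("s", 1:30)))
  m <- fitScoreModel(x, c("g1", "g2"), rep(1:2, each = 15))
  sc <- suppressWarnings(applyScore(m, x["g1", , drop = FALSE]))
  expect_equal(abs(cor(sc, x["g1", ], method = "spearman")), 1)
})
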