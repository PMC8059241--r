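test_that("eta-squared decomposition is exact on worked designs", {
  # one factor, zero within-group variance
  y <- matrix(c(0, 0, 2, 2), 1, dimnames = list("f1", paste0("s", 1:4)))
  meta <- data.frame(row.names = colnames(y), g = factor(c("a", "a", "b", "b")))
  vp <- sequentialAnovaEtaSquared(y, meta, factorOrder = "g",
                                  minPerLevel = 1L)
  expect_equal(vp$g, 1)
  expect_equal(vp$residual, 0)

  # balanced 2x2 with values 0,1,2,3: factor A explains 4 of 5
  y2 <- matrix(c(0, 1, 2, 3), 1, dimnames = list("f1", paste0("s", 1:4)))
  meta2 <- data.frame(row.names = colnames(y2),
                      A = factor(c("a1", "a1", "a2", "a2")),
                      B = factor(c("b1", "b2", "b1", "b2")))
  for (ord in list(c("A", "B"), c("B", "A"))) {
    vp2 <- sequentialAnovaEtaSquared(y2, meta2, factorOrder = ord,
                                     minPerLevel = 1L)
    expect_equal(vp2$A, 0.8)                 # order-invariant when balanced
    expect_equal(vp2$B, 0.2)
    expect_equal(vp2$residual, 0)
  }
})

test_that("Type-I eta-squared is order-dependent only when unbalanced", {
  set.seed(31)
  y <- matrix(rnorm(8), 1, dimnames = list("f", paste0("s", 1:8)))
  metaU <- data.frame(row.names = colnames(y),
                      A = factor(c("a", "a", "a", "a", "a", "b", "b", "b")),
                      B = factor(c("x", "x", "y", "y", "y", "x", "y", "y")))
  ab <- sequentialAnovaEtaSquared(y, metaU, c("A", "B"), minPerLevel = 1L)
  ba <- sequentialAnovaEtaSquared(y, metaU, c("B", "A"), minPerLevel = 1L)
  expect_false(isTRUE(all.equal(ab$A, ba$A)))
  # residual is order-invariant either way
  expect_equal(ab$residual, ba$residual)
})

test_that("per-feature fractions always sum to one", {
  b <- simulateDataset(simulationConfig(nMirna = 200L), seed = 32)
  pre <- preprocessPipeline(b$mir)
  vp <- sequentialAnovaEtaSquared(pre$expr)
  expect_lt(max(abs(rowSums(vp) - 1)), 1e-9)
  expect_true(all(as.matrix(vp) >= -1e-12 & as.matrix(vp) <= 1 + 1e-12))
})

test_that("the sequential engine matches aov Type-I sums of squares", {
  b <- simulateDataset(tinyConfig(60L), seed = 33)
  pre <- preprocessPipeline(b$mir)
  Y <- exprValues(pre$expr)
  meta <- sampleData(pre$expr)
  ord <- demographicFactorOrder()
  vp <- sequentialAnovaEtaSquared(pre$expr)
  for (f in rownames(Y)) {
    df <- cbind(y = Y[f, ], meta[colnames(Y), ord])
    fit <- aov(y ~ ., data = df)
    ss <- summary(fit)[[1]][, "Sum Sq"]
    eta <- ss / sum(ss)
    expect_equal(unname(as.numeric(vp[f, ])), unname(eta), tolerance = 1e-10)
  }
})

test_that("null eta-squared matches the df/(n-1) expectation", {
  b <- simulateDataset(nullConfig(nMirna = 2000L), seed = 34)
  pre <- preprocessPipeline(b$mir)
  vp <- sequentialAnovaEtaSquared(pre$expr)
  n <- ncol(exprValues(pre$expr))
  dfs <- attr(vp, "df")
  for (f in c("population", "sex_of_newborn", "maternal_bmi")) {
    expect_lt(abs(mean(vp[[f]]) - dfs[[f]] / (n - 1)), 0.012)
  }
})

test_that("residualization removes exactly the covariate span", {
  b <- simulateDataset(tinyConfig(60L), seed = 35)
  pre <- preprocessPipeline(b$mir)
  meta <- sampleData(pre$expr)
  covs <- c("maternal_bmi", "birth_weight", "mother_age", "birth_length")
  # a feature exactly linear in BMI residualizes to ~0
  Y <- exprValues(pre$expr)
  Y[1, ] <- 3 + 2 * meta$maternal_bmi
  res <- residualizeContinuous(Y, meta, covs)
  expect_lt(max(abs(res[1, ])), 1e-9)
  # residuals are orthogonal to every covariate
  for (cv in covs)
    expect_lt(max(abs(res %*% (meta[[cv]] - mean(meta[[cv]])))), 1e-6)
  # ordinary-least-squares agreement with lm per feature
  set.seed(36)
  y <- matrix(rnorm(nrow(meta)), 1, dimnames = list("f", rownames(meta)))
  resid1 <- residualizeContinuous(y, meta, covs)
  fit <- lm(as.numeric(y) ~ as.matrix(meta[, covs]))
  expect_equal(as.numeric(resid1), unname(fit$residuals), tolerance = 1e-9)
  # a response built orthogonal to the covariates residualizes to its
  # centered self
  ortho <- qr.resid(qr(cbind(1, as.matrix(meta[, covs]))), rnorm(nrow(meta)))
  y2 <- matrix(ortho + 5, 1, dimnames = list("f", rownames(meta)))
  resid2 <- residualizeContinuous(y2, meta, covs)
  expect_equal(as.numeric(resid2), as.numeric(y2 - mean(y2)),
               tolerance = 1e-9)
  # constant covariate dropped with a warning
  meta3 <- meta; meta3$birth_length <- 50
  expect_warning(residualizeContinuous(y, meta3, covs), "constant")
})

test_that("deAnova matches anova() and flags at the stated thresholds", {
  b <- simulateDataset(simulationConfig(nMirna = 5L, popEffect = 0,
                                        sexEffect = 0, imprintedSlope = 0,
                                        couplingStrength = 0, nMrna = 10L,
                                        nTissueDatasets = 12L), seed = 37)
  pre <- preprocessPipeline(b$mir)
  res <- residualizeContinuous(pre$expr)
  de <- deAnova(res, testFactor = "population")
  meta <- sampleData(res)
  Y <- exprValues(res)
  for (f in rownames(Y)) {
    fit <- lm(Y[f, ] ~ delivery_type + sex_of_newborn + population,
              data = meta)
    tab <- anova(fit)
    expect_equal(de[f, "F"], tab["population", "F value"], tolerance = 1e-9)
    expect_equal(de[f, "p"], tab["population", "Pr(>F)"], tolerance = 1e-9)
  }
  expect_equal(attr(de, "alpha"), 0.05)
  expect_equal(attr(deAnova(res, testFactor = "sex_of_newborn"), "alpha"),
               0.01)
  expect_error(deAnova(res, testFactor = "drinker"), "testFactor")
})

test_that("a strong planted shift is detected at extreme significance", {
  set.seed(38)
  n <- 36
  meta <- data.frame(row.names = sprintf("s%02d", 1:n),
                     delivery_type = factor(rep_len(c("n", "n", "c"), n)),
                     sex_of_newborn = factor(rep_len(c("F", "M"), n)),
                     population = factor(rep(c("A", "E", "S", "X"),
                                             each = 9)))
  y <- matrix(rnorm(n, sd = 0.1), 1, dimnames = list("f", rownames(meta)))
  y[1, meta$population == "A"] <- y[1, meta$population == "A"] + 5
  de <- deAnova(y, meta, testFactor = "population")
  expect_lt(de$p, 1e-10)
})

test_that("nominal p-values are uniform under the null", {
  b <- simulateDataset(nullConfig(nMirna = 2000L), seed = 39)
  pre <- preprocessPipeline(b$mir)
  de <- deAnova(residualizeContinuous(pre$expr), testFactor = "population")
  ks <- suppressWarnings(stats::ks.test(de$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation p follows the greater-or-equal counting rule", {
  b <- simulateDataset(nullConfig(nMirna = 150L), seed = 40)
  pre <- preprocessPipeline(b$mir)
  res <- residualizeContinuous(pre$expr)
  # alpha so small that the observed count is zero -> p must be 1
  pc <- permutationCalibrate(res, testFactor = "population", alpha = 1e-12,
                             nPerm = 20, seed = 1)
  expect_equal(pc$observed, 0)
  expect_equal(pc$p, 1)

  # strong planted signal: no permutation reaches the observed count
  b2 <- simulateDataset(recoveryConfig(nMirna = 300L), seed = 41)
  res2 <- residualizeContinuous(preprocessPipeline(b2$mir)$expr)
  pc2 <- permutationCalibrate(res2, testFactor = "population", nPerm = 50,
                              seed = 2)
  expect_equal(pc2$p, 0)
  pc2s <- permutationCalibrate(res2, testFactor = "population", nPerm = 50,
                               seed = 2, smooth = TRUE)
  expect_equal(pc2s$p, 1 / 51)
  expect_identical(pc2$nullCounts, pc2s$nullCounts)  # same seeded stream
})

test_that("pairwise tests reproduce pairwise.t.test with pooled SD", {
  set.seed(42)
  n <- 24
  pop <- factor(rep(c("A", "E", "S", "X"), each = 6))
  Y <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("f%d", 1:5), sprintf("s%02d", 1:n)))
  Y[1, pop == "A"] <- Y[1, pop == "A"] + 3
  out <- pairwisePopulationTests(Y, pop, bhScope = "within")
  for (f in rownames(Y)) {
    oracle <- pairwise.t.test(Y[f, ], pop, p.adjust.method = "none",
                              pool.sd = TRUE)$p.value
    sub <- out[out$feature_id == f, ]
    for (i in seq_len(nrow(sub))) {
      a <- sub$group1[i]; b <- sub$group2[i]
      expected <- if (!is.na(oracle[b, a])) oracle[b, a] else oracle[a, b]
      expect_equal(sub$p[i], unname(expected), tolerance = 1e-12)
    }
  }
  expect_true("f1" %in% attr(out, "flaggedFeatures"))

  # identical group means: no flags
  flat <- matrix(rep(rep(1:6, 4), 2), 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), sprintf("s%02d", 1:n)))
  out2 <- pairwisePopulationTests(flat, pop)
  expect_length(attr(out2, "flaggedFeatures"), 0)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  set.seed(43)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-12)
  }
  expect_error(bhAdjust(c(0.1, NA)), "NA")
  expect_error(bhAdjust(c(0.1, 1.7)), "\\[0, 1\\]")
})

test_that("direction-consistency binomial p matches direct summation", {
  # 24 of 32 features consistent across 4 populations at null prob 1/8
  direct <- sum(vapply(24:32, function(k)
    choose(32, k) * 0.125^k * 0.875^(32 - k), numeric(1)))
  set.seed(44)
  fc <- matrix(abs(rnorm(32 * 4)) + 0.2, 32, 4,
               dimnames = list(sprintf("m%02d", 1:32), c("A", "E", "S", "X")))
  flip <- sample(32, 8)            # 8 inconsistent features
  fc[flip, 1] <- -fc[flip, 1]
  overall <- setNames(rowMeans(fc) + 1, rownames(fc))  # all positive overall
  out <- directionConsistencyBinomial(fc, overall)
  expect_equal(out$nConsistent, 24)
  expect_equal(out$p, direct, tolerance = 1e-12)

  # all consistent: closed form p = (1/8)^32
  out2 <- directionConsistencyBinomial(abs(fc), overall)
  expect_equal(out2$p, 0.125^32, tolerance = 1e-15)

  # zero successes: upper tail is 1
  out3 <- directionConsistencyBinomial(-abs(fc), overall)
  expect_equal(out3$p, 1)

  # zero fold changes are inconsistent by definition
  fcz <- abs(fc); fcz[1, 1] <- 0
  expect_message(out4 <- directionConsistencyBinomial(fcz, overall), "zero")
  expect_equal(out4$nConsistent, 31)
})

test_that("per-population fold changes carry a declared orientation", {
  b <- simulateDataset(recoveryConfig(nMirna = 300L), seed = 45)
  pre <- preprocessPipeline(b$mir)
  fc <- foldChangeByPopulation(pre$expr)
  expect_identical(attr(fc, "orientation"), "M - F")
  expect_identical(colnames(fc), c("A", "E", "S", "X"))
  # planted sex effects reproduce in most populations
  aff <- b$truth$sexAffected
  signMatch <- sign(fc[aff, ]) == -sign(b$truth$sexFc[aff])  # M-F vs F-M
  expect_gt(mean(signMatch), 0.9)
})
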