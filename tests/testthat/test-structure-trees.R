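test_that("z-scoring centers and scales features with the n-1 SD", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("f", c("a", "b", "c")))
  z <- zscoreFeatures(m)
  expect_equal(as.numeric(z), c(-1, 0, 1))   # sample SD of (1,2,3) is 1
  set.seed(51)
  m2 <- matrix(rnorm(60, 5, 3), 6, 10,
               dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:10)))
  z2 <- zscoreFeatures(m2)
  expect_lt(max(abs(rowMeans(z2))), 1e-12)
  expect_equal(unname(apply(z2, 1, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(zscoreFeatures(z2), z2, tolerance = 1e-12)   # idempotent
  m2[2, ] <- 7
  expect_error(zscoreFeatures(m2), "f2")
})

test_that("correlation distance is 1 - Spearman rho", {
  m <- rbind(up = 1:6, up2 = (1:6)^2, down = 6:1)
  colnames(m) <- sprintf("s%d", 1:6)
  d <- correlationDistance(m)
  expect_equal(d["up", "up2"], 0)          # identical ranks
  expect_equal(d["up", "down"], 2)         # perfect anti-monotone
  set.seed(52)
  for (i in 1:100) {
    x <- rnorm(9); y <- rnorm(9)
    dd <- correlationDistance(rbind(a = x, b = y))
    expect_equal(dd["a", "b"], 1 - bruteForceSpearman(x, y),
                 tolerance = 1e-12)
  }
  expect_error(correlationDistance(rbind(a = 1:5, b = rep(2, 5))),
               "constant")
})

test_that("hierarchical cut recovers planted blobs and labels by appearance", {
  set.seed(53)
  m <- rbind(matrix(rnorm(10 * 8, 0, 0.1), 10, 8),
             matrix(rnorm(10 * 8, 5, 0.1), 10, 8))
  dimnames(m) <- list(sprintf("f%02d", 1:20), sprintf("s%d", 1:8))
  d <- as.matrix(dist(m))
  cl <- hierarchicalCut(asDistanceMatrix(d), k = 2)
  expect_identical(unname(cl[1:10]), rep("C1", 10))
  expect_identical(unname(cl[11:20]), rep("C2", 10))
  # invariant to feature order up to label names
  perm <- sample(20)
  clp <- hierarchicalCut(asDistanceMatrix(d[perm, perm]), k = 2)
  agree <- outer(cl[rownames(m)], cl[rownames(m)], "==")
  agreeP <- outer(clp[rownames(m)], clp[rownames(m)], "==")
  expect_identical(agree, agreeP)
  # k = n gives singletons; k > n errors
  expect_length(unique(hierarchicalCut(asDistanceMatrix(d), k = 20)), 20)
  expect_error(hierarchicalCut(asDistanceMatrix(d), k = 21), "k exceeds")
})

test_that("neighbor joining solves the hand-worked additive 4-taxon tree", {
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4, dimnames = list(lab, lab))
  tr <- njTree(d)
  # split {A,B} | {C,D}; pendant lengths 1, internal 2
  expect_true(sameTopology(tr, ape::read.tree(text = "((A:1,B:1):2,C:1,D:1);")))
  path <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(path, d, tolerance = 1e-9)

  # three taxa: closed-form pendant lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(lab[1:3], lab[1:3]))
  tr3 <- njTree(d3)
  path3 <- ape::cophenetic.phylo(tr3)[lab[1:3], lab[1:3]]
  expect_equal(path3, d3, tolerance = 1e-9)

  expect_error(njTree(d3[1:2, 1:2]), "at least 3")
  bad <- d; bad[1, 2] <- 3
  expect_error(njTree(bad), "symmetric")
})

test_that("neighbor joining is exact on random additive matrices", {
  for (s in 1:20) {
    n <- sample(4:8, 1)
    gen <- randomAdditiveDistance(n, seed = 500 + s)
    tr <- njTree(gen$d)
    expect_true(sameTopology(tr, gen$tree))
    path <- ape::cophenetic.phylo(tr)
    expect_equal(path[rownames(gen$d), colnames(gen$d)], gen$d,
                 tolerance = 1e-9)
  }
})

test_that("population mean trees respond to planted divergence", {
  # identical populations: every distance ~0
  set.seed(54)
  base <- matrix(rnorm(40, 8, 2), 40, 1)[, rep(1, 12)]
  dimnames(base) <- list(sprintf("f%02d", 1:40), sprintf("s%02d", 1:12))
  pop <- factor(rep(c("A", "E", "S", "X"), each = 3))
  d0 <- populationMeanDistance(base, pop)
  expect_lt(max(d0), 1e-12)

  # planted divergence: A carries the largest pendant branch
  b <- simulateDataset(recoveryConfig(), seed = 55)
  pre <- preprocessPipeline(b$mir)
  tr <- populationMeanTree(pre$expr, features = b$truth$popAffected)
  tipEdges <- tr$edge[, 2] <= length(tr$tip.label)
  pend <- setNames(tr$edge.length[tipEdges],
                   tr$tip.label[tr$edge[tipEdges, 2]])
  expect_identical(names(which.max(pend)), "A")
  expect_error(populationMeanDistance(base, factor(rep("A", 12))),
               "at least 3")
})

test_that("Fst collapsing averages source populations arithmetically", {
  src <- c("out", "h1", "h2", "h3")
  fst <- matrix(0, 4, 4, dimnames = list(src, src))
  fst["out", c("h1", "h2", "h3")] <- c(0.1, 0.2, 0.3)
  fst[c("h1", "h2", "h3"), "out"] <- c(0.1, 0.2, 0.3)
  fst["h1", "h2"] <- fst["h2", "h1"] <- 0.01
  fst["h1", "h3"] <- fst["h3", "h1"] <- 0.01
  fst["h2", "h3"] <- fst["h3", "h2"] <- 0.01
  grouping <- list(O = "out", H = c("h1", "h2", "h3"))
  collapsed <- collapseDistance(fst, grouping)
  expect_equal(collapsed["O", "H"], mean(c(0.1, 0.2, 0.3)))  # 0.2
  expect_error(fstTree(fst, list(O = "out", H = "nope", A = "h1", B = "h2")),
               "valid source")

  # identity grouping reproduces plain neighbor joining
  b <- simulateDataset(tinyConfig(12L), seed = 56)
  ident <- setNames(as.list(rownames(b$fst)), rownames(b$fst))
  expect_true(sameTopology(fstTree(b$fst, ident), njTree(b$fst)))
})

test_that("the genetic tree carries the planted population relationships", {
  b <- simulateDataset(tinyConfig(12L), seed = 57)
  tr <- fstTree(b$fst, b$fstGrouping)
  expect_true(sameTopology(tr,
                           ape::read.tree(text = "((E,(S,X)),A);")))
  tipEdges <- tr$edge[, 2] <= 4
  pend <- setNames(tr$edge.length[tipEdges],
                   tr$tip.label[tr$edge[tipEdges, 2]])
  expect_identical(names(which.max(pend)), "A")
})

test_that("the Mantel test enumerates small label sets exactly", {
  gen <- randomAdditiveDistance(4, seed = 58)
  d1 <- gen$d
  self <- mantelTest(d1, d1)
  expect_equal(self$rho, 1)
  expect_true(self$exact)
  expect_equal(self$nPerm, 24)

  set.seed(59)
  d2 <- randomAdditiveDistance(4, seed = 60)$d
  exact <- mantelTest(d1, d2)
  mc <- mantelTest(d1, d2, exactIfSmall = FALSE, nPerm = 20000, seed = 3)
  expect_lt(abs(exact$p - mc$p), 0.02)

  dc <- d1; dc[upper.tri(dc)] <- 1; dc[lower.tri(dc)] <- 1
  expect_error(mantelTest(d1, asDistanceMatrix(dc)), "constant")
  d3 <- d2; dimnames(d3) <- list(letters[1:4], letters[1:4])
  expect_error(mantelTest(d1, d3), "labels")
})

test_that("tree topology is stable across DE feature subsets", {
  b <- simulateDataset(recoveryConfig(), seed = 61)
  pre <- preprocessPipeline(b$mir)
  res <- residualizeContinuous(pre$expr)
  de <- deAnova(res, testFactor = "population")
  anovaSet <- rownames(de)[de$p < 0.05]
  pw <- pairwisePopulationTests(res)
  pairSet <- intersect(anovaSet, attr(pw, "flaggedFeatures"))
  expect_gt(length(pairSet), 20)
  t1 <- populationMeanTree(pre$expr, features = anovaSet)
  t2 <- populationMeanTree(pre$expr, features = pairSet)
  expect_true(sameTopology(t1, t2))
})
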