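# Shared fixtures and independent oracles used across the suite.

# Study-shaped configs: the default simulationConfig() carries the
# variance-calibrated conditions (population ~11%, newborn sex ~4% of total
# variance); recoveryConfig() carries strong planted effects for
# structure-recovery checks; nullConfig() plants nothing.
recoveryConfig <- function(...)
  simulationConfig(popEffect = 1.2, sexEffect = 1.2, ...)

# Down-scaled bundle for structural fixtures where only shapes matter.
tinyConfig <- function(nMirna, ...)
  simulationConfig(nMirna = nMirna,
                   imprintedSize = max(2L, nMirna %/% 10L),
                   nTargetMirna = 0L, nMrna = 60L, nTissueDatasets = 12L,
                   ...)

nullConfig <- function(nMirna = 400L, ...)
  simulationConfig(nMirna = nMirna, popEffect = 0, sexEffect = 0,
                   imprintedSlope = 0, couplingStrength = 0,
                   nMrna = 50L, nTissueDatasets = 12L, ...)

randomCounts <- function(nf, ns, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(nf * ns, mu = 60, size = 10), nf, ns,
              dimnames = list(sprintf("mir%03d", seq_len(nf)),
                              sprintf("s%02d", seq_len(ns))))
  storage.mode(m) <- "integer"
  m
}

# Brute-force Benjamini-Hochberg step-up, written independently of p.adjust.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Rank-then-Pearson Spearman, written independently of cor(method).
bruteForceSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-group rank-sum p by enumeration of all C(n1+n2, n1) group
# assignments (tie-free inputs).
enumerateRankSumP <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  stat <- function(idx) sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
  obs <- stat(seq_len(n1))
  splits <- combn(length(pooled), n1)
  stats <- apply(splits, 2L, stat)
  mu <- n1 * length(b) / 2
  switch(alternative,
         two.sided = mean(abs(stats - mu) >= abs(obs - mu) - 1e-12),
         less = mean(stats <= obs + 1e-12),
         greater = mean(stats >= obs - 1e-12))
}

# Random additive (tree-metric) distance matrix from a random topology with
# positive branch lengths, plus the generating tree's path distances.
randomAdditiveDistance <- function(nTips, seed) {
  set.seed(seed)
  tr <- ape::rtree(nTips, rooted = FALSE,
                   tip.label = paste0("t", seq_len(nTips)))
  tr$edge.length <- runif(length(tr$edge.length), 0.2, 2)
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# Small randomized metadata for design-matrix tests (shuffled fixed counts,
# so no factor is aliased with another).
toyMetadata <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    row.names = sprintf("s%02d", seq_len(n)),
    population = factor(sample(rep_len(c("A", "E", "S", "X"), n))),
    sex_of_newborn = factor(sample(rep_len(c("F", "M"), n))),
    delivery_type = factor(sample(rep_len(c("natural", "natural",
                                            "cesarean"), n))),
    maternal_bmi = rnorm(n, 26, 4))
}
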