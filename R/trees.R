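## Co-expression clustering, population dendrograms (neighbor joining) and
## the Mantel concordance test against genetic (Fst) distances.

#' Z-score features across samples
#'
#' Centers each feature and scales it to unit standard deviation (n-1
#' denominator) across samples.
#'
#' @param x a [MirExperiment-class] or matrix (features x samples).
#' @return same kind of object at stage `zscored`.
#' @export
zscoreFeatures <- function(x) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  sds <- apply(m, 1L, sd)
  if (any(sds == 0))
    stop("zero-variance features: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  out <- (m - rowMeans(m)) / sds
  if (is(x, "MirExperiment")) .advanceStage(x, out, "zscored") else out
}

#' Spearman correlation distance between features
#'
#' `d(i, j) = 1 - rho(i, j)` with Spearman's rho (average ranks for ties);
#' distances lie in \[0, 2\].
#'
#' @param x a [MirExperiment-class] or matrix (features x samples).
#' @return symmetric distance matrix over features.
#' @export
correlationDistance <- function(x) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  const <- apply(m, 1L, function(z) var(z) == 0)
  if (any(const))
    stop("constant profiles have undefined correlation: ",
         paste(rownames(m)[const], collapse = ", "))
  d <- 1 - cor(t(m), method = "spearman")
  diag(d) <- 0
  asDistanceMatrix(d)
}

#' Cut a hierarchical clustering into k groups
#'
#' Agglomerative clustering on a distance matrix, cut into exactly `k`
#' clusters; cluster labels `C1..Ck` are assigned by order of first
#' appearance along the feature list.
#'
#' @param d distance matrix over features.
#' @param k number of clusters, default 6.
#' @param linkage agglomeration method, default `"complete"`.
#' @return named character vector feature -> cluster label.
#' @export
hierarchicalCut <- function(d, k = 6L, linkage = "complete") {
  d <- asDistanceMatrix(d)
  if (k > nrow(d)) stop("k exceeds the number of features")
  cl <- cutree(hclust(as.dist(d), method = linkage), k = k)
  relabel <- match(cl, unique(cl))
  setNames(paste0("C", relabel), names(cl))
}

#' Mean-expression distance matrix between populations
#'
#' Each feature is scaled by its mean across all samples; population mean
#' profiles are formed; per feature, the distance between two populations is
#' the absolute difference of their scaled means, and the population
#' distance is the mean of these across features.
#'
#' @param x a [MirExperiment-class] or matrix.
#' @param population population labels; defaults to the `population`
#'   metadata column.
#' @param features optional feature subset (ids).
#' @return symmetric distance matrix over populations.
#' @export
populationMeanDistance <- function(x, population = NULL, features = NULL) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(population)) population <- sampleData(x)$population
  g <- droplevels(factor(population))
  if (nlevels(g) < 3L) stop("at least 3 populations are required")
  if (any(table(g) == 0L)) stop("every population needs at least one sample")
  if (!is.null(features)) m <- m[features, , drop = FALSE]
  scaled <- m / rowMeans(m)
  popMeans <- vapply(levels(g), function(l)
    rowMeans(scaled[, g == l, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) popMeans <- matrix(popMeans, nrow = 1L,
                                        dimnames = list(NULL, levels(g)))
  ks <- levels(g)
  d <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j) {
    d[i, j] <- d[j, i] <- mean(abs(popMeans[, i] - popMeans[, j]))
  }
  asDistanceMatrix(d)
}

#' Unrooted neighbor-joining population tree from expression
#'
#' [populationMeanDistance()] followed by neighbor joining.
#'
#' @inheritParams populationMeanDistance
#' @param clampNegative clamp negative branch lengths to zero, default FALSE.
#' @return an [ape::phylo] tree.
#' @export
populationMeanTree <- function(x, population = NULL, features = NULL,
                               clampNegative = FALSE) {
  njTree(populationMeanDistance(x, population, features),
         clampNegative = clampNegative)
}

#' Neighbor joining
#'
#' Classical Saitou-Nei neighbor joining (via [ape::nj]) on a validated
#' symmetric distance matrix. Negative branch lengths are reported as
#' produced unless `clampNegative = TRUE`.
#'
#' @param d symmetric distance matrix, n >= 3 labels.
#' @param clampNegative clamp negative branch lengths to zero.
#' @return an [ape::phylo] tree.
#' @export
njTree <- function(d, clampNegative = FALSE) {
  d <- asDistanceMatrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 labels")
  tr <- ape::nj(as.dist(d))
  if (clampNegative) tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Genetic (Fst) tree with source-population averaging
#'
#' Collapses source populations into analysis populations by arithmetic mean
#' of the pairwise Fst entries (e.g. several East Asian source populations
#' averaged into one), then neighbor joining on the collapsed matrix.
#'
#' @param fst symmetric Fst matrix over source populations.
#' @param grouping named list: analysis population -> character vector of
#'   source populations.
#' @param clampNegative clamp negative branch lengths to zero.
#' @return an [ape::phylo] tree over the analysis populations.
#' @export
fstTree <- function(fst, grouping, clampNegative = FALSE) {
  njTree(collapseDistance(fst, grouping), clampNegative = clampNegative)
}

#' Collapse a distance matrix over groups of source labels
#'
#' Entry (i, j) of the result is the arithmetic mean of all source-level
#' entries between group i and group j.
#'
#' @param d symmetric distance matrix over source labels.
#' @param grouping named list: group label -> source labels.
#' @return symmetric distance matrix over the groups.
#' @export
collapseDistance <- function(d, grouping) {
  d <- asDistanceMatrix(d)
  bad <- vapply(grouping, function(src) length(src) == 0L ||
                  !all(src %in% rownames(d)), logical(1L))
  if (any(bad))
    stop("groups without valid source populations: ",
         paste(names(grouping)[bad], collapse = ", "))
  ks <- names(grouping)
  out <- matrix(0, length(ks), length(ks), dimnames = list(ks, ks))
  for (i in seq_along(ks)) for (j in seq_along(ks)) if (i < j) {
    out[i, j] <- out[j, i] <-
      mean(d[grouping[[i]], grouping[[j]], drop = FALSE])
  }
  asDistanceMatrix(out)
}

## All permutations of 1..n (n small), as a list of integer vectors.
.allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, rest[p])
    }
  }
  out
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the upper-triangle entries, with a two-sided
#' permutation p-value obtained by relabeling one matrix (rows and columns
#' jointly): the fraction of permutations with `|rho| >= |rho observed|`.
#' For `n <= 6` labels (and `exactIfSmall = TRUE`) all `n!` permutations are
#' enumerated; otherwise `nPerm` random permutations are drawn.
#'
#' @param d1,d2 distance matrices over the same labels.
#' @param nPerm number of random permutations when not enumerating,
#'   default 9999.
#' @param seed seed for the random permutation stream.
#' @param exactIfSmall enumerate all permutations when n <= 6, default TRUE.
#' @return list with `rho`, `p`, `nPerm` and `exact`.
#' @export
mantelTest <- function(d1, d2, nPerm = 9999L, seed = 1L,
                       exactIfSmall = TRUE) {
  d1 <- asDistanceMatrix(d1); d2 <- asDistanceMatrix(d2)
  if (!identical(sort(rownames(d1)), sort(rownames(d2))))
    stop("distance matrices must share the same labels")
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (sd(v1) == 0 || sd(d2[ut]) == 0)
    stop("constant distance matrix: correlation undefined")
  rho <- cor(v1, d2[ut], method = "spearman")
  permRho <- function(p) {
    dp <- d2[p, p]
    cor(v1, dp[ut], method = "spearman")
  }
  tol <- 1e-12
  if (exactIfSmall && n <= 6L) {
    perms <- .allPermutations(n)
    rhos <- vapply(perms, permRho, numeric(1L))
    p <- mean(abs(rhos) >= abs(rho) - tol)
    list(rho = rho, p = p, nPerm = length(perms), exact = TRUE)
  } else {
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPerm))
      if (abs(permRho(sample.int(n))) >= abs(rho) - tol) hits <- hits + 1L
    list(rho = rho, p = hits / nPerm, nPerm = nPerm, exact = FALSE)
  }
}

#' Unrooted topology comparison
#'
#' TRUE when two trees share the same unrooted topology (Robinson-Foulds
#' distance zero on unrooted trees).
#'
#' @param t1,t2 [ape::phylo] trees over the same tips.
#' @export
sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1L] == 0
}
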