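## Variance partitioning (sequential Type-I ANOVA, eta-squared) and
## differential expression with permutation calibration.

#' The demographic variables in model entry order
#'
#' The order in which the twelve demographic variables enter the sequential
#' ANOVA: delivery type, newborn sex, maternal BMI, number of pregnancies,
#' pregnancy infection, first pregnancy, mother's age, birth length, birth
#' weight, number of children, drinker, population.
#'
#' @return character vector of variable names.
#' @export
demographicFactorOrder <- function() {
  c("delivery_type", "sex_of_newborn", "maternal_bmi", "n_pregnancies",
    "pregnancy_infection", "first_pregnancy", "mother_age", "birth_length",
    "birth_weight", "n_children", "drinker", "population")
}

## Build the ordered design and compute sequential (Type-I) sums of squares
## for every feature at once. Y: features x samples. Returns per-term SS,
## residual SS, total (centered) SS, and degrees of freedom.
.sequentialSS <- function(Y, metadata, terms) {
  n <- ncol(Y)
  blocks <- lapply(terms, function(tm) {
    v <- metadata[[tm]]
    if (is.null(v)) stop("metadata variable not found: ", tm)
    if (is.character(v) || is.logical(v)) v <- factor(v)
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) < 2L)
        stop("variable '", tm, "' has fewer than 2 observed levels")
      model.matrix(~ v)[, -1L, drop = FALSE]
    } else {
      matrix(as.numeric(v), ncol = 1L)
    }
  })
  df <- vapply(blocks, ncol, integer(1L))
  X <- cbind(1, do.call(cbind, blocks))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    stop("rank-deficient design; aliased columns at positions: ",
         paste(aliased, collapse = ", "),
         " (terms: ", paste(terms, collapse = " + "), ")")
  }
  Q <- qr.Q(qrX)
  C <- crossprod(Q, t(Y))                 # p x features
  ends <- 1L + cumsum(df)
  starts <- c(2L, head(ends, -1L) + 1L)
  ss <- vapply(seq_along(terms), function(j) {
    colSums(C[starts[j]:ends[j], , drop = FALSE]^2)
  }, numeric(nrow(Y)))
  if (nrow(Y) == 1L) ss <- matrix(ss, nrow = 1L)
  colnames(ss) <- terms
  ssTot <- rowSums(Y^2) - n * rowMeans(Y)^2
  ssRes <- ssTot - rowSums(ss)
  ssRes[ssRes < 0] <- 0                  # guard against rounding
  list(ss = ss, ssRes = ssRes, ssTot = ssTot,
       df = setNames(df, terms), dfRes = n - 1L - sum(df))
}

.dropIncomplete <- function(Y, metadata, vars) {
  cc <- complete.cases(metadata[, vars, drop = FALSE])
  if (!all(cc))
    message("excluding ", sum(!cc), " sample(s) with missing values for: ",
            paste(vars, collapse = ", "))
  list(Y = Y[, cc, drop = FALSE], metadata = metadata[cc, , drop = FALSE])
}

#' Sequential (Type-I) ANOVA variance partitioning by eta-squared
#'
#' Per feature, fits a fixed-order sequential ANOVA over the given variables
#' and attributes to each one the fraction of the total sum of squares it
#' explains (eta-squared); per-feature fractions plus the residual fraction
#' sum to one. Categorical variables must have at least `minPerLevel`
#' observations in every level.
#'
#' @param x a [MirExperiment-class] or expression matrix (features x samples).
#' @param metadata sample metadata; defaults to `sampleData(x)`.
#' @param factorOrder ordered variable names, default
#'   [demographicFactorOrder()].
#' @param minPerLevel eligibility threshold for categorical levels, default 5.
#' @return data.frame of per-feature eta-squared values (one column per
#'   variable plus `residual`), with the across-feature mean per variable in
#'   `attr(, "meanEtaSq")`.
#' @export
sequentialAnovaEtaSquared <- function(x, metadata = NULL,
                                      factorOrder = demographicFactorOrder(),
                                      minPerLevel = 5L) {
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  d <- .dropIncomplete(Y, metadata, factorOrder)
  elig <- eligibleFactors(d$metadata, factorOrder, minPerLevel = minPerLevel)
  if (!setequal(elig, factorOrder))
    stop("ineligible variables (need >= ", minPerLevel,
         " observations per level): ",
         paste(setdiff(factorOrder, elig), collapse = ", "))
  fit <- .sequentialSS(d$Y, d$metadata, factorOrder)
  eta <- fit$ss / fit$ssTot
  out <- data.frame(eta, residual = fit$ssRes / fit$ssTot,
                    check.names = FALSE)
  rownames(out) <- rownames(Y)
  attr(out, "meanEtaSq") <- colMeans(out)
  attr(out, "df") <- c(fit$df, residual = fit$dfRes)
  out
}

#' Residualize expression on continuous covariates
#'
#' Per feature, ordinary least-squares residuals on the given continuous
#' covariates fitted jointly with an intercept; samples with a missing
#' covariate are excluded (complete cases per analysis). Constant covariates
#' are dropped with a warning.
#'
#' @param x a [MirExperiment-class] or matrix.
#' @param metadata sample metadata; defaults to `sampleData(x)`.
#' @param covariates covariate names, default maternal BMI, birth weight,
#'   mother's age and birth length.
#' @return same kind of object at stage `residualized` (possibly with fewer
#'   samples).
#' @export
residualizeContinuous <- function(x, metadata = NULL,
                                  covariates = c("maternal_bmi",
                                                 "birth_weight",
                                                 "mother_age",
                                                 "birth_length")) {
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  missing <- setdiff(covariates, names(metadata))
  if (length(missing)) stop("covariates not found: ",
                            paste(missing, collapse = ", "))
  d <- .dropIncomplete(Y, metadata, covariates)
  covs <- vapply(covariates, function(v) as.numeric(d$metadata[[v]]),
                 numeric(nrow(d$metadata)))
  keep <- apply(covs, 2L, function(z) var(z) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
    covs <- covs[, keep, drop = FALSE]
  }
  X <- cbind(1, covs)
  res <- t(qr.resid(qr(X), t(d$Y)))
  dimnames(res) <- dimnames(d$Y)
  if (is(x, "MirExperiment")) {
    sub <- x[, colnames(res)]
    .advanceStage(sub, res, "residualized")
  } else res
}

#' Differential expression by sequential ANOVA
#'
#' Per feature, the sequential ANOVA F-test for `testFactor` entered after
#' the factors preceding it in `factors` (default order: delivery type,
#' newborn sex, population), on covariate-residualized expression.
#' Benjamini-Hochberg adjustment is applied across features.
#'
#' @param x a residualized [MirExperiment-class] or matrix.
#' @param metadata sample metadata; defaults to `sampleData(x)`.
#' @param factors ordered model factors.
#' @param testFactor the factor whose F-test is reported; must be in
#'   `factors`.
#' @param alpha nominal significance threshold for the `significant` flag;
#'   defaults to 0.05 for population and 0.01 for newborn sex.
#' @return data.frame with columns `feature_id`, `F`, `p`, `padj`,
#'   `significant`, and log2 fold-change columns: for a two-level factor a
#'   single `fc` (second level minus first, orientation recorded in
#'   `attr(, "orientation")`), otherwise one `fc_<level>` column per level
#'   (level mean minus grand mean).
#' @export
deAnova <- function(x, metadata = NULL,
                    factors = c("delivery_type", "sex_of_newborn",
                                "population"),
                    testFactor = "population",
                    alpha = if (testFactor == "sex_of_newborn") 0.01 else 0.05) {
  if (!testFactor %in% factors)
    stop("testFactor must be one of the model factors")
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  d <- .dropIncomplete(Y, metadata, factors)
  fit <- .sequentialSS(d$Y, d$metadata, factors)
  dfT <- fit$df[[testFactor]]
  Fstat <- (fit$ss[, testFactor] / dfT) / (fit$ssRes / fit$dfRes)
  p <- pf(Fstat, dfT, fit$dfRes, lower.tail = FALSE)
  out <- data.frame(feature_id = rownames(Y), F = Fstat, p = p,
                    padj = bhAdjust(p), row.names = rownames(Y))
  g <- droplevels(factor(d$metadata[[testFactor]]))
  means <- vapply(levels(g), function(l)
    rowMeans(d$Y[, g == l, drop = FALSE]), numeric(nrow(d$Y)))
  if (nrow(d$Y) == 1L) means <- matrix(means, nrow = 1L,
                                       dimnames = list(NULL, levels(g)))
  if (nlevels(g) == 2L) {
    out$fc <- means[, 2L] - means[, 1L]
    attr(out, "orientation") <- paste(levels(g)[2L], "-", levels(g)[1L])
  } else {
    fc <- means - rowMeans(d$Y)
    colnames(fc) <- paste0("fc_", levels(g))
    out <- cbind(out, fc)
  }
  out$significant <- out$p < alpha
  attr(out, "alpha") <- alpha
  attr(out, "testFactor") <- testFactor
  out
}

#' Permutation calibration of the significant-feature count
#'
#' Permutes whole metadata rows against the expression columns (individual
#' labels, preserving the covariate correlation structure), reruns the
#' sequential ANOVA each time, and counts features with nominal p below
#' `alpha`. The permutation p-value is the proportion of permutations whose
#' count is greater than or equal to the observed count; with
#' `smooth = TRUE` the add-one rule (b+1)/(n+1) is used instead so the
#' result can never be exactly zero.
#'
#' @inheritParams deAnova
#' @param nPerm number of permutations, default 1000.
#' @param seed integer seed for the permutation stream.
#' @param smooth use add-one smoothing, default FALSE.
#' @return list with `observed` (count of nominally significant features),
#'   `nullCounts` (length `nPerm`), and `p`.
#' @export
permutationCalibrate <- function(x, metadata = NULL,
                                 factors = c("delivery_type",
                                             "sex_of_newborn", "population"),
                                 testFactor = "population",
                                 alpha = if (testFactor == "sex_of_newborn")
                                   0.01 else 0.05,
                                 nPerm = 1000L, seed = 1L, smooth = FALSE) {
  stopifnot(nPerm >= 1L)
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  d <- .dropIncomplete(Y, metadata, factors)
  countSig <- function(meta) {
    fit <- .sequentialSS(d$Y, meta, factors)
    dfT <- fit$df[[testFactor]]
    Fstat <- (fit$ss[, testFactor] / dfT) / (fit$ssRes / fit$dfRes)
    sum(pf(Fstat, dfT, fit$dfRes, lower.tail = FALSE) < alpha)
  }
  observed <- countSig(d$metadata)
  nullCounts <- integer(nPerm)
  n <- ncol(d$Y)
  set.seed(seed)
  for (b in seq_len(nPerm))
    nullCounts[b] <- countSig(d$metadata[sample.int(n), , drop = FALSE])
  hits <- sum(nullCounts >= observed)
  p <- if (smooth) (hits + 1) / (nPerm + 1) else hits / nPerm
  list(observed = observed, nullCounts = nullCounts, p = p,
       alpha = alpha, testFactor = testFactor)
}

#' Pairwise population t-tests with pooled SD
#'
#' Per feature and population pair, a two-sided t-test whose denominator
#' uses the standard deviation pooled across all groups (as in
#' `pairwise.t.test(pool.sd = TRUE)`); Benjamini-Hochberg correction is
#' applied within each feature across the pairs by default (set
#' `bhScope = "global"` to correct across all feature-pair combinations).
#'
#' @param x a residualized [MirExperiment-class] or matrix.
#' @param population population labels per sample; defaults to the
#'   `population` metadata column.
#' @param alpha significance threshold on adjusted p, default 0.05.
#' @param bhScope `"within"` (per feature, across pairs) or `"global"`.
#' @return long data.frame (feature_id, group1, group2, diff, t, p, padj,
#'   significant); features with any significant pair are listed in
#'   `attr(, "flaggedFeatures")`.
#' @export
pairwisePopulationTests <- function(x, population = NULL, alpha = 0.05,
                                    bhScope = c("within", "global")) {
  bhScope <- match.arg(bhScope)
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(population)) population <- sampleData(x)$population
  g <- droplevels(factor(population))
  if (nlevels(g) < 2L) stop("at least two populations are required")
  ns <- table(g)
  small <- names(ns)[ns < 2L]
  if (length(small))
    warning("groups with <2 samples skipped: ", paste(small, collapse = ", "))
  use <- names(ns)[ns >= 2L]
  ## pooled residual SD across all groups with >=2 samples
  resSS <- 0; resDf <- 0
  means <- list()
  for (l in use) {
    sub <- Y[, g == l, drop = FALSE]
    means[[l]] <- rowMeans(sub)
    resSS <- resSS + rowSums((sub - means[[l]])^2)
    resDf <- resDf + ncol(sub) - 1L
  }
  pooledVar <- resSS / resDf
  pairs <- combn(use, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    diff <- means[[a]] - means[[b]]
    se <- sqrt(pooledVar * (1 / ns[[a]] + 1 / ns[[b]]))
    t <- diff / se
    data.frame(feature_id = rownames(Y), group1 = a, group2 = b,
               diff = diff, t = t,
               p = 2 * pt(abs(t), resDf, lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bhScope == "within") {
    out$padj <- ave(out$p, out$feature_id, FUN = bhAdjust)
  } else {
    out$padj <- bhAdjust(out$p)
  }
  out$significant <- out$padj < alpha
  attr(out, "flaggedFeatures") <-
    sort(unique(out$feature_id[out$significant]))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p))) stop("NA/NaN p-values are not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cross-population direction consistency by exact binomial test
#'
#' A feature is fully consistent when its per-population fold changes all
#' share the sign of the overall fold change (a zero anywhere counts as
#' inconsistent). The count of fully consistent features is tested against
#' an upper-tail exact binomial null with success probability
#' `(1/2)^(k-1)` for `k` populations by default.
#'
#' @param fcByPopulation features x populations matrix of per-population
#'   fold changes (same orientation everywhere).
#' @param overallFc named vector of overall fold changes per feature.
#' @param nullProb null consistency probability; default `(1/2)^(k-1)`.
#' @return list with `consistent` (named logical), `nConsistent`, `nTotal`,
#'   `nullProb` and upper-tail `p` (probability of at least the observed
#'   count).
#' @export
directionConsistencyBinomial <- function(fcByPopulation, overallFc,
                                         nullProb = NULL) {
  fcByPopulation <- as.matrix(fcByPopulation)
  k <- ncol(fcByPopulation)
  if (k < 2L) stop("at least two populations of fold changes are required")
  if (is.null(nullProb)) nullProb <- 0.5 ^ (k - 1L)
  stopifnot(nullProb > 0, nullProb < 1)
  overallFc <- overallFc[rownames(fcByPopulation)]
  zero <- overallFc == 0 | apply(fcByPopulation == 0, 1L, any)
  if (any(zero))
    message(sum(zero), " feature(s) with a zero fold change treated as ",
            "inconsistent")
  consistent <- !zero &
    apply(sign(fcByPopulation) == sign(overallFc), 1L, all)
  nC <- sum(consistent); nT <- length(consistent)
  p <- pbinom(nC - 1L, nT, nullProb, lower.tail = FALSE)
  list(consistent = setNames(consistent, rownames(fcByPopulation)),
       nConsistent = nC, nTotal = nT, nullProb = nullProb, p = p)
}

#' Per-population fold changes for a two-level factor
#'
#' Within each population, the difference of group means of `testFactor`
#' (second level minus first, matching [deAnova()]'s orientation).
#'
#' @param x a [MirExperiment-class] or matrix.
#' @param metadata sample metadata; defaults to `sampleData(x)`.
#' @param testFactor two-level factor, default `sex_of_newborn`.
#' @param by stratifying variable, default `population`.
#' @return features x populations matrix of fold changes.
#' @export
foldChangeByPopulation <- function(x, metadata = NULL,
                                   testFactor = "sex_of_newborn",
                                   by = "population") {
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  f <- droplevels(factor(metadata[[testFactor]]))
  if (nlevels(f) != 2L) stop("testFactor must have exactly two levels")
  g <- droplevels(factor(metadata[[by]]))
  fc <- vapply(levels(g), function(l) {
    sel <- g == l
    rowMeans(Y[, sel & f == levels(f)[2L], drop = FALSE]) -
      rowMeans(Y[, sel & f == levels(f)[1L], drop = FALSE])
  }, numeric(nrow(Y)))
  if (nrow(Y) == 1L) fc <- matrix(fc, nrow = 1L,
                                  dimnames = list(rownames(Y), levels(g)))
  attr(fc, "orientation") <- paste(levels(f)[2L], "-", levels(f)[1L])
  fc
}
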