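## miRNA -> target repression analysis and imprinted-cluster correlations
## with maternal anthropometry.

#' Filter target predictions by method support
#'
#' Retains miRNA-mRNA pairs predicted by at least `minMethods` of the five
#' underlying algorithms.
#'
#' @param preds data.frame with columns `mirna_id`, `mrna_id`,
#'   `n_supporting_methods` (0-5).
#' @param minMethods support threshold, default 3.
#' @return filtered data.frame.
#' @export
filterPredictions <- function(preds, minMethods = 3L) {
  stopifnot(all(c("mirna_id", "mrna_id", "n_supporting_methods") %in%
                  names(preds)))
  if (any(preds$n_supporting_methods < 0 | preds$n_supporting_methods > 5))
    stop("n_supporting_methods must lie in [0, 5]")
  if (anyDuplicated(preds[, c("mirna_id", "mrna_id")]))
    stop("duplicate miRNA-mRNA pairs")
  preds[preds$n_supporting_methods >= minMethods, , drop = FALSE]
}

## Spearman rho between one profile and the rows of a matrix.
.spearmanTo <- function(profile, m) {
  as.vector(cor(rank(profile), apply(m, 1L, rank)))
}

#' Repression test for a miRNA cluster's predicted targets
#'
#' Per predicted pair, Spearman's rho between the miRNA and the mRNA across
#' shared samples (miRNA by miRNA). The non-target pool is every mRNA with
#' no predicted pair to any cluster miRNA (at any support level in
#' `allPreds`, when given); pool correlations are computed against the
#' cluster-mean miRNA profile. The group test is a one-sided Wilcoxon
#' rank-sum test of target rho values against pool rho values, alternative
#' "targets lower". Retained targets are pairs with `rho < rhoThreshold`.
#'
#' @param mirnaExpr cluster miRNAs x samples matrix (or
#'   [MirExperiment-class]).
#' @param mrnaExpr mRNAs x samples matrix.
#' @param preds filtered prediction table (see [filterPredictions()]).
#' @param allPreds optional unfiltered prediction table used to exclude
#'   weakly predicted mRNAs from the non-target pool; defaults to `preds`.
#' @param rhoThreshold repression flag threshold, default -0.5.
#' @return list with `pairs` (data.frame mirna_id, mrna_id, rho, repressed),
#'   `retained` (flagged pairs), `nonTargetRho`, `p` (one-sided group
#'   p-value) and `nShared` (sample count used).
#' @export
clusterRepressionTest <- function(mirnaExpr, mrnaExpr, preds,
                                  allPreds = preds, rhoThreshold = -0.5) {
  mi <- if (is(mirnaExpr, "MirExperiment")) exprValues(mirnaExpr)
        else mirnaExpr
  shared <- intersect(colnames(mi), colnames(mrnaExpr))
  if (length(shared) < 5L)
    stop("need at least 5 shared samples between miRNA and mRNA matrices")
  mi <- mi[, shared, drop = FALSE]
  mr <- mrnaExpr[, shared, drop = FALSE]
  preds <- preds[preds$mirna_id %in% rownames(mi) &
                   preds$mrna_id %in% rownames(mr), , drop = FALSE]
  if (!nrow(preds)) stop("no predictions involve the cluster miRNAs")
  rho <- mapply(function(mir, gene)
    cor(mi[mir, ], mr[gene, ], method = "spearman"),
    preds$mirna_id, preds$mrna_id)
  pairs <- data.frame(mirna_id = preds$mirna_id, mrna_id = preds$mrna_id,
                      rho = as.numeric(rho))
  pairs$repressed <- pairs$rho < rhoThreshold
  excluded <- unique(allPreds$mrna_id[allPreds$mirna_id %in% rownames(mi) &
                                        allPreds$n_supporting_methods >= 1])
  pool <- setdiff(rownames(mr), excluded)
  if (!length(pool)) stop("empty non-target pool")
  clusterMean <- colMeans(mi)
  poolRho <- .spearmanTo(clusterMean, mr[pool, , drop = FALSE])
  gt <- compareGroupsRank(pairs$rho, poolRho, alternative = "less")
  list(pairs = pairs,
       retained = pairs[pairs$repressed, , drop = FALSE],
       nonTargetRho = setNames(poolRho, pool),
       p = gt$p, nShared = length(shared))
}

#' Select sex-associated miRNA targets by opposite-direction fold change
#'
#' An mRNA is retained as a target of a sex-associated miRNA when the pair
#' is predicted, the mRNA's absolute fold change exceeds `minAbsFc`, and its
#' direction is opposite to the miRNA's. Both fold-change vectors must be on
#' the same female-vs-male orientation, declared via `orientation`.
#'
#' @param mirnaFc named vector of fold changes for sex-associated miRNAs.
#' @param mrnaFc named vector of mRNA fold changes (same orientation).
#' @param preds filtered prediction table.
#' @param minAbsFc minimum absolute mRNA fold change (strict), default 0.1.
#' @param orientation orientation tag, e.g. `"F - M"`; required, and must be
#'   identical for both inputs by construction.
#' @return list with `female` and `male` data.frames (mirna_id, mrna_id,
#'   mirna_fc, mrna_fc): targets of female-up and male-up miRNAs.
#' @export
sexTargetSelection <- function(mirnaFc, mrnaFc, preds, minAbsFc = 0.1,
                               orientation = NULL) {
  if (is.null(orientation))
    stop("fold-change orientation must be declared (e.g. \"F - M\")")
  preds <- preds[preds$mirna_id %in% names(mirnaFc) &
                   preds$mrna_id %in% names(mrnaFc), , drop = FALSE]
  mifc <- mirnaFc[preds$mirna_id]
  mrfc <- mrnaFc[preds$mrna_id]
  keep <- abs(mrfc) > minAbsFc & sign(mrfc) == -sign(mifc) & mifc != 0
  sel <- data.frame(mirna_id = preds$mirna_id, mrna_id = preds$mrna_id,
                    mirna_fc = as.numeric(mifc),
                    mrna_fc = as.numeric(mrfc))[keep, , drop = FALSE]
  list(female = sel[sel$mirna_fc > 0, , drop = FALSE],
       male = sel[sel$mirna_fc < 0, , drop = FALSE],
       orientation = orientation)
}

#' Imprinted-cluster correlation with maternal anthropometry
#'
#' For every miRNA in the named imprinted cluster, Spearman correlation
#' (rho and p) with each covariate; at the group level, a two-sided
#' one-sample Wilcoxon signed-rank test of the per-miRNA rho distribution
#' against zero, per covariate. Covariates missing from the metadata are
#' skipped with a warning.
#'
#' @param x a [MirExperiment-class] or matrix of normalized expression.
#' @param annotation data.frame with columns `feature_id` and
#'   `named_cluster`.
#' @param metadata sample metadata; defaults to `sampleData(x)`.
#' @param covariates covariate names, default maternal BMI, weight, height.
#' @param cluster cluster label, default `"C19MC"`.
#' @return list with `perMirna` (long data.frame feature_id, covariate, rho,
#'   p) and `groupP` (named vector of group-level two-sided p-values).
#' @export
imprintingAnalysis <- function(x, annotation, metadata = NULL,
                               covariates = c("maternal_bmi",
                                              "maternal_weight",
                                              "maternal_height"),
                               cluster = "C19MC") {
  Y <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(metadata)) metadata <- sampleData(x)
  members <- annotation$feature_id[annotation$named_cluster %in% cluster]
  members <- intersect(members, rownames(Y))
  if (!length(members)) stop("no expressed members of cluster ", cluster)
  avail <- covariates %in% names(metadata)
  if (!all(avail)) {
    warning("skipping absent covariate(s): ",
            paste(covariates[!avail], collapse = ", "))
    covariates <- covariates[avail]
  }
  if (!length(covariates)) stop("no usable covariates")
  rows <- list(); groupP <- setNames(numeric(0), character(0))
  for (cv in covariates) {
    z <- metadata[[cv]]
    ok <- !is.na(z)
    if (sum(ok) < 5L) {
      warning("fewer than 5 samples with '", cv, "': skipped")
      next
    }
    res <- t(vapply(members, function(f) {
      ct <- suppressWarnings(
        cor.test(Y[f, ok], z[ok], method = "spearman"))
      c(rho = unname(ct$estimate), p = ct$p.value)
    }, numeric(2L)))
    rows[[cv]] <- data.frame(feature_id = members, covariate = cv,
                             rho = res[, "rho"], p = res[, "p"],
                             row.names = NULL)
    gp <- suppressWarnings(
      wilcox.test(res[, "rho"], mu = 0, alternative = "two.sided"))$p.value
    groupP[cv] <- gp
  }
  list(perMirna = do.call(rbind, rows), groupP = groupP)
}
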