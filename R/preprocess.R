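## Count filtering, log2 + quantile normalization, batch removal and
## PCA-based outlier flagging. Stage tags advance strictly forward.

#' Drop features with low total counts
#'
#' Retains features whose total count across samples is strictly greater
#' than `minTotal` (default 100 reads across the cohort).
#'
#' @param x a [MirExperiment-class] at the `counts` stage, or a count matrix.
#' @param minTotal total-count threshold (strict inequality), default 100.
#' @return object of the same kind with low-total features removed.
#' @export
filterLowExpression <- function(x, minTotal = 100) {
  stopifnot(minTotal >= 0)
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  keep <- rowSums(m) > minTotal
  if (!any(keep)) warning("no features pass the total-count filter")
  if (is(x, "MirExperiment")) x[keep, ] else m[keep, , drop = FALSE]
}

## Quantile-normalize columns of a matrix. Each column's sorted values are
## replaced by the across-column mean of order statistics; a tie group takes
## the mean of the reference values at its tied ranks.
.quantileNormalize <- function(m) {
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    assigned <- numeric(length(x))
    assigned[order(x)] <- ref
    out[, j] <- ave(assigned, match(x, x))
  }
  out
}

#' Log2-transform and quantile-normalize counts
#'
#' Adds a pseudocount, takes log2, then forces every sample onto the common
#' reference distribution of across-sample mean order statistics. Ties within
#' a sample receive the mean of the reference values at their tied ranks.
#'
#' @param x a [MirExperiment-class] of counts, or a non-negative matrix.
#' @param pseudocount added before log2, default 1.
#' @return same kind of object at stage `quantile_normalized` (log2-only with
#'   a warning when there is a single sample).
#' @export
log2QuantileNormalize <- function(x, pseudocount = 1) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (any(m < 0)) stop("counts must be non-negative")
  lg <- log2(m + pseudocount)
  if (ncol(lg) < 2L) {
    warning("single sample: log2 transform only, no quantile normalization")
    out <- lg
  } else {
    out <- .quantileNormalize(lg)
  }
  if (is(x, "MirExperiment")) .advanceStage(x, out, "quantile_normalized")
  else out
}

#' Remove additive batch effects
#'
#' Fits, per feature, a linear model with intercept, sum-coded batch
#' indicators and any protected covariates, and subtracts the fitted batch
#' terms only (via [limma::removeBatchEffect]); feature means are preserved.
#'
#' @param x a [MirExperiment-class] of normalized expression, or a matrix.
#' @param batch batch labels per sample; for a `MirExperiment` defaults to
#'   the `batch` metadata column.
#' @param preserve optional design matrix (or data.frame of covariates) whose
#'   effects must not be absorbed into the batch correction.
#' @return same kind of object at stage `batch_removed`.
#' @export
removeBatch <- function(x, batch = NULL, preserve = NULL) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (is.null(batch)) {
    if (!is(x, "MirExperiment") || is.null(sampleData(x)$batch))
      stop("batch labels are required")
    batch <- sampleData(x)$batch
  }
  batch <- factor(batch)
  if (length(batch) != ncol(m)) stop("one batch label per sample is required")
  if (nlevels(batch) < 2L) {
    warning("single batch: nothing to remove")
    out <- m
  } else {
    design <- matrix(1, ncol(m), 1L)
    if (!is.null(preserve)) {
      pv <- if (is.data.frame(preserve))
        model.matrix(~ ., preserve)[, -1L, drop = FALSE]
      else as.matrix(preserve)
      design <- cbind(design, pv)
      bm <- model.matrix(~ batch)[, -1L, drop = FALSE]
      full <- cbind(design, bm)
      if (qr(full)$rank < ncol(full))
        stop("batch is confounded with a protected covariate: ",
             paste(colnames(pv), collapse = ", "))
    }
    out <- limma::removeBatchEffect(m, batch = batch, design = design)
  }
  if (is(x, "MirExperiment")) .advanceStage(x, out, "batch_removed")
  else out
}

#' Flag outlying samples on principal components
#'
#' PCA on the feature-centered matrix; a sample is flagged when its
#' Mahalanobis-style distance over the first `nPcs` components (each scaled
#' by its score standard deviation) exceeds `sdThreshold`.
#'
#' @param x a [MirExperiment-class] or expression matrix (features x samples).
#' @param nPcs number of leading components, default 2.
#' @param sdThreshold flagging radius in score-SD units, default 2.5.
#' @return list with `flagged` (sample ids), `distance` (named per-sample
#'   radius), `scores` (sample x PC score matrix) and `report` (a
#'   preprocess-report list: sample counts and flagged coordinates).
#' @export
detectOutliersPCA <- function(x, nPcs = 2L, sdThreshold = 2.5) {
  m <- if (is(x, "MirExperiment")) exprValues(x) else x
  if (ncol(m) < 3L) stop("at least 3 samples are required")
  if (nPcs >= ncol(m)) stop("nPcs must be smaller than the number of samples")
  centered <- m - rowMeans(m)
  pc <- prcomp(t(centered), center = FALSE)
  sc <- pc$x[, seq_len(nPcs), drop = FALSE]
  sdev <- apply(sc, 2L, sd)
  sdev[sdev == 0] <- 1
  z <- sweep(sc, 2L, sdev, "/")
  d <- sqrt(rowSums(z^2))
  flagged <- colnames(m)[d > sdThreshold]
  list(flagged = flagged,
       distance = setNames(d, colnames(m)),
       scores = sc,
       report = list(n_samples_in = ncol(m),
                     n_flagged = length(flagged),
                     flagged_coordinates = sc[flagged, , drop = FALSE],
                     sd_threshold = sdThreshold,
                     n_pcs = nPcs))
}

#' Run the preprocessing pipeline
#'
#' filter -> log2 + quantile normalize -> batch removal -> outlier flagging;
#' when `dropOutliers = TRUE`, flagged samples are removed and normalization
#' plus batch removal are re-run on the remaining samples.
#'
#' @param x a [MirExperiment-class] of counts with a `batch` metadata column.
#' @param minTotal,pseudocount,nPcs,sdThreshold stage parameters, see the
#'   individual stage functions.
#' @param dropOutliers remove flagged samples and re-normalize, default FALSE
#'   (flagging is always reported; removal is explicit).
#' @return list with `expr` (a `MirExperiment` at stage `batch_removed`) and
#'   `report` (counts of features/samples in and out, dropped ids, outlier
#'   coordinates).
#' @export
preprocessPipeline <- function(x, minTotal = 100, pseudocount = 1,
                               nPcs = 2L, sdThreshold = 2.5,
                               dropOutliers = FALSE) {
  stopifnot(is(x, "MirExperiment"), exprStage(x) == "counts")
  filtered <- filterLowExpression(x, minTotal)
  norm <- removeBatch(log2QuantileNormalize(filtered, pseudocount))
  out <- detectOutliersPCA(norm, nPcs = nPcs, sdThreshold = sdThreshold)
  droppedSamples <- character()
  if (dropOutliers && length(out$flagged)) {
    droppedSamples <- out$flagged
    keep <- setdiff(colnames(filtered), droppedSamples)
    norm <- removeBatch(log2QuantileNormalize(filtered[, keep], pseudocount))
  }
  list(expr = norm,
       report = list(n_features_in = nrow(x),
                     n_features_out = nrow(norm),
                     dropped_features = setdiff(rownames(x), rownames(norm)),
                     flagged_samples = out$flagged,
                     dropped_samples = droppedSamples,
                     outlier_coordinates = out$report$flagged_coordinates))
}
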