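#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats anova aov approx ave binom.test coef complete.cases cor
#'   cor.test dist hclust cutree lm mad median model.matrix p.adjust pbinom
#'   optimize pchisq pf phyper prcomp pt qr.Q qr.resid quantile rbinom
#'   pnorm rlnorm rnbinom rnorm runif sd setNames t.test var wilcox.test
#' @importFrom utils head read.delim write.table combn
NULL

## Ordered normalization stages; transitions are only ever forward.
.STAGES <- c("counts", "raw_log2", "quantile_normalized", "batch_removed",
             "residualized", "zscored")

#' MirExperiment: miRNA counts or expression with sample metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single miRNA-by-sample matrix together with per-sample demographic
#' metadata, plus a `stage` tag recording how far along the normalization
#' pipeline the values are. Stages advance only forward through
#' `counts -> raw_log2 -> quantile_normalized -> batch_removed ->
#' residualized -> zscored`.
#'
#' @slot stage character(1), one of the stage tags above.
#' @export
setClass("MirExperiment",
         contains = "SummarizedExperiment",
         representation(stage = "character"),
         prototype(stage = "counts"))

setValidity("MirExperiment", function(object) {
  msg <- character()
  if (length(object@stage) != 1L || !object@stage %in% .STAGES)
    msg <- c(msg, sprintf("stage must be one of: %s",
                          paste(.STAGES, collapse = ", ")))
  x <- SummarizedExperiment::assay(object)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    msg <- c(msg, "feature and sample ids (dimnames) are required")
  else {
    if (anyDuplicated(rownames(x)))
      msg <- c(msg, "duplicate feature ids")
    if (anyDuplicated(colnames(x)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (!all(is.finite(x)))
    msg <- c(msg, "values must be finite")
  if (identical(object@stage, "counts")) {
    if (any(x < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(x - round(x)) > 1e-8))
      msg <- c(msg, "counts must be integral")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MirExperiment
#'
#' @param values numeric matrix, features x samples, with dimnames.
#' @param sampleData data.frame of per-sample metadata (row order matched to
#'   `colnames(values)` by sample id if rownames or a `sample_id` column are
#'   present, otherwise taken as given).
#' @param stage normalization stage tag, default `"counts"`.
#' @return A [MirExperiment-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'             dimnames = list(paste0("mir", 1:4), paste0("s", 1:5)))
#' me <- MirExperiment(m, data.frame(row.names = colnames(m),
#'                                   population = gl(1, 5)))
#' exprStage(me)
#' @export
MirExperiment <- function(values, sampleData = NULL, stage = "counts") {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(sampleData)) {
    sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    sampleData <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sampleData) &&
        !identical(rownames(sampleData), sampleData$sample_id))
      rownames(sampleData) <- sampleData$sample_id
    missing <- setdiff(colnames(values), rownames(sampleData))
    if (length(missing))
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    sampleData <- sampleData[colnames(values), , drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = setNames(list(values), if (stage == "counts") "counts" else "expr"),
    colData = S4Vectors::DataFrame(sampleData))
  new("MirExperiment", se, stage = stage)
}

#' @describeIn MirExperiment the normalization stage tag.
#' @param x a `MirExperiment`.
#' @export
exprStage <- function(x) x@stage

#' @describeIn MirExperiment the feature-by-sample matrix.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x)

#' @describeIn MirExperiment per-sample metadata as a plain data.frame.
#' @export
sampleData <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

## Replace the matrix and advance the stage (forward-only).
.advanceStage <- function(x, values, stage) {
  old <- match(x@stage, .STAGES)
  new_i <- match(stage, .STAGES)
  if (is.na(new_i)) stop("unknown stage: ", stage)
  if (new_i < old)
    stop(sprintf("stage may only advance forward (%s -> %s)", x@stage, stage))
  MirExperiment(values, sampleData(x), stage = stage)
}

setMethod("show", "MirExperiment", function(object) {
  cat(sprintf("MirExperiment: %d features x %d samples [stage: %s]\n",
              nrow(object), ncol(object), object@stage))
  cat("sample variables:",
      paste(names(SummarizedExperiment::colData(object)), collapse = ", "),
      "\n")
})

#' Validate a distance matrix
#'
#' Checks symmetry (within 1e-12 relative to the matrix scale), an exactly
#' zero diagonal, non-negativity and label completeness, and returns the
#' matrix with symmetrized rounding noise removed.
#'
#' @param d square numeric matrix with identical row and column labels.
#' @return The validated matrix (labels preserved).
#' @export
asDistanceMatrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    stop("distance matrix must carry identical row/column labels")
  tol <- 1e-12 * max(1, max(abs(d)))
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix is not symmetric")
  if (any(diag(d) != 0))
    stop("distance matrix diagonal must be exactly zero")
  if (any(d < 0))
    stop("distances must be non-negative")
  (d + t(d)) / 2
}
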