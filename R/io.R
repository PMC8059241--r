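## Readers and writers for the tabular interchange formats (TSV with header,
## "." decimal point) and Newick trees.

#' Read a miRNA count table
#'
#' First column holds feature ids, remaining columns integer counts; the
#' header row holds sample ids. Duplicated ids or negative / non-integer
#' values are rejected.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @return integer matrix, features x samples, with dimnames.
#' @export
readCountTable <- function(path, delimiter = "\t") {
  raw <- read.delim(path, sep = delimiter, header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count table needs a feature id column plus samples")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in count table")
  if (anyDuplicated(names(raw)[-1L])) stop("duplicate sample ids in header")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric")
  if (any(!is.finite(m))) stop("counts must be finite")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) stop("counts must be integers")
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a feature-by-sample table as TSV
#'
#' @param x matrix with dimnames.
#' @param path output path.
#' @param idColumn name for the leading feature-id column.
#' @export
writeCountTable <- function(x, path, idColumn = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Demographic variables analyzed by the variance models, in model entry
## order; the first eight listed types are categorical, the rest continuous.
.CATEGORICAL_VARS <- c("batch", "population", "delivery_type",
                       "sex_of_newborn", "pregnancy_infection",
                       "first_pregnancy", "drinker")
.CONTINUOUS_VARS <- c("n_pregnancies", "n_children", "maternal_bmi",
                      "maternal_weight", "maternal_height", "mother_age",
                      "birth_weight", "birth_length")

#' Read per-sample demographic metadata
#'
#' One row per sample; known categorical columns are coerced to factors with
#' levels inferred from the observed values, known continuous columns to
#' numeric; any additional columns are carried through untouched.
#'
#' @param path file path.
#' @param delimiter field separator, default tab.
#' @param idColumn name of the sample id column, default `sample_id`.
#' @return data.frame with rownames set to sample ids.
#' @export
readSampleMetadata <- function(path, delimiter = "\t",
                               idColumn = "sample_id") {
  df <- read.delim(path, sep = delimiter, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!idColumn %in% names(df))
    stop("metadata must contain a '", idColumn, "' column")
  ids <- as.character(df[[idColumn]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  rownames(df) <- ids
  for (v in intersect(.CATEGORICAL_VARS, names(df)))
    df[[v]] <- factor(df[[v]])
  for (v in intersect(.CONTINUOUS_VARS, names(df))) {
    df[[v]] <- as.numeric(df[[v]])
    if (any(!is.finite(df[[v]]) & !is.na(df[[v]])))
      stop("non-finite values in continuous variable '", v, "'")
  }
  df
}

#' Variables eligible for variance partitioning
#'
#' A categorical variable is eligible when every observed level has at least
#' `minPerLevel` observations and there are at least two levels; a continuous
#' variable when it is non-constant among non-missing values.
#'
#' @param metadata data.frame of sample metadata.
#' @param variables candidate variable names, default every known demographic
#'   variable present in `metadata`.
#' @param minPerLevel minimum observations per categorical level, default 5.
#' @return character vector of eligible variable names, in input order.
#' @export
eligibleFactors <- function(metadata,
                            variables = intersect(demographicFactorOrder(),
                                                  names(metadata)),
                            minPerLevel = 5L) {
  ok <- vapply(variables, function(v) {
    x <- metadata[[v]]
    if (is.null(x)) return(FALSE)
    x <- x[!is.na(x)]
    if (is.factor(x) || is.character(x) || is.logical(x)) {
      tab <- table(as.character(x))
      length(tab) >= 2L && all(tab >= minPerLevel)
    } else {
      length(unique(x)) >= 2L
    }
  }, logical(1L))
  variables[ok]
}

#' Align counts and metadata by sample id
#'
#' Intersects sample ids in deterministic (sorted) order; unmatched samples
#' on either side are dropped with a warning, never imputed.
#'
#' @param counts matrix with sample ids as column names.
#' @param metadata data.frame with sample ids as rownames.
#' @return a [MirExperiment-class] over the shared samples.
#' @export
alignSamples <- function(counts, metadata) {
  shared <- sort(intersect(colnames(counts), rownames(metadata)))
  if (!length(shared)) stop("no shared samples between counts and metadata")
  lost <- c(setdiff(colnames(counts), shared),
            setdiff(rownames(metadata), shared))
  if (length(lost))
    warning("dropping unmatched samples: ", paste(sort(lost), collapse = ", "))
  MirExperiment(counts[, shared, drop = FALSE],
                metadata[shared, , drop = FALSE])
}

#' Write a result table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
writeResultTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a generic TSV result table
#' @param path file path.
#' @export
readResultTable <- function(path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path output path.
#' @export
writeNewickTree <- function(tree, path) {
  if (!inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0L)
    stop("not a valid tree")
  if (is.null(tree$edge.length))
    stop("tree must carry branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path file path.
#' @return an [ape::phylo] tree.
#' @export
readNewickTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}
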