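## Tissue specificity (tau), evolutionary-age assignment from a homology
## table, rank tests and category enrichment.

#' Tau tissue-specificity index
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over `n` tissues: 0 for a
#' uniformly expressed (house-keeping) feature, 1 for a single-tissue
#' feature. Requires non-negative input with a positive maximum.
#'
#' @param x non-negative expression vector over tissues.
#' @return tau in \[0, 1\].
#' @export
tauIndex <- function(x) {
  if (any(x < 0)) stop("tau requires non-negative input")
  mx <- max(x)
  if (mx == 0) stop("tau undefined for an all-zero profile")
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Tau for every row of a tissue panel
#'
#' Values below zero (possible after log2 normalization) are floored at 0
#' before computing tau; all-zero rows yield NA with a warning.
#'
#' @param panel features x tissues matrix.
#' @return named numeric vector of tau values.
#' @export
tauPanel <- function(panel) {
  m <- pmax(panel, 0)
  allZero <- rowSums(m) == 0
  if (any(allZero)) warning(sum(allZero), " all-zero feature(s): tau is NA")
  out <- rep(NA_real_, nrow(m))
  out[!allZero] <- apply(m[!allZero, , drop = FALSE], 1L, tauIndex)
  setNames(out, rownames(m))
}

#' Build a tissue expression panel from replicate datasets
#'
#' Quantile-normalizes the log2-scale dataset columns jointly, floors
#' residual negatives at zero, and aggregates replicate datasets per tissue
#' (mean by default). Tissues with no dataset are dropped with a warning.
#'
#' @param datasets features x datasets matrix of log2-scale expression.
#' @param tissues tissue label per dataset column.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return features x tissues matrix.
#' @export
buildTissuePanel <- function(datasets, tissues,
                             aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(tissues) != ncol(datasets))
    stop("one tissue label per dataset column is required")
  tissues <- as.character(tissues)
  qn <- pmax(.quantileNormalize(datasets), 0)
  present <- unique(tissues)
  fn <- if (aggregate == "mean") rowMeans else
    function(m) apply(m, 1L, median)
  out <- vapply(present, function(ti)
    fn(qn[, tissues == ti, drop = FALSE]), numeric(nrow(datasets)))
  if (nrow(datasets) == 1L)
    out <- matrix(out, nrow = 1L, dimnames = list(rownames(datasets), present))
  out
}

#' Assign evolutionary age groups from reciprocal-homology presence
#'
#' Each feature's age is the age group of the oldest species group in which
#' it has a reciprocal homolog: the minimum group index (0 = oldest, the
#' maximum index = species-of-interest-specific) among species with
#' presence.
#'
#' @param presence features x species logical matrix (TRUE = reciprocal
#'   one-to-one homolog found).
#' @param speciesAges named integer vector species -> age group.
#' @param referenceSpecies the species whose column must always be TRUE,
#'   default `"Homo_sapiens"`.
#' @return named integer vector feature -> age group.
#' @export
assignAge <- function(presence, speciesAges,
                      referenceSpecies = "Homo_sapiens") {
  presence <- as.matrix(presence)
  missing <- setdiff(colnames(presence), names(speciesAges))
  if (length(missing))
    stop("species without an age group: ", paste(missing, collapse = ", "))
  if (!referenceSpecies %in% colnames(presence))
    stop("reference species column missing: ", referenceSpecies)
  absent <- !presence[, referenceSpecies]
  if (any(absent))
    stop("features absent in the reference species: ",
         paste(rownames(presence)[absent], collapse = ", "))
  ages <- speciesAges[colnames(presence)]
  out <- apply(presence, 1L, function(hit) min(ages[hit]))
  setNames(as.integer(out), rownames(presence))
}

#' Two-group rank-sum comparison
#'
#' Wilcoxon/Mann-Whitney rank-sum test with tie correction; exact p-values
#' for small tie-free samples (both groups n <= 12), normal approximation
#' otherwise. When every value is tied across both groups, returns p = 1
#' with a warning.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `U` (rank-sum statistic for `a`) and `p`.
#' @export
compareGroupsRank <- function(a, b,
                              alternative = c("two.sided", "less",
                                              "greater")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both groups")
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  hasTies <- anyDuplicated(c(a, b)) > 0L
  exact <- !hasTies && length(a) <= 12L && length(b) <= 12L
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Hypergeometric category enrichment
#'
#' Per category, the upper-tail hypergeometric probability of an overlap
#' with the query at least as large as observed, corrected across
#' categories (Bonferroni or Benjamini-Hochberg).
#'
#' @param query feature ids of interest (subset of `background`).
#' @param categories named list: category label -> feature ids (subsets of
#'   `background`).
#' @param background universe of feature ids.
#' @param correction `"bonferroni"` (default) or `"bh"`.
#' @return data.frame (category, overlap, category_size, query_size,
#'   background_size, p, p_adj), sorted by p.
#' @export
hypergeometricEnrichment <- function(query, categories, background,
                                     correction = c("bonferroni", "bh")) {
  correction <- match.arg(correction)
  background <- unique(background)
  if (!length(background)) stop("empty background")
  if (!all(query %in% background))
    stop("query features outside the background")
  query <- unique(query)
  rows <- lapply(names(categories), function(lab) {
    cat <- unique(categories[[lab]])
    if (!all(cat %in% background))
      stop("category '", lab, "' has features outside the background")
    q <- length(intersect(query, cat))
    data.frame(category = lab, overlap = q, category_size = length(cat),
               query_size = length(query),
               background_size = length(background),
               p = phyper(q - 1L, length(cat),
                          length(background) - length(cat),
                          length(query), lower.tail = FALSE))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bonferroni")
    pmin(1, length(categories) * out$p) else bhAdjust(out$p)
  out[order(out$p), , drop = FALSE]
}
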