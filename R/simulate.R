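## Seeded generator for study-shaped data bundles: negative-binomial miRNA
## counts over 4 populations x 2 newborn sexes x 3 sequencing batches, with
## planted population, sex, batch and imprinting effects; coupled mRNA
## targets; a designed tissue panel; a homology table; and an Fst matrix
## whose genetic tree has the African-ancestry population most distant and
## the two Asian populations as sisters.

#' Simulation configuration
#'
#' Bundles every tunable of [simulateDataset()] with validated defaults.
#' Effects are additive on the log2 scale before exponentiation into
#' negative-binomial means. Population effects are drawn per feature as
#' fixed-magnitude, random-sign contributions along the five branches of the
#' population tree (pendants A, E, S, X plus the shared S-X branch), scaled
#' by `divergenceScale` times `popEffect`, so that A is most divergent and
#' S/X are sisters. Maternal weight is derived as height^2 x BMI / 10^4 with
#' lognormal height, and the imprinted block declines with the BMI-driven
#' component of weight, so weight and BMI associate with the block while
#' height stays independent by construction.
#'
#' @param nMirna number of miRNAs.
#' @param samplesPerPopPerSex samples per population per newborn sex
#'   (default 5: 10 per population, 40 in total).
#' @param nBatches sequencing batches (additive log2 shifts).
#' @param batchShift spacing of the per-batch additive shifts, log2 units.
#' @param popAffectedFrac fraction of miRNAs carrying population effects.
#' @param popEffect population branch effect magnitude, log2 units.
#' @param divergenceScale named branch scales `A`, `E`, `SX`, `S`, `X`.
#' @param sexAffectedFrac fraction of miRNAs carrying newborn-sex effects.
#' @param sexEffect female-vs-male log2 fold change magnitude.
#' @param imprintedSize size of the imprinted (C19MC-like) block.
#' @param imprintedSlope log2 expression change per kg of the BMI-driven
#'   weight component (negative = decline).
#' @param dispersion negative-binomial dispersion (1/size).
#' @param librarySdLog log-normal spread of library size factors.
#' @param baselineMean,baselineSd per-miRNA baseline log2 mean distribution.
#' @param biolNoiseSd per-sample biological log2 noise SD.
#' @param nMrna number of mRNAs in the coupled expression matrix.
#' @param nTargetMirna cluster miRNAs with planted target repression.
#' @param targetsPerMirna true targets per cluster miRNA.
#' @param couplingStrength repression coupling (log2 mRNA per log2 miRNA).
#' @param mrnaNoiseSd mRNA residual log2 noise SD.
#' @param nTissues tissues in the designed specificity panel.
#' @param nTissueDatasets replicate datasets spread over the tissues.
#' @param replicateControl re-sequence one sample in every batch (technical
#'   replicate control), default FALSE.
#' @return object of class `SimulationConfig`.
#' @export
simulationConfig <- function(nMirna = 1000L,
                             samplesPerPopPerSex = 5L,
                             nBatches = 3L,
                             batchShift = 0.3,
                             popAffectedFrac = 0.139,
                             popEffect = 0.5,
                             divergenceScale = c(A = 1.5, E = 0.8,
                                                 SX = 0.8, S = 0.5, X = 0.5),
                             sexAffectedFrac = 0.032,
                             sexEffect = 0.9,
                             imprintedSize = 66L,
                             imprintedSlope = -0.025,
                             dispersion = 0.02,
                             librarySdLog = 0.2,
                             baselineMean = 6.5,
                             baselineSd = 1.5,
                             biolNoiseSd = 0.4,
                             nMrna = 1200L,
                             nTargetMirna = 10L,
                             targetsPerMirna = 5L,
                             couplingStrength = 1.5,
                             mrnaNoiseSd = 0.35,
                             nTissues = 12L,
                             nTissueDatasets = 36L,
                             replicateControl = FALSE) {
  cfg <- list(nMirna = as.integer(nMirna),
              samplesPerPopPerSex = as.integer(samplesPerPopPerSex),
              nBatches = as.integer(nBatches),
              batchShift = batchShift,
              popAffectedFrac = popAffectedFrac,
              popEffect = popEffect,
              divergenceScale = divergenceScale,
              sexAffectedFrac = sexAffectedFrac,
              sexEffect = sexEffect,
              imprintedSize = as.integer(imprintedSize),
              imprintedSlope = imprintedSlope,
              dispersion = dispersion,
              librarySdLog = librarySdLog,
              baselineMean = baselineMean,
              baselineSd = baselineSd,
              biolNoiseSd = biolNoiseSd,
              nMrna = as.integer(nMrna),
              nTargetMirna = as.integer(nTargetMirna),
              targetsPerMirna = as.integer(targetsPerMirna),
              couplingStrength = couplingStrength,
              mrnaNoiseSd = mrnaNoiseSd,
              nTissues = as.integer(nTissues),
              nTissueDatasets = as.integer(nTissueDatasets),
              replicateControl = isTRUE(replicateControl))
  fr <- c(cfg$popAffectedFrac, cfg$sexAffectedFrac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (!all(is.finite(c(cfg$popEffect, cfg$sexEffect, cfg$imprintedSlope))))
    stop("effect sizes must be finite")
  if (!all(c("A", "E", "SX", "S", "X") %in% names(cfg$divergenceScale)))
    stop("divergenceScale needs entries A, E, SX, S, X")
  ## effective planted-set sizes: a zero effect plants nothing
  nPop <- if (cfg$popEffect > 0) round(cfg$popAffectedFrac * cfg$nMirna)
          else 0L
  nSex <- if (cfg$sexEffect > 0) round(cfg$sexAffectedFrac * cfg$nMirna)
          else 0L
  nImp <- if (cfg$imprintedSlope != 0) cfg$imprintedSize else 0L
  if (nPop + nSex + nImp > cfg$nMirna)
    stop("affected sets (population + sex + imprinted) exceed nMirna")
  if (cfg$couplingStrength > 0 && cfg$popEffect > 0 &&
      cfg$nTargetMirna > nPop)
    stop("nTargetMirna exceeds the population-affected set")
  if (cfg$dispersion <= 0 || cfg$librarySdLog < 0)
    stop("dispersion must be positive and librarySdLog non-negative")
  structure(cfg, class = "SimulationConfig")
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig:", x$nMirna, "miRNAs,",
      4L * 2L * x$samplesPerPopPerSex, "samples,",
      x$nBatches, "batches\n")
  invisible(x)
}

#' Species and age groups for evolutionary dating
#'
#' A 23-species panel spanning age groups 0 (oldest, teleost fish) through
#' 12 (human-specific), used by the simulated homology table and by
#' [assignAge()].
#'
#' @return named integer vector species -> age group.
#' @export
mirSpeciesAges <- function() {
  c(Danio_rerio = 0L, Xenopus_tropicalis = 1L, Gallus_gallus = 2L,
    Ornithorhynchus_anatinus = 3L, Monodelphis_domestica = 4L,
    Bos_taurus = 5L, Sus_scrofa = 5L, Canis_familiaris = 5L,
    Equus_caballus = 5L,
    Mus_musculus = 6L, Rattus_norvegicus = 6L, Oryctolagus_cuniculus = 6L,
    Callithrix_jacchus = 7L, Saimiri_boliviensis = 7L,
    Macaca_mulatta = 8L, Macaca_nemestrina = 8L, Papio_hamadryas = 8L,
    Nomascus_leucogenys = 9L, Pongo_pygmaeus = 9L,
    Gorilla_gorilla = 10L,
    Pan_troglodytes = 11L, Pan_paniscus = 11L,
    Homo_sapiens = 12L)
}

## Shuffle a vector of fixed level counts: guarantees per-level minimums.
.shuffleCounts <- function(levels, counts, n) {
  sample(rep_len(rep(levels, counts), n))
}

#' Simulate a complete study-shaped data bundle
#'
#' Generates miRNA counts with planted population / sex / batch / imprinting
#' structure, matching sample metadata, a coupled mRNA matrix with a target
#' prediction table, a designed tissue panel, a homology table and an Fst
#' matrix, together with the truth labels of every planted effect. The same
#' `seed` reproduces the bundle exactly.
#'
#' @param config a [simulationConfig()] object.
#' @param seed integer seed.
#' @return list with elements `mir` ([MirExperiment-class] of counts plus
#'   metadata), `mrna` (matrix), `predictions` (data.frame), `tissueDatasets`
#'   (matrix) and `tissueLabels`, `homology` (list: presence, speciesAges),
#'   `fst` (matrix) and `fstGrouping`, `annotation` (data.frame) and `truth`
#'   (list of planted-effect labels).
#' @export
simulateDataset <- function(config = simulationConfig(), seed = 1L) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(as.integer(seed))
  cfg <- config
  pops <- c("A", "E", "S", "X")

  ## ---- samples and demographics -------------------------------------
  perPop <- 2L * cfg$samplesPerPopPerSex
  n <- 4L * perPop
  population <- factor(rep(pops, each = perPop), levels = pops)
  sex <- factor(rep(rep(c("F", "M"), each = cfg$samplesPerPopPerSex), 4L),
                levels = c("F", "M"))
  sampleId <- sprintf("%s%02d", population, sequence(rep(perPop, 4L)))
  batch <- factor(.shuffleCounts(seq_len(cfg$nBatches),
                                 rep(ceiling(n / cfg$nBatches), cfg$nBatches),
                                 n))
  height <- rlnorm(n, log(162), 0.04)                    # cm
  bmi <- pmax(rnorm(n, 26.5, 4.5), 16)                   # kg/m^2
  weight <- height^2 * bmi / 1e4                         # kg
  nPreg <- .shuffleCounts(1:4, ceiling(n * c(0.35, 0.3, 0.2, 0.15)), n)
  meta <- data.frame(
    sample_id = sampleId,
    population = population,
    sex_of_newborn = sex,
    batch = batch,
    delivery_type = factor(.shuffleCounts(c("natural", "cesarean"),
                                          c(ceiling(0.6 * n), n), n)),
    pregnancy_infection = factor(.shuffleCounts(c("no", "yes"),
                                                c(ceiling(0.75 * n), n), n)),
    drinker = factor(.shuffleCounts(c("no", "yes"),
                                    c(ceiling(0.7 * n), n), n)),
    n_pregnancies = nPreg,
    first_pregnancy = factor(ifelse(nPreg == 1L, "yes", "no")),
    n_children = pmax(nPreg - rbinom(n, 1L, 0.4), 1L),
    maternal_bmi = bmi,
    maternal_weight = weight,
    maternal_height = height,
    mother_age = pmin(pmax(rnorm(n, 30, 5), 18), 45),
    birth_weight = rnorm(n, 3400, 450),
    stringsAsFactors = FALSE)
  meta$birth_length <- 38 + 0.0035 * meta$birth_weight + rnorm(n, 0, 1.5)
  rownames(meta) <- sampleId

  ## ---- feature sets --------------------------------------------------
  mirIds <- sprintf("mir%04d", seq_len(cfg$nMirna))
  nPopAff <- if (cfg$popEffect > 0) round(cfg$popAffectedFrac * cfg$nMirna)
             else 0L
  nSexAff <- if (cfg$sexEffect > 0) round(cfg$sexAffectedFrac * cfg$nMirna)
             else 0L
  nImp <- if (cfg$imprintedSlope != 0) cfg$imprintedSize else 0L
  pool <- sample(mirIds)
  popAffected <- pool[seq_len(nPopAff)]
  sexAffected <- pool[nPopAff + seq_len(nSexAff)]
  imprinted <- pool[nPopAff + nSexAff + seq_len(nImp)]

  ## ---- planted effects ----------------------------------------------
  ds <- cfg$divergenceScale * cfg$popEffect
  popEffects <- matrix(0, cfg$nMirna, 4L, dimnames = list(mirIds, pops))
  if (nPopAff > 0) {
    sgn <- function(k) sample(c(-1, 1), k, replace = TRUE)
    zA <- sgn(nPopAff); zE <- sgn(nPopAff); zSX <- sgn(nPopAff)
    zS <- sgn(nPopAff); zX <- sgn(nPopAff)
    popEffects[popAffected, "A"] <- ds[["A"]] * zA
    popEffects[popAffected, "E"] <- ds[["E"]] * zE
    popEffects[popAffected, "S"] <- ds[["SX"]] * zSX + ds[["S"]] * zS
    popEffects[popAffected, "X"] <- ds[["SX"]] * zSX + ds[["X"]] * zX
  }
  sexFc <- setNames(rep(0, cfg$nMirna), mirIds)       # F - M orientation
  if (nSexAff > 0)
    sexFc[sexAffected] <- sample(c(-1, 1), nSexAff, TRUE) * cfg$sexEffect
  ## BMI-driven weight component (mean-height basis), orthogonalized
  ## against height within the sample so that the imprinted block is
  ## independent of height by construction, not just in expectation.
  ## The downstream association statistic is Spearman, so the residual
  ## rank correlation with height is nulled as well (level orthogonality
  ## alone leaves a rank correlation of a few percent, which a block of
  ## correlated miRNAs turns into a spurious group signal).
  bmiWeight <- mean(height)^2 * bmi / 1e4
  ## orthogonalize against batch too: batch-mean removal downstream would
  ## otherwise re-inject a height-correlated component via the driver's
  ## batch-mean projections
  impDriver <- qr.resid(qr(cbind(1, height,
                                 model.matrix(~ batch)[, -1L])), bmiWeight)
  ## null the rank-space association as well: the block statistic downstream
  ## is Spearman, and per-miRNA noise smooths the realized ranks, so the
  ## objective combines the plain rank correlation with a noise-smoothed
  ## one (expected rank of driver + noise). The rank correlation is a step
  ## function of the coefficient, so a fine grid beats smooth optimization.
  if (nImp > 0 && cfg$imprintedSlope != 0) {
    sigmaDrv <- (cfg$biolNoiseSd + sqrt(cfg$dispersion) / log(2)) /
      abs(cfg$imprintedSlope)
    smoothRank <- function(x) {
      vapply(x, function(xi)
        sum(pnorm((xi - x) / (sqrt(2) * sigmaDrv))), numeric(1L))
    }
    hRank <- rank(height)
    span <- 2 * sd(impDriver) / sd(height)
    grid <- seq(-span, span, length.out = 1001L)
    obj <- vapply(grid, function(cc) {
      z <- impDriver - cc * height
      abs(cor(rank(z), hRank)) + abs(cor(smoothRank(z), hRank))
    }, numeric(1L))
    impDriver <- impDriver - grid[which.min(obj)] * height
  }
  impDriver <- impDriver - mean(impDriver)
  impTerm <- matrix(0, cfg$nMirna, n, dimnames = list(mirIds, sampleId))
  if (nImp > 0)
    impTerm[imprinted, ] <- matrix(cfg$imprintedSlope * impDriver,
                                   nImp, n, byrow = TRUE)

  ## ---- latent log2 signal and counts ---------------------------------
  baseline <- pmax(rnorm(cfg$nMirna, cfg$baselineMean, cfg$baselineSd), 2)
  batchShifts <- cfg$batchShift *
    (seq_len(cfg$nBatches) - (cfg$nBatches + 1) / 2)
  sexSigned <- ifelse(sex == "F", 0.5, -0.5)
  latent <- baseline +
    popEffects[, as.character(population)] +
    outer(sexFc, sexSigned) +
    impTerm +
    matrix(batchShifts[batch], cfg$nMirna, n, byrow = TRUE) +
    matrix(rnorm(cfg$nMirna * n, 0, cfg$biolNoiseSd), cfg$nMirna, n)
  dimnames(latent) <- list(mirIds, sampleId)
  libFactor <- rlnorm(n, 0, cfg$librarySdLog)
  libFactor <- libFactor / exp(mean(log(libFactor)))
  mu <- 2^latent * matrix(libFactor, cfg$nMirna, n, byrow = TRUE)
  counts <- matrix(rnbinom(cfg$nMirna * n, mu = mu, size = 1 / cfg$dispersion),
                   cfg$nMirna, n, dimnames = list(mirIds, sampleId))
  storage.mode(counts) <- "integer"
  if (cfg$replicateControl) {
    ctrl <- sampleId[n]
    for (b in seq_len(cfg$nBatches)) {
      rid <- sprintf("%s_L%d", ctrl, b)
      muR <- 2^(latent[, ctrl] - batchShifts[batch[n]] + batchShifts[b]) *
        libFactor[n]
      counts <- cbind(counts, rnbinom(cfg$nMirna, mu = muR,
                                      size = 1 / cfg$dispersion))
      colnames(counts)[ncol(counts)] <- rid
      extra <- meta[ctrl, ]
      extra$sample_id <- rid
      extra$batch <- factor(b, levels = levels(batch))
      rownames(extra) <- rid
      meta <- rbind(meta, extra)
    }
  }

  ## ---- coupled mRNA matrix and target predictions ---------------------
  geneIds <- sprintf("gene%04d", seq_len(cfg$nMrna))
  mrna <- matrix(rnorm(cfg$nMrna * n, rep(rnorm(cfg$nMrna, 8, 1.5), n),
                       cfg$mrnaNoiseSd),
                 cfg$nMrna, n, dimnames = list(geneIds, sampleId))
  targetPairs <- data.frame(mirna_id = character(0), mrna_id = character(0))
  predictions <- data.frame(mirna_id = character(0), mrna_id = character(0),
                            n_supporting_methods = integer(0))
  if (cfg$couplingStrength > 0 && nPopAff >= cfg$nTargetMirna &&
      cfg$nTargetMirna > 0) {
    ## plant the repression cluster on well-expressed miRNAs: at low read
    ## depth sampling noise dominates and masks any real coupling
    expressed <- popAffected[baseline[match(popAffected, mirIds)] >= 6]
    if (length(expressed) < cfg$nTargetMirna) expressed <- popAffected
    clusterMirs <- sample(expressed, cfg$nTargetMirna)
    nTrue <- cfg$nTargetMirna * cfg$targetsPerMirna
    trueGenes <- sample(geneIds, nTrue)
    targetPairs <- data.frame(
      mirna_id = rep(clusterMirs, each = cfg$targetsPerMirna),
      mrna_id = trueGenes, stringsAsFactors = FALSE)
    dev <- latent[targetPairs$mirna_id, , drop = FALSE]
    dev <- dev - rowMeans(dev)
    mrna[targetPairs$mrna_id, ] <- mrna[targetPairs$mrna_id, ] -
      cfg$couplingStrength * dev
    decoyGenes <- sample(setdiff(geneIds, trueGenes),
                         3L * cfg$nTargetMirna + 10L)
    predictions <- rbind(
      data.frame(mirna_id = targetPairs$mirna_id,
                 mrna_id = targetPairs$mrna_id,
                 n_supporting_methods = sample(3:5, nTrue, TRUE)),
      data.frame(mirna_id = sample(clusterMirs, 3L * cfg$nTargetMirna, TRUE),
                 mrna_id = decoyGenes[seq_len(3L * cfg$nTargetMirna)],
                 n_supporting_methods = sample(1:2, 3L * cfg$nTargetMirna,
                                               TRUE)),
      data.frame(mirna_id = sample(clusterMirs, 10L, TRUE),
                 mrna_id = decoyGenes[3L * cfg$nTargetMirna + 1:10],
                 n_supporting_methods = 3L))
    predictions <- predictions[!duplicated(predictions[, 1:2]), ]
    targetPairs$cluster <- "T1"
  }

  ## ---- designed tissue panel ------------------------------------------
  designedTau <- runif(cfg$nMirna, 0.2, 0.95)
  designedTau[seq_len(min(5L, cfg$nMirna))] <- 1       # single-tissue features
  maxTissue <- sample.int(cfg$nTissues, cfg$nMirna, replace = TRUE)
  kOther <- rbinom(cfg$nMirna, cfg$nTissues - 1L, 0.5)
  kOther[designedTau == 1] <- 0L
  tissueProfile <- matrix(0, cfg$nMirna, cfg$nTissues,
                          dimnames = list(mirIds,
                                          sprintf("tissue%02d",
                                                  seq_len(cfg$nTissues))))
  topExpr <- 8
  for (i in seq_len(cfg$nMirna)) {
    tissueProfile[i, maxTissue[i]] <- topExpr
    if (kOther[i] > 0L) {
      others <- sample(setdiff(seq_len(cfg$nTissues), maxTissue[i]),
                       kOther[i])
      ## value solving the designed tau given kOther expressed tissues
      nm1 <- cfg$nTissues - 1L
      v <- topExpr * (1 - (designedTau[i] * nm1 - (nm1 - kOther[i])) /
                        kOther[i])
      tissueProfile[i, others] <- max(min(v, topExpr), 0)
    }
  }
  tissueLabels <- sprintf("tissue%02d",
                          rep_len(seq_len(cfg$nTissues), cfg$nTissueDatasets))
  tissueDatasets <- vapply(seq_len(cfg$nTissueDatasets), function(d) {
    x <- tissueProfile[, match(tissueLabels[d], colnames(tissueProfile))]
    pos <- x > 0
    x[pos] <- pmax(x[pos] + rnorm(sum(pos), 0, 0.2), 0.05)
    x
  }, numeric(cfg$nMirna))
  colnames(tissueDatasets) <- sprintf("dataset%02d",
                                      seq_len(cfg$nTissueDatasets))

  ## ---- homology table -------------------------------------------------
  speciesAges <- mirSpeciesAges()
  ageProbs <- c(rep(2, 6), rep(1.2, 4), rep(0.6, 3))   # older ages commoner
  trueAge <- sample(0:12, cfg$nMirna, TRUE, prob = ageProbs)
  presence <- outer(trueAge, speciesAges, "<=")
  dimnames(presence) <- list(mirIds, names(speciesAges))

  ## ---- Fst over source populations ------------------------------------
  pend <- c(A = 0.09, E = 0.02, S = 0.012, X = 0.012); internal <- 0.02
  d4 <- matrix(0, 4, 4, dimnames = list(pops, pops))
  for (i in 1:4) for (j in 1:4) if (i < j) {
    cross <- (pops[i] %in% c("A", "E")) != (pops[j] %in% c("A", "E"))
    d4[i, j] <- d4[j, i] <- pend[[pops[i]]] + pend[[pops[j]]] +
      if (cross) internal else 0
  }
  srcX <- c("Han_Chinese", "Southern_Han_Chinese", "Kinh_Vietnamese")
  src <- c("African_American", "CEPH", "Telugu", srcX)
  fst <- matrix(0, 6, 6, dimnames = list(src, src))
  base <- c(African_American = "A", CEPH = "E", Telugu = "S",
            Han_Chinese = "X", Southern_Han_Chinese = "X",
            Kinh_Vietnamese = "X")
  for (i in 1:6) for (j in 1:6) if (i < j) {
    bi <- base[[src[i]]]; bj <- base[[src[j]]]
    fst[i, j] <- fst[j, i] <- if (bi == bj) 0.008 else
      d4[bi, bj] + 0.004 * ((bi == "X") + (bj == "X"))
  }
  fstGrouping <- list(A = "African_American", E = "CEPH", S = "Telugu",
                      X = srcX)

  ## ---- annotation ------------------------------------------------------
  chrom <- paste0("chr", sample(c(1:22, "X"), cfg$nMirna, TRUE))
  clusterLab <- rep("", cfg$nMirna); names(clusterLab) <- mirIds
  clusterLab[imprinted] <- "C19MC"
  chrom[match(imprinted, mirIds)] <- "chr19"
  c14 <- character(0)
  if (nSexAff >= 2L) {
    c14 <- c(sample(sexAffected, min(18L, nSexAff)),
             sample(pool[-seq_len(nPopAff + nSexAff + nImp)], 22L))
    clusterLab[c14] <- "C14MC"
    chrom[match(c14, mirIds)] <- "chr14"
  }
  annotation <- data.frame(feature_id = mirIds, chromosome = chrom,
                           named_cluster = unname(clusterLab),
                           is_novel = runif(cfg$nMirna) < 0.07,
                           stringsAsFactors = FALSE)

  list(mir = MirExperiment(counts, meta),
       mrna = mrna,
       predictions = predictions,
       tissueDatasets = tissueDatasets,
       tissueLabels = tissueLabels,
       homology = list(presence = presence, speciesAges = speciesAges),
       fst = fst,
       fstGrouping = fstGrouping,
       annotation = annotation,
       truth = list(popAffected = popAffected,
                    popEffects = popEffects,
                    sexAffected = sexAffected,
                    sexFc = sexFc,
                    imprinted = imprinted,
                    targetPairs = targetPairs,
                    designedTau = setNames(designedTau, mirIds),
                    trueAge = setNames(trueAge, mirIds),
                    config = cfg, seed = as.integer(seed)))
}

#' Write a simulated bundle as TSV files
#'
#' Emits the counts, metadata, mRNA matrix, predictions, tissue datasets,
#' homology presence table, Fst matrix, annotation and truth labels as
#' plain TSV files into a directory.
#'
#' @param bundle result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeDatasetBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeCountTable(exprValues(bundle$mir), fp("mirna_counts.tsv"))
  writeResultTable(sampleData(bundle$mir), fp("sample_metadata.tsv"))
  writeCountTable(round(bundle$mrna, 6), fp("mrna_expression.tsv"),
                  idColumn = "gene_id")
  writeResultTable(bundle$predictions, fp("target_predictions.tsv"))
  writeCountTable(round(bundle$tissueDatasets, 6), fp("tissue_datasets.tsv"))
  writeCountTable(1L * bundle$homology$presence, fp("homology_presence.tsv"))
  writeCountTable(bundle$fst, fp("fst.tsv"), idColumn = "population")
  writeResultTable(bundle$annotation, fp("annotation.tsv"))
  truthDf <- data.frame(
    feature_id = names(bundle$truth$sexFc),
    pop_affected = names(bundle$truth$sexFc) %in% bundle$truth$popAffected,
    sex_affected = names(bundle$truth$sexFc) %in% bundle$truth$sexAffected,
    imprinted = names(bundle$truth$sexFc) %in% bundle$truth$imprinted,
    sex_fc = unname(bundle$truth$sexFc))
  writeResultTable(truthDf, fp("truth_labels.tsv"))
  invisible(dir)
}
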