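# placentaMiR

Demographic drivers of miRNA expression variation in the human placenta.

Bulk small-RNA sequencing of placental tissue from donors of several
ancestries makes it possible to ask which demographic characteristics of
mother and newborn — population identity, newborn sex, delivery type,
maternal BMI, parity, and so on — actually move miRNA expression, and by how
much. `placentaMiR` implements that analysis end to end for a study design
of four populations (A: African, E: European, S: South Asian, X: East Asian
ancestry), two newborn sexes and multiplexed sequencing batches, together
with a seeded simulator that generates complete study-shaped datasets with
known truth labels, so every stage of the pipeline is testable without any
data download.

## The statistics at the core

* **Normalization.** Counts with a cohort-wide total ≤ 100 reads are
  dropped; the rest are log2(x+1)-transformed and quantile-normalized
  (ties receive the mean of the reference order statistics at their tied
  ranks); additive batch effects are removed by a per-feature linear model
  (limma's `removeBatchEffect`); outlying samples are flagged by their
  radius on the leading principal components.
* **Variance partitioning (Model 1).** For each miRNA *g*, a sequential
  (Type-I) ANOVA over the twelve demographic variables in a fixed entry
  order attributes to each variable *v* the fraction
  η²(v) = SS(v) / SS(total); per feature the η² values plus the residual
  fraction sum to 1. The mean η² per variable across features summarizes
  how much of total expression variance each variable explains.
* **Differential expression (Model 2).** Expression is first residualized
  on four continuous covariates (maternal BMI, birth weight, mother's age,
  birth length); DE is then the sequential ANOVA F-test for population
  (nominal p < 0.05) or newborn sex (p < 0.01) after delivery type and sex,
  with Benjamini–Hochberg adjustment across features. The *count* of
  significant miRNAs is calibrated against 1000 whole-row label
  permutations: the permutation p is the fraction of permutations whose
  count reaches the observed one.
* **Population structure.** Per-feature expression scaled by its mean,
  averaged into population profiles; the mean absolute difference across
  features gives a population distance matrix; neighbor joining (`ape::nj`)
  yields an unrooted dendrogram that is compared against the Fst-based
  genetic tree (with multi-source populations collapsed by arithmetic mean)
  via a two-sided Mantel test with full enumeration for ≤ 6 labels.
* **Annotation metrics.** The tau tissue-specificity index
  τ = Σᵢ(1 − xᵢ/x_max)/(n−1); table-driven evolutionary age groups
  (0 = oldest … 12 = human-specific, the minimum group index among species
  with a reciprocal homolog); hypergeometric category enrichment and exact
  binomial cross-population consistency tests.
* **Targets and imprinting.** Predicted miRNA→mRNA pairs supported by ≥ 3
  of 5 methods; per-pair Spearman ρ with repression flagged at ρ < −0.5 and
  a one-sided rank test of target vs non-target correlations; and, for the
  imprinted C19MC block, per-miRNA Spearman correlations with maternal BMI,
  weight and height plus a group-level signed-rank test.

## Worked example

```r
library(placentaMiR)

bundle <- simulateDataset(simulationConfig(), seed = 7)
bundle$mir
#> MirExperiment: 1000 features x 40 samples [stage: counts]

pre <- preprocessPipeline(bundle$mir)            # filter, normalize, de-batch
vp  <- sequentialAnovaEtaSquared(pre$expr)       # Model 1
round(100 * attr(vp, "meanEtaSq")[c("population", "sex_of_newborn")], 1)
#>     population sex_of_newborn
#>           11.3            3.5

res <- residualizeContinuous(pre$expr)           # Model 2
de  <- deAnova(res, testFactor = "population")
sum(de$significant)
#> [1] 153

tree <- populationMeanTree(pre$expr,
                           features = rownames(de)[de$significant])
ape::write.tree(tree)
#> (X:0.0226,S:0.0289,(A:0.0770,E:0.0342):0.0114);

imp <- imprintingAnalysis(pre$expr, bundle$annotation)
signif(imp$groupP, 2)
#>    maternal_bmi maternal_weight maternal_height
#>         1.7e-12         1.7e-12         9.5e-01
```

Population explains ~11% of total variance and newborn sex ~4%; 153 of
1000 miRNAs are called population-DE at the nominal threshold (139 carry
planted effects); the expression dendrogram places the African-ancestry
population on the longest branch with the two Asian populations as
sisters, matching the genetic tree; and the imprinted C19MC block tracks
maternal BMI and weight but not height.

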