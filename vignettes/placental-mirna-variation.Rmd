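---
title: "Methods: demographic drivers of placental miRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demographic drivers of placental miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `placentaMiR`, the
design decisions taken where the methodology was genuinely open, and what
the synthetic-data generator does and does not emulate.

# Study design and data model

The package targets a bulk small-RNA study of placental tissue: roughly a
thousand miRNAs quantified by read counts in ~40 samples spanning four
populations (labelled A, E, S, X), two newborn sexes, and three sequencing
batches, with twelve demographic variables per sample. The central
container is `MirExperiment`, a `SummarizedExperiment` carrying one
feature-by-sample matrix plus the demographic metadata, with a `stage` tag
that moves only forward through

`counts -> raw_log2 -> quantile_normalized -> batch_removed -> residualized -> zscored`.

A variable is *eligible* for the variance models when every observed level
has at least five observations (`eligibleFactors()`), the rule that selects
the twelve analyzed variables out of a larger metadata sheet.

# Preprocessing

1. **Filtering.** Features with a cohort-wide total of at most 100 reads
   are removed (`filterLowExpression()`, strict inequality).
2. **log2 + quantile normalization.** A pseudocount of 1 precedes the log2
   transform; the transform preserves zero ordering and is the standard
   choice where the handling of zeros is otherwise unspecified. Quantile
   normalization replaces each sample's order statistics by the
   across-sample mean of order statistics. Ties within a sample receive the
   *mean of the reference values at their tied ranks* — a deterministic,
   permutation-invariant rule. A consequence worth knowing: with ties, a
   tie group collapses several distinct reference values into their mean,
   so the "all columns share one multiset" identity and idempotence hold
   exactly only for tie-free columns; the package's tests check the exact
   identities on tie-free data and the tie rule on worked examples.
3. **Batch removal.** Additive per-feature batch terms are estimated by a
   linear model with sum-coded batch indicators (via
   `limma::removeBatchEffect`) and subtracted; feature means are preserved,
   and a protected design that is confounded with batch is refused with an
   error rather than silently absorbed.
4. **Outlier flagging.** Samples are scored by their radius over the first
   two principal components, each scaled by its score standard deviation;
   the default flagging radius is 2.5. Flagging is automated and reported;
   *removal* requires an explicit `dropOutliers = TRUE`, after which
   normalization and batch removal are re-run on the remaining samples.
   An automated threshold replaces visual inspection deliberately:
   reproducibility over eyeballing.

# Variance partitioning and differential expression

**Model 1** is a sequential (Type-I) ANOVA per feature over the twelve
variables in a fixed entry order (delivery type, newborn sex, maternal BMI,
number of pregnancies, pregnancy infection, first pregnancy, mother's age,
birth length, birth weight, number of children, drinker, population).
η²(v) = SS(v)/SS(total); the per-feature fractions plus the residual sum
to one exactly, which the suite asserts to 1e-9. Type-I sums of squares are
order-invariant on balanced designs and order-dependent otherwise — both
properties are tested. The engine computes all features at once through a
single QR decomposition of the ordered design; it matches `aov()` per
feature to 1e-10 in the cross-check tests.

**Model 2** residualizes each feature on four continuous covariates
(maternal BMI, birth weight, mother's age, birth length) by OLS, then runs
the sequential ANOVA F-test over (delivery type, newborn sex, population).
Missing covariates are handled complete-case per analysis — samples missing
a covariate are dropped from that model only, never imputed. Thresholds
follow the study design: nominal p < 0.05 for population, p < 0.01 for
newborn sex; BH-adjusted p-values are reported alongside.

**Permutation calibration.** The count of nominally significant features is
compared with the same count under 1000 permutations of whole metadata rows
against the expression columns (individual-level permutation, preserving
the covariate correlation structure). The permutation p is the plain
proportion of permutations with a count at least the observed one, which
can legitimately be zero; an add-one smoothing option ((b+1)/(n+1)) exists
for users who prefer a strictly positive estimate. A reported permutation
p below 1/n_perm is unattainable under the plain rule — the package
reproduces the rule as stated and leaves the interpretation to the user.

**Pairwise tests** use a two-sided t statistic with the standard deviation
pooled across all groups (the `pairwise.t.test(pool.sd = TRUE)` dialect),
BH-corrected *within each feature* across the six population pairs by
default; the scope is configurable to global correction because the
methodological convention is ambiguous. **Direction consistency** of a
two-level effect across k populations is tested by an exact upper-tail
binomial with null probability (1/2)^(k-1); a zero fold change anywhere
counts as inconsistent.

# Population structure and concordance with genetics

Expression distances between populations are built per feature after
scaling by the feature's mean: the distance contributed by one feature is
the absolute difference of scaled population means, and the population
distance is the mean across features. Neighbor joining (`ape::nj`) produces
the unrooted dendrogram; negative branch lengths are reported as produced
(clamping is an option, not the default), because silently clamping hides
non-additivity. The genetic reference tree is built the same way from an
Fst matrix after collapsing multi-source populations by the arithmetic
mean of their entries. Concordance uses a Mantel test: Spearman correlation
of upper-triangle distances, two-sided via |rho|, with all n! relabelings
enumerated for n ≤ 6 labels (24 permutations for four populations, so the
smallest attainable p is 1/24 ≈ 0.042) and seeded random permutations
otherwise. Co-expression clustering of DE miRNAs uses (1 − Spearman rho)
distance, complete-linkage hierarchical clustering (the default of the
cited interface; average and Ward remain available) cut at k = 6.

# Annotation metrics

The tau index uses the canonical formula on non-negative input; values
that fall below zero after log-scale normalization are floored at zero
first (the standard tau convention). Replicate tissue datasets are
quantile-normalized jointly and aggregated per tissue by mean (median
optional). Evolutionary ages are assigned from a reciprocal-homology
presence table as the minimum age-group index among species with a hit
(0 = oldest, 12 = human-specific); when a feature hits species in several
groups the oldest wins — the only reading consistent with "age of origin".
Category enrichment is a generic upper-tail hypergeometric over any
label→feature-set table with Bonferroni (default) or BH correction, so
disease, cluster-membership, or functional annotations are all just
category files.

# Targets and imprinting

Predicted pairs need support from at least 3 of 5 prediction methods.
Per-pair Spearman rho is computed miRNA-by-miRNA across shared samples;
the non-target pool excludes every mRNA with *any* prediction (support ≥ 1)
to a cluster miRNA — conservative contamination control — and pool
correlations are computed against the cluster-mean profile. The group test
is one-sided Wilcoxon (targets lower); retained targets satisfy
rho < −0.5. For sex-associated miRNAs, an mRNA is kept as a target when
the pair is predicted, |mRNA fold change| > 0.1, and the direction opposes
the miRNA's; both fold changes must be declared on the same orientation,
and the selection is exactly antisymmetric under a global orientation
flip. The imprinting analysis computes per-miRNA Spearman rho and p
against maternal BMI, weight and height, and summarizes each covariate by
a two-sided one-sample signed-rank test of the rho distribution against
zero — the test family is fixed but its one-sample reading is a design
choice (a two-sample variant against a background rho distribution is
available). Because the per-miRNA correlations within an imprinted block
share the block's common signal, this group test is anti-conservative
under dependence; it is reproduced as designed, and the simulator is
constructed so that its height null actually holds (below).

# The synthetic-data generator

`simulateDataset()` draws a complete study bundle from an explicit
generative model: counts are negative-binomial with mean
2^(baseline + population effect + sex effect + batch shift + imprinting
term + biological noise) × library factor. Defaults (the package's study
conditions, chosen once):

* 1000 miRNAs, 4 populations × 2 sexes × 5 samples = 40 samples, 3 batches
  with additive log2 shifts of ±0.3.
* Population effects on 13.9% of miRNAs, built from fixed-magnitude,
  random-sign contributions on the five branches of the population tree
  (pendant scales A 1.5, E 0.8, S 0.5, X 0.5, shared S–X branch 0.8, times
  `popEffect`). The default `popEffect = 0.5` is calibrated so that Model 1
  attributes ≈11% of total variance to population and ≈4% to newborn sex
  (sex effects of 0.9 log2 units on 3.2% of miRNAs) — the variance shares
  the analysis is designed around. Note that under a sequential ANOVA the
  null expectation of η² is df/(n−1), so population "explains" ~7.7% even
  with nothing planted; the planted effects account for the rest.
* A stronger *recovery condition* (`popEffect = 1.2, sexEffect = 1.2`) is
  used wherever a test asks for reliable re-detection of every planted
  feature (DE sensitivity/FDR, tree-topology recovery): at the
  variance-calibrated effect sizes a fraction of planted features is
  intentionally near the detection limit, which is realistic but not a
  useful recovery benchmark. DE recovery is scored on BH-adjusted calls
  (padj < 0.05): with 861 null features, a nominal 0.05 threshold implies
  ~43 expected false positives against 139 true effects, so no effect size
  can push the empirical FDR of nominal calls below ~0.24 — an
  FDR-controlling threshold is the rule the FDR bound presupposes.
* Negative-binomial dispersion 0.02 plus a per-sample log-normal biological
  layer of SD 0.4 log2 units. The biological layer is what couples to
  targets: mRNA targets are `baseline − 1.5 × (miRNA log2 deviation) +
  noise(0.35)`, and read-sampling noise on the miRNA side attenuates the
  observable correlation, so the repression cluster is planted on
  well-expressed miRNAs (baseline ≥ 6 log2), where detected clusters live
  in practice.
* Maternal covariates: height log-normal (median 162 cm, σ_log 0.04), BMI
  normal (26.5 ± 4.5 kg/m², truncated at 16), weight = height² × BMI / 10⁴.
  The 66-miRNA imprinted block declines with the *BMI-driven component of
  weight* at 0.025 log2 per kg. That driver is orthogonalized, within the
  simulated sample, against height in level space, against the batch
  subspace (batch-mean removal downstream would otherwise re-inject a
  height-correlated component), and against height in rank space including
  a noise-smoothed rank criterion (the downstream statistic is Spearman).
  Without this construction the block's common signal turns chance sample
  correlations with height into spurious group-level significance — the
  dependence problem noted above.
* The designed tissue panel plants a known tau per miRNA (including exact
  single-tissue features) across 12 tissues × 36 replicate datasets; the
  homology table encodes a known age for each miRNA over a 23-species,
  13-age-group panel; the Fst matrix is built from an additive tree with
  topology ((E,(S,X)),A) and the African-ancestry population on the longest
  pendant branch, emitted at source-population resolution (three East Asian
  sources) so the averaging rule is exercised.

What the generator does **not** emulate: sequence content and read-level
artifacts, mapping ambiguity, compositional (library-sum) coupling between
features, correlated co-expression beyond the planted blocks, population
stratification of the demographic covariates, and missing metadata.
Passing recovery tests therefore demonstrates that the estimators detect
the structure they model, not that real placental data satisfy that model.

# Numerical choices

* Quantile-normalization ties: mean of reference values over tied ranks.
* η² engine: one QR per design; rank deficiency raises an error naming the
  aliased columns rather than dropping terms silently.
* Distance matrices are validated (symmetry 1e-12, exact zero diagonal)
  and symmetrized against rounding before use.
* Mantel enumeration kicks in at n ≤ 6 labels; comparisons of |rho| use a
  1e-12 slack so ties at the observed value count as "at least as
  extreme".
* Rank tests use exact p-values for tie-free groups of at most 12,
  normal approximation with tie correction otherwise; fully tied inputs
  return p = 1 with a warning.
* Problem sizes in the test suite (1000 miRNAs × 40 samples; 20 seeded
  replicates for every recovery property; 200 permutations per null
  replicate; 1000 random vectors for the BH oracle) were chosen so the
  whole suite completes in a few minutes while keeping Monte-Carlo error
  well inside each tolerance.

# Known limitations

* The sequential η² attribution depends on the entry order for unbalanced
  designs; the fixed order is part of the method's definition, not a
  statistical recommendation.
* The permutation p of the DE count has resolution 1/n_perm and can be 0
  under the plain rule.
* The imprinting group test assumes independent per-miRNA correlations;
  within a co-regulated block this is optimistic, as the simulator makes
  explicit.
* Complete-case handling of missing covariates can shrink different models
  to different sample sets.
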