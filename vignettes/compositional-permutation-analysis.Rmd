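---
title: "Permutation-based compositional analysis of mucosal microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation-based compositional analysis of mucosal microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clrperm)
```

## The scientific problem

Mucosal 16S rRNA surveys of the ileum in inflammatory bowel disease ask
whether community composition shifts with host phenotype (ileal Crohn's
disease, colitis, non-IBD controls), innate-immunity genotypes (the NOD2
composite of the Leu1007fs/R702W/G908R risk alleles; ATG16L1 T300A), and
clinical covariates (age, BMI, smoking, *C. difficile* toxin status, IBD
medications). The data are counts of reads binned into seven phylum/subphylum
categories -- Actinobacteria, Bacteroidetes, Firmicutes Clostridium Group IV,
Firmicutes Clostridium Group XIVa, Firmicutes Bacillus, Proteobacteria, and
Other -- per subject and per sequencing platform (Sanger full-length, 454
V1--V3, 454 V3--V5). Counts are compositional: only relative information is
meaningful, sequencing depth is arbitrary, and the components are constrained,
so ordinary multivariate ANOVA on raw frequencies is not appropriate.

`clrperm` implements the full analysis chain: taxonomic binning and read
filtering, the centered log-ratio (CLR) transform, a distance-based
permutation MANCOVA with forward stepwise term selection, per-category and
qPCR permutation ANCOVAs, a repeated-measures permutation ANCOVA across
platforms, cohort-characteristic tests, and Benjamini--Hochberg FDR control,
together with a Dirichlet--multinomial cohort generator that stands in for the
controlled-access study data.

## Model and procedure

### CLR transform

For the six named categories (Other is excluded as a heterogeneous remainder),
counts $x_1,\dots,x_6$ are adjusted by a +0.5 pseudocount and transformed to

$$\mathrm{clr}_i = \ln x_i - \frac{1}{6}\sum_{j=1}^{6}\ln x_j .$$

The pseudocount is applied to counts *before* closure; because the geometric
mean divides out, the result is identical on counts and proportions (scale
invariance), and every sample's CLR vector sums to zero. Natural logarithms
are used; the base only rescales distances and cannot affect permutation
inference. Euclidean distance between CLR vectors is the Aitchison distance,
which makes the distance-based machinery below exactly a multivariate
ANOVA in the Aitchison geometry.

### Distance-based partition and pseudo-F

Given an $n \times n$ distance matrix $d$ and an ordered term list, the
engine forms the Gower-centered Gram matrix
$G = -\tfrac12 C\, d^{\circ 2}\, C$ with $C = I - \mathbf{1}\mathbf{1}'/n$,
builds the cumulative design (intercept, then each term's block) and
its orthonormal basis by QR, and takes sequential (Type I) sums of squares
$SS_k = \mathrm{tr}(\Delta H_k G)$, where $\Delta H_k$ is the increment of
the projection operator. Pseudo-F is
$(SS_k/df_k)/(SS_{res}/df_{res})$. For a univariate response with
$d_{ij}=|y_i-y_j|$ the Gram matrix is the outer product of the centered
response and every statistic equals classical sequential ANOVA/ANCOVA
exactly (the univariate entry point computes it through that identity; the
test suite asserts equality with the distance route to $10^{-10}$ and with
`lm`/`anova` on a battery of random designs).

Categorical covariates get full-rank treatment dummies with the
lexicographically first level as reference; continuous covariates enter
linearly and untransformed. Interaction blocks are elementwise products of
the parent encodings, with one refinement: continuous parents are
mean-centered inside the product. Without centering, `phenotype:bmi` is
numerically almost `25 * phenotype` -- a near-copy of the main effect's
column space -- and during selection such interactions impersonate their
parents. Centering leaves every model that contains the parents unchanged
(the spanned space is identical, verified against `vegan::adonis2`) and only
redefines parentless interactions, where the centered version is the
defensible meaning of "interaction".

### Permutation inference

P-values come from permuting whole metadata rows against the fixed distance
matrix (free raw-data permutation, the default of the distance-based MANCOVA
tradition this reimplements). All terms are evaluated on one permutation
stream. In Monte-Carlo mode

$$p = \frac{1 + \#\{b: F_b \ge F_{obs}\}}{1 + B},$$

so $p$ can never be 0 and the floor is $1/(B+1)$; with the default
$B = 999$ the smallest attainable p is 0.001. The number of permutations is
configurable because no single value is canonical; 999 balances the p floor
against runtime. For $n \le 8$ an exhaustive mode enumerates all $n!$
relabelings and reports the plain tail proportion (the observed identity
labeling is one of the $n!$, so no +1 correction is applied or needed).

The comparison $F_b \ge F_{obs}$ counts *mathematical* ties with a relative
slack of $10^{-8}$: relabelings that preserve the group partition reproduce
$F_{obs}$ exactly in exact arithmetic but differ by summation-order rounding
in floating point. With a strict float comparison, p would not be invariant
under affine rescaling of the response and exhaustive-mode p would disagree
with the true tail proportion on tied designs; with the slack both
properties hold (and are tested). The slack is far below any F difference a
real effect produces at these sample sizes.

### Forward stepwise selection

The candidate pool is the 13 cohort covariates and all 78 unordered
first-order interactions. Interaction "hierarchy" is *not* enforced --
interactions compete regardless of whether their parents are in the model --
because the analyses this package reproduces report interactions without
the corresponding mains. At each step, every remaining candidate is tested
as the last sequential term of the current model, all candidates sharing the
step's permutation stream so their p-values are comparable; the smallest p
enters if $p \le \alpha$ (default 0.05). Ties, which are routine at the p
floor, are broken by the larger pseudo-F -- the per-degree-of-freedom
increment -- then pool order. Breaking ties on raw incremental $R^2$, the
obvious alternative, systematically prefers wide interaction blocks (more
columns absorb more sum of squares) over the main effect actually carrying
the signal; with the calibrated phenotype effect this mis-selection was
frequent, while the pseudo-F rule recovers the true term essentially always.
Selection is forward-only (no elimination step), candidates that would make
the design rank-deficient are skipped with a log entry, and the final model
is re-partitioned once in selection order, with BH-FDR across its rows. The
FDR family is one reported table (one analysis run).

### Repeated measures across platforms

For one category's CLR value measured on all three platforms, complete-case
subjects are stacked long and partitioned sequentially: between-subject
terms first, then a `Measurements` (platform) factor. Balance makes the
Measurements increment orthogonal to every between-subject column, so its
SS is the pure within-subject platform effect; explicit subject-mean
centering is therefore unnecessary, though it is what the decomposition
amounts to. Two restricted permutation schemes respect the two
exchangeability units: subjects move as whole blocks for between-subject
terms (leaving platform sums, hence Measurements SS, invariant), and
platform labels shuffle within subjects for Measurements (leaving every
between-subject SS invariant). $R^2$ uses the total stacked SS as
denominator -- the within-subject denominator is the other defensible
choice, but the total-SS version keeps the Measurements row comparable in
magnitude to the covariate rows of the same table.

### qPCR responses and the cohort table

qPCR gives relative frequencies (target copies / total-bacteria copies),
not counts, so the count pseudocount has no analogue; values are mapped
through the empirical logit $\ln((p+\varepsilon)/(1-p+\varepsilon))$, finite
at 0 and 1. No canonical $\varepsilon$ exists for ratio data: the default is
half the smallest nonzero observed frequency (data-adaptive, keeps zeros
below every nonzero value), and a fixed constant can be configured for
strict reproducibility across datasets. Frequencies above 1, possible when
the two assays use independent standard curves, are clamped to 1 with a
warning. Cohort characteristics use Pearson chi-square without continuity
correction for categorical variables (anti-TNF exposure as one 3-level
block, so the table gets a single p-value for it) and Kruskal--Wallis for
age and BMI, with BH across the table's rows; exact tests are out of scope
at these margins.

## The synthetic cohort generator

The generator's defaults are the study conditions: 52/58/60 subjects (ileal
CD/colitis/control), platform mean depths 500, 7260 and 5400 reads/sample,
and covariate marginals matching the reported cohort table, including the
structural zeros (controls take no IBD medication and none were *C.
difficile* positive). Specific choices:

* **Overdispersion.** Counts are Dirichlet--multinomial: one latent
  composition per subject, drawn from a Dirichlet with parameters
  `base_composition * dirichlet_concentration`, then multinomial counts per
  platform. Mucosal 16S counts are overdispersed relative to multinomial;
  the concentration (default 40) is the single overdispersion dial.
* **Coupling across platforms.** The latent composition is shared by all
  platforms of a subject. The true within-subject coupling is unknowable
  from the published material; sharing the Dirichlet draw is the simplest
  mechanism that makes the repeated-measures analysis meaningful.
* **Depths.** Negative-binomial around the platform mean (size 5):
  realistic spread while keeping integer depths.
* **Covariates.** Sampled marginally per phenotype (only marginals are
  reported). Age and BMI come from a Beta(2, b) rescaled to the reported
  range with b solved so the median matches the reported median. The
  ATG16L1 table reports only the NR/NR fraction; the remainder is split 2:1
  R/NR : R/R (heterozygotes commoner).
* **Effects.** `effect_map` rows shift a category's log Dirichlet parameter
  for subjects matching a covariate level (or proportionally to the z-scored
  value of a continuous covariate). `phenotype_effect_preset()` is
  calibrated so the realized composition $R^2$ for phenotype averages
  ~0.13 -- the effect-size scale the overall-composition analysis is meant
  to detect. The CD and colitis shifts point in different compositional
  directions (Proteobacteria up / Clostridium IV down in CD; Bacteroidetes
  down / Bacillus up in colitis): the two dysbioses differ in kind, and a
  single graded CD > colitis > control axis would be a gift to any
  covariate correlated with phenotype (age, under these marginals).
* **qPCR.** Relative frequency = sum of the tracked categories' latent
  proportions times lognormal noise (sd 0.3), clamped into (0, 1):
  copy-number ratios are positive and right-skewed.
* **Seeding.** One master seed; metadata, compositions, each platform and
  each qPCR target use fixed offsets from it, so adding a platform leaves
  earlier draws untouched, and identical configs give byte-identical
  outputs.

What the generator does *not* emulate: sequencing error, chimeras,
classifier mistakes, longitudinal sampling, joint covariate dependence
beyond phenotype (covariates are conditionally independent given
phenotype), and platform-specific taxonomic bias (a platform offset can be
injected per category, but the default has none). Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated under
a faithful null and a realistic effect structure -- not that real mucosal
data meet those assumptions.

## Numerical choices and degenerate inputs

* Zero total SS (constant response) is an error, as is a cumulative design
  whose new term does not raise the rank by its full column count (the
  offending term is named; during stepwise selection such candidates are
  skipped instead).
* The sample filter removes samples with fewer than 100 total screened
  reads, strictly ("less than"): a total of exactly 100 is retained.
* Missing covariate values are never imputed: subjects are dropped from any
  model using that covariate, with a logged count.
* Firmicutes subdivision into Clostridium IV/XIVa/Bacillus follows an
  editable concordance table shipped as plain CSV; name matching is
  case-insensitive with punctuation stripped. Unmatched Firmicutes and all
  minor phyla go to Other.

## Problem sizes used by the tests

The test suite and acceptance script run entirely on generated data: the
type-I calibration uses 500 null cohorts of n = 170 with B = 199 and checks
a pre-specified term's rejection rate against [0.03, 0.07]; effect recovery
uses 100 cohorts with the calibrated phenotype preset and checks that
phenotype enters the selection first in at least 90%; the exhaustive oracle
runs at n <= 7; the classical-limit battery uses 20+ random designs of
n = 12--24. These sizes give stable Monte-Carlo estimates (binomial SE
under 0.01 for the calibration rate) at desk-scale runtimes.

## Known limitations

* Sequential (Type I) partitions are order-dependent by construction; the
  reported order is the selection order, and a different entry order gives
  different per-term SS. This matches the cited engine but means R^2 values
  are not variance components.
* Stepwise selection over 91 candidates at alpha = 0.05 is exploratory:
  on null data the first-entry family-wise error is far above 0.05 (it is
  the minimum of ~91 correlated p-values). The BH column adjusts only the
  final table, not the selection path -- as in the analyses reproduced here.
* The repeated-measures engine requires complete cases and balance; with
  incomplete platform coverage, subjects must be dropped (done by
  `align_tables()`), not imputed.
* Published FDR columns are reproduced by standard BH from printed
  p-values except where a printed column is internally non-monotone in p
  (one qPCR table row pair), which no step-up variant produces; the
  implementation follows standard BH.
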