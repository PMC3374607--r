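# clrperm

Permutation-based compositional association analysis for mucosal
microbiota surveys.

## What this is for

Ileal 16S rRNA surveys in inflammatory bowel disease produce per-subject
read counts over a small number of phylum/subphylum categories
(Actinobacteria, Bacteroidetes, three Firmicutes subdivisions,
Proteobacteria, Other), from several sequencing platforms, linked to host
phenotype (ileal Crohn's disease / colitis / non-IBD control), NOD2 and
ATG16L1 genotypes, and clinical covariates (age, BMI, smoking,
*C. difficile* toxin status, IBD medications). The scientific question is
which of those variables are associated with shifts in community
composition. Counts are compositional — only relative abundance is
meaningful — so the analysis works in the Aitchison geometry.

`clrperm` provides the full chain as tested R functions:

* **Ingestion**: lineage binning into the seven categories (editable
  Firmicutes concordance), the <100-reads sample filter, table validation
  and alignment (`bin_lineages()`, `filter_min_reads()`, `align_tables()`).
* **Transforms**: centered log-ratio with +0.5 pseudocount on the six
  named categories, `clr_i = ln x_i − mean_j ln x_j`; empirical logit
  `ln((p+ε)/(1−p+ε))` for qPCR relative frequencies.
* **Inference engine**: distance-based permutation MANCOVA — Gower-centered
  Gram matrix `G = −(1/2) C d² C`, sequential (Type I) sums of squares
  via projection operators, pseudo-F = `(SS_t/df_t)/(SS_res/df_res)`,
  p = `(1 + #{F_b ≥ F_obs}) / (1 + B)` under free row permutation, with an
  exhaustive n! mode for small n (`permutation_test()`,
  `univariate_permutation_test()`, `dm_partition()`).
* **Model selection**: forward stepwise entry by permutation p over the 13
  cohort covariates and all first-order interactions, BH-FDR on the final
  table (`stepwise_select()`, `bh_fdr()`).
* **Repeated measures**: platforms as within-subject measurements, with
  whole-subject block permutations for covariates and within-subject
  label shuffles for the platform (`Measurements`) effect
  (`rm_permutation_ancova()`).
* **Cohort table**: chi-square / Kruskal–Wallis per covariate with FDR
  (`cohort_table()`).
* **Synthetic cohorts**: a Dirichlet–multinomial generator reproducing the
  study design (52/58/60 subjects, three platforms at mean depths
  500/7260/5400 reads, covariate marginals per phenotype, qPCR-style
  ratios) with configurable injected effects (`simulate_cohort()`,
  `phenotype_effect_preset()`), so the entire pipeline is testable without
  controlled-access data.

The `analysis/` directory holds the numbered workflow —
`01_simulate.R` … `05_qpcr_ancova.R` — each a thin driver over the package
that writes its tables under `results/`. `run_pipeline()` runs the same
sequence as one call from a single config.

## Worked example

Simulate a cohort with the calibrated phenotype effect, CLR-transform the
Sanger counts, and run stepwise selection over a small pool:

```r
library(clrperm)

co   <- simulate_cohort(sim_config(effect_map = phenotype_effect_preset(), seed = 1))
comp <- clr_transform(co$counts$sanger)            # 170 x 6 CLR matrix
d    <- euclidean_distances(comp)                  # Aitchison distances
sel  <- stepwise_select(d, candidate_pool(c("phenotype", "nod2", "cdiff",
                                            "age", "smoker", "bmi")),
                        co$metadata, B = 199, seed = 1)
print(sel)
```

```
Selected terms (entry order):
 step         term     p      R2
    1    phenotype 0.005 0.12050
    2 cdiff:smoker 0.030 0.01239
Stopping: no candidate below alpha
Final model partition:
         term        kind df      SS      R2       F     p   fdr
    phenotype        main  2 33.1130 0.12050 11.5380 0.005 0.010
 cdiff:smoker interaction  1  3.4024 0.01239  2.3711 0.045 0.045
Residual SS 238.21 on 166 df; total SS 274.72; n = 170
199 permutations, seed 1
Skipped (rank-deficient): phenotype:cdiff
```

Reading this: disease phenotype explains ~12% of the total Aitchison
variance (its entry p is at the floor 1/(B+1) = 0.005), matching the
injected effect size; one spurious interaction slips in at p = 0.045, as
expected for stepwise entry at α = 0.05 over many candidates; and
`phenotype:cdiff` is skipped because controls have no positive
*C. difficile* toxin, so that interaction block is rank-deficient. The
`fdr` column is BH across the final table.

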