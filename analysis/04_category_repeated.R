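#!/usr/bin/env Rscript

## Step 4: per-category permutation ANCOVAs and the repeated-measures
## analysis across platforms.
##
## Each of the six CLR categories is analysed per platform by univariate
## stepwise permutation ANCOVA; the union of the terms selected for a
## category is then re-assessed on the complete-case subjects (all three
## platforms available) by a repeated-measures permutation ANCOVA with a
## final Measurements row that quantifies systematic between-platform
## differences (subjects permuted as whole blocks for the covariate terms,
## platform labels shuffled within subject for Measurements).

library(clrperm)

seed <- 42L
B <- 199L

metadata <- read_metadata("results/data/metadata.csv")
counts <- lapply(stats::setNames(nm = PLATFORMS), function(p)
  read_counts(file.path("results/data", paste0("counts_", p, ".tsv"))))
counts <- lapply(counts, filter_min_reads)
aligned <- align_tables(metadata, counts)

pool <- candidate_pool(c("phenotype", "nod2", "atg16l1", "gender", "race",
                         "age", "smoker", "cdiff", "bmi", "asa5", "steroids",
                         "immunomodulators", "anti_tnf"))

anc_rows <- list()
union_terms <- stats::setNames(vector("list", length(CATEGORIES6)), CATEGORIES6)
for (plat in PLATFORMS) {
  pp <- aligned$per_platform[[plat]]
  comp <- clr_transform(pp$counts)
  for (cat_ in CATEGORIES6) {
    sel <- stepwise_select(comp[[cat_]], pool, pp$metadata, B = B, seed = seed)
    union_terms[[cat_]] <- union(union_terms[[cat_]], sel$trace$term)
    if (!is.null(sel$final))
      anc_rows[[paste(plat, cat_)]] <-
        cbind(platform = plat, category = cat_,
              sel$final$table[, c("term", "kind", "R2", "p", "fdr")])
  }
}
anc <- do.call(rbind, anc_rows)
utils::write.table(anc, "results/ancova_per_category.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cm <- aligned$complete$metadata
clr_by_plat <- lapply(aligned$complete$counts, clr_transform)
rep_rows <- list()
for (cat_ in CATEGORIES6) {
  vals <- data.frame(subject_id = cm$subject_id)
  for (plat in PLATFORMS) vals[[plat]] <- clr_by_plat[[plat]][[cat_]]
  terms <- union_terms[[cat_]]
  terms <- c(terms[!grepl(":", terms)], terms[grepl(":", terms)])
  res <- rm_permutation_ancova(vals, terms, cm, B = B, seed = seed)
  res$table$fdr <- bh_fdr(res$table$p)
  cat("\n==", cat_, "(complete cases n =", nrow(cm), ") ==\n")
  print(res)
  rep_rows[[cat_]] <- cbind(category = cat_,
                            res$table[, c("term", "kind", "R2", "p", "fdr")])
}
utils::write.table(do.call(rbind, rep_rows), "results/repeated_measures.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("\nWrote results/ancova_per_category.tsv and results/repeated_measures.tsv\n")
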