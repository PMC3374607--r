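#!/usr/bin/env Rscript

## Step 5: empirical-logit ANCOVA of the qPCR relative frequencies.
##
## The target-group / total-bacteria copy ratio is transformed with the
## empirical logit ln((p + eps)/(1 - p + eps)) -- eps defaulting to half the
## smallest nonzero observed frequency keeps 0 and 1 finite -- and analysed
## by the same stepwise permutation ANCOVA as the sequence data.

library(clrperm)

seed <- 42L
B <- 199L

metadata <- read_metadata("results/data/metadata.csv")
targets <- c("c_coccoides_e_rectales", "f_prausnitzii")
pool <- candidate_pool(c("phenotype", "nod2", "atg16l1", "gender", "race",
                         "age", "smoker", "cdiff", "bmi", "asa5", "steroids",
                         "immunomodulators", "anti_tnf"))

for (tg in targets) {
  q <- read_qpcr(file.path("results/data", paste0("qpcr_", tg, ".csv")))
  m <- metadata[match(q$subject_id, metadata$subject_id), , drop = FALSE]
  eps <- default_logit_epsilon(q$relative_frequency)
  y <- empirical_logit(q$relative_frequency, eps)
  sel <- stepwise_select(y, pool, m, B = B, seed = seed)
  cat("\n==", tg, "(n =", nrow(m), ", epsilon =", signif(eps, 3), ") ==\n")
  print(sel)
  out <- if (is.null(sel$final)) {
    data.frame(term = character(0), kind = character(0), R2 = numeric(0),
               p = numeric(0), fdr = numeric(0))
  } else sel$final$table[, c("term", "kind", "R2", "p", "fdr")]
  utils::write.table(out, file.path("results", paste0("qpcr_", tg, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
cat("\nWrote results/qpcr_<target>.tsv\n")
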