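make_metadata_csv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "md.csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

base_md <- function(n = 3) {
  data.frame(subject_id = paste0("s", seq_len(n)),
             phenotype = rep(c("ileal_CD", "colitis", "control"), length.out = n),
             nod2 = "NR", atg16l1 = "R/NR", gender = "male", race = "caucasian",
             age = 40, smoker = FALSE, cdiff = FALSE, bmi = 25, asa5 = FALSE,
             steroids = FALSE, immunomodulators = FALSE, anti_tnf = "never",
             stringsAsFactors = FALSE)
}

test_that("read_metadata validates schema and values", {
  expect_equal(nrow(read_metadata(make_metadata_csv(base_md(3)))), 3L)
  md <- base_md(3); md$phenotype <- NULL
  expect_error(read_metadata(make_metadata_csv(md)), "phenotype")
  md <- base_md(3); md$age[2] <- -5
  expect_error(read_metadata(make_metadata_csv(md)), "age.*2")
  md <- base_md(3); md$subject_id[2] <- "s1"
  expect_error(read_metadata(make_metadata_csv(md)), "duplicate")
  md <- base_md(3); md$phenotype[1] <- NA
  expect_warning(got <- read_metadata(make_metadata_csv(md)), "missing phenotype")
  expect_equal(nrow(got), 2L)
  md <- base_md(3); md$anti_tnf[1] <- "sometimes"
  expect_error(read_metadata(make_metadata_csv(md)), "anti_tnf")
})

test_that("lineage binning is total and respects the concordance lookup", {
  asg <- data.frame(
    subject_id = "s1",
    phylum = c("Proteobacteria", "Firmicutes", "Firmicutes", "Firmicutes",
               "Fusobacteria", "Bacteroidetes", "Actinobacteria", "Firmicutes"),
    group = c(NA, "Clostridium XIVa", "Ruminococcaceae", "Lactobacillus",
              NA, NA, NA, "Unknownaceae"),
    stringsAsFactors = FALSE)
  ct <- bin_lineages(asg)
  expect_equal(ct$Proteobacteria, 1)
  expect_equal(ct$Firmicutes_ClostridiumXIVa, 1)  # lookup: group label match
  expect_equal(ct$Firmicutes_ClostridiumIV, 1)    # Ruminococcaceae -> Group IV
  expect_equal(ct$Firmicutes_Bacillus, 1)
  expect_equal(ct$Bacteroidetes, 1)
  expect_equal(ct$Actinobacteria, 1)
  expect_equal(ct$Other, 2)  # Fusobacteria + unmatched Firmicutes group
  ## totality: every row lands in exactly one category
  expect_equal(sum(ct[, CATEGORIES7]), nrow(asg))
})

test_that("binning canonicalises names and warns on empty phyla", {
  asg <- data.frame(subject_id = c("a", "a", "b"),
                    phylum = c("  PROTEO-bacteria ", "", "firmicutes"),
                    group = c(NA, NA, "clostridium-group-XIVA"),
                    stringsAsFactors = FALSE)
  expect_warning(ct <- bin_lineages(asg), "empty phylum")
  expect_equal(ct$Proteobacteria[ct$subject_id == "a"], 1)
  expect_equal(ct$Other[ct$subject_id == "a"], 1)
  expect_equal(ct$Firmicutes_ClostridiumXIVa[ct$subject_id == "b"], 1)
  expect_equal(attr(ct, "n_unassigned"), 1L)
})

test_that("filter_min_reads uses a strict threshold and is idempotent", {
  rows <- rbind(c(99, 0, 0, 0, 0, 0, 0),      # total 99: removed
                c(100, 0, 0, 0, 0, 0, 0),     # total 100: retained
                c(50, 50, 50, 0, 0, 0, 0))    # total 150: retained
  ct <- toy_counts(rows)
  f1 <- filter_min_reads(ct)
  expect_equal(f1$subject_id, c("s2", "s3"))
  expect_equal(attr(f1, "removed")$subject_id, "s1")
  f2 <- filter_min_reads(f1)
  expect_equal(f2$subject_id, f1$subject_id)
  ## identity when everything passes
  all_ok <- toy_counts(matrix(100, 2, 7))
  expect_equal(filter_min_reads(all_ok)$subject_id, all_ok$subject_id)
  ## empty result allowed
  expect_equal(nrow(filter_min_reads(toy_counts(matrix(0, 2, 7)))), 0L)
})

test_that("align_tables forms per-platform joins and the complete-case set", {
  co <- simulate_cohort(sim_config(n_per_phenotype = c(6, 6, 6), seed = 12))
  counts <- co$counts
  ## identical subjects: intersection equals any platform
  al <- align_tables(co$metadata, counts)
  expect_equal(al$complete$metadata$subject_id, sort(co$metadata$subject_id))
  ## drop 5 subjects from one platform: complete-case set shrinks by those 5
  dropped <- counts$v1v3$subject_id[3:7]
  counts$v1v3 <- counts$v1v3[-(3:7), ]
  al2 <- align_tables(co$metadata, counts)
  expect_equal(al2$complete$metadata$subject_id,
               sort(setdiff(co$metadata$subject_id, dropped)))
  expect_equal(al2$exclusions$v1v3, 5L)
  ## random drops: intersection equals brute-force set algebra
  set.seed(13)
  counts2 <- lapply(co$counts, function(ct) ct[sample(nrow(ct), 12), ])
  al3 <- align_tables(co$metadata, counts2)
  oracle <- sort(Reduce(intersect, c(list(co$metadata$subject_id),
                                     lapply(counts2, `[[`, "subject_id"))))
  expect_equal(al3$complete$metadata$subject_id, oracle)
  ## ids are sorted and identical across the joined tables
  for (plat in names(al3$per_platform)) {
    pp <- al3$per_platform[[plat]]
    expect_false(is.unsorted(pp$metadata$subject_id))
    expect_identical(pp$metadata$subject_id, pp$counts$subject_id)
  }
  ## empty intersection errors
  counts3 <- co$counts
  counts3$sanger$subject_id <- paste0("zz", counts3$sanger$subject_id)
  expect_error(align_tables(co$metadata, counts3), "empty intersection")
})

test_that("qPCR reader clamps over-unity frequencies and complete_for drops NA", {
  dir <- withr::local_tempdir()
  q <- data.frame(subject_id = c("a", "b"), target = "t",
                  relative_frequency = c(0.5, 1.04))
  path <- file.path(dir, "q.csv")
  utils::write.csv(q, path, row.names = FALSE)
  expect_warning(got <- read_qpcr(path), "clamped")
  expect_equal(got$relative_frequency, c(0.5, 1))
  q$relative_frequency <- c(-0.1, 0.5)
  utils::write.csv(q, path, row.names = FALSE)
  expect_error(read_qpcr(path), "negative")

  md <- base_md(4)
  md$bmi[2] <- NA
  got <- complete_for(md, c("phenotype", "bmi:age"))
  expect_equal(got$subject_id, md$subject_id[-2])
  expect_equal(attr(got, "n_dropped"), 1L)
})
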