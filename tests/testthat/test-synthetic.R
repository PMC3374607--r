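test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr, b$qpcr)
  c2 <- simulate_cohort(sim_config(seed = 6))
  expect_false(identical(a$counts$sanger, c2$counts$sanger))
})

test_that("default cohort has the study design: 52 + 58 + 60 subjects", {
  co <- simulate_cohort(sim_config(seed = 1))
  expect_equal(nrow(co$metadata), 170L)
  expect_equal(as.integer(table(co$metadata$phenotype)[c("ileal_CD", "colitis", "control")]),
               c(52L, 58L, 60L))
  expect_equal(names(co$counts), c("sanger", "v1v3", "v3v5"))
  ## all tables share the subject identifiers
  for (ct in co$counts) expect_equal(ct$subject_id, co$metadata$subject_id)
  for (q in co$qpcr) expect_equal(q$subject_id, co$metadata$subject_id)
  ## counts are non-negative integers; depths vary around the platform means
  x <- as.matrix(co$counts$v1v3[, CATEGORIES7])
  expect_true(all(x >= 0) && all(x == round(x)))
  expect_gt(mean(rowSums(x)), 7260 * 0.7)
  expect_lt(mean(rowSums(x)), 7260 * 1.3)
  ## control subjects carry no IBD medication and no C. difficile, as in the
  ## covariate model
  ctrl <- co$metadata[co$metadata$phenotype == "control", ]
  expect_true(all(!ctrl$asa5 & !ctrl$steroids & !ctrl$immunomodulators & !ctrl$cdiff))
  expect_true(all(ctrl$anti_tnf == "never"))
  ## qPCR frequencies are valid proportions
  for (q in co$qpcr)
    expect_true(all(q$relative_frequency > 0 & q$relative_frequency < 1))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(n_per_phenotype = c(1, 5, 5)), "n_per_phenotype")
  expect_error(sim_config(dirichlet_concentration = -1), "dirichlet_concentration")
  bc <- c(Actinobacteria = 0.5, Bacteroidetes = 0.5, Firmicutes_ClostridiumIV = 0.1,
          Firmicutes_ClostridiumXIVa = 0.1, Firmicutes_Bacillus = 0.1,
          Proteobacteria = 0.1, Other = 0.1)
  expect_error(sim_config(base_composition = bc), "base_composition")
  expect_error(sim_config(platform_depths = c(sanger = -5)), "platform_depths")
  em <- data.frame(covariate = "phenotype", level = "ileal_CD",
                   category = "NotACategory", lfc = 1)
  expect_error(sim_config(effect_map = em), "effect_map")
})

test_that("an injected Proteobacteria shift is recovered across replicates", {
  ## +2 log-fold Proteobacteria in ileal CD, concentration 50, depth 5000:
  ## the CD group mean relative frequency should exceed the control group's
  ## in nearly every seeded replicate
  em <- data.frame(covariate = "phenotype", level = "ileal_CD",
                   category = "Proteobacteria", lfc = 2, stringsAsFactors = FALSE)
  hits <- vapply(1:100, function(seed) {
    co <- simulate_cohort(sim_config(platform_depths = c(deep = 5000),
                                     dirichlet_concentration = 50,
                                     effect_map = em, seed = seed))
    x <- co$counts$deep
    rel <- x$Proteobacteria / rowSums(x[, CATEGORIES7])
    ph <- co$metadata$phenotype
    mean(rel[ph == "ileal_CD"]) > mean(rel[ph == "control"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("realized phenotype effect grows with the injected scale", {
  r2 <- vapply(c(0, 0.5, 1), function(s) {
    co <- simulate_cohort(sim_config(effect_map = phenotype_effect_preset(s),
                                     seed = 77))
    comp <- clr_transform(co$counts$sanger)
    dm_partition(euclidean_distances(comp), "phenotype", co$metadata)$table$R2
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("write_cohort round-trips through the readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_per_phenotype = c(5, 5, 5), seed = 9))
  write_cohort(co, dir)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  attr(md, "n_missing") <- NULL
  expect_equal(md, co$metadata)
  for (plat in names(co$counts)) {
    ct <- read_counts(file.path(dir, paste0("counts_", plat, ".tsv")))
    expect_equal(ct, co$counts[[plat]])
  }
  for (tg in names(co$qpcr)) {
    q <- read_qpcr(file.path(dir, paste0("qpcr_", tg, ".csv")))
    expect_equal(q, co$qpcr[[tg]], tolerance = 1e-12)
  }
  expect_true(file.exists(file.path(dir, "truth.yaml")))
})

test_that("an empty cohort writes valid files with headers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_per_phenotype = c(2, 2, 2), seed = 9))
  co$metadata <- co$metadata[0, , drop = FALSE]
  co$counts <- lapply(co$counts, function(x) x[0, , drop = FALSE])
  co$qpcr <- lapply(co$qpcr, function(x) x[0, , drop = FALSE])
  write_cohort(co, dir)
  md <- read_metadata(file.path(dir, "metadata.csv"))
  expect_equal(nrow(md), 0L)
  ct <- read_counts(file.path(dir, "counts_sanger.tsv"))
  expect_equal(nrow(ct), 0L)
  expect_true(all(CATEGORIES7 %in% names(ct)))
})
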