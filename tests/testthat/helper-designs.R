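## Shared test fixtures, all built in code.

## The 13 cohort covariates used as the candidate pool.
pool_vars <- c("phenotype", "nod2", "atg16l1", "gender", "race", "age",
               "smoker", "cdiff", "bmi", "asa5", "steroids",
               "immunomodulators", "anti_tnf")

## A random small univariate design with known-good factor structure, for
## comparing the permutation engine's F against classical sequential ANOVA.
random_small_design <- function(seed) {
  repeat {
    set.seed(seed)
    n <- sample(12:24, 1)
    md <- data.frame(g = sample(letters[1:3], n, replace = TRUE),
                     h = sample(c("u", "v"), n, replace = TRUE),
                     x = stats::rnorm(n),
                     stringsAsFactors = FALSE)
    y <- stats::rnorm(n)
    terms <- list(c("g"), c("x"), c("g", "x"), c("x", "g"), c("g", "h"),
                  c("g", "x", "g:x"), c("h", "x", "g"))[[1 + seed %% 7]]
    ok <- length(unique(md$g)) == 3 && length(unique(md$h)) == 2
    if (ok) return(list(y = y, md = md, terms = terms))
    seed <- seed + 1000
  }
}

## Classical sequential (Type I) F via lm/anova, the independent oracle.
classical_F <- function(y, md, terms) {
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  md$y <- y
  a <- stats::anova(stats::lm(f, data = md))
  stats::setNames(a[seq_along(terms), "F value"], rownames(a)[seq_along(terms)])
}

## Covariate model with identical marginals across phenotypes: a cohort in
## which no covariate is associated with phenotype, for calibration tests of
## the cohort table.
null_covariate_model <- function() {
  ph <- c("ileal_CD", "colitis", "control")
  pr <- function(x) stats::setNames(rep(x, 3), ph)
  list(
    nod2_r = pr(0.3), atg16l1_nrnr = pr(0.25), gender_male = pr(0.5),
    race_caucasian = pr(0.85),
    age = list(median = pr(45), min = pr(18), max = pr(75)),
    smoker = pr(0.2), cdiff = pr(0.1),
    bmi = list(median = pr(25), min = pr(16), max = pr(45)),
    asa5 = pr(0.3), steroids = pr(0.3), immunomodulators = pr(0.3),
    anti_tnf = stats::setNames(rep(list(c(current = 0.2, past = 0.1, never = 0.7)), 3), ph)
  )
}

## A tiny deterministic count table over the seven categories.
toy_counts <- function(rows) {
  df <- data.frame(subject_id = paste0("s", seq_len(nrow(rows))), rows,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[-1] <- CATEGORIES7
  df
}
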