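#' Pearson chi-square test for an r x c contingency table
#'
#' No continuity correction, asymptotic p-value -- the standard comparison
#' of categorical covariates between phenotypes. A zero row or column
#' marginal makes the expected counts degenerate and is an error.
#'
#' @param table integer matrix of counts, at least 2 x 2.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) stop("need at least a 2 x 2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero row or column marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1 df;
#' used for the continuous covariates (age, BMI). All values identical is
#' handled as H = 0, p = 1.
#'
#' @param values numeric vector.
#' @param groups grouping vector (>= 2 nonempty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("need at least 2 nonempty groups")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

## Which test each cohort variable gets, and how it is displayed.
cohort_variable_spec <- function() {
  data.frame(
    variable = c("nod2", "atg16l1", "gender", "race", "age", "smoker",
                 "cdiff", "bmi", "asa5", "steroids", "immunomodulators",
                 "anti_tnf"),
    type = c("categorical", "categorical", "categorical", "categorical",
             "continuous", "categorical", "categorical", "continuous",
             "categorical", "categorical", "categorical", "categorical"),
    stringsAsFactors = FALSE
  )
}

#' Cohort characteristics table with per-variable tests and FDR
#'
#' For each variable, a chi-square test (categorical, including the 3-level
#' anti-TNF variable tested as a single block) or Kruskal-Wallis test
#' (continuous) of differences between phenotypes, with BH-FDR across the
#' table. Categorical variables are summarised as per-phenotype percentages
#' of the non-reference level (or of each level for >2 levels), continuous
#' ones as median (range).
#'
#' @param metadata validated metadata.
#' @param variables variable names with declared types; defaults to the 12
#'   tested cohort variables (phenotype is the grouping, not a row).
#' @return data.frame with one row per variable: the per-phenotype summary,
#'   `p` and `fdr`.
#' @export
cohort_table <- function(metadata, variables = cohort_variable_spec()) {
  stopifnot(all(variables$variable %in% names(metadata)))
  ph <- factor(metadata$phenotype, levels = c("ileal_CD", "colitis", "control"))
  rows <- lapply(seq_len(nrow(variables)), function(i) {
    v <- variables$variable[i]
    x <- metadata[[v]]
    ok <- !is.na(x) & !is.na(ph)
    if (variables$type[i] == "continuous") {
      res <- kruskal_wallis(x[ok], ph[ok])
      summ <- vapply(levels(ph), function(l) {
        xi <- x[ok & ph == l]
        sprintf("%.0f (%.0f-%.0f)", stats::median(xi), min(xi), max(xi))
      }, character(1))
    } else {
      tab <- table(factor(x[ok]), droplevels(ph[ok]))
      res <- chi_square(tab)
      show_level <- utils::tail(sort(unique(as.character(x[ok]))), 1L)
      summ <- vapply(levels(ph), function(l) {
        xi <- x[ok & ph == l]
        sprintf("%.0f%%", 100 * mean(as.character(xi) == show_level))
      }, character(1))
    }
    data.frame(variable = v, t(summ), p = res$p,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:4] <- levels(ph)
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
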