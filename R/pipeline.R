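#' Pipeline run configuration
#'
#' @param simulate list of [sim_config()] arguments (a synthetic run), or
#'   NULL when `inputs` is given.
#' @param inputs list with `metadata` (CSV path), `counts` (named list of
#'   TSV paths per platform) and optionally `qpcr` (named list of CSV paths
#'   per target); ignored when `simulate` is given.
#' @param pool_vars covariates forming the candidate pool (defaults to the
#'   13 cohort variables).
#' @param interactions include all first-order interactions in the pool.
#' @param alpha stepwise entry threshold.
#' @param B permutations per test.
#' @param seed master seed (required; every stage derives its stream from it).
#' @param pseudocount CLR pseudocount.
#' @param epsilon empirical-logit epsilon; NULL = half the smallest nonzero
#'   observed relative frequency per target.
#' @param min_reads sample exclusion threshold on total reads.
#' @param outdir where [run_pipeline()] writes its result bundle.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(simulate = list(), inputs = NULL,
                       pool_vars = c("phenotype", "nod2", "atg16l1", "gender",
                                     "race", "age", "smoker", "cdiff", "bmi",
                                     "asa5", "steroids", "immunomodulators",
                                     "anti_tnf"),
                       interactions = TRUE, alpha = 0.05, B = 999L, seed,
                       pseudocount = 0.5, epsilon = NULL, min_reads = 100L,
                       outdir = "clrperm_results") {
  if (missing(seed)) stop("seed is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (B < 1L) stop("B must be >= 1")
  structure(list(simulate = simulate, inputs = inputs, pool_vars = pool_vars,
                 interactions = interactions, alpha = alpha, B = as.integer(B),
                 seed = as.integer(seed), pseudocount = pseudocount,
                 epsilon = epsilon, min_reads = min_reads, outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys are [run_config()] arguments.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

result_table <- function(x) {
  if (inherits(x, "stepwise_trace")) {
    if (is.null(x$final))
      return(data.frame(term = character(0), kind = character(0),
                        R2 = numeric(0), p = numeric(0), fdr = numeric(0),
                        stringsAsFactors = FALSE))
    x <- x$final
  }
  tab <- x$table
  if (is.null(tab$fdr)) tab$fdr <- bh_fdr(tab$p)
  tab[, c("term", "kind", "R2", "p", "fdr")]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' simulate (or ingest) -> filter low-read samples -> CLR transform ->
#' per-platform permutation MANCOVA with stepwise selection -> per-category
#' permutation ANCOVAs -> repeated-measures ANCOVA on the union of selected
#' terms per category -> empirical-logit qPCR ANCOVAs -> cohort table.
#' Writes one TSV per result table plus a `manifest.yaml` (full config,
#' seed, package and R versions) under `config$outdir`; identical configs
#' produce byte-identical bundles.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all result tables and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  ## ingest -----------------------------------------------------------------
  if (!is.null(config$inputs)) {
    inp <- config$inputs
    metadata <- stage("read_metadata", read_metadata(inp$metadata))
    counts <- stage("read_counts", {
      out <- list()
      for (plat in names(inp$counts)) out[[plat]] <- read_counts(inp$counts[[plat]], plat)
      out
    })
    qpcr <- NULL
    if (!is.null(inp$qpcr))
      qpcr <- stage("read_qpcr", lapply(inp$qpcr, read_qpcr))
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- stage("simulate", simulate_cohort(do.call(sim_config, sim_args)))
    metadata <- cohort$metadata
    counts <- cohort$counts
    qpcr <- cohort$qpcr
  }

  ## filter + align ---------------------------------------------------------
  counts <- stage("filter_min_reads",
                  lapply(counts, filter_min_reads, threshold = config$min_reads))
  aligned <- stage("align_tables", align_tables(metadata, counts, qpcr))

  tables <- list()
  tables$cohort <- stage("cohort_table", cohort_table(metadata))

  pool <- candidate_pool(config$pool_vars, config$interactions)

  ## per-platform MANCOVA with stepwise selection ---------------------------
  tables$mancova <- list()
  for (plat in names(aligned$per_platform)) {
    pp <- aligned$per_platform[[plat]]
    m <- complete_for(pp$metadata, config$pool_vars)
    ct <- pp$counts[match(m$subject_id, pp$counts$subject_id), , drop = FALSE]
    comp <- clr_transform(ct, config$pseudocount)
    d <- euclidean_distances(comp)
    tables$mancova[[plat]] <- stage(paste0("mancova_", plat),
      stepwise_select(d, pool, m, alpha = config$alpha, B = config$B,
                      seed = config$seed))
  }

  ## per-category ANCOVA per platform, then repeated measures ---------------
  tables$ancova <- list()
  union_terms <- stats::setNames(vector("list", length(CATEGORIES6)), CATEGORIES6)
  for (plat in names(aligned$per_platform)) {
    pp <- aligned$per_platform[[plat]]
    m <- complete_for(pp$metadata, config$pool_vars)
    ct <- pp$counts[match(m$subject_id, pp$counts$subject_id), , drop = FALSE]
    comp <- clr_transform(ct, config$pseudocount)
    for (cat in CATEGORIES6) {
      sel <- stage(paste0("ancova_", plat, "_", cat),
        stepwise_select(comp[[cat]], pool, m, alpha = config$alpha,
                        B = config$B, seed = config$seed))
      tables$ancova[[paste(plat, cat, sep = ".")]] <- sel
      union_terms[[cat]] <- union(union_terms[[cat]], sel$trace$term)
    }
  }

  tables$repeated <- list()
  cm <- complete_for(aligned$complete$metadata, config$pool_vars)
  if (nrow(cm) >= 3L && length(aligned$complete$counts) >= 2L) {
    clr_by_plat <- lapply(aligned$complete$counts, function(ct)
      clr_transform(ct[match(cm$subject_id, ct$subject_id), , drop = FALSE],
                    config$pseudocount))
    for (cat in CATEGORIES6) {
      vals <- data.frame(subject_id = cm$subject_id, stringsAsFactors = FALSE)
      for (plat in names(clr_by_plat)) vals[[plat]] <- clr_by_plat[[plat]][[cat]]
      terms <- union_terms[[cat]]
      terms <- c(terms[!grepl(":", terms)], terms[grepl(":", terms)])  # mains first
      tables$repeated[[cat]] <- stage(paste0("repeated_", cat),
        rm_permutation_ancova(vals, terms, cm, B = config$B, seed = config$seed))
    }
  }

  ## qPCR empirical-logit ANCOVAs -------------------------------------------
  tables$qpcr <- list()
  if (!is.null(aligned$qpcr)) {
    for (target in names(aligned$qpcr)) {
      q <- aligned$qpcr[[target]]
      m <- complete_for(metadata[match(q$subject_id, metadata$subject_id), , drop = FALSE],
                        config$pool_vars)
      q <- q[match(m$subject_id, q$subject_id), , drop = FALSE]
      eps <- if (is.null(config$epsilon)) default_logit_epsilon(q$relative_frequency)
             else config$epsilon
      y <- empirical_logit(q$relative_frequency, eps)
      tables$qpcr[[target]] <- stage(paste0("qpcr_", target),
        stepwise_select(y, pool, m, alpha = config$alpha, B = config$B,
                        seed = config$seed))
    }
  }

  ## write bundle -----------------------------------------------------------
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  paths <- c(paths, write_tsv(tables$cohort, file.path(config$outdir, "cohort_table.tsv")))
  for (plat in names(tables$mancova))
    paths <- c(paths, write_tsv(result_table(tables$mancova[[plat]]),
                                file.path(config$outdir, paste0("mancova_", plat, ".tsv"))))
  anc <- do.call(rbind, lapply(names(tables$ancova), function(k) {
    tb <- result_table(tables$ancova[[k]])
    if (nrow(tb)) cbind(analysis = k, tb) else NULL
  }))
  if (is.null(anc))
    anc <- data.frame(analysis = character(0), term = character(0),
                      kind = character(0), R2 = numeric(0), p = numeric(0),
                      fdr = numeric(0))
  paths <- c(paths, write_tsv(anc, file.path(config$outdir, "ancova_per_category.tsv")))
  rep_tab <- do.call(rbind, lapply(names(tables$repeated), function(cat)
    cbind(category = cat, result_table(tables$repeated[[cat]]))))
  if (is.null(rep_tab))
    rep_tab <- data.frame(category = character(0), term = character(0),
                          kind = character(0), R2 = numeric(0), p = numeric(0),
                          fdr = numeric(0))
  paths <- c(paths, write_tsv(rep_tab, file.path(config$outdir, "repeated_measures.tsv")))
  for (target in names(tables$qpcr))
    paths <- c(paths, write_tsv(result_table(tables$qpcr[[target]]),
                                file.path(config$outdir, paste0("qpcr_", target, ".tsv"))))

  manifest <- list(config = unclass(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("clrperm")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."))
  manifest$config$simulate <- NULL  # full sim config may hold data.frames; store args below
  if (length(config$simulate))
    manifest$simulate_args <- lapply(config$simulate, function(x)
      if (is.data.frame(x)) as.list(x) else x)
  yaml::write_yaml(manifest, file.path(config$outdir, "manifest.yaml"))
  paths <- c(paths, file.path(config$outdir, "manifest.yaml"))

  invisible(list(tables = tables, paths = paths, aligned = aligned))
}
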