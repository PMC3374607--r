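## Canonical form for category / taxon names coming out of classifiers:
## case-insensitive, punctuation and whitespace stripped.
canon_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

METADATA_COLS <- c("subject_id", "phenotype", "nod2", "atg16l1", "gender",
                   "race", "age", "smoker", "cdiff", "bmi", "asa5",
                   "steroids", "immunomodulators", "anti_tnf")

validate_metadata <- function(df, source = "metadata") {
  missing_cols <- setdiff(METADATA_COLS, names(df))
  if (length(missing_cols))
    stop(source, " lacks required column(s): ", paste(missing_cols, collapse = ", "))
  ## rows with missing phenotype are rejected (dropped with a warning)
  bad_ph <- is.na(df$phenotype) | df$phenotype == ""
  if (any(bad_ph)) {
    warning(sum(bad_ph), " row(s) with missing phenotype rejected")
    df <- df[!bad_ph, , drop = FALSE]
  }
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in ", source, ": ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  enum <- list(phenotype = c("ileal_CD", "colitis", "control"),
               nod2 = c("NR", "R"),
               atg16l1 = c("NR/NR", "R/NR", "R/R"),
               gender = c("male", "female"),
               race = c("caucasian", "other"),
               anti_tnf = c("current", "past", "never"))
  for (v in names(enum)) {
    bad <- !is.na(df[[v]]) & !(df[[v]] %in% enum[[v]])
    if (any(bad))
      stop("invalid ", v, " value(s) in ", source, ": ",
           paste(unique(df[[v]][bad]), collapse = ", "))
  }
  for (v in c("age", "bmi")) {
    bad <- !is.na(df[[v]]) & df[[v]] <= 0
    if (any(bad))
      stop(v, " must be strictly positive; offending row(s): ",
           paste(which(bad), collapse = ", "))
  }
  for (v in c("smoker", "cdiff", "asa5", "steroids", "immunomodulators"))
    df[[v]] <- as.logical(df[[v]])
  df
}

#' Read and validate a subject metadata table
#'
#' CSV with `subject_id` first and the 13 cohort covariates. Rows with a
#' missing phenotype are dropped with a warning; a missing required column,
#' a duplicate subject id, an out-of-enumeration category or a non-positive
#' age/BMI is an error. Other missing values are kept as NA and counted --
#' subjects with an NA are dropped per-model downstream (see
#' [complete_for()]).
#'
#' @param path CSV file path.
#' @return validated metadata data.frame; attribute `n_missing` counts NA
#'   cells per covariate.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- validate_metadata(df, source = path)
  attr(df, "n_missing") <- colSums(is.na(df[setdiff(METADATA_COLS, "subject_id")]))
  df
}

#' Read a category count table
#'
#' Tab-separated `subject_id` x 7 named categories, one file per platform.
#'
#' @param path TSV file path.
#' @param platform optional platform label to attach (taken from the file's
#'   `platform` column when present).
#' @return data.frame with subject_id, the 7 integer category columns and a
#'   platform column.
#' @export
read_counts <- function(path, platform = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("subject_id", CATEGORIES7), names(df))
  if (length(missing_cols))
    stop(path, " lacks required column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in CATEGORIES7) {
    v <- df[[cc]]
    if (any(is.na(v)) || any(v < 0) || any(v != round(v)))
      stop("counts for ", cc, " must be non-negative integers in ", path)
    df[[cc]] <- as.numeric(v)
  }
  if (is.null(platform))
    platform <- if ("platform" %in% names(df) && nrow(df)) df$platform[1] else NA_character_
  df$platform <- rep(platform, nrow(df))
  df[, c("subject_id", CATEGORIES7, "platform")]
}

#' Read a qPCR relative-frequency table
#'
#' CSV with `subject_id`, `target`, `relative_frequency` (target copies /
#' total-bacteria copies). Values above 1 -- possible when target and total
#' assays use independent standard curves -- are clamped to 1 with a
#' warning; negative values are an error.
#'
#' @param path CSV file path.
#' @return data.frame with the three columns, relative_frequency in [0, 1].
#' @export
read_qpcr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "target", "relative_frequency")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(path, " lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (any(df$relative_frequency < 0, na.rm = TRUE))
    stop("negative relative_frequency in ", path)
  over <- !is.na(df$relative_frequency) & df$relative_frequency > 1
  if (any(over)) {
    warning(sum(over), " relative_frequency value(s) > 1 clamped to 1")
    df$relative_frequency[over] <- 1
  }
  df[, need]
}

#' Firmicutes subdivision lookup
#'
#' The classifier reports Firmicutes reads with lower-rank names; this
#' editable concordance maps those names to the Clostridium Group IV,
#' Clostridium Group XIVa or Bacillus subdivision. Shipped as plain CSV in
#' `inst/extdata/firmicutes_groups.csv` so the rule stays auditable; pass
#' your own table to [bin_lineages()] to change it.
#'
#' @return data.frame with columns `name` and `category`.
#' @export
firmicutes_lookup <- function() {
  path <- system.file("extdata", "firmicutes_groups.csv", package = "clrperm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bin per-read lineage assignments into the seven categories
#'
#' Actinobacteria, Bacteroidetes and Proteobacteria map directly by phylum;
#' Firmicutes reads are subdivided into Clostridium Group IV, Clostridium
#' Group XIVa or Bacillus by matching the `group` field (a class, family or
#' genus label) against the concordance lookup; every other phylum -- and
#' any Firmicutes read whose group is not in the lookup, or a row with an
#' empty phylum -- lands in `Other`. Name matching is case-insensitive with
#' punctuation stripped.
#'
#' @param assignments data.frame with `subject_id`, `phylum` and (for
#'   Firmicutes rows) `group` columns, one row per read.
#' @param lookup concordance data.frame (`name`, `category`); defaults to
#'   the shipped table.
#' @return count table: `subject_id` x the 7 category columns; attribute
#'   `n_unassigned` counts rows with an empty phylum (warned about).
#' @export
bin_lineages <- function(assignments, lookup = firmicutes_lookup()) {
  stopifnot(all(c("subject_id", "phylum") %in% names(assignments)))
  n <- nrow(assignments)
  phy <- canon_name(ifelse(is.na(assignments$phylum), "", assignments$phylum))
  grp <- if ("group" %in% names(assignments))
    canon_name(ifelse(is.na(assignments$group), "", assignments$group)) else rep("", n)
  lk <- stats::setNames(lookup$category, canon_name(lookup$name))

  cat_of <- rep("Other", n)
  cat_of[phy == "actinobacteria"] <- "Actinobacteria"
  cat_of[phy == "bacteroidetes"]  <- "Bacteroidetes"
  cat_of[phy == "proteobacteria"] <- "Proteobacteria"
  firm <- phy == "firmicutes"
  hit <- firm & grp %in% names(lk)
  cat_of[hit] <- lk[grp[hit]]
  n_empty <- sum(phy == "")
  if (n_empty) warning(n_empty, " row(s) with empty phylum counted as Other")

  ids <- unique(assignments$subject_id)
  tab <- table(factor(assignments$subject_id, levels = ids),
               factor(cat_of, levels = CATEGORIES7))
  out <- data.frame(subject_id = ids, unclass(as.matrix(tab)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_empty
  out
}

#' Drop samples with too few screened reads
#'
#' Samples whose total category count is strictly below `threshold` are
#' removed (the study rule: fewer than 100 total screened sequences).
#' Idempotent; an empty result is allowed.
#'
#' @param table category count table.
#' @param threshold minimum total reads to retain a sample (default 100).
#' @return filtered table; attribute `removed` lists the dropped subject
#'   ids and their totals.
#' @export
filter_min_reads <- function(table, threshold = 100L) {
  stopifnot(all(CATEGORIES7 %in% names(table)))
  tot <- rowSums(table[, CATEGORIES7])
  drop <- tot < threshold
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(subject_id = table$subject_id[drop],
                                     total = tot[drop],
                                     stringsAsFactors = FALSE)
  out
}

#' Join metadata, per-platform counts and qPCR tables on subject id
#'
#' Returns per-platform joined sets (metadata intersected with each
#' platform's samples) and the complete-case intersection across all
#' requested platforms, as needed for the repeated-measures analysis. All
#' returned tables are sorted by subject id and share identical id sets
#' within each join.
#'
#' @param metadata validated metadata.
#' @param counts named list of count tables (one per platform).
#' @param qpcr optional list of qPCR tables; joined on the intersection with
#'   metadata only.
#' @return list with `per_platform` (list of `list(metadata, counts)`),
#'   `complete` (list of `metadata` and per-platform `counts` restricted to
#'   subjects present everywhere), `qpcr`, and `exclusions` (per-source
#'   counts of subjects dropped).
#' @export
align_tables <- function(metadata, counts, qpcr = NULL) {
  stopifnot(is.list(counts), length(counts) >= 1L)
  ids_meta <- metadata$subject_id
  excl <- list()
  per_platform <- list()
  common <- ids_meta
  for (plat in names(counts)) {
    ids <- sort(intersect(ids_meta, counts[[plat]]$subject_id))
    if (!length(ids)) stop("empty intersection between metadata and platform ", plat)
    m <- metadata[match(ids, metadata$subject_id), , drop = FALSE]
    ct <- counts[[plat]][match(ids, counts[[plat]]$subject_id), , drop = FALSE]
    rownames(m) <- rownames(ct) <- NULL
    per_platform[[plat]] <- list(metadata = m, counts = ct)
    excl[[plat]] <- length(ids_meta) - length(ids)
    common <- intersect(common, ids)
  }
  common <- sort(common)
  if (!length(common)) stop("empty complete-case intersection across platforms")
  complete <- list(metadata = metadata[match(common, metadata$subject_id), , drop = FALSE],
                   counts = lapply(counts, function(ct)
                     ct[match(common, ct$subject_id), , drop = FALSE]))
  rownames(complete$metadata) <- NULL
  complete$counts <- lapply(complete$counts, function(x) { rownames(x) <- NULL; x })
  qpcr_joined <- NULL
  if (!is.null(qpcr)) {
    qpcr_joined <- lapply(qpcr, function(q) {
      ids <- sort(intersect(ids_meta, q$subject_id))
      out <- q[match(ids, q$subject_id), , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  }
  list(per_platform = per_platform, complete = complete, qpcr = qpcr_joined,
       exclusions = excl)
}

#' Complete-case subset for a set of covariates
#'
#' Subjects with a missing value in any of `vars` are dropped (the logged
#' count is returned as an attribute); models never impute.
#'
#' @param metadata metadata data.frame.
#' @param vars covariate names the model will use.
#' @return metadata subset; attribute `n_dropped`.
#' @export
complete_for <- function(metadata, vars) {
  vars <- unique(unlist(strsplit(vars, ":", fixed = TRUE)))
  keep <- stats::complete.cases(metadata[, vars, drop = FALSE])
  out <- metadata[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
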