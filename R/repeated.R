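#' Repeated-measures permutation ANCOVA across sequencing platforms
#'
#' Treats the per-platform values of one response (e.g. the CLR value of one
#' phylum/subphylum category) as repeated within-subject measurements. The
#' response is stacked long (one row per subject x platform) and partitioned
#' sequentially: the supplied between-subject terms first, in the given
#' order, then a `Measurements` factor distinguishing the platforms. Because
#' the design is balanced (complete cases only), the Measurements increment
#' is orthogonal to the between-subject columns and equals the
#' within-subject platform sum of squares.
#'
#' Two restricted permutation schemes give the p-values, matching the two
#' exchangeability units:
#' * between-subject terms: subjects are permuted as whole blocks (all
#'   platform rows move together), which leaves the platform sums - and
#'   hence the Measurements SS - invariant;
#' * Measurements: platform labels are shuffled independently within each
#'   subject, which leaves every between-subject SS invariant (subject
#'   totals are preserved).
#'
#' R-squared uses the total (stacked) sum of squares as denominator.
#'
#' @param values data.frame with `subject_id` and one numeric column per
#'   platform; complete cases only (no NA).
#' @param terms between-subject model terms, tested in this order.
#' @param metadata covariate data.frame with `subject_id` matching `values`.
#' @param B permutations per scheme (default 999).
#' @param seed integer; the block scheme uses `seed`, the within-subject
#'   scheme `seed + 1`.
#' @return `perm_partition` whose table carries the between terms plus a
#'   final `Measurements` row (kind `"measurements"`). With a single
#'   platform column the Measurements row is omitted and the result equals
#'   [univariate_permutation_test()] on that platform.
#' @export
rm_permutation_ancova <- function(values, terms, metadata, B = 999L, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(is.data.frame(values), "subject_id" %in% names(values))
  plat <- setdiff(names(values), "subject_id")
  k <- length(plat)
  if (k < 1L) stop("no platform columns in values")
  if (anyNA(values[plat]))
    stop("incomplete subjects in repeated-measures response; use align_tables() to form the complete-case set")
  m <- metadata[match(values$subject_id, metadata$subject_id), , drop = FALSE]
  if (anyNA(m$subject_id)) stop("subjects in values missing from metadata")
  n <- nrow(values)

  if (k == 1L)
    return(univariate_permutation_test(values[[plat]], terms, m, B = B, seed = seed))

  ## subject-major long stacking: block j occupies rows (j-1)k+1 .. jk
  y <- as.numeric(t(as.matrix(values[plat])))
  N <- n * k
  ml <- m[rep(seq_len(n), each = k), , drop = FALSE]
  ml$Measurements <- rep(plat, n)
  terms_all <- c(terms, "Measurements")
  des <- build_design(terms_all, ml)
  if (N <= des$p) stop("n must exceed the total model degrees of freedom")
  resp <- list(kind = "vec", y = y)
  obs <- seq_ss(resp, des)
  if (obs$total <= 1e-12 * N) stop("degenerate response: total sum of squares is zero")
  df_res <- N - des$p
  F_obs <- (obs$ss / des$df) / (obs$resid / df_res)
  thr <- F_tie_threshold(F_obs)

  nt <- length(terms)
  count <- numeric(nt + 1L)

  ## scheme 1: whole-subject blocks, for between-subject terms
  if (nt > 0L) {
    perms <- make_perms(n, B, seed)
    for (b in seq_len(B)) {
      lp <- rep((perms[, b] - 1L) * k, each = k) + rep(seq_len(k), n)
      s <- seq_ss(resp, des, perm = lp)
      Fb <- (s$ss / des$df) / (s$resid / df_res)
      count[seq_len(nt)] <- count[seq_len(nt)] +
        (Fb[seq_len(nt)] >= thr[seq_len(nt)])
    }
  }

  ## scheme 2: platform labels shuffled within each subject, for Measurements
  set.seed(seed + 1L)
  for (b in seq_len(B)) {
    wp <- as.vector(vapply(seq_len(n), function(j) (j - 1L) * k + sample.int(k),
                           integer(k)))
    s <- seq_ss(resp, des, perm = wp)
    Fb <- (s$ss / des$df) / (s$resid / df_res)
    count[nt + 1L] <- count[nt + 1L] + (Fb[nt + 1L] >= thr[nt + 1L])
  }

  p <- (1 + count) / (1 + B)
  tab <- partition_from_ss(terms_all, des, obs)
  tab$kind[nt + 1L] <- "measurements"
  tab$p <- p
  structure(list(table = tab, residual = obs$resid, df_residual = df_res,
                 total = obs$total, n = N, B = B, seed = seed,
                 exhaustive = FALSE),
            class = "perm_partition")
}
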