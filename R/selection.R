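#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1,
#' returned in the input order. Computed via [stats::p.adjust()]; this
#' wrapper adds the domain check used throughout the pipeline.
#'
#' @param pvalues numeric vector of p-values in `(0, 1]`.
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues <= 0 | pvalues > 1))
    stop("p-values must be in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Candidate term pool: main effects and all first-order interactions
#'
#' @param vars character vector of covariate names (the 13 cohort variables
#'   by default in the pipeline).
#' @param interactions include all unordered pairs as `"a:b"` terms.
#' @return character vector of terms, mains first.
#' @export
candidate_pool <- function(vars, interactions = TRUE) {
  stopifnot(length(vars) >= 1L, !anyDuplicated(vars))
  pool <- vars
  if (interactions && length(vars) >= 2L) {
    prs <- utils::combn(vars, 2L)
    pool <- c(pool, paste(prs[1L, ], prs[2L, ], sep = ":"))
  }
  pool
}

#' Forward stepwise term selection by permutation p-value
#'
#' At each step every not-yet-selected candidate is tested as the *last*
#' sequential term appended to the current model; all candidates within a
#' step share one permutation stream so their p-values are comparable at
#' fixed `B`. The candidate with the smallest permutation p enters if
#' `p <= alpha`. Ties -- frequent at the attainable p floor `1/(B+1)` --
#' are broken by the larger pseudo-F, i.e. the larger per-degree-of-freedom
#' increment, then by pool order; breaking on raw incremental R-squared
#' would systematically prefer many-column interaction blocks over the main
#' effect that actually carries the signal. Selection stops when no candidate passes, when every remaining
#' candidate would make the design rank-deficient (such candidates are
#' skipped, not fatal), or after `max_steps` entries. The final model is
#' re-partitioned once in selection order to produce the reported
#' R-squared/p table, and BH-FDR is applied across that table.
#'
#' @param response either a symmetric distance matrix (multivariate MANCOVA)
#'   or a numeric vector (univariate ANCOVA).
#' @param pool character vector of candidate terms (see [candidate_pool()]).
#' @param metadata covariate data.frame, complete cases for all pool
#'   variables.
#' @param alpha entry threshold on the permutation p-value (default 0.05).
#' @param B permutations per test (default 999).
#' @param seed master seed; step `s` uses stream `seed + s`, the final
#'   re-partition uses `seed` itself.
#' @param max_steps cap on the number of entries (default unlimited); useful
#'   when only the first entrants are of interest.
#' @return object of class `stepwise_trace`: list with `trace` (step, term,
#'   entry p and R2), `final` (a `perm_partition` with p and fdr columns, or
#'   NULL if nothing was selected), `stopping`, and `skipped`.
#' @export
stepwise_select <- function(response, pool, metadata, alpha = 0.05, B = 999L,
                            seed, max_steps = Inf) {
  if (missing(seed)) stop("seed is required")
  stopifnot(length(pool) >= 1L, alpha > 0, alpha < 1, B >= 1L)
  n <- nrow(metadata)
  is_gram <- is.matrix(response)
  if (is_gram) {
    stopifnot(nrow(response) == n)
    G <- gower_gram(response)
    total <- sum(diag(G))
  } else {
    stopifnot(is.numeric(response), length(response) == n, all(is.finite(response)))
    yc <- as.numeric(response) - mean(response)
    total <- sum(yc^2)
  }
  if (total <= 1e-12 * n) stop("degenerate response: total sum of squares is zero")

  selected <- character(0)
  skipped <- character(0)
  trace <- data.frame(step = integer(0), term = character(0),
                      p = numeric(0), R2 = numeric(0), stringsAsFactors = FALSE)
  stopping <- "max_steps reached"
  step <- 0L

  while (length(selected) < max_steps) {
    step <- step + 1L
    remaining <- setdiff(pool, selected)
    if (!length(remaining)) { stopping <- "pool exhausted"; break }

    base <- build_design(selected, metadata)  # intercept-only when empty
    perms <- make_perms(n, B, seed + step)
    if (is_gram) {
      Gp <- lapply(seq_len(B), function(b) G[perms[, b], perms[, b]])
      Hbase <- tcrossprod(base$Q)
      sbase_obs <- sum(Hbase * G)
      sbase <- vapply(Gp, function(g) sum(Hbase * g), numeric(1))
    } else {
      Yp <- apply(perms, 2L, function(p) yc[p])
      Zb <- crossprod(base$Q, Yp)
      sbase_obs <- sum(as.numeric(crossprod(base$Q, yc))^2)
      sbase <- colSums(Zb^2)
    }

    best <- NULL
    Xbase_cols <- base$p
    for (ci in seq_along(remaining)) {
      cand <- remaining[ci]
      M <- term_matrix(cand, metadata)
      ## reconstruct base X implicitly through Q: orthonormal basis suffices
      qrc <- qr(cbind(base$Q, M))
      dfc <- ncol(M)
      if (dfc == 0L || qrc$rank < Xbase_cols + dfc) {
        skipped <- c(skipped, cand)
        next
      }
      Qc <- qr.Q(qrc)[, (Xbase_cols + 1L):(Xbase_cols + dfc), drop = FALSE]
      df_res <- n - Xbase_cols - dfc
      if (df_res <= 0L) { skipped <- c(skipped, cand); next }
      if (is_gram) {
        ss_obs <- sum(crossprod(Qc, G) * t(Qc))
        ssc <- vapply(Gp, function(g) sum(crossprod(Qc, g) * t(Qc)), numeric(1))
      } else {
        ss_obs <- sum(as.numeric(crossprod(Qc, yc))^2)
        ssc <- colSums(crossprod(Qc, Yp)^2)
      }
      F_obs <- (ss_obs / dfc) / ((total - sbase_obs - ss_obs) / df_res)
      Fb <- (ssc / dfc) / ((total - sbase - ssc) / df_res)
      p <- (1 + sum(Fb >= F_tie_threshold(F_obs))) / (1 + B)
      r2 <- ss_obs / total
      if (is.null(best) || p < best$p ||
          (p == best$p && F_obs > best$F + 1e-12)) {
        best <- list(term = cand, p = p, r2 = r2, F = F_obs)
      }
    }

    if (is.null(best)) { stopping <- "all remaining candidates rank-deficient"; break }
    if (best$p > alpha) { stopping <- "no candidate below alpha"; break }
    selected <- c(selected, best$term)
    trace <- rbind(trace, data.frame(step = step, term = best$term,
                                     p = best$p, R2 = best$r2,
                                     stringsAsFactors = FALSE))
  }

  final <- NULL
  if (length(selected)) {
    final <- if (is_gram)
      permutation_test(response, selected, metadata, B = B, seed = seed)
    else
      univariate_permutation_test(response, selected, metadata, B = B, seed = seed)
    final$table$fdr <- bh_fdr(final$table$p)
  }
  structure(list(trace = trace, final = final, stopping = stopping,
                 skipped = unique(skipped), alpha = alpha, B = B, seed = seed),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  if (!nrow(x$trace)) {
    cat("No terms selected (", x$stopping, ")\n", sep = "")
  } else {
    cat("Selected terms (entry order):\n")
    tr <- x$trace; tr$p <- signif(tr$p, 4); tr$R2 <- signif(tr$R2, 4)
    print(tr, row.names = FALSE)
    cat("Stopping: ", x$stopping, "\nFinal model partition:\n", sep = "")
    print(x$final)
  }
  if (length(x$skipped))
    cat("Skipped (rank-deficient):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
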