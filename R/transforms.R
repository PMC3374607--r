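#' Centered log-ratio transform of category counts
#'
#' Drops the `Other` category, adds a pseudocount to the six remaining counts
#' and applies the centered log-ratio (CLR) transform
#' \eqn{clr_i = \ln x_i - \frac{1}{D}\sum_j \ln x_j}. Because the geometric
#' mean is divided out, the result is identical whether computed on adjusted
#' counts or on their closed proportions (scale invariance), and each row
#' sums to zero, which makes Euclidean distances between rows the Aitchison
#' distance between compositions.
#'
#' @param counts data.frame with a `subject_id` column and the seven category
#'   count columns (`CATEGORIES7`), or at least the six of `CATEGORIES6`.
#' @param pseudocount positive value added to each count before the log;
#'   default 0.5, which keeps zero counts finite.
#' @return data.frame with `subject_id` and the six CLR columns; the
#'   `platform` column is carried through when present.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  stopifnot(is.data.frame(counts))
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  missing_cols <- setdiff(CATEGORIES6, names(counts))
  if (length(missing_cols))
    stop("counts table lacks category columns: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(counts[, CATEGORIES6, drop = FALSE])
  if (ncol(x) < 2L) stop("need at least 2 categories for a log-ratio transform")
  if (any(x < 0)) stop("negative counts")
  lx <- log(x + pseudocount)
  clr <- lx - rowMeans(lx)
  out <- data.frame(subject_id = counts$subject_id, clr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(counts$platform)) out$platform <- counts$platform
  out
}

#' Empirical logit
#'
#' `ln((p + eps) / (1 - p + eps))`: a logit that stays finite at relative
#' frequencies of exactly 0 or 1, as needed for qPCR copy-number ratios.
#' Strictly increasing in `p` and antisymmetric about `p = 0.5`.
#'
#' @param p proportions in `[0, 1]` (vectorised).
#' @param epsilon positive smoothing constant. The default used downstream is
#'   half the smallest nonzero observed relative frequency (see
#'   [default_logit_epsilon()]); no single constant is canonical for ratio
#'   data, so the value is always explicit here.
#' @return numeric vector of transformed values.
#' @export
empirical_logit <- function(p, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("epsilon must be a single positive number")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  log((p + epsilon) / (1 - p + epsilon))
}

#' Data-adaptive epsilon for the empirical logit
#'
#' Half the smallest nonzero relative frequency observed, so that zero
#' observations map below every nonzero one; falls back to 0.025 when all
#' values are zero.
#'
#' @param p vector of proportions.
#' @return positive scalar.
#' @export
default_logit_epsilon <- function(p) {
  nz <- p[!is.na(p) & p > 0]
  if (!length(nz)) return(0.025)
  min(nz) / 2
}
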