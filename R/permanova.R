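#' Euclidean distance matrix between CLR vectors
#'
#' Pairwise Euclidean distances between the CLR rows; on CLR-transformed
#' compositions this is the Aitchison distance, the geometry under which the
#' distance-based MANCOVA partition equals a classical multivariate ANOVA.
#'
#' @param comp data.frame from [clr_transform()] (or any data.frame with
#'   `subject_id` and numeric response columns).
#' @return symmetric matrix with subject ids as dimnames.
#' @export
euclidean_distances <- function(comp) {
  stopifnot(is.data.frame(comp), nrow(comp) >= 2L)
  num <- vapply(comp, is.numeric, logical(1)) & names(comp) != "subject_id"
  x <- as.matrix(comp[, num, drop = FALSE])
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(comp$subject_id, comp$subject_id)
  d
}

## ---- design construction -------------------------------------------------

## One term is "var" (main effect) or "var1:var2" (first-order interaction).
## Categorical variables get full-rank treatment dummies with the
## lexicographically first level as reference; numerics enter linearly;
## interaction columns are elementwise products of the parent encodings,
## with continuous parents mean-centered first -- raw-scale products of a
## dummy with an uncentered covariate nearly duplicate the main effect's
## column space, which would let interactions impersonate their parents
## during selection.
encode_variable <- function(v, name, center = FALSE) {
  if (is.numeric(v)) {
    m <- matrix(if (center) as.numeric(v) - mean(v) else as.numeric(v), ncol = 1)
    colnames(m) <- name
    return(m)
  }
  f <- factor(v)  # levels() sorts lexicographically for character input
  lv <- levels(f)
  if (length(lv) < 2L) {
    m <- matrix(numeric(0), nrow = length(v), ncol = 0)
    return(m)
  }
  m <- vapply(lv[-1L], function(l) as.numeric(f == l), numeric(length(v)))
  m <- matrix(m, nrow = length(v))
  colnames(m) <- paste0(name, lv[-1L])
  m
}

term_components <- function(term) strsplit(term, ":", fixed = TRUE)[[1L]]

term_matrix <- function(term, metadata) {
  comp <- term_components(term)
  if (!all(comp %in% names(metadata)))
    stop("unknown covariate(s) in term '", term, "': ",
         paste(setdiff(comp, names(metadata)), collapse = ", "))
  for (v in comp)
    if (anyNA(metadata[[v]]))
      stop("covariate '", v, "' has missing values; drop incomplete subjects first")
  if (length(comp) == 1L) return(encode_variable(metadata[[comp]], comp))
  if (length(comp) != 2L) stop("only first-order interactions are supported: ", term)
  a <- encode_variable(metadata[[comp[1L]]], comp[1L], center = TRUE)
  b <- encode_variable(metadata[[comp[2L]]], comp[2L], center = TRUE)
  if (ncol(a) == 0L || ncol(b) == 0L)
    return(matrix(numeric(0), nrow = nrow(metadata), ncol = 0))
  out <- matrix(0, nrow(metadata), ncol(a) * ncol(b))
  cn <- character(ncol(out))
  k <- 0L
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    k <- k + 1L
    out[, k] <- a[, i] * b[, j]
    cn[k] <- paste0(colnames(a)[i], ":", colnames(b)[j])
  }
  colnames(out) <- cn
  out
}

## Cumulative design: intercept then each term's block, QR-orthonormalised.
## Returns Q (n x (1+sum df)), per-term column index list and df; errors (or
## flags, when `strict = FALSE`) on a term whose block does not raise the
## design rank by its full column count.
build_design <- function(terms, metadata, strict = TRUE) {
  n <- nrow(metadata)
  X <- matrix(1, n, 1)
  idx <- vector("list", length(terms))
  df <- integer(length(terms))
  rank <- 1L
  for (i in seq_along(terms)) {
    M <- term_matrix(terms[i], metadata)
    Xtry <- cbind(X, M)
    r <- qr(Xtry)$rank
    if (ncol(M) == 0L || r < rank + ncol(M)) {
      if (strict)
        stop("rank-deficient cumulative design at term '", terms[i], "'")
      return(list(ok = FALSE, offending = terms[i]))
    }
    idx[[i]] <- (ncol(X) + 1L):(ncol(Xtry))
    df[i] <- ncol(M)
    X <- Xtry
    rank <- r
  }
  qrX <- qr(X)
  list(ok = TRUE, Q = qr.Q(qrX), idx = idx, df = df, p = ncol(X), n = n)
}

## ---- Gower centering and sums of squares ---------------------------------

## G = -(1/2) C d^2 C with C = I - 11'/n; tr(G) is the total sum of squares.
gower_gram <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(abs(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  A <- -0.5 * d^2
  rm_ <- rowMeans(A)
  A - outer(rm_, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) + mean(A)
}

## Sequential SS of every term plus residual, for a response given either as
## a Gower gram matrix (multivariate, via tr(dH G)) or as a numeric vector
## (univariate fast path, identical by G = y_c y_c'). `perm` permutes the
## response against the fixed design.
seq_ss <- function(resp, des, perm = NULL) {
  Q <- des$Q
  if (resp$kind == "gram") {
    G <- if (is.null(perm)) resp$G else resp$G[perm, perm]
    ss <- vapply(seq_along(des$idx), function(i) {
      Qi <- Q[, des$idx[[i]], drop = FALSE]
      sum((crossprod(Qi, G)) * t(Qi))
    }, numeric(1))
    total <- sum(diag(G))
  } else {
    y <- if (is.null(perm)) resp$y else resp$y[perm]
    yc <- y - mean(y)
    z <- as.numeric(crossprod(Q, yc))
    ss <- vapply(des$idx, function(ix) sum(z[ix]^2), numeric(1))
    total <- sum(yc^2)
  }
  resid <- total - sum(ss)
  list(ss = ss, resid = max(resid, 0), total = total)
}

partition_from_ss <- function(terms, des, ss) {
  df_res <- des$n - des$p
  Fv <- (ss$ss / des$df) / (ss$resid / df_res)
  data.frame(
    term = terms,
    kind = ifelse(grepl(":", terms, fixed = TRUE), "interaction", "main"),
    df = des$df,
    SS = ss$ss,
    R2 = ss$ss / ss$total,
    F = Fv,
    stringsAsFactors = FALSE
  )
}

## ---- public partition / permutation tests --------------------------------

#' Sequential distance-based partition (no permutations)
#'
#' Partitions the total sum of squares of a distance matrix among an ordered
#' list of model terms via Gower centering, \eqn{G = -\frac{1}{2} C d^2 C},
#' and projection operators of the cumulative design:
#' \eqn{SS_{term} = tr(\Delta H \, G)}, pseudo-F =
#' (SS_term/df_term)/(SS_res/df_res). The partition is sequential (Type I):
#' each term's SS is its increment over the terms listed before it, so the
#' result depends on term order.
#'
#' @param d symmetric distance matrix (see [euclidean_distances()]).
#' @param terms character vector; `"var"` for a main effect,
#'   `"var1:var2"` for a first-order interaction, tested in this order.
#' @param metadata data.frame of covariates, rows aligned with `d`.
#' @return object of class `perm_partition`: a list with `table` (per-term
#'   df, SS, R2, F), `residual`, `total`, `n`.
#' @export
dm_partition <- function(d, terms, metadata) {
  stopifnot(nrow(metadata) == nrow(d))
  des <- build_design(terms, metadata)
  G <- gower_gram(d)
  total <- sum(diag(G))
  if (total <= 1e-12 * nrow(d)) stop("degenerate response: total sum of squares is zero")
  if (des$n <= des$p) stop("n must exceed the total model degrees of freedom")
  ss <- seq_ss(list(kind = "gram", G = G), des)
  tab <- partition_from_ss(terms, des, ss)
  structure(list(table = tab, residual = ss$resid, df_residual = des$n - des$p,
                 total = ss$total, n = des$n),
            class = "perm_partition")
}

#' @export
print.perm_partition <- function(x, ...) {
  tab <- x$table
  tab$SS <- signif(tab$SS, 5); tab$R2 <- signif(tab$R2, 4); tab$F <- signif(tab$F, 5)
  if (!is.null(tab$p)) tab$p <- signif(tab$p, 4)
  if (!is.null(tab$fdr)) tab$fdr <- signif(tab$fdr, 4)
  print(tab, row.names = FALSE)
  cat(sprintf("Residual SS %.5g on %d df; total SS %.5g; n = %d\n",
              x$residual, x$df_residual, x$total, x$n))
  if (!is.null(x$B)) cat(sprintf("%s permutations, seed %d\n",
                                 if (isTRUE(x$exhaustive)) "exhaustive" else format(x$B), x$seed))
  invisible(x)
}

## Tail comparisons "F_b >= F_obs" count mathematical ties: permutations that
## tie the observed statistic exactly can differ from it by rounding when the
## sums are accumulated in a different order, so the comparison uses a small
## relative slack. This keeps p invariant under affine rescaling of the
## response and makes exhaustive-mode p equal the true tail proportion on
## tied designs.
F_tie_threshold <- function(F_obs) F_obs - 1e-8 * pmax(1, abs(F_obs))

make_perms <- function(n, B, seed) {
  set.seed(seed)
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

all_perms <- function(n) {
  if (n > 8L) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n, ncol = n * ncol(sub))
  k <- 0L
  for (pos in seq_len(n)) for (j in seq_len(ncol(sub))) {
    k <- k + 1L
    out[, k] <- append(sub[, j], n, after = pos - 1L)
  }
  out
}

perm_engine <- function(resp, d_or_null, terms, metadata, B, seed, exhaustive) {
  des <- build_design(terms, metadata)
  n <- des$n
  if (n <= des$p) stop("n must exceed the total model degrees of freedom")
  obs <- seq_ss(resp, des)
  if (obs$total <= 1e-12 * n) stop("degenerate response: total sum of squares is zero")
  df_res <- n - des$p
  F_obs <- (obs$ss / des$df) / (obs$resid / df_res)
  thr <- F_tie_threshold(F_obs)

  if (exhaustive) {
    perms <- all_perms(n)
    nb <- ncol(perms)
    count <- numeric(length(terms))
    for (b in seq_len(nb)) {
      s <- seq_ss(resp, des, perm = perms[, b])
      Fb <- (s$ss / des$df) / (s$resid / df_res)
      count <- count + (Fb >= thr)
    }
    p <- count / nb  # identity permutation is among the nb labelings
  } else {
    stopifnot(B >= 1)
    perms <- make_perms(n, B, seed)
    count <- numeric(length(terms))
    for (b in seq_len(B)) {
      s <- seq_ss(resp, des, perm = perms[, b])
      Fb <- (s$ss / des$df) / (s$resid / df_res)
      count <- count + (Fb >= thr)
    }
    p <- (1 + count) / (1 + B)
  }
  tab <- partition_from_ss(terms, des, obs)
  tab$p <- p
  structure(list(table = tab, residual = obs$resid, df_residual = df_res,
                 total = obs$total, n = n,
                 B = if (exhaustive) ncol(perms) else B,
                 seed = if (exhaustive) NA_integer_ else seed,
                 exhaustive = exhaustive),
            class = "perm_partition")
}

#' Permutation MANCOVA on a distance matrix
#'
#' Sequential partition as in [dm_partition()], with per-term p-values from
#' permuting whole metadata rows against the fixed distance matrix. All terms
#' are evaluated on the same permutation stream. In Monte-Carlo mode
#' \eqn{p = (1 + \#\{F_b \ge F_{obs}\}) / (1 + B)}, so p can never be 0 and
#' the smallest attainable value is `1/(B+1)`. With `exhaustive = TRUE`
#' (n <= 8) every one of the n! relabelings is enumerated and p is the plain
#' tail proportion (identity included, no +1 correction).
#'
#' @inheritParams dm_partition
#' @param B number of Monte-Carlo permutations (default 999).
#' @param seed integer seed for the permutation stream (required).
#' @param exhaustive enumerate all n! permutations instead of sampling.
#' @return `perm_partition` with a `p` column.
#' @export
permutation_test <- function(d, terms, metadata, B = 999L, seed, exhaustive = FALSE) {
  stopifnot(nrow(metadata) == nrow(d))
  if (!exhaustive && missing(seed)) stop("seed is required")
  if (exhaustive) seed <- NA_integer_
  G <- gower_gram(d)
  perm_engine(list(kind = "gram", G = G), d, terms, metadata, B, seed, exhaustive)
}

#' Univariate permutation ANCOVA
#'
#' The same engine as [permutation_test()] applied to a scalar response:
#' the implied distance is `|y_i - y_j|`, whose Gower gram matrix is the
#' outer product of the centered response, so the pseudo-F equals the
#' classical sequential ANOVA/ANCOVA F exactly. Used for single CLR
#' categories and empirical-logit qPCR values.
#'
#' @param y numeric response vector.
#' @inheritParams permutation_test
#' @return `perm_partition` with a `p` column.
#' @export
univariate_permutation_test <- function(y, terms, metadata, B = 999L, seed,
                                        exhaustive = FALSE) {
  stopifnot(is.numeric(y), length(y) == nrow(metadata), all(is.finite(y)))
  if (!exhaustive && missing(seed)) stop("seed is required")
  if (exhaustive) seed <- NA_integer_
  perm_engine(list(kind = "vec", y = as.numeric(y)), NULL, terms, metadata,
              B, seed, exhaustive)
}
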