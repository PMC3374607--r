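test_that("euclidean distances match a brute-force pairwise loop", {
  set.seed(2)
  comp <- data.frame(subject_id = paste0("s", 1:5), matrix(rnorm(30), 5))
  d <- euclidean_distances(comp)
  x <- as.matrix(comp[, -1])
  for (i in 1:5) for (j in 1:5)
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  expect_equal(diag(d), setNames(rep(0, 5), comp$subject_id))
  ## two explicit rows: (0,...,0) vs (1,0,...,0,-1) are sqrt(2) apart
  comp2 <- data.frame(subject_id = c("a", "b"),
                      rbind(rep(0, 6), c(1, 0, 0, 0, 0, -1)))
  expect_equal(euclidean_distances(comp2)["a", "b"], sqrt(2))
})

test_that("partition reproduces the hand-computed one-way ANOVA", {
  ## y = (1,2,3,10,11,12), groups AAABBB: SS_between = 121.5, SS_within = 4,
  ## F = (121.5/1)/(4/4) = 121.5
  y <- c(1, 2, 3, 10, 11, 12)
  md <- data.frame(g = rep(c("A", "B"), each = 3))
  d <- abs(outer(y, y, "-")); diag(d) <- 0
  pr <- dm_partition(d, "g", md)
  expect_equal(pr$table$SS, 121.5)
  expect_equal(pr$residual, 4)
  expect_equal(pr$table$F, 121.5)
  expect_equal(pr$table$R2, 121.5 / 125.5)
})

test_that("degenerate and invalid inputs error informatively", {
  md <- data.frame(g = rep(c("A", "B"), each = 3))
  d0 <- matrix(0, 6, 6)
  expect_error(dm_partition(d0, "g", md), "degenerate response")
  y <- rnorm(6)
  d <- abs(outer(y, y, "-"))
  md$g2 <- md$g  # duplicate factor makes the cumulative design rank-deficient
  expect_error(dm_partition(d, c("g", "g2"), md), "rank-deficient.*g2")
  expect_error(dm_partition(d, "nope", md), "unknown covariate")
})

test_that("total and residual SS are invariant to term order", {
  set.seed(3)
  n <- 20
  md <- data.frame(g = sample(c("a", "b"), n, TRUE), x = rnorm(n),
                   h = sample(c("u", "v"), n, TRUE))
  d <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  orders <- list(c("g", "x", "h"), c("h", "g", "x"), c("x", "h", "g"))
  prs <- lapply(orders, function(tt) dm_partition(d, tt, md))
  for (pr in prs) {
    expect_equal(pr$total, prs[[1]]$total, tolerance = 1e-10)
    expect_equal(pr$residual, prs[[1]]$residual, tolerance = 1e-10)
    expect_equal(sum(pr$table$SS) + pr$residual, pr$total, tolerance = 1e-8)
  }
})

test_that("univariate pseudo-F equals classical sequential ANOVA/ANCOVA F", {
  ## battery of random small designs against the lm/anova oracle
  for (seed in 1:20) {
    des <- random_small_design(seed)
    got <- univariate_permutation_test(des$y, des$terms, des$md, B = 3, seed = 1)
    expect_equal(unname(got$table$F), unname(classical_F(des$y, des$md, des$terms)),
                 tolerance = 1e-10, label = paste("design seed", seed))
  }
})

test_that("exhaustive enumeration reproduces the worked 4-sample case", {
  ## y = (1,2,3,4), groups AABB: F for the observed split is 8.0 and two of
  ## the six distinct labelings (the split and its mirror) reach it: p = 2/6
  y <- c(1, 2, 3, 4)
  md <- data.frame(g = c("A", "A", "B", "B"))
  pe <- univariate_permutation_test(y, "g", md, exhaustive = TRUE)
  expect_equal(pe$table$F, 8)
  expect_equal(pe$table$p, 2 / 6, tolerance = 1e-12)
})

test_that("exhaustive p equals an independent enumeration oracle", {
  set.seed(4)
  y <- c(0.3, 1.2, -0.5, 2.1, 0.9, -1.3)
  md <- data.frame(g = c("A", "A", "B", "B", "C", "C"))
  pe <- univariate_permutation_test(y, "g", md, exhaustive = TRUE)
  ## oracle: enumerate all 6! relabelings, compute classical F via lm each time
  perms <- clrperm:::all_perms(6)
  F_of <- function(yy) {
    a <- stats::anova(stats::lm(yy ~ g, data = md))
    a[1, "F value"]
  }
  F_obs <- F_of(y)
  ## count mathematical ties: relabelings that preserve the group partition
  ## reproduce F_obs only up to summation-order rounding
  tie_thr <- F_obs - 1e-8 * max(1, abs(F_obs))
  tail_count <- sum(vapply(seq_len(ncol(perms)),
                           function(b) F_of(y[perms[, b]]) >= tie_thr, logical(1)))
  expect_equal(pe$table$p, tail_count / factorial(6), tolerance = 1e-12)
  ## Monte-Carlo mode converges to the exhaustive proportion
  pm <- univariate_permutation_test(y, "g", md, B = 1999, seed = 9)
  se <- sqrt(pe$table$p * (1 - pe$table$p) / 1999)
  expect_lt(abs(pm$table$p - pe$table$p), 3 * se + 2 / 2000)
})

test_that("permutation p has the +1/+1 floor and is deterministic", {
  y <- c(1, 2, 3, 10, 11, 12)
  md <- data.frame(g = rep(c("A", "B"), each = 3))
  p1 <- univariate_permutation_test(y, "g", md, B = 999, seed = 5)
  p2 <- univariate_permutation_test(y, "g", md, B = 999, seed = 5)
  expect_identical(p1$table$p, p2$table$p)
  expect_gte(p1$table$p, 1 / 1000)
  ## affine transformation of the response leaves F and p unchanged
  p3 <- univariate_permutation_test(3.7 * y - 11, "g", md, B = 999, seed = 5)
  expect_equal(p3$table$F, p1$table$F, tolerance = 1e-10)
  expect_identical(p3$table$p, p1$table$p)
})

test_that("multivariate partition agrees with vegan::adonis2 sequential terms", {
  skip_if_not_installed("vegan")
  set.seed(6)
  n <- 25
  md <- data.frame(g = sample(c("a", "b", "c"), n, TRUE), x = rnorm(n))
  Y <- matrix(rnorm(n * 4), n)
  d <- as.matrix(dist(Y))
  pr <- dm_partition(d, c("g", "x", "g:x"), md)
  a2 <- vegan::adonis2(dist(Y) ~ g * x, data = md, permutations = 2, by = "terms")
  expect_equal(pr$table$SS, a2$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(pr$table$F, a2$F[1:3], tolerance = 1e-8)
  expect_equal(pr$residual, a2$SumOfSqs[4], tolerance = 1e-8)
})

test_that("univariate engine equals the gram-matrix route", {
  set.seed(7)
  y <- rnorm(12)
  md <- data.frame(g = rep(c("a", "b", "c"), 4), x = rnorm(12))
  d <- abs(outer(y, y, "-")); diag(d) <- 0
  pv <- univariate_permutation_test(y, c("g", "x"), md, B = 199, seed = 3)
  pg <- permutation_test(d, c("g", "x"), md, B = 199, seed = 3)
  expect_equal(pv$table$SS, pg$table$SS, tolerance = 1e-10)
  expect_equal(pv$table$F, pg$table$F, tolerance = 1e-10)
  expect_identical(pv$table$p, pg$table$p)
})
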