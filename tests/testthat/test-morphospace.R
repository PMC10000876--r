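test_that("covariance PCA matches an eigendecomposition oracle", {
  x <- withr::with_seed(1L, matrix(stats::rnorm(20L * 6L), 20L, 6L))
  res <- pca(x)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(res$sdev^2, ev$values[seq_along(res$sdev)],
               tolerance = 1e-9)
  for (j in 1:6) {
    ratio <- res$loadings[, j] / ev$vectors[, j]
    expect_lt(max(abs(abs(ratio) - 1)), 1e-8)  # equal up to sign
  }
  expect_equal(sum(res$explained_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
  ## scores have diagonal covariance and reconstruct the centered data
  sc_cov <- stats::cov(res$scores)
  expect_lt(max(abs(sc_cov[upper.tri(sc_cov)])), 1e-9)
  rec <- res$scores %*% t(res$loadings)
  expect_equal(rec, unname(sweep(x, 2L, res$center)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("PCA handles degenerate inputs deterministically", {
  line <- cbind(1:10, 2 * (1:10))  # collinear data
  res <- pca(line)
  expect_equal(res$explained_fraction[1L], 1, tolerance = 1e-12)
  expect_error(pca(matrix(1, 5L, 3L)), "constant")
  dup <- rbind(c(1, 2), c(3, 4), c(1, 2), c(5, 1))
  r2 <- pca(dup)
  expect_equal(r2$scores[1L, ], r2$scores[3L, ])
})

test_that("axis retention finds the 95% threshold", {
  expect_equal(retain_axes_95(c(0.96, 0.04)), 1L)
  expect_equal(retain_axes_95(c(0.5, 0.3, 0.1, 0.06, 0.04)), 4L)
  expect_equal(retain_axes_95(rep(0.05, 20L)), 19L)
})

test_that("rank transform uses midranks and kills monotone distortion", {
  expect_equal(rank_transform(cbind(c(3.2, 1.1, 2.5)))[, 1L], c(3, 1, 2))
  expect_equal(rank_transform(cbind(c(2, 2, 5)))[, 1L], c(1.5, 1.5, 3))
  x <- withr::with_seed(2L, matrix(stats::rnorm(30L * 4L), 30L, 4L))
  g <- rep(c("a", "b"), 15L)
  m1 <- wilks_manova(rank_transform(x), g)
  m2 <- wilks_manova(rank_transform(exp(x)), g)
  expect_equal(m1$wilks_lambda, m2$wilks_lambda, tolerance = 1e-12)
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
})

test_that("Wilks lambda matches Hotelling and stats::manova oracles", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(stats::rnorm(12L * 3L), 12L, 3L))
    g <- rep(c("a", "b"), each = 6L)
    mv <- wilks_manova(x, g)
    ## Hotelling T2 identity for two groups
    m1 <- colMeans(x[1:6, ]); m2 <- colMeans(x[7:12, ])
    S <- (5 * stats::cov(x[1:6, ]) + 5 * stats::cov(x[7:12, ])) / 10
    T2 <- (6 * 6 / 12) * drop(t(m1 - m2) %*% solve(S) %*% (m1 - m2))
    expect_equal(mv$wilks_lambda, 1 / (1 + T2 / 10), tolerance = 1e-9)
    ## independent library implementation
    sm <- summary(stats::manova(x ~ factor(g)), test = "Wilks")$stats
    expect_equal(mv$wilks_lambda, unname(sm[1L, 2L]), tolerance = 1e-9)
    expect_equal(mv$F, unname(sm[1L, 3L]), tolerance = 1e-9)
    expect_equal(mv$p_value, unname(sm[1L, 6L]), tolerance = 1e-9)
  }
})

test_that("Wilks lambda is invariant under common linear transforms", {
  x <- withr::with_seed(6L, matrix(stats::rnorm(16L * 3L), 16L, 3L))
  g <- rep(c("a", "b"), each = 8L)
  A <- withr::with_seed(7L, matrix(stats::rnorm(9L), 3L, 3L))
  expect_gt(abs(det(A)), 1e-3)
  m1 <- wilks_manova(x, g)
  m2 <- wilks_manova(x %*% A, g)
  expect_equal(m1$wilks_lambda, m2$wilks_lambda, tolerance = 1e-9)
})

test_that("degenerate MANOVA cases behave as prescribed", {
  x <- withr::with_seed(8L, matrix(stats::rnorm(10L * 2L), 10L, 2L))
  ## identical group means: duplicate the same rows into both groups
  xx <- rbind(x, x)
  g <- rep(c("a", "b"), each = 10L)
  mv <- wilks_manova(xx, g)
  expect_equal(mv$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(mv$F, 0, tolerance = 1e-12)
  expect_equal(mv$df2, 20L - 2L - 1L)
  ## too many variables
  expect_error(wilks_manova(matrix(stats::rnorm(6L * 5L), 6L, 5L),
                            rep(c("a", "b"), 3L)), "N - 1 - p")
  ## singular within-group matrix
  xs <- cbind(1:8, 1:8)
  expect_error(wilks_manova(xs, rep(c("a", "b"), 4L)), "singular|axes")
})

test_that("the printed-lambda F transform matches published values", {
  ## two-group exact transform applied to rounded lambdas from a
  ## published MANOVA table must reproduce the printed F values
  up <- wilks_to_f(0.340, 11L, 42L)
  expect_lt(abs(up$F - 7.427), 0.05)
  expect_lt(up$p_value, 0.001)
  lo <- wilks_to_f(0.557, 8L, 45L)
  expect_lt(abs(lo$F - 4.470), 0.05)
  expect_lt(lo$p_value, 0.001)
})

test_that("extreme outlines bracket the mean shape symmetrically", {
  outlines <- simulate_cohorts(15L, dtheta1 = 0.3, seed = 31L)
  res <- outline_pipeline(outlines)
  tmpl <- eft_normalize(eft_forward(resample_equal_arclength(
    outlines[[1L]], 64L), 9L))
  ## multiplier 0: both extremes equal the mean shape
  e0 <- extreme_outlines(res$pca, 1L, tmpl, multiplier = 0)
  expect_equal(e0$negative$points, e0$positive$points, tolerance = 1e-12)
  ## +-1 sd: extremes differ most near the injected cusp angle
  e1 <- extreme_outlines(res$pca, res$extreme_axis, tmpl, multiplier = 1)
  d <- sqrt(rowSums((e1$positive$points - e1$negative$points)^2))
  ang <- atan2(e1$positive$points[, 2L], e1$positive$points[, 1L])
  ang_max <- ang[which.max(d)]
  ## cusp 1 sits near angle 0 (wild type) to 0.3 (mutant); the
  ## normalized frame may place the start point at either tip of the
  ## major axis, so accept the cusp angle modulo pi
  wrapped <- atan2(sin(ang_max - 0.15), cos(ang_max - 0.15))
  expect_lt(min(abs(wrapped), abs(abs(wrapped) - pi)), 0.6)
})

test_that("full pipeline recovers an injected effect and respects null", {
  outlines <- simulate_cohorts(30L, dtheta1 = 0.3, seed = 55L)
  res <- outline_pipeline(outlines)
  expect_lt(res$manova$p_value, 0.01)
  expect_equal(res$manova$df2,
               nrow(res$variables$x) - 1L - res$manova$df1)
  ## one cohort duplicated as both groups: lambda ~ 1 (exact ties in the
  ## rank step are broken only by floating-point jitter in the scores,
  ## so equality holds to rank-resolution rather than machine precision)
  half <- outlines[1:30]
  dup <- outline_pipeline(c(half, half),
                          groups = rep(c("x", "y"), each = 30L))
  expect_gt(dup$manova$wilks_lambda, 0.999)
  expect_gt(dup$manova$p_value, 0.5)
})

test_that("side reduction averages bilateral coefficients per animal", {
  outlines <- simulate_cohorts(8L, dtheta1 = 0, seed = 91L)
  ids <- rep(sprintf("an%02d", 1:8), 2L)[order(rep(1:8, 2L))]
  ## treat consecutive pairs as left/right of the same animal
  animal <- rep(sprintf("an%02d", 1:8), each = 2L)
  res <- outline_pipeline(outlines, animal_ids = animal,
                          reduce_sides = TRUE)
  expect_equal(nrow(res$variables$x), 8L)
  res2 <- outline_pipeline(outlines, animal_ids = animal,
                           reduce_sides = FALSE)
  expect_equal(nrow(res2$variables$x), 16L)
})
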