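#' Principal component analysis of shape variables
#'
#' Covariance-matrix PCA (variables centered, not standardized: after
#' Fourier normalization all coefficients share the same dimensionless
#' unit). Component signs are fixed by forcing the largest-magnitude
#' loading of each component to be positive, so results are deterministic.
#'
#' @param x a [build_variable_matrix()] result or a plain numeric matrix
#'   (specimens x variables).
#' @return object of class `pca_result`: `scores` (specimens x
#'   components), `loadings` (variables x components), `sdev`,
#'   `explained_fraction`, `center`.
#' @export
pca <- function(x) {
  m <- if (inherits(x, "shape_variable_matrix")) x$x else as.matrix(x)
  if (nrow(m) < 3L) stop("PCA needs at least 3 specimens")
  if (anyNA(m)) stop("shape variable matrix must have no missing cells")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop("constant matrix: no variance to analyze")
  ## deterministic component signs
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
                 explained_fraction = expl, center = p$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d specimens, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_fraction, 5L)),
            collapse = " "), if (length(x$explained_fraction) > 5L) "...",
      "\n")
  invisible(x)
}

#' Number of axes reaching a cumulative variance threshold
#'
#' Smallest k such that the first k explained-variance fractions sum to at
#' least `threshold` (default 95%).
#'
#' @param explained_fraction non-increasing fractions summing to 1, or a
#'   [pca()] result.
#' @param threshold cumulative variance to reach, in (0, 1].
#' @return integer k.
#' @export
retain_axes_95 <- function(explained_fraction, threshold = 0.95) {
  if (inherits(explained_fraction, "pca_result"))
    explained_fraction <- explained_fraction$explained_fraction
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  k <- which(cumsum(explained_fraction) >= threshold - 1e-12)[1L]
  if (is.na(k)) length(explained_fraction) else as.integer(k)
}

#' Column-wise rank transformation
#'
#' Replaces each column by its ranks (midranks for ties), making any
#' downstream statistic invariant to strictly monotone transformations of
#' the raw values.
#'
#' @param scores numeric matrix.
#' @return matrix of ranks with the same dimensions.
#' @export
rank_transform <- function(scores) {
  m <- as.matrix(scores)
  apply(m, 2L, rank, ties.method = "average")
}

#' Two-group Wilks' lambda MANOVA
#'
#' Computes Wilks' lambda from the within- and between-group cross-product
#' matrices, Lambda = det(W) / det(W + B), and converts it with the exact
#' two-group F transform F = ((1 - Lambda)/Lambda) ((N - p - 1)/p) on
#' (p, N - p - 1) degrees of freedom (for two groups this is exact, not an
#' approximation: it coincides with Hotelling's T-squared test).
#'
#' @param scores numeric matrix (observations x variables), typically
#'   rank-transformed retained PC coordinates.
#' @param groups vector with exactly two distinct levels.
#' @return object of class `manova_result`: `wilks_lambda`, `F`,
#'   `df1`, `df2`, `p_value`, `n_axes_used`.
#' @export
wilks_manova <- function(scores, groups) {
  m <- as.matrix(scores)
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (length(g) != nrow(m)) stop("groups length must match row count")
  if (any(table(g) < 2L)) stop("each group needs at least 2 observations")
  N <- nrow(m); p <- ncol(m)
  if (N - 1L - p < 1L)
    stop("too many variables for the sample size (need N - 1 - p >= 1); ",
         "retain fewer axes")
  grand <- colMeans(m)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    xg <- m[g == lev, , drop = FALSE]
    mg <- colMeans(xg)
    cx <- sweep(xg, 2L, mg)
    W <- W + crossprod(cx)
    B <- B + nrow(xg) * tcrossprod(mg - grand)
  }
  dW <- determinant(W, logarithm = TRUE)
  dT <- determinant(W + B, logarithm = TRUE)
  if (dW$sign <= 0 || !is.finite(dW$modulus))
    stop("singular within-group matrix; retain fewer axes")
  lambda <- exp(as.numeric(dW$modulus - dT$modulus))
  lambda <- min(lambda, 1)
  df1 <- p; df2 <- N - p - 1L
  F <- (1 - lambda) / lambda * df2 / df1
  pval <- stats::pf(F, df1, df2, lower.tail = FALSE)
  structure(list(wilks_lambda = lambda, F = F, df1 = df1, df2 = df2,
                 p_value = pval, n_axes_used = p),
            class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf(
    "Wilks MANOVA: Lambda = %.4f, F(%d, %d) = %.3f, p = %.4g\n",
    x$wilks_lambda, x$df1, x$df2, x$F, x$p_value))
  invisible(x)
}

#' Exact F statistic from a printed Wilks' lambda
#'
#' Applies the two-group Wilks-to-F transform to an already-computed
#' lambda with known degrees of freedom; useful to check the internal
#' consistency of published MANOVA tables.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param df1 number of variables p.
#' @param df2 error degrees of freedom N - p - 1.
#' @return list with `F` and `p_value`.
#' @export
wilks_to_f <- function(lambda, df1, df2) {
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  F <- (1 - lambda) / lambda * df2 / df1
  list(F = F, p_value = stats::pf(F, df1, df2, lower.tail = FALSE))
}

#' Extreme outlines along a principal axis
#'
#' Reconstructs the outline pair at the mean shape plus/minus
#' `multiplier` standard deviations of the scores along one component,
#' the standard way to visualize what a morphospace axis encodes.
#'
#' @param pca_res a [pca()] result computed on shape variables.
#' @param axis component index.
#' @param coeff_template normalized [efa_coefficients()] providing the
#'   first harmonic (ellipse aspect) and harmonic count for
#'   reconstruction; typically any specimen, or the mean shape.
#' @param multiplier how many score standard deviations to move.
#' @param n_points points per reconstructed outline.
#' @return list with `negative` and `positive` [closed_outline()]s.
#' @export
extreme_outlines <- function(pca_res, axis, coeff_template, multiplier = 2,
                             n_points = 128L) {
  stopifnot(inherits(pca_res, "pca_result"),
            inherits(coeff_template, "efa_coefficients"))
  if (!coeff_template$normalized) stop("template must be normalized")
  H <- nrow(coeff_template$harmonics)
  if (length(pca_res$center) != 4L * (H - 1L))
    stop("template harmonic count does not match the variable space")
  s <- stats::sd(pca_res$scores[, axis])
  build <- function(vec, lab) {
    h <- coeff_template$harmonics
    h[-1L, ] <- matrix(vec, H - 1L, 4L, byrow = TRUE)
    eft_inverse(efa_coefficients(h, perimeter = coeff_template$perimeter,
                                 normalized = TRUE),
                n_points = n_points, label = lab)
  }
  dirv <- pca_res$loadings[, axis]
  list(negative = build(pca_res$center - multiplier * s * dirv, "negative"),
       positive = build(pca_res$center + multiplier * s * dirv, "positive"))
}

#' Full outline-morphometrics pipeline
#'
#' Chains the standard outline analysis: equal-arc-length resampling,
#' elliptic Fourier decomposition and normalization, shape-variable matrix
#' (first harmonic dropped), covariance PCA, retention of the leading axes
#' reaching the variance threshold, column-wise rank transformation, and
#' the exact two-group Wilks' lambda MANOVA. Optionally reduces bilateral
#' observations to one row per animal by averaging normalized coefficients.
#'
#' @param outlines list of [closed_outline()]s with `cohort` set (or
#'   supply `groups`).
#' @param groups optional explicit group labels (overrides `cohort`).
#' @param animal_ids optional vector identifying the animal each outline
#'   belongs to; used when `reduce_sides = TRUE` to average left/right
#'   coefficients. Defaults to outline labels (i.e. no pooling).
#' @param n_points resampling density (default 64).
#' @param n_harmonics harmonics to retain (9 for upper first molars, 5 for
#'   lower, by convention).
#' @param variance_threshold cumulative variance for axis retention.
#' @param reduce_sides average normalized coefficients within animal?
#' @param extreme_axis axis for extreme-shape reconstruction; defaults to
#'   the axis with the largest standardized group mean difference.
#' @param extreme_multiplier score standard deviations for the extremes.
#' @return list of class `outline_analysis`: `variables` (the
#'   shape-variable matrix), `pca`, `n_axes`, `manova`, `extremes`,
#'   `extreme_axis`, `groups`.
#' @export
outline_pipeline <- function(outlines, groups = NULL, animal_ids = NULL,
                             n_points = 64L, n_harmonics = 9L,
                             variance_threshold = 0.95,
                             reduce_sides = FALSE,
                             extreme_axis = NULL, extreme_multiplier = 2) {
  if (!length(outlines)) stop("no outlines supplied")
  if (is.null(groups))
    groups <- vapply(outlines, function(o) o$cohort, character(1L))
  if (anyNA(groups)) stop("every outline needs a cohort/group label")
  labels <- vapply(outlines, function(o) o$label, character(1L))
  if (is.null(animal_ids)) animal_ids <- labels
  coeffs <- lapply(outlines, function(o)
    eft_normalize(eft_forward(resample_equal_arclength(o, n_points),
                              n_harmonics)))
  names(coeffs) <- make.unique(labels)
  if (reduce_sides) {
    key <- paste(groups, animal_ids, sep = "\r")
    agg <- lapply(split(seq_along(coeffs), key), function(ix) {
      hs <- Reduce(`+`, lapply(coeffs[ix], function(cf) cf$harmonics)) /
        length(ix)
      Tm <- mean(vapply(coeffs[ix], function(cf) cf$perimeter, numeric(1L)))
      hs[1L, c("A", "B", "C")] <- c(1, 0, 0)
      efa_coefficients(hs, perimeter = Tm, normalized = TRUE)
    })
    groups <- vapply(strsplit(names(agg), "\r", fixed = TRUE), `[`,
                     character(1L), 1L)
    names(agg) <- vapply(strsplit(names(agg), "\r", fixed = TRUE), `[`,
                         character(1L), 2L)
    coeffs <- agg
  }
  vm <- build_variable_matrix(coeffs, groups = groups)
  pc <- pca(vm)
  k <- retain_axes_95(pc, variance_threshold)
  k <- min(k, nrow(vm$x) - 2L)  # keep the exact F transform well-defined
  ranked <- rank_transform(pc$scores[, seq_len(k), drop = FALSE])
  mv <- wilks_manova(ranked, vm$groups)
  if (is.null(extreme_axis)) {
    std_diff <- apply(pc$scores, 2L, function(s) {
      sp <- split(s, vm$groups)
      abs(mean(sp[[1L]]) - mean(sp[[2L]])) / stats::sd(s)
    })
    extreme_axis <- which.max(std_diff)
  }
  ext <- extreme_outlines(pc, extreme_axis, coeffs[[1L]],
                          multiplier = extreme_multiplier)
  structure(list(variables = vm, pca = pc, n_axes = k, manova = mv,
                 extremes = ext, extreme_axis = extreme_axis,
                 groups = vm$groups),
            class = "outline_analysis")
}

#' @export
print.outline_analysis <- function(x, ...) {
  cat(sprintf("outline_analysis: %d specimens, %d variables\n",
              nrow(x$variables$x), ncol(x$variables$x)))
  cat(sprintf("  axes retained (>=95%% variance): %d\n", x$n_axes))
  print(x$manova)
  invisible(x)
}
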