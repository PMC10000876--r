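#' Elliptic Fourier coefficients
#'
#' Container for the harmonic decomposition of a closed outline. Each
#' harmonic n contributes four coefficients: A_n, B_n for x(t) and C_n,
#' D_n for y(t), t being cumulative arc length along the outline. The
#' first harmonic is the best-fitting ellipse; after [eft_normalize()] it
#' is reduced to the identity pattern (A1 = 1, B1 = C1 = 0) so that the
#' remaining coefficients are pure shape variables.
#'
#' @param harmonics H x 4 matrix with columns `A`, `B`, `C`, `D`.
#' @param A0,C0 constant (centroid) terms of x(t) and y(t).
#' @param perimeter outline perimeter T in mm.
#' @param normalized has size/orientation/start-point normalization been
#'   applied?
#' @return object of class `efa_coefficients`.
#' @export
efa_coefficients <- function(harmonics, A0 = 0, C0 = 0, perimeter = NA_real_,
                             normalized = FALSE) {
  h <- as.matrix(harmonics)
  if (ncol(h) != 4L) stop("harmonics must be an H x 4 matrix")
  if (nrow(h) < 1L) stop("at least one harmonic is required")
  if (!all(is.finite(h))) stop("coefficients must be finite")
  colnames(h) <- c("A", "B", "C", "D")
  if (normalized) {
    if (abs(h[1L, "A"] - 1) > 1e-9 || abs(h[1L, "B"]) > 1e-9 ||
        abs(h[1L, "C"]) > 1e-9)
      stop("normalized coefficients must have A1 = 1, B1 = C1 = 0")
  }
  structure(list(harmonics = h, A0 = A0, C0 = C0, perimeter = perimeter,
                 normalized = normalized),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("efa_coefficients: %d harmonics, T = %.4f mm, %s\n",
              nrow(x$harmonics), x$perimeter,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Resample a closed outline to equal arc-length spacing
#'
#' Places `n_points` points on the closed polygonal curve so that
#' consecutive points are separated by exactly T/n_points of arc length
#' (T = perimeter). The first output point coincides with the first input
#' point.
#'
#' @param outline a [closed_outline()].
#' @param n_points number of points (default 64).
#' @return a resampled [closed_outline()].
#' @export
resample_equal_arclength <- function(outline, n_points = 64L) {
  stopifnot(inherits(outline, "closed_outline"))
  if (n_points < 8L) stop("n_points must be at least 8")
  pts <- outline$points
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate outline with zero perimeter")
  s <- (seq_len(n_points) - 1L) * total / n_points
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= length(cum)] <- length(cum) - 1L
  frac <- (s - cum[idx]) / seg[idx]
  new_pts <- closed[idx, , drop = FALSE] +
    frac * (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE])
  out <- outline
  out$points <- new_pts
  dimnames(out$points) <- list(NULL, c("x", "y"))
  out
}

#' Elliptic Fourier decomposition of a closed outline
#'
#' Computes the elliptic Fourier coefficients of the polygonal outline in
#' the chain (piecewise-linear) formulation: the incremental changes in x
#' and y are decomposed as functions of cumulative chord length along the
#' loop, so no prior resampling is required and the result is exact for
#' the polygon.
#'
#' @param outline a [closed_outline()].
#' @param n_harmonics number of harmonics H; must not exceed half the
#'   number of outline points (Nyquist bound).
#' @return an unnormalized [efa_coefficients()].
#' @export
eft_forward <- function(outline, n_harmonics) {
  stopifnot(inherits(outline, "closed_outline"))
  pts <- outline$points
  K <- nrow(pts)
  if (n_harmonics < 1L) stop("n_harmonics must be at least 1")
  if (n_harmonics > K / 2)
    stop("n_harmonics exceeds the Nyquist bound (n_points / 2)")
  closed <- rbind(pts, pts[1L, , drop = FALSE])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  t <- c(0, cumsum(dt))
  T <- t[K + 1L]
  phi <- 2 * pi * t / T                      # length K + 1
  h <- matrix(0, n_harmonics, 4L,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  dx_dt <- dxy[, 1L] / dt
  dy_dt <- dxy[, 2L] / dt
  for (n in seq_len(n_harmonics)) {
    cs <- cos(n * phi); sn <- sin(n * phi)
    dcos <- cs[-1L] - cs[-(K + 1L)]
    dsin <- sn[-1L] - sn[-(K + 1L)]
    k <- T / (2 * pi^2 * n^2)
    h[n, ] <- k * c(sum(dx_dt * dcos), sum(dx_dt * dsin),
                    sum(dy_dt * dcos), sum(dy_dt * dsin))
  }
  ## constant terms (outline centroid under arc-length parameterization)
  t0 <- t[-(K + 1L)]; t1 <- t[-1L]
  xi <- cumsum(c(0, dxy[-K, 1L])) - dx_dt * t0
  dl <- cumsum(c(0, dxy[-K, 2L])) - dy_dt * t0
  A0 <- pts[1L, 1L] + sum(dx_dt / 2 * (t1^2 - t0^2) + xi * (t1 - t0)) / T
  C0 <- pts[1L, 2L] + sum(dy_dt / 2 * (t1^2 - t0^2) + dl * (t1 - t0)) / T
  efa_coefficients(h, A0 = A0, C0 = C0, perimeter = T, normalized = FALSE)
}

## rotate the coefficient pattern of harmonic n by start-phase theta and
## spatial angle psi, divide by scale
.rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)

#' Normalize elliptic Fourier coefficients
#'
#' Standardizes size, orientation and starting point using the first
#' harmonic: the start phase is shifted to the tip of the first-harmonic
#' ellipse's semi-major axis, the outline is rotated so that axis lies on
#' +x, and all coefficients are divided by the semi-major axis length.
#' After normalization A1 = 1 and B1 = C1 = 0, and two outlines differing
#' only by rotation, uniform scaling, translation and starting point have
#' identical coefficients. Reflection (chirality) is deliberately not
#' removed.
#'
#' @param coeffs unnormalized [efa_coefficients()].
#' @return normalized [efa_coefficients()] with attributes `scale`
#'   (semi-major axis, mm), `theta` (start-point phase) and `psi`
#'   (orientation angle).
#' @export
eft_normalize <- function(coeffs) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  if (coeffs$normalized) stop("coefficients are already normalized")
  h <- coeffs$harmonics
  a1 <- h[1L, "A"]; b1 <- h[1L, "B"]; c1 <- h[1L, "C"]; d1 <- h[1L, "D"]
  if (a1^2 + b1^2 + c1^2 + d1^2 < 1e-300)
    stop("zero first harmonic: outline degenerate")
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  ## theta is defined modulo pi/2 between major and minor axes; pick the
  ## candidate giving the larger first semi-axis, then fix sign so A1 > 0
  best <- NULL
  for (th in c(theta, theta + pi / 2)) {
    m1 <- matrix(c(a1, c1, b1, d1), 2L, 2L) %*% .rot2(th)[, 1L, drop = FALSE]
    if (is.null(best) || sum(m1^2) > best$len) best <- list(th = th,
                                                            len = sum(m1^2))
  }
  theta <- best$th
  m1 <- matrix(c(a1, c1, b1, d1), 2L, 2L) %*% .rot2(theta)
  E <- sqrt(sum(m1[, 1L]^2))
  psi <- atan2(m1[2L, 1L], m1[1L, 1L])
  H <- nrow(h)
  out <- h
  Rpsi <- .rot2(-psi)
  for (n in seq_len(H)) {
    M <- Rpsi %*% matrix(c(h[n, "A"], h[n, "C"], h[n, "B"], h[n, "D"]),
                         2L, 2L) %*% .rot2(n * theta) / E
    out[n, ] <- c(M[1L, 1L], M[1L, 2L], M[2L, 1L], M[2L, 2L])
  }
  ## theta is determined only modulo pi (two tips of the major axis); the
  ## residual flip negates every even harmonic while leaving odd ones
  ## unchanged, so pick the representative whose dominant even-harmonic
  ## coefficient is positive (vacuous when even harmonics vanish)
  if (H >= 2L) {
    even <- seq(2L, H, by = 2L)
    ev <- out[even, , drop = FALSE]
    if (any(ev != 0) && ev[which.max(abs(ev))] < 0) {
      out[even, ] <- -out[even, ]
      theta <- theta + pi
      psi <- psi + pi
    }
  }
  out[1L, c("A", "B", "C")] <- c(1, 0, 0)  # clamp rounding residue
  res <- efa_coefficients(out, A0 = 0, C0 = 0,
                          perimeter = coeffs$perimeter, normalized = TRUE)
  attr(res, "scale") <- E
  attr(res, "theta") <- theta
  attr(res, "psi") <- psi
  res
}

#' Reconstruct an outline from elliptic Fourier coefficients
#'
#' Truncated Fourier synthesis: samples x(t), y(t) at `n_points` equally
#' spaced parameter values over one period.
#'
#' @param coeffs an [efa_coefficients()].
#' @param n_points number of points to generate.
#' @param label,tooth_class,cohort passed to [closed_outline()].
#' @return a [closed_outline()].
#' @export
eft_inverse <- function(coeffs, n_points = 64L, label = NA_character_,
                        tooth_class = NA_character_,
                        cohort = NA_character_) {
  stopifnot(inherits(coeffs, "efa_coefficients"))
  h <- coeffs$harmonics
  phi <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  x <- rep(coeffs$A0, n_points)
  y <- rep(coeffs$C0, n_points)
  for (n in seq_len(nrow(h))) {
    cs <- cos(n * phi); sn <- sin(n * phi)
    x <- x + h[n, "A"] * cs + h[n, "B"] * sn
    y <- y + h[n, "C"] * cs + h[n, "D"] * sn
  }
  closed_outline(cbind(x, y), label = label, tooth_class = tooth_class,
                 cohort = cohort)
}

#' Assemble the shape-variable matrix from per-specimen coefficients
#'
#' Stacks normalized coefficients into a specimens x variables matrix,
#' dropping the four first-harmonic coefficients (A1-D1), which are
#' constants/background after normalization. With H harmonics this yields
#' 4(H - 1) variables: 32 for the upper first molar at H = 9 and 16 for
#' the lower at H = 5.
#'
#' @param coeff_sets named list of normalized [efa_coefficients()], all
#'   with the same harmonic count.
#' @param groups factor or character vector of group labels (one per
#'   specimen), optional.
#' @param tooth_class `"M1_upper"` or `"M1_lower"`, optional bookkeeping.
#' @return object of class `shape_variable_matrix`: list with `x`
#'   (specimens x variables matrix, columns `A2`...`D{H}`), `groups`,
#'   `tooth_class`.
#' @export
build_variable_matrix <- function(coeff_sets, groups = NULL,
                                  tooth_class = NA_character_) {
  if (!length(coeff_sets)) stop("no coefficient sets supplied")
  hc <- vapply(coeff_sets, function(cf) nrow(cf$harmonics), integer(1L))
  if (length(unique(hc)) != 1L)
    stop("all specimens must share the same harmonic count; got ",
         paste(sort(unique(hc)), collapse = ", "))
  H <- hc[1L]
  if (H < 2L) stop("need at least 2 harmonics to form shape variables")
  norm <- vapply(coeff_sets, function(cf) isTRUE(cf$normalized), logical(1L))
  if (!all(norm)) stop("all coefficient sets must be normalized")
  rows <- t(vapply(coeff_sets, function(cf)
    as.vector(t(cf$harmonics[-1L, , drop = FALSE])),
    numeric(4L * (H - 1L))))
  colnames(rows) <- as.vector(t(outer(2:H, c("A", "B", "C", "D"),
                                      function(n, l) paste0(l, n))))
  if (is.null(rownames(rows)) || all(rownames(rows) == ""))
    rownames(rows) <- names(coeff_sets)
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != nrow(rows))
      stop("groups length must match specimen count")
  }
  structure(list(x = rows, groups = groups, tooth_class = tooth_class),
            class = "shape_variable_matrix")
}

#' @export
print.shape_variable_matrix <- function(x, ...) {
  cat(sprintf("shape_variable_matrix: %d specimens x %d variables (%s)\n",
              nrow(x$x), ncol(x$x), x$tooth_class))
  invisible(x)
}
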