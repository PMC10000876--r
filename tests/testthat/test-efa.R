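test_that("equal-arc-length resampling matches the brute-force oracle", {
  ## unit square: n = 8 hits all corners and midpoints
  s8 <- resample_equal_arclength(unit_square_outline(), 8L)
  expect_equal(s8$points[1L, ], c(x = 0, y = 0))
  corners <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  for (k in seq_len(4L))
    expect_true(any(rowSums(abs(sweep(s8$points, 2L, corners[k, ]))) < 1e-9))
  ## circle: all chords equal
  c64 <- resample_equal_arclength(circle_outline(256L), 64L)
  ch <- sqrt(rowSums(diff(rbind(c64$points, c64$points[1L, ]))^2))
  expect_lt(diff(range(ch)), 1e-6)
  ## random star outline: arc gaps match a dense-interpolation oracle
  o <- random_star_outline(5L)
  rs <- resample_equal_arclength(o, 64L)
  closed <- rbind(o$points, o$points[1L, ])
  ## oracle: cumulative arc length by very dense linear interpolation
  dense <- do.call(rbind, lapply(seq_len(nrow(closed) - 1L), function(i) {
    t <- seq(0, 1, length.out = 2000L)[-2000L]
    cbind(closed[i, 1L] + t * (closed[i + 1L, 1L] - closed[i, 1L]),
          closed[i, 2L] + t * (closed[i + 1L, 2L] - closed[i, 2L]))
  }))
  dd <- c(0, cumsum(sqrt(rowSums(diff(rbind(dense, dense[1L, ]))^2))))
  total <- dd[length(dd)]
  pos_of <- function(p) {
    i <- which.min(rowSums(sweep(dense, 2L, p)^2))
    dd[i]
  }
  s <- vapply(seq_len(64L), function(k) pos_of(rs$points[k, ]), numeric(1L))
  gaps <- diff(s)
  expect_lt(max(abs(gaps - total / 64)), total * 1e-3)
  expect_error(resample_equal_arclength(unit_square_outline(), 4L),
               "at least 8")
})

test_that("forward transform reproduces closed-form shapes", {
  ## circle -> identity pattern at harmonic 1, nothing above
  cf <- eft_forward(circle_outline(256L), 8L)
  expect_equal(unname(cf$harmonics[1L, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(cf$harmonics[-1L, ])), 1e-6)
  ## near-circular ellipse traversed from (a, 0): harmonic 1 ~ (a,0,0,b)
  ## (under arc-length parameterization the agreement is to O(e^4), so a
  ## mild eccentricity is used and off-diagonal terms are tight)
  ce <- eft_forward(resample_equal_arclength(
    ellipse_outline(512L, 1.05, 0.95), 512L), 8L)
  expect_equal(ce$harmonics[1L, "A"], 1.05, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_equal(ce$harmonics[1L, "D"], 0.95, tolerance = 0.02,
               ignore_attr = TRUE)
  expect_lt(max(abs(ce$harmonics[1L, c("B", "C")])), 1e-9)
  expect_lt(max(abs(ce$harmonics[-1L, ])), 0.02 * 1.05)
  ## square: even harmonics vanish by symmetry
  sq <- eft_forward(resample_equal_arclength(unit_square_outline(), 64L),
                    16L)
  mag <- sqrt(rowSums(sq$harmonics^2))
  expect_lt(max(mag[seq(2L, 16L, 2L)]), 1e-9)
  expect_gt(mag[3L], 1e-3)
  expect_error(eft_forward(circle_outline(16L), 9L), "Nyquist")
})

test_that("forward transform agrees with a numerical Fourier oracle", {
  ## oracle: the chain coefficients are the continuous Fourier
  ## coefficients of the piecewise-linear x(t), y(t) under cumulative
  ## chord-length parameterization; recompute them by dense quadrature
  o <- resample_equal_arclength(random_star_outline(12L), 64L)
  cf <- eft_forward(o, 9L)
  closed <- rbind(o$points, o$points[1L, ])
  tt <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  total <- tt[length(tt)]
  tf <- seq(0, total, length.out = 200001L)[-200001L]
  xf <- stats::approx(tt, closed[, 1L], xout = tf)$y
  yf <- stats::approx(tt, closed[, 2L], xout = tf)$y
  for (nh in c(1L, 2L, 5L, 9L)) {
    w <- 2 * pi * nh * tf / total
    oracle <- 2 * c(mean(xf * cos(w)), mean(xf * sin(w)),
                    mean(yf * cos(w)), mean(yf * sin(w)))
    expect_equal(unname(cf$harmonics[nh, ]), oracle, tolerance = 1e-6)
  }
})

test_that("normalization is invariant to rotation, scale and start point", {
  for (seed in c(3L, 8L, 21L)) {
    o <- resample_equal_arclength(random_star_outline(seed), 64L)
    n1 <- eft_normalize(eft_forward(o, 9L))
    expect_true(n1$normalized)
    expect_equal(unname(n1$harmonics[1L, 1:3]), c(1, 0, 0), tolerance = 1e-9)
    ## rotate 37 degrees, scale 2.5, translate, cyclic start shift
    pts <- 2.5 * o$points %*% t(rot2d(37 * pi / 180))
    pts <- sweep(pts, 2L, c(-3.2, 1.7), `+`)
    pts <- pts[c(25:64, 1:24), ]
    n2 <- eft_normalize(eft_forward(closed_outline(pts), 9L))
    expect_lt(max(abs(n1$harmonics - n2$harmonics)), 1e-6)
  }
})

test_that("normalization keeps chirality", {
  o <- resample_equal_arclength(simulate_outline(outline_model_params(
    noise_sd = 0), seed = 1), 64L)
  n1 <- eft_normalize(eft_forward(o, 9L))
  mirrored <- closed_outline(cbind(-o$points[, 1L], o$points[, 2L]))
  n2 <- eft_normalize(eft_forward(resample_equal_arclength(mirrored, 64L),
                                  9L))
  expect_gt(max(abs(n1$harmonics - n2$harmonics)), 1e-3)
})

test_that("circle normalizes to the identity pattern", {
  nc <- eft_normalize(eft_forward(circle_outline(256L), 8L))
  expect_equal(unname(nc$harmonics[1L, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(nc$harmonics[-1L, ])), 1e-6)
})

test_that("inverse transform reconstructs outlines", {
  ## harmonic-1-only identity pattern gives the unit circle
  circ <- eft_inverse(efa_coefficients(matrix(c(1, 0, 0, 1), 1L, 4L)), 64L)
  expect_lt(max(abs(sqrt(rowSums(circ$points^2)) - 1)), 1e-9)
  ## round trip: RMS decreasing in H, < 0.5% of perimeter at Nyquist - 1
  o <- resample_equal_arclength(simulate_outline(outline_model_params(
    noise_sd = 0.02), seed = 7), 64L)
  rms <- vapply(c(2L, 4L, 8L, 16L, 31L), function(H) {
    rec <- eft_inverse(eft_forward(o, H), 64L)
    sqrt(mean(rowSums((rec$points - o$points)^2)))
  }, numeric(1L))
  expect_true(all(diff(rms) < 1e-12))
  expect_lt(rms[5L], 0.005 * outline_perimeter(o))
  ## zero-amplitude harmonics appended do not change the reconstruction
  cf <- eft_forward(o, 9L)
  padded <- efa_coefficients(rbind(cf$harmonics, matrix(0, 3L, 4L)),
                             A0 = cf$A0, C0 = cf$C0,
                             perimeter = cf$perimeter)
  expect_equal(eft_inverse(padded, 64L)$points,
               eft_inverse(cf, 64L)$points, tolerance = 1e-12)
})

test_that("smoothing never increases high-harmonic energy", {
  o <- resample_equal_arclength(random_star_outline(9L), 64L)
  smooth_pts <- (o$points + o$points[c(2:64, 1L), ] +
                 o$points[c(64L, 1:63), ]) / 3
  e_of <- function(pts) {
    h <- eft_forward(closed_outline(pts), 9L)$harmonics
    sum(h[-1L, ]^2)
  }
  expect_lte(e_of(smooth_pts), e_of(o$points))
})

test_that("variable matrix drops the first harmonic and counts variables", {
  outlines <- lapply(1:10, function(i)
    resample_equal_arclength(random_star_outline(i), 64L))
  co9 <- lapply(outlines, function(o) eft_normalize(eft_forward(o, 9L)))
  vm <- build_variable_matrix(co9, groups = rep(c("a", "b"), 5L))
  expect_equal(dim(vm$x), c(10L, 32L))
  expect_false(any(grepl("1$", colnames(vm$x))))
  co5 <- lapply(outlines, function(o) eft_normalize(eft_forward(o, 5L)))
  expect_equal(ncol(build_variable_matrix(co5)$x), 16L)
  co3 <- lapply(outlines, function(o) eft_normalize(eft_forward(o, 3L)))
  expect_equal(ncol(build_variable_matrix(co3)$x), 4L * (3L - 1L))
  expect_error(build_variable_matrix(c(co9[1:2], co5[3L])), "harmonic count")
  expect_error(build_variable_matrix(lapply(outlines[1:3], function(o)
    eft_forward(o, 9L))), "normalized")
})
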