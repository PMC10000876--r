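## Shared fixture builders (all generated in code; no binary data).

## regular n-gon approximating a circle of radius r
circle_outline <- function(n = 256L, r = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  closed_outline(cbind(r * cos(th), r * sin(th)))
}

ellipse_outline <- function(n = 256L, a = 1, b = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  closed_outline(cbind(a * cos(th), b * sin(th)))
}

unit_square_outline <- function() {
  closed_outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
}

## random star-shaped outline (smooth radius function), seeded
random_star_outline <- function(seed, n = 64L) {
  withr::with_seed(seed, {
    amp <- stats::runif(4L, 0.02, 0.12)
    ph <- stats::runif(4L, 0, 2 * pi)
    th <- 2 * pi * (seq_len(n) - 1L) / n
    r <- 1 + Reduce(`+`, lapply(1:4, function(k)
      amp[k] * cos((k + 1L) * th + ph[k])))
    closed_outline(cbind(r * cos(th), r * sin(th)))
  })
}

rot2d <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)

## flat rectangular patch mesh in the z = z0 plane
flat_patch_mesh <- function(n = 10L, z0 = 0) {
  g <- expand.grid(x = seq(0, 1, length.out = n),
                   y = seq(0, 1, length.out = n))
  v <- cbind(g$x, g$y, z0)
  ij <- expand.grid(i = seq_len(n - 1L), j = seq_len(n - 1L))
  v00 <- (ij$j - 1L) * n + ij$i
  f <- rbind(cbind(v00, v00 + 1L, v00 + n + 1L),
             cbind(v00, v00 + n + 1L, v00 + n))
  triangle_mesh(v, f)
}

## dome-plus-bump height map on [-1, 1]^2 with the bump centered at bx
bump_height_map <- function(bx, spacing = 0.05, bump_h = 0.4,
                            bump_w = 0.15) {
  xs <- seq(-1, 1, by = spacing)
  g <- expand.grid(x = xs, y = xs)
  z <- 0.3 * pmax(0, 1 - g$x^2 - g$y^2) +
    bump_h * exp(-((g$x - bx)^2 + g$y^2) / (2 * bump_w^2))
  height_map(matrix(z, length(xs), length(xs), byrow = TRUE),
             spacing = spacing, origin = c(-1, -1))
}

## cohorts of simulated outlines for pipeline tests
simulate_cohorts <- function(n_per_group, dtheta1 = 0, seed = 1L,
                             noise_sd = 0.01) {
  wt_par <- outline_model_params(noise_sd = noise_sd)
  mut_par <- outline_model_params(noise_sd = noise_sd, dtheta1 = dtheta1)
  c(lapply(seq_len(n_per_group), function(i)
      simulate_outline(wt_par, seed = seed + i, cohort = "WT",
                       label = sprintf("W%03d", i))),
    lapply(seq_len(n_per_group), function(i)
      simulate_outline(mut_par, seed = seed + 500000L + i, cohort = "mutant",
                       label = sprintf("K%03d", i))))
}
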