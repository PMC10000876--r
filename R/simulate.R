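#' Parameters of the synthetic outline model
#'
#' A crown silhouette is modeled as a star-shaped radius function around
#' an ellipse: r(theta) = ellipse radius + a sum of Gaussian cusp bumps +
#' radial noise. Defaults mimic a mouse upper first molar: an elongated
#' crown about 2.2 mm x 1.5 mm carrying five marginal cusp bulges. The
#' genotype effect moves the first cusp around the outline (an angular
#' shift toward linguo-distal) and can rescale its amplitude, mirroring a
#' mutant-like repositioning of the first cusp.
#'
#' @param a,b ellipse semi-axes in mm.
#' @param cusps data frame with columns `theta` (angular position, rad),
#'   `amplitude` (mm) and `width` (rad).
#' @param dtheta1 genotype shift of cusp 1's angular position (rad).
#' @param amp_scale1 genotype scaling of cusp 1's amplitude.
#' @param noise_sd radial noise standard deviation in mm.
#' @return object of class `outline_model_params`.
#' @export
outline_model_params <- function(a = 1.1, b = 0.75,
                                 cusps = data.frame(
                                   theta = c(0.0, 1.3, 2.5, 3.8, 5.2),
                                   amplitude = c(0.16, 0.12, 0.12, 0.12,
                                                 0.12),
                                   width = 0.35),
                                 dtheta1 = 0, amp_scale1 = 1,
                                 noise_sd = 0.01) {
  if (a <= 0 || b <= 0) stop("semi-axes must be positive")
  if (nrow(cusps) && (any(cusps$amplitude < 0) || any(cusps$width <= 0)))
    stop("cusp amplitudes must be >= 0 and widths > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(a = a, b = b, cusps = cusps, dtheta1 = dtheta1,
                 amp_scale1 = amp_scale1, noise_sd = noise_sd),
            class = "outline_model_params")
}

## smallest signed angular difference, in (-pi, pi]
.ang_diff <- function(x, y) {
  d <- (x - y) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

#' Simulate a closed crown outline
#'
#' Samples the star-shaped radius model of [outline_model_params()] at
#' `n_points` equally spaced angles. Noise is applied radially so the
#' curve stays simple and closed. Deterministic given the seed.
#'
#' @param params an [outline_model_params()].
#' @param n_points number of sampled angles (>= 16).
#' @param seed integer seed.
#' @inheritParams closed_outline
#' @return a [closed_outline()].
#' @export
simulate_outline <- function(params, n_points = 64L, seed = 1L,
                             label = NA_character_,
                             tooth_class = NA_character_,
                             cohort = NA_character_) {
  stopifnot(inherits(params, "outline_model_params"))
  if (n_points < 16L) stop("n_points must be at least 16")
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  r <- params$a * params$b /
    sqrt((params$b * cos(theta))^2 + (params$a * sin(theta))^2)
  cusps <- params$cusps
  if (nrow(cusps)) {
    amp <- cusps$amplitude
    pos <- cusps$theta
    amp[1L] <- amp[1L] * params$amp_scale1
    pos[1L] <- pos[1L] + params$dtheta1
    for (j in seq_len(nrow(cusps)))
      r <- r + amp[j] *
        exp(-0.5 * (.ang_diff(theta, pos[j]) / cusps$width[j])^2)
  }
  if (params$noise_sd > 0)
    r <- r + withr::with_seed(seed,
                              stats::rnorm(n_points, 0, params$noise_sd))
  closed_outline(cbind(r * cos(theta), r * sin(theta)), label = label,
                 tooth_class = tooth_class, cohort = cohort)
}

#' Parameters of the synthetic crown surface model
#'
#' A crown is modeled as an elliptic dome plus Gaussian cusp bumps on a
#' regular grid: z(x, y) = dome + sum of cusps. The genotype effect moves
#' and rescales named cusps, mimicking mutant-like cusp repositioning.
#'
#' @param a,b dome footprint semi-axes in mm.
#' @param h dome height in mm.
#' @param cusps data frame with `name`, `cx`, `cy` (center, mm), `height`
#'   (mm) and `width` (mm); default four distal-cusp-like bumps named
#'   c5, c6, c8, c9.
#' @param resolution grid cells per axis (>= 16).
#' @param cusp_shift named list of c(dx, dy) shifts (mm) applied to the
#'   matching cusps (genotype effect).
#' @param cusp_height_scale named numeric vector of height multipliers.
#' @param noise_sd vertex z noise standard deviation (mm, default 0).
#' @return object of class `crown_model_params`.
#' @export
crown_model_params <- function(a = 1.0, b = 0.8, h = 0.5,
                               cusps = data.frame(
                                 name = c("c5", "c6", "c8", "c9"),
                                 cx = c(-0.35, 0.35, -0.35, 0.35),
                                 cy = c(0.3, 0.3, -0.3, -0.3),
                                 height = 0.35, width = 0.18,
                                 stringsAsFactors = FALSE),
                               resolution = 48L, cusp_shift = list(),
                               cusp_height_scale = numeric(),
                               noise_sd = 0) {
  if (h <= 0) stop("dome height must be positive")
  if (resolution < 16L) stop("resolution must be at least 16 per axis")
  structure(list(a = a, b = b, h = h, cusps = cusps,
                 resolution = as.integer(resolution),
                 cusp_shift = cusp_shift,
                 cusp_height_scale = cusp_height_scale,
                 noise_sd = noise_sd),
            class = "crown_model_params")
}

crown_height_fun <- function(params) {
  cusps <- params$cusps
  if (nrow(cusps)) {
    for (nm in names(params$cusp_shift)) {
      i <- match(nm, cusps$name)
      if (is.na(i)) stop("cusp_shift names unknown cusp: ", nm)
      cusps$cx[i] <- cusps$cx[i] + params$cusp_shift[[nm]][1L]
      cusps$cy[i] <- cusps$cy[i] + params$cusp_shift[[nm]][2L]
    }
    for (nm in names(params$cusp_height_scale)) {
      i <- match(nm, cusps$name)
      if (is.na(i)) stop("cusp_height_scale names unknown cusp: ", nm)
      cusps$height[i] <- cusps$height[i] * params$cusp_height_scale[[nm]]
    }
  }
  list(
    f = function(x, y) {
      z <- params$h * pmax(0, 1 - (x / params$a)^2 - (y / params$b)^2)
      for (j in seq_len(nrow(cusps)))
        z <- z + cusps$height[j] *
          exp(-((x - cusps$cx[j])^2 + (y - cusps$cy[j])^2) /
                (2 * cusps$width[j]^2))
      z
    },
    cusps = cusps
  )
}

#' Simulate a crown mesh with cusp landmarks
#'
#' Evaluates the dome-plus-cusps height model on a regular grid over the
#' footprint, triangulates it, and places one landmark at each cusp apex.
#' Apices are refined numerically on the analytic (noise-free) height
#' function starting from the cusp centers, so they sit at true local
#' maxima of the surface. Deterministic given the seed.
#'
#' @param params a [crown_model_params()].
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list with `mesh` (a [triangle_mesh()]) and `landmarks`
#'   (a [landmark_set()]; empty when there are no cusps).
#' @export
simulate_crown_mesh <- function(params, seed = 1L) {
  stopifnot(inherits(params, "crown_model_params"))
  hf <- crown_height_fun(params)
  res <- params$resolution
  xs <- seq(-params$a, params$a, length.out = res)
  ys <- seq(-params$b, params$b, length.out = res)
  g <- expand.grid(x = xs, y = ys)
  z <- hf$f(g$x, g$y)
  if (params$noise_sd > 0)
    z <- z + withr::with_seed(seed,
                              stats::rnorm(length(z), 0, params$noise_sd))
  v <- cbind(g$x, g$y, z)
  ## two triangles per grid cell, consistent counter-clockwise winding
  ij <- expand.grid(i = seq_len(res - 1L), j = seq_len(res - 1L))
  v00 <- (ij$j - 1L) * res + ij$i
  v10 <- v00 + 1L
  v01 <- v00 + res
  v11 <- v01 + 1L
  f <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  mesh <- triangle_mesh(v, f)
  lms <- NULL
  cusps <- hf$cusps
  if (nrow(cusps)) {
    pts <- lapply(seq_len(nrow(cusps)), function(j) {
      o <- stats::optim(c(cusps$cx[j], cusps$cy[j]),
                        function(p) -hf$f(p[1L], p[2L]),
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12))
      c(o$par, hf$f(o$par[1L], o$par[2L]))
    })
    names(pts) <- cusps$name
    lms <- landmark_set(pts)
  } else {
    lms <- landmark_set(matrix(numeric(0), 0L, 3L))
  }
  list(mesh = mesh, landmarks = lms)
}

#' Simulate a morphotype table
#'
#' Draws per-side Bernoulli trait states for two cohorts: the U-shaped
#' c1-c2 profile of the upper first molar, absence of the c1 spur on the
#' second, and reduction of c1 on the third. Default probabilities are the
#' observed cohort frequencies of the packaged scoring table (mutants:
#' 39/66, 40/66, 20/66; wild types: 0 throughout).
#'
#' @param n_wt,n_mut number of animals per cohort (two sides each).
#' @param trait_probs list with elements `WT` and `mutant`, each a named
#'   vector with `m1_U`, `m2_absent`, `m3_reduced` probabilities.
#' @param seed integer seed.
#' @return a `morphotype_table` data frame (canonical states).
#' @export
simulate_morphotypes <- function(n_wt, n_mut,
                                 trait_probs = list(
                                   WT = c(m1_U = 0, m2_absent = 0,
                                          m3_reduced = 0),
                                   mutant = c(m1_U = 39 / 66,
                                              m2_absent = 40 / 66,
                                              m3_reduced = 20 / 66)),
                                 seed = 1L) {
  pr <- unlist(trait_probs)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  draw <- function(cohort, n, prefix) {
    if (n == 0L) return(NULL)
    p <- trait_probs[[cohort]]
    data.frame(
      specimen = rep(sprintf("%s%03d", prefix, seq_len(n)), each = 2L),
      cohort = cohort,
      side = rep(c("right", "left"), n),
      m1_c1c2_profile = ifelse(stats::runif(2L * n) < p[["m1_U"]],
                               "U", "V"),
      m2_spur = ifelse(stats::runif(2L * n) < p[["m2_absent"]],
                       "absent", "present"),
      m3_c1 = ifelse(stats::runif(2L * n) < p[["m3_reduced"]],
                     "reduced", "normal"),
      abnormal_cusp = "",
      stringsAsFactors = FALSE)
  }
  out <- withr::with_seed(seed,
                          rbind(draw("WT", n_wt, "W"),
                                draw("mutant", n_mut, "K")))
  class(out) <- c("morphotype_table", "data.frame")
  out
}

#' Simulate a negative-binomial count matrix with known truth
#'
#' Generates genes x samples counts for two groups. A `de_fraction` subset
#' of genes is differentially expressed: its second-group mean is the
#' first-group mean times 2^log2fc (direction alternating up/down).
#' `dispersion = 0` gives the Poisson limit. Deterministic given the seed.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group.
#' @param nb_mean baseline negative-binomial mean.
#' @param nb_dispersion dispersion (variance = mean + dispersion * mean^2).
#' @param de_fraction fraction of genes that are truly DE.
#' @param log2fc log2 fold change of DE genes.
#' @param seed integer seed.
#' @return list with `counts` (matrix, genes x samples), `groups`
#'   (factor), `is_de` (logical truth labels).
#' @export
simulate_counts <- function(n_genes, n_per_group, nb_mean = 100,
                            nb_dispersion = 0.1, de_fraction = 0.1,
                            log2fc = 1, seed = 1L) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must be in [0, 1]")
  if (nb_dispersion < 0) stop("dispersion must be >= 0")
  n_de <- round(de_fraction * n_genes)
  is_de <- seq_len(n_genes) <= n_de
  mu1 <- rep(nb_mean, n_genes)
  dir <- rep_len(c(1, -1), n_de)
  mu2 <- mu1
  if (n_de > 0) mu2[is_de] <- mu1[is_de] * 2^(dir * log2fc)
  rdraw <- function(mu) {
    if (nb_dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
  }
  counts <- withr::with_seed(seed, {
    m1 <- vapply(seq_len(n_per_group), function(i) rdraw(mu1),
                 numeric(n_genes))
    m2 <- vapply(seq_len(n_per_group), function(i) rdraw(mu2),
                 numeric(n_genes))
    cbind(m1, m2)
  })
  rownames(counts) <- paste0("g", seq_len(n_genes))
  colnames(counts) <- c(paste0("A", seq_len(n_per_group)),
                        paste0("B", seq_len(n_per_group)))
  list(counts = counts,
       groups = factor(rep(c("A", "B"), each = n_per_group)),
       is_de = is_de)
}
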