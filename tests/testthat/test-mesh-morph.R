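test_that("landmark alignment recovers a known similarity transform", {
  crown <- simulate_crown_mesh(crown_model_params(resolution = 24L))
  lms <- crown$landmarks
  ## identity when target equals source
  tf0 <- align_by_landmarks(lms, lms)
  expect_equal(tf0$R, diag(3), tolerance = 1e-9)
  expect_equal(tf0$s, 1, tolerance = 1e-9)
  expect_equal(attr(tf0, "rms"), 0, tolerance = 1e-9)
  ## known rotation + translation + scale 1.7
  ang <- 0.5
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  true_tf <- similarity_transform(R, c(0.4, -0.3, 0.8), 1.7)
  moved <- landmark_set(apply_transform(lms$points, true_tf))
  rownames(moved$points) <- rownames(lms$points)
  tf <- align_by_landmarks(lms, moved)
  expect_lt(max(abs(tf$R - R)), 1e-6)
  expect_lt(abs(tf$s - 1.7), 1e-6)
  expect_lt(max(abs(tf$t - true_tf$t)), 1e-6)
  ## noisy landmarks: residual bounded by the noise scale
  noisy <- landmark_set(apply_transform(lms$points, true_tf) +
                          withr::with_seed(3L,
                            matrix(stats::rnorm(12L, 0, 0.01), 4L, 3L)))
  rownames(noisy$points) <- rownames(lms$points)
  tfn <- align_by_landmarks(lms, noisy)
  expect_lte(attr(tfn, "rms"), 3 * 0.01)
  ## collinear landmarks are rejected
  line <- landmark_set(list(a = c(0, 0, 0), b = c(1, 0, 0),
                            c = c(2, 0, 0)))
  expect_error(align_by_landmarks(line, line), "collinear|degenerate")
})

test_that("ICP refines a small rigid perturbation", {
  mesh <- simulate_crown_mesh(crown_model_params(resolution = 20L))$mesh
  ## pre-aligned identical meshes: no extra motion
  tf0 <- refine_by_icp(mesh, mesh, max_iter = 5L)
  expect_lt(max(abs(tf0$R - diag(3))), 1e-9)
  expect_lt(max(abs(tf0$t)), 1e-9)
  ## small rigid motion (about 3 degrees + small shift) is recovered
  ang <- 3 * pi / 180
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  moved <- mesh
  moved$vertices <- mesh$vertices %*% t(R) +
    matrix(c(0.01, -0.015, 0.02), nrow(mesh$vertices), 3L, byrow = TRUE)
  tf <- refine_by_icp(mesh, moved, max_iter = 40L)
  aligned <- apply_transform(mesh$vertices, tf)
  rms <- sqrt(mean(rowSums((aligned - moved$vertices)^2)))
  expect_lt(rms, 1e-3)
  ## the recorded RMS sequence never increases
  expect_true(all(diff(attr(tf, "rms_history")) <= 1e-12))
})

test_that("dense correspondence is exact on identical meshes", {
  mesh <- simulate_crown_mesh(crown_model_params(resolution = 20L))$mesh
  corr <- dense_correspondence(mesh, mesh)
  expect_true(all(corr$matched))
  expect_equal(corr$target_points, mesh$vertices, tolerance = 1e-9)
  field <- build_displacement_field(corr, mesh)
  expect_equal(max(field$magnitude), 0, tolerance = 1e-9)
})

test_that("rigid offset of a flat patch yields the constant field", {
  flat <- flat_patch_mesh(12L)
  lifted <- flat_patch_mesh(12L, z0 = 0.3)
  corr <- dense_correspondence(flat, lifted)
  expect_true(all(corr$matched))
  d <- corr$target_points - flat$vertices
  expect_lt(max(abs(d[, 1:2])), 1e-9)
  expect_equal(unname(d[, 3L]), rep(0.3, nrow(d)), tolerance = 1e-9)
  ## empty boundary keeps the constant field; norms are consistent
  field <- build_displacement_field(corr, flat)
  expect_equal(field$magnitude,
               sqrt(rowSums(field$vectors^2)), tolerance = 1e-12)
  expect_equal(max(field$magnitude), 0.3, tolerance = 1e-9)
})

test_that("raised-cusp displacement peaks at the cusp center", {
  base <- simulate_crown_mesh(crown_model_params(resolution = 40L))
  taller <- simulate_crown_mesh(crown_model_params(
    resolution = 40L, cusp_height_scale = c(c9 = 1.6)))
  corr <- dense_correspondence(base$mesh, taller$mesh)
  field <- build_displacement_field(corr, base$mesh)
  spacing <- 2 * 1.0 / 39
  at_max <- base$mesh$vertices[which.max(field$magnitude), 1:2]
  apex <- base$landmarks$points["c9", 1:2]
  expect_lt(sqrt(sum((at_max - apex)^2)), 2 * spacing)
})

test_that("no spatial overlap raises a correspondence error", {
  flat <- flat_patch_mesh(8L)
  far <- flat_patch_mesh(8L, z0 = 50)
  expect_error(dense_correspondence(flat, far), "overlap")
})

test_that("boundary vertices are pinned to zero displacement", {
  mesh <- simulate_crown_mesh(crown_model_params(resolution = 20L))$mesh
  lifted <- mesh
  lifted$vertices[, 3L] <- lifted$vertices[, 3L] + 0.1
  corr <- dense_correspondence(mesh, lifted)
  bnd <- cervical_margin_vertices(mesh, 0.15)
  expect_gt(length(bnd), 0L)
  field <- build_displacement_field(corr, mesh, boundary = bnd)
  expect_equal(max(field$magnitude[bnd]), 0)
  expect_gt(max(field$magnitude[-bnd]), 0.05)
})

test_that("morphing carries the source onto the target", {
  wt <- simulate_crown_mesh(crown_model_params(resolution = 40L))
  mut <- simulate_crown_mesh(crown_model_params(
    resolution = 40L, cusp_shift = list(c9 = c(-0.12, 0.1))))
  d_before <- surface_distance(wt$mesh, mut$mesh)
  corr <- dense_correspondence(wt$mesh, mut$mesh)
  field <- build_displacement_field(corr, wt$mesh)
  morphed <- apply_morph(wt$mesh, field)
  expect_equal(morphed$faces, wt$mesh$faces)  # topology unchanged
  d_after <- surface_distance(morphed, mut$mesh)
  expect_lt(d_after, 0.2 * d_before)  # >= 80% reduction
  ## zero field and constant field behave trivially
  zf <- field; zf$vectors[] <- 0; zf$magnitude[] <- 0
  expect_equal(apply_morph(wt$mesh, zf)$vertices, wt$mesh$vertices)
  cf <- field; cf$vectors <- matrix(rep(c(1, 2, 3), each = field$n_vertices),
                                    ncol = 3L)
  cf$magnitude <- sqrt(rowSums(cf$vectors^2))
  shifted <- apply_morph(wt$mesh, cf)
  expect_equal(shifted$vertices,
               wt$mesh$vertices + matrix(c(1, 2, 3), field$n_vertices, 3L,
                                         byrow = TRUE))
})

test_that("displacement field CSV round trips", {
  wt <- simulate_crown_mesh(crown_model_params(resolution = 16L))
  lifted <- wt$mesh
  lifted$vertices[, 3L] <- lifted$vertices[, 3L] + 0.05
  field <- build_displacement_field(dense_correspondence(wt$mesh, lifted),
                                    wt$mesh)
  p <- withr::local_tempfile(fileext = ".csv")
  write_displacement_field(field, p)
  back <- read_displacement_field(p)
  expect_equal(back$vectors, field$vectors, tolerance = 1e-9)
  expect_equal(back$kind, field$kind)
})

test_that("correspondence is equivariant under a common rigid motion", {
  wt <- simulate_crown_mesh(crown_model_params(resolution = 20L))
  mut <- simulate_crown_mesh(crown_model_params(
    resolution = 20L, cusp_shift = list(c9 = c(-0.1, 0.08))))
  corr1 <- dense_correspondence(wt$mesh, mut$mesh)
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
             c(0, 0, 1))
  tf <- similarity_transform(R, c(1, -2, 0.5), 1)
  corr2 <- dense_correspondence(apply_transform(wt$mesh, tf),
                                apply_transform(mut$mesh, tf))
  expect_equal(corr2$target_points,
               apply_transform(corr1$target_points, tf), tolerance = 1e-6)
})

test_that("transfer with identity alignment reproduces apply_morph", {
  wt <- simulate_crown_mesh(crown_model_params(resolution = 20L))
  mut <- simulate_crown_mesh(crown_model_params(
    resolution = 20L, cusp_shift = list(c9 = c(-0.1, 0.08))))
  field <- build_displacement_field(dense_correspondence(wt$mesh, mut$mesh),
                                    wt$mesh)
  pred <- transfer_morph(field, wt$mesh, wt$landmarks, wt$mesh,
                         wt$landmarks)
  direct <- apply_morph(wt$mesh, field)
  expect_equal(pred$vertices, direct$vertices, tolerance = 1e-9)
  ## zero field leaves the third mesh unchanged
  zf <- field; zf$vectors[] <- 0; zf$magnitude[] <- 0
  same <- transfer_morph(zf, wt$mesh, wt$landmarks, wt$mesh, wt$landmarks)
  expect_equal(same$vertices, wt$mesh$vertices, tolerance = 1e-9)
})

test_that("transferred cusp shift scales with the landmark frame", {
  ## mouse-like source and an exactly 4x scaled homolog with human cusp
  ## names; a constructed lateral-shift field at c9 must move the
  ## homologous hypocone by the shift over the alignment scale
  wt <- simulate_crown_mesh(crown_model_params(resolution = 32L))
  hp <- crown_model_params(
    a = 4, b = 3.2, h = 2, resolution = 32L,
    cusps = data.frame(name = c("protocone", "paracone", "metacone",
                                "hypocone"),
                       cx = 4 * c(-0.35, -0.35, 0.35, 0.35),
                       cy = 4 * c(0.3, -0.3, 0.3, -0.3),
                       height = 1.4, width = 0.72,
                       stringsAsFactors = FALSE))
  hum <- simulate_crown_mesh(hp)
  ## analytic field: Gaussian-weighted lateral shift centered at c9 apex
  shift <- c(0.12, 0.1, 0)
  apex <- wt$landmarks$points["c9", ]
  w <- exp(-rowSums(sweep(wt$mesh$vertices[, 1:2], 2L,
                          apex[1:2])^2) / (2 * 0.18^2))
  field <- structure(list(vectors = outer(w, shift),
                          magnitude = w * sqrt(sum(shift^2)),
                          boundary = integer(0),
                          kind = rep("projected", nrow(wt$mesh$vertices)),
                          n_vertices = nrow(wt$mesh$vertices)),
                     class = "displacement_field")
  pairing <- c(protocone = "c5", paracone = "c8", metacone = "c6",
               hypocone = "c9")
  pred <- transfer_morph(field, wt$mesh, wt$landmarks, hum$mesh,
                         hum$landmarks, pairing = pairing)
  s <- attr(pred, "alignment")$s
  expect_equal(s, 0.25, tolerance = 1e-6)
  i <- which.min(rowSums(sweep(hum$mesh$vertices, 2L,
                               hum$landmarks$points["hypocone", ])^2))
  moved <- pred$vertices[i, ] - hum$mesh$vertices[i, ]
  expect_equal(unname(moved[1:2]), shift[1:2] / s, tolerance = 0.1 * 0.48)
  ## per-cusp mode with a constant field translates uniformly
  cfield <- field
  cfield$vectors <- matrix(rep(c(0.05, 0, 0), each = field$n_vertices),
                           ncol = 3L)
  cfield$magnitude <- rep(0.05, field$n_vertices)
  pc <- transfer_morph(cfield, wt$mesh, wt$landmarks, hum$mesh,
                       hum$landmarks, pairing = pairing,
                       mode = "per_cusp")
  d <- pc$vertices - hum$mesh$vertices
  expect_equal(unname(colMeans(d)), c(0.05, 0, 0) / s, tolerance = 1e-6)
  expect_lt(max(abs(sweep(d, 2L, colMeans(d)))), 1e-6)
})
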