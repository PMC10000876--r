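## Correspondence-based averaging of gridded crown surfaces: maps are
## first superimposed on a reference (in-plane shift + z offset, least
## squares), then registered non-rigidly by a multi-resolution dense 2D
## displacement estimation (regularized, coarse-to-fine), and finally the
## corresponded x, y, z coordinates are averaged cell-wise. Averaging
## corresponded coordinates — not raw cells — is what keeps shared
## features (cusps) sharp when their positions vary between specimens.

## bilinear sampling of matrix m at fractional (row, col); clamped to the
## grid border, NA where any contributing cell is NA
bilinear_sample <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(as.numeric(ri), 1), nr)
  ci <- pmin(pmax(as.numeric(ci), 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); c0 <- pmin(floor(ci), nc - 1L)
  fr <- ri - r0; fc <- ci - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

## 4-neighbor average with border replication
neighbor_mean <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nr - 1L) + 1L, nr), , drop = FALSE]
  lf <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  (up + dn + lf + rt) / 4
}

downsample2 <- function(m) {
  nr <- 2L * floor(nrow(m) / 2L); nc <- 2L * floor(ncol(m) / 2L)
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  (m[seq(1L, nr, 2L), seq(1L, nc, 2L)] + m[seq(2L, nr, 2L), seq(1L, nc, 2L)] +
   m[seq(1L, nr, 2L), seq(2L, nc, 2L)] + m[seq(2L, nr, 2L), seq(2L, nc, 2L)]) / 4
}

upsample_to <- function(m, nr, nc) {
  ri <- seq(1, nrow(m), length.out = nr)
  ci <- seq(1, ncol(m), length.out = nc)
  g <- expand.grid(ri = ri, ci = ci)
  matrix(bilinear_sample(m, g$ri, g$ci), nr, nc)
}

## dense 2D displacement (u along columns/x, v along rows/y, in cells)
## such that img(x + u, y + v) ~ ref(x, y); Horn-Schunck-style global
## regularization, coarse-to-fine with warping
dense_flow_2d <- function(ref, img, alpha = 0.25, n_warp = 3L,
                          n_iter = 80L, min_size = 12L) {
  stopifnot(all(dim(ref) == dim(img)))
  pyr_ref <- list(ref); pyr_img <- list(img)
  while (min(dim(pyr_ref[[length(pyr_ref)]])) >= 2L * min_size) {
    pyr_ref[[length(pyr_ref) + 1L]] <- downsample2(pyr_ref[[length(pyr_ref)]])
    pyr_img[[length(pyr_img) + 1L]] <- downsample2(pyr_img[[length(pyr_img)]])
  }
  lev <- length(pyr_ref)
  u <- matrix(0, nrow(pyr_ref[[lev]]), ncol(pyr_ref[[lev]]))
  v <- u
  for (l in lev:1L) {
    R <- pyr_ref[[l]]; I <- pyr_img[[l]]
    nr <- nrow(R); nc <- ncol(R)
    if (nrow(u) != nr || ncol(u) != nc) {
      sc_r <- nr / nrow(u); sc_c <- nc / ncol(u)
      u <- upsample_to(u, nr, nc) * sc_c
      v <- upsample_to(v, nr, nc) * sc_r
    }
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    for (w in seq_len(n_warp)) {
      u0 <- u; v0 <- v
      W <- matrix(bilinear_sample(I, rows + v0, cols + u0), nr, nc)
      ## gradients of the warped image (central differences)
      Ix <- (W[, c(2:nc, nc)] - W[, c(1L, 1:(nc - 1L))]) / 2
      Iy <- (W[c(2:nr, nr), ] - W[c(1L, 1:(nr - 1L)), ]) / 2
      It <- W - R - Ix * u0 - Iy * v0
      denom <- alpha^2 + Ix^2 + Iy^2
      for (k in seq_len(n_iter)) {
        ub <- neighbor_mean(u); vb <- neighbor_mean(v)
        common <- (Ix * ub + Iy * vb + It) / denom
        u <- ub - Ix * common
        v <- vb - Iy * common
      }
    }
  }
  list(u = u, v = v)
}

#' Average crown surfaces with dense correspondence
#'
#' Builds a representative mean surface from several gridded crown scans.
#' Each map is (1) superimposed on the reference by least squares over
#' valid cells — an in-plane integer-cell shift plus a z offset, with the
#' corrections centered across maps so the ensemble position is unbiased;
#' (2) registered non-rigidly to the reference by multi-resolution dense
#' 2D displacement estimation minimizing the squared z difference with a
#' smoothness penalty; and (3) the corresponded x, y, z coordinates are
#' averaged cell-wise and re-gridded onto the reference lattice. Cells
#' lacking valid data in any map are masked, with a per-cell sample count
#' reported.
#'
#' @param maps list of [height_map()]s on commensurate grids (same
#'   spacing; equal dimensions).
#' @param reference index of the map serving as the reference frame.
#' @param align estimate the in-plane shift and z offset (TRUE) or assume
#'   the maps pre-superimposed.
#' @param nonrigid apply the dense-displacement correspondence step.
#' @param alpha smoothness weight of the displacement estimation.
#' @param max_shift shift search half-window in cells.
#' @return object of class `average_surface`: `map` (a [height_map()] of
#'   the mean surface) and `count` (per-cell contributing samples).
#' @export
average_surfaces <- function(maps, reference = 1L, align = TRUE,
                             nonrigid = TRUE, alpha = 0.25,
                             max_shift = NULL) {
  if (length(maps) < 2L) stop("need at least 2 height maps")
  if (!all(vapply(maps, inherits, logical(1L), "height_map")))
    stop("maps must be height_map objects")
  dims <- vapply(maps, function(m) dim(m$z), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("maps must share grid dimensions")
  sp <- vapply(maps, function(m) m$spacing, numeric(1L))
  if (any(abs(sp - sp[1L]) > 1e-12))
    stop("maps must share grid spacing")
  ref_hm <- maps[[reference]]
  nr <- nrow(ref_hm$z); nc <- ncol(ref_hm$z)
  K <- length(maps)
  if (is.null(max_shift)) max_shift <- max(2L, round(min(nr, nc) / 8))

  ## --- step 1: rigid superimposition (shift + z offset), centered ---
  shifts <- matrix(0, K, 2L)  # (drow, dcol) moving map toward reference
  zoffs <- numeric(K)
  if (align) {
    for (k in seq_len(K)) {
      if (k == reference) next
      best <- c(0L, 0L); best_sse <- Inf; best_dz <- 0
      for (dr in -max_shift:max_shift) for (dc in -max_shift:max_shift) {
        r_ref <- max(1L, 1L + dr):min(nr, nr + dr)
        r_map <- r_ref - dr
        c_ref <- max(1L, 1L + dc):min(nc, nc + dc)
        c_map <- c_ref - dc
        a <- ref_hm$z[r_ref, c_ref]; b <- maps[[k]]$z[r_map, c_map]
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) < 16L) next
        dz <- mean(a[ok] - b[ok])
        sse <- sum((a[ok] - b[ok] - dz)^2) / sum(ok)
        if (sse < best_sse) {
          best_sse <- sse; best <- c(dr, dc); best_dz <- dz
        }
      }
      shifts[k, ] <- best
      zoffs[k] <- best_dz
    }
    ## center corrections so the ensemble mean position is preserved
    shifts <- sweep(shifts, 2L, colMeans(shifts))
    zoffs <- zoffs - mean(zoffs)
  }
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  aligned <- vector("list", K)
  for (k in seq_len(K)) {
    z <- maps[[k]]$z
    fill <- mean(z[is.finite(z)])
    zf <- z; zf[!is.finite(zf)] <- fill
    ## shifted map sampled into the reference lattice
    zs <- matrix(bilinear_sample(zf, rows - shifts[k, 1L],
                                 cols - shifts[k, 2L]), nr, nc) + zoffs[k]
    ms <- matrix(bilinear_sample(maps[[k]]$mask + 0, rows - shifts[k, 1L],
                                 cols - shifts[k, 2L]), nr, nc) > 0.999
    aligned[[k]] <- list(z = zs, mask = ms)
  }

  ## --- step 2: dense correspondence to the reference ---
  flows <- vector("list", K)
  for (k in seq_len(K)) {
    if (!nonrigid || k == reference) {
      flows[[k]] <- list(u = matrix(0, nr, nc), v = matrix(0, nr, nc))
    } else {
      flows[[k]] <- dense_flow_2d(aligned[[reference]]$z, aligned[[k]]$z,
                                  alpha = alpha)
    }
  }

  ## --- step 3: average corresponded coordinates, re-grid ---
  mx <- my <- mz <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  valid <- matrix(TRUE, nr, nc)
  for (k in seq_len(K)) {
    px <- cols + flows[[k]]$u
    py <- rows + flows[[k]]$v
    pz <- matrix(bilinear_sample(aligned[[k]]$z, py, px), nr, nc)
    pm <- matrix(bilinear_sample(aligned[[k]]$mask + 0, py, px), nr, nc) > 0.999
    mx <- mx + px; my <- my + py; mz <- mz + pz
    cnt <- cnt + pm
    valid <- valid & pm
  }
  mx <- mx / K; my <- my / K; mz <- mz / K
  ## invert the mean in-plane motion: find q with mean position = grid
  qr_ <- rows; qc <- cols
  for (it in seq_len(15L)) {
    ex <- matrix(bilinear_sample(mx, qr_, qc), nr, nc) - cols
    ey <- matrix(bilinear_sample(my, qr_, qc), nr, nc) - rows
    qc <- qc - ex
    qr_ <- qr_ - ey
  }
  z_avg <- matrix(bilinear_sample(mz, qr_, qc), nr, nc)
  ok <- matrix(bilinear_sample(valid + 0, qr_, qc), nr, nc) > 0.999
  z_avg[!ok] <- NA_real_
  out_map <- height_map(z_avg, spacing = ref_hm$spacing,
                        origin = ref_hm$origin)
  structure(list(map = out_map,
                 count = matrix(as.integer(round(
                   bilinear_sample(cnt, qr_, qc))), nr, nc)),
            class = "average_surface")
}

#' @export
print.average_surface <- function(x, ...) {
  cat(sprintf("average_surface: %d x %d cells, %d fully covered\n",
              nrow(x$map$z), ncol(x$map$z), sum(x$map$mask)))
  invisible(x)
}
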