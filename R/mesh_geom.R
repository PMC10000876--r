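## Low-level mesh geometry: normals, spatial indexing, closest-point and
## ray-triangle queries. All queries are vectorized over candidate
## triangles fetched from a uniform grid over triangle bounding boxes, so
## meshes with 1e5+ triangles stay tractable without compiled code.

cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Mean edge length of a mesh
#' @param mesh a [triangle_mesh()].
#' @return mean over unique edges, mm.
#' @export
mean_edge_length <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  mean(sqrt(rowSums((v[e[, 1L], , drop = FALSE] -
                     v[e[, 2L], , drop = FALSE])^2)))
}

#' Area-weighted vertex normals
#' @param mesh a [triangle_mesh()].
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  fn <- cross3(v[f[, 2L], , drop = FALSE] - a,
               v[f[, 3L], , drop = FALSE] - a)  # length = 2 * area
  acc <- matrix(0, nrow(v), 3L)
  for (k in 1:3) {
    s <- rowsum(fn, f[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}

## vertex adjacency list (by index)
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  e <- rbind(e, e[, 2:1])
  e <- unique(e)
  split(e[, 2L], factor(e[, 1L], levels = seq_len(nrow(mesh$vertices))))
}

## uniform grid over triangle AABBs; cell size defaults to 2x mean edge
build_tri_index <- function(mesh, cell = NULL) {
  v <- mesh$vertices; f <- mesh$faces
  if (is.null(cell)) cell <- 2 * mean_edge_length(mesh)
  p1 <- v[f[, 1L], , drop = FALSE]
  p2 <- v[f[, 2L], , drop = FALSE]
  p3 <- v[f[, 3L], , drop = FALSE]
  lo <- pmin(p1, p2, p3); hi <- pmax(p1, p2, p3)
  org <- apply(lo, 2L, min)
  lo_c <- floor(sweep(lo, 2L, org) / cell)
  hi_c <- floor(sweep(hi, 2L, org) / cell)
  keys <- character(0); ids <- integer(0)
  for (i in seq_len(nrow(f))) {
    gx <- lo_c[i, 1L]:hi_c[i, 1L]
    gy <- lo_c[i, 2L]:hi_c[i, 2L]
    gz <- lo_c[i, 3L]:hi_c[i, 3L]
    cells <- expand.grid(gx, gy, gz)
    keys <- c(keys, paste(cells[, 1L], cells[, 2L], cells[, 3L], sep = ","))
    ids <- c(ids, rep.int(i, nrow(cells)))
  }
  ht <- new.env(parent = emptyenv(), hash = TRUE)
  sp <- split(ids, keys)
  for (k in names(sp)) assign(k, sp[[k]], envir = ht)
  list(ht = ht, cell = cell, org = org, mesh = mesh,
       p1 = p1, e1 = p2 - p1, e2 = p3 - p1)
}

## candidate triangle ids within radius r of point p
tri_candidates <- function(index, p, r) {
  lo <- floor((p - r - index$org) / index$cell)
  hi <- floor((p + r - index$org) / index$cell)
  cells <- expand.grid(lo[1L]:hi[1L], lo[2L]:hi[2L], lo[3L]:hi[3L])
  keys <- paste(cells[, 1L], cells[, 2L], cells[, 3L], sep = ",")
  out <- integer(0)
  for (k in keys) {
    hit <- get0(k, envir = index$ht, inherits = FALSE)
    if (!is.null(hit)) out <- c(out, hit)
  }
  unique(out)
}

## closest points on a set of triangles to a single query point
## (Ericson's region decomposition, vectorized over triangles);
## returns list(points, dist2, bary)
closest_on_triangles <- function(p, a, e1, e2) {
  n <- nrow(a)
  b <- a + e1; c_ <- a + e2
  ap <- matrix(p, n, 3L, byrow = TRUE) - a
  d1 <- rowSums(e1 * ap); d2 <- rowSums(e2 * ap)
  bp <- matrix(p, n, 3L, byrow = TRUE) - b
  d3 <- rowSums(e1 * bp); d4 <- rowSums(e2 * bp)
  cp <- matrix(p, n, 3L, byrow = TRUE) - c_
  d5 <- rowSums(e1 * cp); d6 <- rowSums(e2 * cp)
  vc <- d1 * d4 - d3 * d2
  vb <- d5 * d2 - d1 * d6
  va <- d3 * d6 - d5 * d4
  u <- v <- w <- numeric(n)  # barycentric for a, b, c
  done <- rep(FALSE, n)
  set_bary <- function(m, uu, vv, ww) {
    m <- m & !done
    u[m] <<- uu[m]; v[m] <<- vv[m]; w[m] <<- ww[m]
    done[m] <<- TRUE
  }
  one <- rep(1, n); zero <- rep(0, n)
  set_bary(d1 <= 0 & d2 <= 0, one, zero, zero)                 # vertex a
  set_bary(d3 >= 0 & d4 <= d3, zero, one, zero)                # vertex b
  tv <- d1 / (d1 - d3)
  set_bary(vc <= 0 & d1 >= 0 & d3 <= 0, 1 - tv, tv, zero)      # edge ab
  set_bary(d6 >= 0 & d5 <= d6, zero, zero, one)                # vertex c
  tw <- d2 / (d2 - d6)
  set_bary(vb <= 0 & d2 >= 0 & d6 <= 0, 1 - tw, zero, tw)      # edge ac
  tb <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_bary(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
           zero, 1 - tb, tb)                                   # edge bc
  denom <- va + vb + vc
  denom[denom == 0] <- 1
  set_bary(rep(TRUE, n), va / denom, vb / denom, vc / denom)   # interior
  pts <- a * u + b * v + c_ * w
  d <- matrix(p, n, 3L, byrow = TRUE) - pts
  list(points = pts, dist2 = rowSums(d^2), bary = cbind(u, v, w))
}

## Moller-Trumbore over a set of triangles for one ray (both directions);
## returns signed distances t (NA = miss)
ray_hits <- function(orig, dir, a, e1, e2, eps = 1e-12) {
  n <- nrow(a)
  dm <- matrix(dir, n, 3L, byrow = TRUE)
  pvec <- cross3(dm, e2)
  det <- rowSums(e1 * pvec)
  t <- rep(NA_real_, n)
  ok <- abs(det) > eps
  if (!any(ok)) return(t)
  inv <- 1 / det[ok]
  tvec <- matrix(orig, sum(ok), 3L, byrow = TRUE) - a[ok, , drop = FALSE]
  u <- rowSums(tvec * pvec[ok, , drop = FALSE]) * inv
  qvec <- cross3(tvec, e1[ok, , drop = FALSE])
  v <- rowSums(dm[ok, , drop = FALSE] * qvec) * inv
  tt <- rowSums(e2[ok, , drop = FALSE] * qvec) * inv
  good <- u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9
  tt[!good] <- NA_real_
  t[ok] <- tt
  t
}

#' Rigid similarity transform
#'
#' @param R 3x3 rotation matrix (determinant +1).
#' @param t length-3 translation (mm).
#' @param s uniform scale (> 0).
#' @return object of class `similarity_transform`.
#' @export
similarity_transform <- function(R = diag(3), t = c(0, 0, 0), s = 1) {
  R <- as.matrix(R)
  if (abs(det(R) - 1) > 1e-6) stop("R must be a proper rotation (det +1)")
  if (s <= 0) stop("scale must be positive")
  structure(list(R = R, t = as.numeric(t), s = s),
            class = "similarity_transform")
}

#' Apply a similarity transform to points or a mesh
#'
#' Maps x to s R x + t.
#'
#' @param x n x 3 matrix, length-3 vector, or [triangle_mesh()].
#' @param tf a [similarity_transform()].
#' @return transformed object of the same kind.
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  if (inherits(x, "triangle_mesh")) {
    x$vertices <- apply_transform(x$vertices, tf)
    return(x)
  }
  if (inherits(x, "landmark_set")) {
    x$points <- apply_transform(x$points, tf)
    return(x)
  }
  single <- is.null(dim(x))
  m <- if (single) matrix(x, 1L, 3L) else as.matrix(x)
  out <- tf$s * m %*% t(tf$R) + matrix(tf$t, nrow(m), 3L, byrow = TRUE)
  dimnames(out) <- dimnames(m)
  if (single) out[1L, ] else out
}

#' Invert a similarity transform
#' @param tf a [similarity_transform()].
#' @return the inverse [similarity_transform()].
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$R)
  similarity_transform(Rt, -Rt %*% tf$t / tf$s, 1 / tf$s)
}

#' Least-squares landmark alignment (similarity transform)
#'
#' Finds the rotation, uniform scale and translation minimizing the RMS
#' distance between paired landmarks (Umeyama's closed-form solution), so
#' that `apply_transform(source points, result)` best matches the target.
#'
#' @param source,target [landmark_set()]s.
#' @param pairing named character vector mapping source landmark names to
#'   target names; default pairs identical names.
#' @param allow_scale estimate the uniform scale (TRUE) or fix it at 1.
#' @return a [similarity_transform()] with attribute `rms` (residual, mm).
#' @export
align_by_landmarks <- function(source, target, pairing = NULL,
                               allow_scale = TRUE) {
  stopifnot(inherits(source, "landmark_set"),
            inherits(target, "landmark_set"))
  if (is.null(pairing)) {
    common <- intersect(rownames(source$points), rownames(target$points))
    pairing <- stats::setNames(common, common)
  }
  if (length(pairing) < 3L)
    stop("at least 3 paired landmarks are required")
  if (!all(names(pairing) %in% rownames(source$points)))
    stop("pairing names missing from source landmarks")
  if (!all(pairing %in% rownames(target$points)))
    stop("pairing values missing from target landmarks")
  X <- source$points[names(pairing), , drop = FALSE]
  Y <- target$points[pairing, , drop = FALSE]
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  sv <- svd(crossprod(Xc, Yc) / nrow(X))
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    stop("degenerate (collinear) landmark configuration")
  d <- sign(det(sv$v %*% t(sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  var_x <- mean(rowSums(Xc^2))
  s <- if (allow_scale) sum(sv$d * diag(S)) * nrow(X) / (nrow(X) * var_x)
       else 1
  tr <- my - s * as.numeric(R %*% mx)
  tf <- similarity_transform(R, tr, s)
  res <- apply_transform(X, tf) - Y
  attr(tf, "rms") <- sqrt(mean(rowSums(res^2)))
  tf
}

## closest point on a whole mesh (via index); returns point, dist,
## triangle id and barycentric coordinates
closest_on_mesh <- function(index, p, r_start) {
  r <- r_start
  for (i in 1:6) {
    cand <- tri_candidates(index, p, r)
    if (length(cand)) {
      res <- closest_on_triangles(p, index$p1[cand, , drop = FALSE],
                                  index$e1[cand, , drop = FALSE],
                                  index$e2[cand, , drop = FALSE])
      j <- which.min(res$dist2)
      d <- sqrt(res$dist2[j])
      ## accept only if the true nearest cannot be outside searched cells
      if (d <= r)
        return(list(point = res$points[j, ], dist = d, tri = cand[j],
                    bary = res$bary[j, ]))
    }
    r <- r * 2
  }
  list(point = rep(NA_real_, 3L), dist = Inf, tri = NA_integer_,
       bary = rep(NA_real_, 3L))
}

#' Iterative closest point refinement
#'
#' Point-to-plane ICP refining an initial similarity alignment by rigid
#' motion (the scale of `init` is kept fixed). Iterations stop when the
#' RMS improvement falls below `tol` or after `max_iter` rounds; a step
#' that would increase the RMS is rejected, so the reported RMS sequence
#' is non-increasing.
#'
#' @param source,target [triangle_mesh()]es.
#' @param init initial [similarity_transform()] (default identity).
#' @param max_iter iteration cap.
#' @param tol RMS improvement tolerance in mm.
#' @param sample_n maximum number of source vertices used per iteration.
#' @return a [similarity_transform()] with attribute `rms_history`.
#' @export
refine_by_icp <- function(source, target, init = similarity_transform(),
                          max_iter = 100L, tol = 1e-6, sample_n = 2000L) {
  stopifnot(inherits(source, "triangle_mesh"),
            inherits(target, "triangle_mesh"))
  idx <- build_tri_index(target)
  fn <- cross3(idx$e1, idx$e2)
  fn <- fn / pmax(sqrt(rowSums(fn^2)), 1e-300)
  vsrc <- source$vertices
  if (nrow(vsrc) > sample_n)
    vsrc <- vsrc[round(seq(1L, nrow(vsrc), length.out = sample_n)), ,
                 drop = FALSE]
  tf <- init
  r0 <- 3 * mean_edge_length(target)
  rms_of <- function(tf) {
    p <- apply_transform(vsrc, tf)
    d2 <- vapply(seq_len(nrow(p)), function(i)
      closest_on_mesh(idx, p[i, ], r0)$dist^2, numeric(1L))
    sqrt(mean(d2[is.finite(d2)]))
  }
  rms <- rms_of(tf)
  history <- rms
  for (it in seq_len(max_iter)) {
    p <- apply_transform(vsrc, tf)
    q <- matrix(NA_real_, nrow(p), 3L)
    nrm <- matrix(NA_real_, nrow(p), 3L)
    for (i in seq_len(nrow(p))) {
      cp <- closest_on_mesh(idx, p[i, ], r0)
      if (is.finite(cp$dist)) {
        q[i, ] <- cp$point
        nrm[i, ] <- fn[cp$tri, ]
      }
    }
    ok <- is.finite(q[, 1L])
    if (sum(ok) < 6L) break
    pp <- p[ok, , drop = FALSE]; qq <- q[ok, , drop = FALSE]
    nn <- nrm[ok, , drop = FALSE]
    A <- cbind(cross3(pp, nn), nn)
    b <- -rowSums((pp - qq) * nn)
    x <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (is.null(x)) break
    th <- sqrt(sum(x[1:3]^2))
    Rup <- if (th < 1e-300) diag(3) else {
      k <- x[1:3] / th
      K <- matrix(c(0, k[3L], -k[2L], -k[3L], 0, k[1L], k[2L], -k[1L], 0),
                  3L, 3L)
      diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    cand <- similarity_transform(Rup %*% tf$R,
                                 as.numeric(Rup %*% tf$t) + x[4:6], tf$s)
    new_rms <- rms_of(cand)
    if (!is.finite(new_rms) || new_rms > rms) break
    improved <- rms - new_rms
    tf <- cand; rms <- new_rms
    history <- c(history, rms)
    if (improved < tol) break
  }
  attr(tf, "rms_history") <- history
  attr(tf, "rms") <- rms
  tf
}
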