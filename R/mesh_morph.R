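#' Dense source-to-target vertex correspondence
#'
#' For every vertex of the source mesh, finds a corresponding point on the
#' target surface by the minimum projected distance: the vertex is cast
#' along its outward normal (in both directions) and the nearest
#' intersection with the target within the cutoff is taken
#' (`kind = "projected"`). Vertices whose ray misses fall back to the
#' nearest point on the target surface within the cutoff
#' (`kind = "closest"`). Remaining vertices are treated as in-between
#' positions (`kind = "interpolated"`): their target points are filled by
#' iterative averaging over the source mesh neighbor graph (discrete
#' Laplacian relaxation) until the largest update falls below 1e-9.
#'
#' @param source,target [triangle_mesh()]es in a common frame.
#' @param cutoff match cutoff as a multiple of the mean source edge
#'   length (default 5).
#' @return object of class `correspondence_map`: `target_points` (n x 3),
#'   `kind` (per-vertex match kind), `matched` (logical), `cutoff_mm`.
#' @export
dense_correspondence <- function(source, target, cutoff = 5) {
  stopifnot(inherits(source, "triangle_mesh"),
            inherits(target, "triangle_mesh"))
  cutoff_mm <- cutoff * mean_edge_length(source)
  idx <- build_tri_index(target)
  nrm <- vertex_normals(source)
  v <- source$vertices
  n <- nrow(v)
  tp <- matrix(NA_real_, n, 3L)
  kind <- rep("interpolated", n)
  for (i in seq_len(n)) {
    cand <- tri_candidates(idx, v[i, ], cutoff_mm)
    if (!length(cand)) next
    a <- idx$p1[cand, , drop = FALSE]
    e1 <- idx$e1[cand, , drop = FALSE]
    e2 <- idx$e2[cand, , drop = FALSE]
    t_hit <- ray_hits(v[i, ], nrm[i, ], a, e1, e2)
    t_hit[abs(t_hit) > cutoff_mm] <- NA_real_
    if (any(!is.na(t_hit))) {
      j <- which.min(abs(t_hit))
      tp[i, ] <- v[i, ] + t_hit[j] * nrm[i, ]
      kind[i] <- "projected"
    } else {
      res <- closest_on_triangles(v[i, ], a, e1, e2)
      j <- which.min(res$dist2)
      if (sqrt(res$dist2[j]) <= cutoff_mm) {
        tp[i, ] <- res$points[j, ]
        kind[i] <- "closest"
      }
    }
  }
  dimnames(tp) <- list(NULL, c("x", "y", "z"))
  matched <- kind != "interpolated"
  if (!any(matched))
    stop("meshes do not overlap: no vertex found a correspondence ",
         "within the cutoff")
  if (any(!matched)) {
    adj <- mesh_adjacency(source)
    free <- which(!matched)
    for (it in seq_len(10000L)) {
      maxchange <- 0
      any_new <- FALSE
      for (i in free) {
        nb <- adj[[i]]
        defined <- nb[!is.na(tp[nb, 1L])]
        if (!length(defined)) next
        newp <- colMeans(tp[defined, , drop = FALSE])
        old <- tp[i, ]
        tp[i, ] <- newp
        if (anyNA(old)) any_new <- TRUE
        else maxchange <- max(maxchange, max(abs(newp - old)))
      }
      if (!any_new && maxchange < 1e-9) break
    }
  }
  structure(list(target_points = tp, kind = kind, matched = matched,
                 cutoff_mm = cutoff_mm),
            class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf(
    "correspondence_map: %d vertices (%d projected, %d closest, %d interpolated)\n",
    length(x$kind), sum(x$kind == "projected"), sum(x$kind == "closest"),
    sum(x$kind == "interpolated")))
  invisible(x)
}

#' Vertices near the cervical margin
#'
#' Selects the vertices in the lowest fraction of the crown height range,
#' used as the pinned boundary below the functional surface when building
#' a displacement field.
#'
#' @param mesh a [triangle_mesh()].
#' @param frac height fraction (default 0.15).
#' @return integer vertex indices.
#' @export
cervical_margin_vertices <- function(mesh, frac = 0.15) {
  z <- mesh$vertices[, 3L]
  which(z <= min(z) + frac * (max(z) - min(z)))
}

#' Build a displacement field from a correspondence map
#'
#' The per-vertex transformation vector is the corresponding target point
#' minus the source vertex. Boundary vertices (near the cervical margin)
#' are pinned to zero so the crown base stays put during morphing.
#'
#' @param corr a [dense_correspondence()] result.
#' @param source the source [triangle_mesh()] the map refers to.
#' @param boundary integer indices of pinned vertices (e.g. from
#'   [cervical_margin_vertices()]).
#' @return object of class `displacement_field`: `vectors` (n x 3, mm),
#'   `magnitude`, `boundary`, `kind`, `n_vertices`.
#' @export
build_displacement_field <- function(corr, source, boundary = integer(0)) {
  stopifnot(inherits(corr, "correspondence_map"),
            inherits(source, "triangle_mesh"))
  if (nrow(corr$target_points) != nrow(source$vertices))
    stop("correspondence map does not match the source mesh")
  vec <- corr$target_points - source$vertices
  vec[!is.finite(vec)] <- 0  # isolated vertices with no neighbors
  dimnames(vec) <- NULL
  boundary <- as.integer(boundary)
  if (length(boundary)) vec[boundary, ] <- 0
  structure(list(vectors = vec, magnitude = sqrt(rowSums(vec^2)),
                 boundary = boundary, kind = corr$kind,
                 n_vertices = nrow(vec)),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "displacement_field: %d vertices, max |v| = %.4f mm, %d pinned\n",
    x$n_vertices, max(x$magnitude), length(x$boundary)))
  invisible(x)
}

#' Write / read a displacement field as CSV
#'
#' Columns: vertex, dx, dy, dz, magnitude, kind.
#' @param field a [build_displacement_field()] result.
#' @param path destination CSV.
#' @export
write_displacement_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  df <- data.frame(vertex = seq_len(field$n_vertices),
                   dx = field$vectors[, 1L], dy = field$vectors[, 2L],
                   dz = field$vectors[, 3L],
                   magnitude = field$magnitude, kind = field$kind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_displacement_field
#' @export
read_displacement_field <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vec <- as.matrix(df[, c("dx", "dy", "dz")])
  dimnames(vec) <- NULL
  structure(list(vectors = vec, magnitude = sqrt(rowSums(vec^2)),
                 boundary = integer(0), kind = df$kind,
                 n_vertices = nrow(vec)),
            class = "displacement_field")
}

#' Morph a mesh by a displacement field
#'
#' Moves each vertex by its transformation vector; topology is unchanged.
#'
#' @param mesh a [triangle_mesh()].
#' @param field a [displacement_field()] defined on this mesh.
#' @return the morphed [triangle_mesh()].
#' @export
apply_morph <- function(mesh, field) {
  stopifnot(inherits(mesh, "triangle_mesh"),
            inherits(field, "displacement_field"))
  if (field$n_vertices != nrow(mesh$vertices))
    stop("field does not match mesh vertex count")
  mesh$vertices <- mesh$vertices + field$vectors
  mesh
}

#' Transfer a deformation field onto a homologous mesh
#'
#' Applies a displacement field learned on a source crown (e.g. mouse
#' wild-type to mutant) to a third, homologous mesh (e.g. the average
#' human first upper molar). The third mesh is brought into the source
#' frame by least-squares alignment of paired cusp landmarks; each of its
#' vertices then samples the field at the nearest point of the source
#' surface (barycentric interpolation over the source triangle) and the
#' displaced position is mapped back to the native frame, which rescales
#' the displacement by the inverse of the alignment scale. Vertices
#' farther from the source surface than the cutoff receive zero
#' displacement.
#'
#' In `mode = "per_cusp"` the source surface is partitioned by nearest
#' paired landmark, a mean transformation vector is computed per cusp
#' region, and each third-mesh vertex receives a distance-weighted blend
#' of the per-cusp vectors — the coarser, cusp-level reading of the
#' transfer.
#'
#' @param field [displacement_field()] on the source mesh.
#' @param source the source [triangle_mesh()].
#' @param source_landmarks [landmark_set()] on the source.
#' @param third_mesh the homologous [triangle_mesh()] to morph.
#' @param third_landmarks [landmark_set()] on the third mesh.
#' @param pairing named character vector mapping third-mesh landmark
#'   names to source landmark names (e.g. `c(protocone = "c5",
#'   paracone = "c8", metacone = "c6", hypocone = "c9")`); default pairs
#'   identical names.
#' @param cutoff sampling cutoff as a multiple of the mean source edge
#'   length.
#' @param mode `"global"` (dense field sampling) or `"per_cusp"`.
#' @return the morphed third [triangle_mesh()], with attribute
#'   `alignment` (the [similarity_transform()] used).
#' @export
transfer_morph <- function(field, source, source_landmarks, third_mesh,
                           third_landmarks, pairing = NULL, cutoff = 5,
                           mode = c("global", "per_cusp")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "displacement_field"),
            inherits(source, "triangle_mesh"),
            inherits(third_mesh, "triangle_mesh"))
  if (field$n_vertices != nrow(source$vertices))
    stop("field does not match source mesh")
  tf <- align_by_landmarks(third_landmarks, source_landmarks,
                           pairing = pairing)
  inv <- invert_transform(tf)
  x <- apply_transform(third_mesh$vertices, tf)
  cutoff_mm <- cutoff * mean_edge_length(source)
  n <- nrow(x)
  disp <- matrix(0, n, 3L)
  idx <- build_tri_index(source)
  if (mode == "global") {
    fcs <- source$faces
    for (i in seq_len(n)) {
      cp <- closest_on_mesh(idx, x[i, ], cutoff_mm)
      if (is.finite(cp$dist) && cp$dist <= cutoff_mm) {
        tri <- fcs[cp$tri, ]
        disp[i, ] <- cp$bary %*% field$vectors[tri, , drop = FALSE]
      }
    }
  } else {
    if (is.null(pairing)) {
      common <- intersect(rownames(third_landmarks$points),
                          rownames(source_landmarks$points))
      pairing <- stats::setNames(common, common)
    }
    L <- source_landmarks$points[pairing, , drop = FALSE]
    ## partition source vertices by nearest paired landmark; one mean
    ## transformation vector per cusp region
    d2l <- vapply(seq_len(nrow(L)), function(k)
      rowSums(sweep(source$vertices, 2L, L[k, ])^2),
      numeric(nrow(source$vertices)))
    region <- max.col(-d2l)
    Dk <- t(vapply(seq_len(nrow(L)), function(k)
      colMeans(field$vectors[region == k, , drop = FALSE]), numeric(3L)))
    sigma <- mean(stats::dist(L)) / 2
    for (i in seq_len(n)) {
      cp <- closest_on_mesh(idx, x[i, ], cutoff_mm)
      if (!is.finite(cp$dist) || cp$dist > cutoff_mm) next
      w <- exp(-colSums((t(L) - x[i, ])^2) / (2 * sigma^2))
      disp[i, ] <- (w / sum(w)) %*% Dk
    }
  }
  out <- third_mesh
  out$vertices <- apply_transform(x + disp, inv)
  attr(out, "alignment") <- tf
  out
}

#' Symmetric surface distance between two meshes
#'
#' Mean of the two directed mean vertex-to-surface distances; a compact
#' summary of how far apart two crown surfaces are.
#'
#' @param mesh_a,mesh_b [triangle_mesh()]es.
#' @return distance in mm.
#' @export
surface_distance <- function(mesh_a, mesh_b) {
  one_way <- function(m1, m2) {
    idx <- build_tri_index(m2)
    r0 <- 3 * mean_edge_length(m2)
    d <- vapply(seq_len(nrow(m1$vertices)), function(i)
      closest_on_mesh(idx, m1$vertices[i, ], r0)$dist, numeric(1L))
    mean(d[is.finite(d)])
  }
  (one_way(mesh_a, mesh_b) + one_way(mesh_b, mesh_a)) / 2
}
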