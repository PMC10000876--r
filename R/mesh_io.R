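#' Triangle mesh
#'
#' A surface mesh of a tooth crown: vertices in mm and triangular faces as
#' 1-based vertex index triples. On construction, vertices closer than
#' `merge_tol` are merged and zero-area faces are removed.
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param merge_tol vertices within this distance are considered identical.
#' @return an object of class `triangle_mesh` with `vertices` and `faces`.
#' @export
triangle_mesh <- function(vertices, faces, merge_tol = 1e-9) {
  v <- as.matrix(vertices); storage.mode(v) <- "double"
  f <- as.matrix(faces); storage.mode(f) <- "integer"
  if (ncol(v) != 3L) stop("vertices must be n x 3")
  if (ncol(f) != 3L) stop("faces must be m x 3")
  if (!all(is.finite(v))) stop("mesh coordinates must be finite")
  if (nrow(f) && (min(f) < 1L || max(f) > nrow(v)))
    stop("face indices out of vertex range")
  ## merge duplicate vertices (exact up to merge_tol via rounded keys)
  key <- apply(round(v / merge_tol) * merge_tol, 1L, paste, collapse = "/")
  first <- match(key, key)
  remap <- match(first, sort(unique(first)))
  v <- v[sort(unique(first)), , drop = FALSE]
  f[] <- remap[f]
  ## drop degenerate faces (repeated index or zero area)
  if (nrow(f)) {
    rep_idx <- f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]
    a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area <- sqrt(rowSums(cr^2)) / 2
    f <- f[!rep_idx & area > 0, , drop = FALSE]
  }
  dimnames(v) <- list(NULL, c("x", "y", "z"))
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL and ASCII PLY; the format is chosen from
#' the file extension, and STL flavour is auto-detected. Duplicate vertices
#' are merged on load (STL stores each triangle's corners independently).
#'
#' @param path path to a `.stl` or `.ply` file.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path destination (`.stl` writes ASCII STL, `.ply` ASCII PLY).
#' @param binary write binary STL instead of ASCII.
#' @export
write_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = if (binary) write_stl_binary(mesh, path)
               else write_stl_ascii(mesh, path),
         ply = write_ply(mesh, path),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

read_stl <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz == 0) stop("empty or unreadable STL file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 80L))
  is_ascii <- sz >= 6 && identical(rawToChar(head[1:5]), "solid") &&
    !stl_binary_plausible(path, sz)
  if (is_ascii) return(read_stl_ascii(path))
  if (sz < 84) stop("truncated binary STL: ", path)
  seek(con, 80)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (sz < 84 + 50 * as.numeric(ntri)) stop("truncated binary STL: ", path)
  tri <- matrix(NA_real_, ntri * 3L, 3L)
  for (i in seq_len(ntri)) {
    vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  soup_to_mesh(tri)
}

## a file starting with "solid" can still be binary; check the declared
## triangle count against the file size
stl_binary_plausible <- function(path, sz) {
  if (sz < 84) return(FALSE)
  con <- file(path, "rb"); on.exit(close(con))
  seek(con, 80)
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  !is.na(ntri) && ntri > 0 && sz == 84 + 50 * as.numeric(ntri)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) stop("no vertices found in ASCII STL: ", path)
  vals <- suppressWarnings(lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  tri <- do.call(rbind, vals)
  if (anyNA(tri) || nrow(tri) %% 3L != 0L)
    stop("malformed ASCII STL: ", path)
  soup_to_mesh(tri)
}

soup_to_mesh <- function(tri) {
  ntri <- nrow(tri) / 3L
  faces <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  triangle_mesh(tri, faces)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid mesh", con)
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- tri_normal(p)
    writeLines(c(sprintf(" facet normal %.9e %.9e %.9e", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("   vertex %.9e %.9e %.9e", p[, 1], p[, 2], p[, 3]),
                 "  endloop",
                 " endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(f))) {
    p <- v[f[i, ], , drop = FALSE]
    n <- tri_normal(p)
    writeBin(c(n, t(p)), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
}

tri_normal <- function(p) {
  ab <- p[2, ] - p[1, ]; ac <- p[3, ] - p[1, ]
  n <- c(ab[2] * ac[3] - ab[3] * ac[2],
         ab[3] * ac[1] - ab[1] * ac[3],
         ab[1] * ac[2] - ab[2] * ac[1])
  len <- sqrt(sum(n^2))
  if (len > 0) n / len else c(0, 0, 1)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1L] != "ply") stop("not a PLY file: ", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated: ", path)
  nv <- as.integer(sub("element vertex\\s+", "",
                       grep("^element vertex", lines[1:end], value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "",
                       grep("^element face", lines[1:end], value = TRUE)))
  if (!length(nv) || !length(nf)) stop("PLY missing vertex/face elements")
  body <- lines[(end + 1L):length(lines)]
  vv <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                              function(p) as.numeric(p[1:3])))
  ff <- do.call(rbind, lapply(
    strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
    function(p) as.integer(p[2:4]) + 1L))
  triangle_mesh(vv, ff)
}

write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L),
             con)
}

#' Named cusp landmarks
#'
#' A set of named 3D points (mm) marking cusp apices, e.g. `c5`, `c6`,
#' `c8`, `c9` on a mouse upper first molar or `protocone`, `paracone`,
#' `metacone`, `hypocone` on a human one.
#'
#' @param entries named list of length-3 numeric vectors, or a 3-column
#'   matrix with rownames.
#' @return object of class `landmark_set`: a named n x 3 matrix wrapper.
#' @export
landmark_set <- function(entries) {
  if (is.matrix(entries)) {
    m <- entries
  } else {
    if (is.null(names(entries)) || any(names(entries) == ""))
      stop("landmarks must be named")
    m <- do.call(rbind, lapply(entries, function(p) as.numeric(p)))
  }
  storage.mode(m) <- "double"
  if (nrow(m) && ncol(m) != 3L) stop("landmarks must be 3D points")
  if (anyDuplicated(rownames(m))) stop("landmark names must be unique")
  if (!all(is.finite(m))) stop("landmark coordinates must be finite")
  colnames(m) <- c("x", "y", "z")
  structure(list(points = m), class = "landmark_set")
}

#' Read landmarks from JSON
#'
#' Expects an object mapping landmark name to a 3-vector,
#' e.g. `{"c5": [x, y, z], ...}`.
#'
#' @param path path to the JSON file.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write landmarks to JSON
#' @param lms a [landmark_set()].
#' @param path destination file.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  obj <- stats::setNames(lapply(seq_len(nrow(lms$points)),
                                function(i) unname(lms$points[i, ])),
                         rownames(lms$points))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
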