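#' Gridded crown height map
#'
#' A surface z(x, y) sampled on a regular lattice, as produced by optical
#' 3D scanning of crown replicas. Cells without a valid measurement are NA
#' and excluded from all fits.
#'
#' @param z numeric matrix, rows indexing y (increasing), columns x.
#' @param spacing lattice spacing in mm (default 0.05 mm, i.e. a 50 um x
#'   50 um measuring grid).
#' @param origin (x, y) of the first cell center, mm.
#' @return object of class `height_map` with `z`, `spacing`, `origin`,
#'   `mask` (TRUE where valid).
#' @export
height_map <- function(z, spacing = 0.05, origin = c(0, 0)) {
  z <- as.matrix(z); storage.mode(z) <- "double"
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a single positive number")
  if (any(is.infinite(z))) stop("height map values must be finite or NA")
  structure(list(z = z, spacing = spacing, origin = as.numeric(origin),
                 mask = is.finite(z)),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("height_map: %d x %d cells, spacing %g mm, %d valid\n",
              nrow(x$z), ncol(x$z), x$spacing, sum(x$mask)))
  invisible(x)
}

## cell-center coordinate vectors
hm_x <- function(hm) hm$origin[1] + (seq_len(ncol(hm$z)) - 1L) * hm$spacing
hm_y <- function(hm) hm$origin[2] + (seq_len(nrow(hm$z)) - 1L) * hm$spacing

#' Read a height map from an ESRI-style ASCII grid
#'
#' Header lines `ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `nodata_value` followed by `nrows` rows of `ncols` values, first row
#' northernmost (largest y), as written by common GIS and scanning tools.
#'
#' @param path path to the `.asc` file.
#' @return a [height_map()].
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) stop("height map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[a-zA-Z]", trimws(lines[i]))) {
    p <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(p[1L])]] <- as.numeric(p[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("incomplete ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("ASCII grid value count does not match header")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  ## file rows run north->south; store with y increasing along rows
  m <- m[hdr$nrows:1L, , drop = FALSE]
  height_map(m, spacing = hdr$cellsize,
             origin = c(hdr$xllcorner + hdr$cellsize / 2,
                        hdr$yllcorner + hdr$cellsize / 2))
}

#' Write a height map to an ESRI-style ASCII grid
#' @param hm a [height_map()].
#' @param path destination `.asc` file.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(inherits(hm, "height_map"))
  z <- hm$z
  z[!is.finite(z)] <- -9999
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(z)),
               sprintf("nrows %d", nrow(z)),
               sprintf("xllcorner %.10g", hm$origin[1] - hm$spacing / 2),
               sprintf("yllcorner %.10g", hm$origin[2] - hm$spacing / 2),
               sprintf("cellsize %.10g", hm$spacing),
               "nodata_value -9999"), con)
  for (i in nrow(z):1L)
    writeLines(paste(sprintf("%.10g", z[i, ]), collapse = " "), con)
  invisible(path)
}
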