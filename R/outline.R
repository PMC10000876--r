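#' Closed crown outline
#'
#' Construct a validated closed outline: an ordered loop of 2D points (mm)
#' tracing a tooth crown silhouette. The closure edge from the last point
#' back to the first is implicit; a final point identical to the first is
#' dropped on construction. Exactly repeated consecutive points are
#' collapsed. Orientation is forced counter-clockwise (signed-area test) so
#' that chirality conventions are uniform across specimens.
#'
#' @param points two-column numeric matrix (or data frame) of x, y
#'   coordinates in mm.
#' @param label specimen identifier.
#' @param tooth_class `"M1_upper"` or `"M1_lower"` (optional, `NA` allowed).
#' @param cohort `"WT"` or `"mutant"` (optional, `NA` allowed).
#' @return An object of class `closed_outline` with elements `points`
#'   (n x 2 matrix), `label`, `tooth_class`, `cohort`.
#' @export
closed_outline <- function(points, label = NA_character_,
                           tooth_class = NA_character_,
                           cohort = NA_character_) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2L)
    stop("outline points must have exactly two columns (x, y)")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    stop("outline coordinates must all be finite")
  ## drop explicit closure point, then collapse exact consecutive duplicates
  n <- nrow(pts)
  if (n >= 2L && all(pts[n, ] == pts[1L, ])) pts <- pts[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("an outline needs at least 3 distinct points")
  if (outline_signed_area(pts) < 0)
    pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  if (!is.na(tooth_class))
    tooth_class <- match.arg(tooth_class, c("M1_upper", "M1_lower"))
  if (!is.na(cohort))
    cohort <- match.arg(cohort, c("WT", "mutant"))
  dimnames(pts) <- list(NULL, c("x", "y"))
  structure(list(points = pts, label = label,
                 tooth_class = tooth_class, cohort = cohort),
            class = "closed_outline")
}

## shoelace; positive for counter-clockwise loops
outline_signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Outline perimeter
#'
#' Total length of the closed polygonal outline, including the implicit
#' closure edge.
#'
#' @param outline a [closed_outline()].
#' @return perimeter in mm.
#' @export
outline_perimeter <- function(outline) {
  pts <- outline$points
  d <- diff(rbind(pts, pts[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' @export
print.closed_outline <- function(x, ...) {
  cat(sprintf("closed_outline: %d points, perimeter %.4f mm\n",
              nrow(x$points), outline_perimeter(x)))
  cat(sprintf("  label: %s  tooth: %s  cohort: %s\n",
              x$label, x$tooth_class, x$cohort))
  invisible(x)
}

#' Read a closed outline from a two-column CSV
#'
#' The file holds one x,y pair per row, in mm; a header row is optional
#' (detected by non-numeric first fields). A final row equal to the first is
#' treated as an explicit closure point and dropped.
#'
#' @param path path to the CSV file.
#' @inheritParams closed_outline
#' @return a [closed_outline()].
#' @export
read_outline <- function(path, label = NA_character_,
                         tooth_class = NA_character_,
                         cohort = NA_character_) {
  if (!file.exists(path)) stop("outline file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- anyNA(suppressWarnings(
    as.numeric(strsplit(first, ",", fixed = TRUE)[[1L]][1:2])))
  dat <- utils::read.csv(path, header = has_header,
                         colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(dat) < 2L) stop("outline CSV must have two numeric columns")
  xy <- suppressWarnings(cbind(as.numeric(dat[[1L]]), as.numeric(dat[[2L]])))
  if (anyNA(xy)) stop("non-numeric cell in outline file: ", path)
  if (is.na(label)) label <- tools::file_path_sans_ext(basename(path))
  closed_outline(xy, label = label, tooth_class = tooth_class,
                 cohort = cohort)
}

#' Write a closed outline to CSV
#'
#' @param outline a [closed_outline()].
#' @param path destination file.
#' @export
write_outline <- function(outline, path) {
  stopifnot(inherits(outline, "closed_outline"))
  df <- data.frame(x = outline$points[, 1L], y = outline$points[, 2L])
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
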