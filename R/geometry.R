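#' Create a molecular geometry
#'
#' A geometry is a tibble with one row per atom and columns `element`,
#' `x`, `y`, `z` (coordinates in angstrom). A free-text label travels in
#' the `"label"` attribute and becomes the XYZ comment line on write.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric N x 3 matrix of Cartesian coordinates (angstrom).
#' @param label Free-text label for the structure.
#' @return A tibble of class `ms_geometry` with columns `element`, `x`,
#'   `y`, `z`.
#' @examples
#' geometry("He", matrix(0, 1, 3), label = "helium atom")
#' @export
geometry <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry needs at least one atom", call. = FALSE)
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be an N x 3 matrix matching length(elements)", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("all coordinates must be finite", call. = FALSE)
  out <- tibble::tibble(
    element = as.character(elements),
    x = as.numeric(coords[, 1]),
    y = as.numeric(coords[, 2]),
    z = as.numeric(coords[, 3])
  )
  attr(out, "label") <- as.character(label)
  class(out) <- c("ms_geometry", class(out))
  out
}

#' Number of atoms in a geometry
#' @param geom A geometry tibble.
#' @return Integer atom count.
#' @export
n_atoms <- function(geom) nrow(geom)

# N x 3 coordinate matrix of a geometry.
coord_matrix <- function(geom) {
  as.matrix(geom[, c("x", "y", "z")])
}

#' Read a geometry from an XYZ file
#'
#' Standard XYZ: first line the atom count, second line a comment, then
#' one `element x y z` row per atom (coordinates in angstrom).
#'
#' @param path Path to an XYZ file.
#' @return A geometry tibble (see [geometry()]); the comment line is kept
#'   as the `"label"` attribute.
#' @export
load_geometry <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error at line 1: file too short", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("XYZ parse error at line 1: malformed atom count '", lines[1], "'", call. = FALSE)
  }
  if (length(lines) < 2L + n) {
    stop("XYZ parse error: count line says ", n, " atoms but only ",
         length(lines) - 2L, " atom rows present", call. = FALSE)
  }
  rows <- lines[3:(2 + n)]
  parts <- strsplit(trimws(rows), "\\s+")
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    p <- parts[[k]]
    if (length(p) < 4L) {
      stop("XYZ parse error at line ", k + 2L, ": expected 'element x y z'", call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(xyz)) {
      stop("XYZ parse error at line ", k + 2L, ": non-numeric coordinate", call. = FALSE)
    }
    elements[k] <- p[1]
    coords[k, ] <- xyz
  }
  geometry(elements, coords, label = lines[2])
}

#' Write a geometry to an XYZ file
#'
#' Coordinates are written with 6 decimal places.
#'
#' @param geom A geometry tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  label <- attr(geom, "label") %||% ""
  rows <- sprintf("%-2s %14.6f %14.6f %14.6f", geom$element, geom$x, geom$y, geom$z)
  writeLines(c(as.character(nrow(geom)), label, rows), path)
  invisible(path)
}
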