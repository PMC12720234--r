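#' Build a displacement grid of scaling factors
#'
#' The scan abscissa is the unitless scaling factor applied to a
#' unit-norm Cartesian mode vector. The default grid is -0.10 to +0.10
#' in steps of 0.01 (21 points including zero); larger grids (e.g. the
#' +/-1.0 range) are accepted but trigger a warning, since distortions of
#' that size are known to be too large for typical modes.
#'
#' @param from,to,by Grid limits and step.
#' @return Numeric vector of strictly increasing factors of class
#'   `displacement_grid`, containing 0 exactly once.
#' @examples
#' length(displacement_grid())  # 21
#' @export
displacement_grid <- function(from = -0.10, to = 0.10, by = 0.01) {
  if (by <= 0 || to <= from) stop("need by > 0 and to > from", call. = FALSE)
  g <- seq(from, to, by = by)
  g <- round(g, 10)  # kill seq() accumulation so 0 is exact
  if (!any(g == 0)) {
    stop("displacement grid must include the equilibrium point i = 0", call. = FALSE)
  }
  if (max(abs(g)) > 0.5) {
    warning("scaling factors beyond |i| = 0.5 produce very large distortions; ",
            "the +/-0.1 grid is the intended operating range", call. = FALSE)
  }
  structure(g, class = c("displacement_grid", "numeric"))
}

#' Displaced geometries along one normal mode
#'
#' For every scaling factor i in the grid, returns the geometry with
#' coordinates equal to the equilibrium plus i times the unit-norm mode
#' displacement. The i = 0 entry is bit-identical to the equilibrium.
#'
#' @param ms A [mode_set()].
#' @param mode_index Mode number to displace along.
#' @param grid A [displacement_grid()] (or numeric vector of factors).
#' @return A named list of geometry tibbles, one per factor; each carries
#'   a label `mode{MM}_i{+/-0.NN}`.
#' @export
generate_displacements <- function(ms, mode_index, grid = displacement_grid()) {
  v <- mode_vector(ms, mode_index)
  eq <- coord_matrix(ms$equilibrium)
  out <- lapply(as.numeric(grid), function(i) {
    cc <- if (i == 0) eq else eq + i * v
    geometry(ms$equilibrium$element, cc, label = displacement_label(mode_index, i))
  })
  names(out) <- vapply(as.numeric(grid), function(i) displacement_label(mode_index, i), "")
  out
}

displacement_label <- function(mode_index, i) {
  sprintf("mode%02d_i%+0.2f", mode_index, i)
}

#' Generate the full displaced-geometry batch
#'
#' Writes one XYZ file per displaced geometry for every mode in the set
#' (the single equilibrium structure is shared, written once as
#' `equilibrium.xyz`), plus a manifest CSV mapping file names to
#' (mode, i). For M modes and a grid of G factors including zero this
#' produces M x (G - 1) new geometries.
#'
#' @param ms A [mode_set()].
#' @param grid A [displacement_grid()].
#' @param outdir Output directory (created if missing). `NULL` skips
#'   writing files and returns the manifest and geometries only.
#' @return A list with `manifest` (tibble `file`, `mode`, `i`) and
#'   `n_new` (count of new, non-equilibrium geometries).
#' @export
generate_all <- function(ms, grid = displacement_grid(), outdir = NULL) {
  write_files <- !is.null(outdir)
  if (write_files && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  factors <- as.numeric(grid)
  rows <- list()
  if (write_files) {
    eq <- ms$equilibrium
    attr(eq, "label") <- "equilibrium"
    write_geometry(eq, file.path(outdir, "equilibrium.xyz"))
  }
  for (k in ms$modes$mode) {
    geoms <- generate_displacements(ms, k, grid)
    for (j in seq_along(factors)) {
      i <- factors[j]
      if (i == 0) next  # equilibrium is shared, not duplicated per mode
      fname <- paste0(displacement_label(k, i), ".xyz")
      if (write_files) write_geometry(geoms[[j]], file.path(outdir, fname))
      rows[[length(rows) + 1L]] <- tibble::tibble(file = fname, mode = k, i = i)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (write_files) {
    readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  }
  list(manifest = manifest, n_new = nrow(manifest))
}
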