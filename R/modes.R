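#' Construct a set of normal modes
#'
#' A mode set couples an equilibrium geometry with M Cartesian normal
#' modes. Each mode's 3N-component displacement vector is renormalized to
#' unit L2 norm (the sum of squares over all atoms and directions is 1);
#' the norm of the raw input vector is kept in `norm_orig` so any source
#' convention (mass-weighted, engine-normalized) can be recovered.
#'
#' @param equilibrium A geometry tibble (see [geometry()]).
#' @param frequencies Numeric vector of harmonic frequencies in cm-1, one
#'   per mode, in mode order.
#' @param vectors List of N x 3 numeric matrices, one per mode, each the
#'   per-atom Cartesian displacement.
#' @param linear Logical; is the molecule linear (affects the expected
#'   3N-5 vs 3N-6 mode count, not the stored modes).
#' @return An object of class `mode_set`: a list with elements
#'   `equilibrium` (geometry), `modes` (tibble `mode`, `freq_cm1`,
#'   `norm_orig`), `vectors` (list of unit-norm N x 3 matrices) and
#'   `linear`.
#' @export
mode_set <- function(equilibrium, frequencies, vectors, linear = FALSE) {
  n <- n_atoms(equilibrium)
  m <- length(vectors)
  if (length(frequencies) != m) {
    stop("need one frequency per mode vector", call. = FALSE)
  }
  norms <- numeric(m)
  unit <- vector("list", m)
  for (k in seq_len(m)) {
    v <- as.matrix(vectors[[k]])
    if (nrow(v) != n || ncol(v) != 3L) {
      stop("mode ", k, ": displacement must be ", n, " x 3 to match the equilibrium geometry",
           call. = FALSE)
    }
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("mode ", k, ": zero-norm displacement vector (degenerate mode)", call. = FALSE)
    norms[k] <- nrm
    unit[[k]] <- v / nrm
  }
  structure(
    list(
      equilibrium = equilibrium,
      modes = tibble::tibble(
        mode = seq_len(m),
        freq_cm1 = as.numeric(frequencies),
        norm_orig = norms
      ),
      vectors = unit,
      linear = isTRUE(linear)
    ),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat("<mode_set> ", nrow(x$modes), " modes over ", n_atoms(x$equilibrium),
      " atoms", if (x$linear) " (linear)", "\n", sep = "")
  print(x$modes, ...)
  invisible(x)
}

#' Number of modes in a mode set
#' @param ms A `mode_set`.
#' @return Integer mode count.
#' @export
n_modes <- function(ms) nrow(ms$modes)

#' Displacement matrix of one mode
#' @param ms A `mode_set`.
#' @param mode_index 1-based mode number.
#' @return The unit-norm N x 3 displacement matrix.
#' @export
mode_vector <- function(ms, mode_index) {
  if (!mode_index %in% ms$modes$mode) {
    stop("unknown mode index: ", mode_index, call. = FALSE)
  }
  ms$vectors[[mode_index]]
}

#' Expected vibrational mode count
#'
#' 3N-6 for a nonlinear molecule, 3N-5 for a linear one.
#'
#' @param geom A geometry tibble.
#' @param linear Logical; is the molecule linear.
#' @return Integer number of vibrational normal modes.
#' @examples
#' g <- generate_mode_fixture(31, 1, seed = 1)$geometry
#' expected_mode_count(g)  # 87
#' @export
expected_mode_count <- function(geom, linear = FALSE) {
  n <- n_atoms(geom)
  if (n < 2L) stop("expected_mode_count requires at least 2 atoms", call. = FALSE)
  as.integer(3L * n - (if (isTRUE(linear)) 5L else 6L))
}

#' Read normal modes from a plain-text modes file
#'
#' Format: a header line `nmodes M natoms N`, then one block per mode:
#' a line `mode k freq F` (F in cm-1) followed by N lines `dx dy dz`.
#' Blocks may be separated by blank lines. Displacements are renormalized
#' to unit L2 norm on load; the original norm is recorded.
#'
#' @param path Path to the modes file.
#' @param equilibrium The equilibrium geometry the vectors belong to.
#' @param linear Logical; is the molecule linear.
#' @return A [mode_set()].
#' @export
load_modes <- function(path, equilibrium, linear = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) != 4L || hd[1] != "nmodes" || hd[3] != "natoms") {
    stop("modes-file parse error: header must be 'nmodes M natoms N'", call. = FALSE)
  }
  m <- as.integer(hd[2]); n <- as.integer(hd[4])
  if (n != n_atoms(equilibrium)) {
    stop("modes file declares ", n, " atoms but equilibrium geometry has ",
         n_atoms(equilibrium), call. = FALSE)
  }
  pos <- 2L
  freqs <- numeric(m)
  vecs <- vector("list", m)
  for (k in seq_len(m)) {
    if (pos > length(lines)) stop("modes-file parse error: missing block for mode ", k, call. = FALSE)
    mh <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (length(mh) != 4L || mh[1] != "mode" || mh[3] != "freq") {
      stop("modes-file parse error at mode ", k, ": expected 'mode k freq F'", call. = FALSE)
    }
    freqs[k] <- as.numeric(mh[4])
    if (pos + n > length(lines)) {
      stop("modes-file shape error: mode ", k, " has fewer than ", n, " atom rows", call. = FALSE)
    }
    block <- lines[(pos + 1L):(pos + n)]
    v <- suppressWarnings(matrix(as.numeric(unlist(strsplit(trimws(block), "\\s+"))),
                                 ncol = 3, byrow = TRUE))
    if (nrow(v) != n || anyNA(v)) {
      stop("modes-file shape error: mode ", k, " displacement rows malformed", call. = FALSE)
    }
    vecs[[k]] <- v
    pos <- pos + n + 1L
    # next block must start with 'mode' unless we are done
    if (k < m && pos <= length(lines) &&
        !startsWith(trimws(lines[pos]), "mode")) {
      stop("modes-file shape error: mode ", k + 1L,
           " block does not start where expected (atom-row count mismatch in mode ", k, "?)",
           call. = FALSE)
    }
  }
  mode_set(equilibrium, freqs, vecs, linear = linear)
}

#' Write a mode set to the plain-text modes-file format
#' @param ms A `mode_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_modes <- function(ms, path) {
  n <- n_atoms(ms$equilibrium)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("nmodes %d natoms %d", n_modes(ms), n), con)
  for (k in seq_len(n_modes(ms))) {
    writeLines(sprintf("mode %d freq %.4f", k, ms$modes$freq_cm1[k]), con)
    v <- ms$vectors[[k]]
    writeLines(sprintf("%16.10f %16.10f %16.10f", v[, 1], v[, 2], v[, 3]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Mass-weighted displacement length of a unit mode step
#'
#' Reporting helper: converts a step of the unitless scaling factor along
#' a mode into a mass-weighted displacement length (amu^1/2 angstrom).
#' The scan abscissa used everywhere else remains the unitless factor.
#'
#' @param ms A `mode_set`.
#' @param mode_index Mode number.
#' @param masses Named numeric vector of atomic masses (amu) by element
#'   symbol; defaults to standard atomic weights for common elements.
#' @return Mass-weighted length per unit scaling factor.
#' @export
mass_weighted_step <- function(ms, mode_index,
                               masses = c(H = 1.008, C = 12.011, N = 14.007,
                                          O = 15.999, S = 32.06, P = 30.974)) {
  v <- mode_vector(ms, mode_index)
  mm <- masses[ms$equilibrium$element]
  if (anyNA(mm)) stop("mass missing for some element(s)", call. = FALSE)
  sqrt(sum(mm * rowSums(v^2)))
}
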