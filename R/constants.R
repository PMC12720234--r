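## Physical constants and element data used across the package.

#' Unit conversion constants
#'
#' Energy conversion factors used throughout the package. All internal
#' energies are in electron-volts (eV).
#'
#' @format A named numeric vector with elements
#'   \describe{
#'     \item{hartree_to_ev}{1 hartree in eV (CODATA).}
#'     \item{ev_to_kcalmol}{1 eV in kcal/mol.}
#'     \item{ev_to_cm1}{1 eV in reciprocal centimetres.}
#'   }
#' @export
energy_units <- c(
  hartree_to_ev = 27.211386245988,
  ev_to_kcalmol = 23.060548,
  ev_to_cm1     = 8065.544
)

# Covalent radii in angstrom (single-bond values from the standard
# Cordero et al. compilation); used for distance-based bond perception.
.covalent_radii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Fe = 1.32, Cu = 1.32, Zn = 1.22,
  Br = 1.20, I = 1.39
)

covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no covalent radius tabulated for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(r)
}
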