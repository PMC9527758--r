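# Physical constants and unit conversions. All internal quantities are in
# Hartree atomic units (energy Hartree, length Bohr, time a.u., dipole a.u.);
# conversions happen only at the I/O boundary.

#' Unit conversion constants
#'
#' Named constants used throughout the package. Internal computations are in
#' atomic units; Angstrom, eV, femtoseconds and amu appear only when reading
#' or writing files.
#'
#' @format A named list with elements
#'   \describe{
#'     \item{bohr_per_ang}{Bohr per Angstrom (1.8897261254578281).}
#'     \item{ev_per_hartree}{eV per Hartree (27.211386245988).}
#'     \item{au_time_per_fs}{atomic time units per femtosecond (41.3413745758).}
#'     \item{au_mass_per_amu}{electron masses per unified amu (1822.888486209).}
#'     \item{kb_hartree}{Boltzmann constant in Hartree/K.}
#'   }
#' @export
polhop_units <- list(
  bohr_per_ang   = 1.8897261254578281,
  ev_per_hartree = 27.211386245988,
  au_time_per_fs = 41.3413745758,
  au_mass_per_amu = 1822.888486209,
  kb_hartree     = 3.166811563e-6
)

#' @rdname unit_helpers
#' @title Unit conversion helpers
#' @description Scalar/vector converters between the package's internal atomic
#'   units and the conventional I/O units (Angstrom, eV, fs, amu).
#' @param x numeric value(s) to convert.
#' @return converted numeric of the same shape.
#' @export
ang_to_bohr <- function(x) x * polhop_units$bohr_per_ang

#' @rdname unit_helpers
#' @export
bohr_to_ang <- function(x) x / polhop_units$bohr_per_ang

#' @rdname unit_helpers
#' @export
ev_to_hartree <- function(x) x / polhop_units$ev_per_hartree

#' @rdname unit_helpers
#' @export
hartree_to_ev <- function(x) x * polhop_units$ev_per_hartree

#' @rdname unit_helpers
#' @export
fs_to_au <- function(x) x * polhop_units$au_time_per_fs

#' @rdname unit_helpers
#' @export
au_to_fs <- function(x) x / polhop_units$au_time_per_fs

#' @rdname unit_helpers
#' @export
amu_to_au <- function(x) x * polhop_units$au_mass_per_amu

# polarizability volume: Ang^3 -> Bohr^3
#' @rdname unit_helpers
#' @export
ang3_to_bohr3 <- function(x) x * polhop_units$bohr_per_ang^3
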