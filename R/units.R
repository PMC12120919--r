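#' Unit system and physical constants
#'
#' All internal computations use hbar = 1. For "toy" unit mode, masses,
#' lengths and energies are dimensionless and eigenvalues are reported as
#' computed. For "physical" mode, masses are in amu, lengths in Angstrom,
#' angles in rad, and energies are converted to cm^-1 with a single
#' conversion constant that takes energies computed with masses in amu and
#' lengths in Angstrom (hbar = 1) to cm^-1.
#'
#' @format A named list with elements `amu_to_me` (atomic mass unit in
#'   electron masses), `angstrom_to_bohr`, and `hartree_to_cm1`.
#' @keywords internal
vf_units <- list(
  amu_to_me = 1822.888486209,
  angstrom_to_bohr = 1.8897259886,
  hartree_to_cm1 = 219474.6313632
)

#' Convert an energy computed in (amu, Angstrom, hbar = 1) units to cm^-1
#'
#' @param e numeric energy in the internal unit system (masses amu,
#'   lengths Angstrom, hbar = 1).
#' @return numeric energy in cm^-1.
#' @export
vf_energy_to_cm1 <- function(e) {
  # E_hartree = E_internal / (amu_to_me * angstrom_to_bohr^2)
  e / (vf_units$amu_to_me * vf_units$angstrom_to_bohr^2) * vf_units$hartree_to_cm1
}
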