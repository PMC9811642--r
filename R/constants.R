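#' Physical constants and unit conversions
#'
#' Force-field arithmetic is carried out in eV and Angstrom (the units of the
#' published Ca parameter tables); thermodynamics in kJ/mol and nm. All
#' conversion factors are centralized here at >= 8 significant digits.
#'
#' @name calcarb-constants
#' @keywords internal
NULL

## CODATA-derived conversion factors
.KCAL_PER_MOL_TO_EV <- 0.043364104   # 1 kcal/mol in eV
.EV_TO_KJ_PER_MOL <- 96.485332       # 1 eV in kJ/mol
.AVOGADRO <- 6.02214076e23           # mol^-1 (exact, SI 2019)
.GAS_CONSTANT_KJ <- 8.314462e-3      # kJ mol^-1 K^-1

#' Convert an energy from kcal/mol to eV
#'
#' AMBER distributes Lennard-Jones well depths in kcal/mol while the Ca
#' parameter sets handled here are tabulated in eV; this is the bridge.
#'
#' @param x numeric vector of energies in kcal/mol.
#' @return Energies in eV.
#' @examples
#' kcal_per_mol_to_ev(0.2100)  # AMBER carboxylate-oxygen well depth
#' @export
kcal_per_mol_to_ev <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric (kcal/mol)")
  }
  x * .KCAL_PER_MOL_TO_EV
}

#' Convert an energy from eV to kJ/mol
#'
#' @param x numeric vector of energies in eV.
#' @return Energies in kJ/mol.
#' @export
ev_to_kj_per_mol <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric (eV)")
  }
  x * .EV_TO_KJ_PER_MOL
}

#' Molar gas constant in kJ/(mol K)
#' @return The molar gas constant R.
#' @export
gas_constant_kj <- function() .GAS_CONSTANT_KJ

#' Avogadro constant in 1/mol
#' @return The Avogadro constant.
#' @export
avogadro <- function() .AVOGADRO
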