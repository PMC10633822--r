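# Physical constants and unit conversions used throughout.
# Energies are kJ/mol, distances Angstrom, concentrations mM unless stated.

.R_GAS_J <- 8.314        # gas constant, J/(mol K)
.R_GAS_KJ <- 8.314e-3    # gas constant, kJ/(mol K)
.KCAL_TO_KJ <- 4.184     # thermochemical calorie
.N_AVOGADRO <- 6.02214076e23
# reference volume per molecule at 1 mol/L, in A^3 (1 L = 1e27 A^3)
.VREF_1M <- 1e27 / .N_AVOGADRO

#' Thermal energy kT in kJ/mol
#'
#' @param temperature temperature in K
#' @return kT in kJ/mol
#' @keywords internal
kT_kj <- function(temperature) .R_GAS_KJ * temperature
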