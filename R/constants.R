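#' Physical constants and unit conventions
#'
#' The toolkit works in the AKMA-style unit system used throughout
#' biomolecular simulation: energies in kcal/mol, lengths in Angstrom,
#' time in ps, temperature in K, mass in amu.
#'
#' @format `kB` is the Boltzmann constant in kcal/(mol K).
#' @name units
NULL

#' Boltzmann constant, kcal/(mol K)
#' @rdname units
#' @export
kB <- 0.0019872041

# 1 kcal/mol = 4184 J/mol; in amu A^2/ps^2 this is 4184/10 per molecule,
# so accelerations F/m (kcal/mol/A/amu) are scaled by this to A/ps^2.
KCAL_PER_MOL_TO_AKMA <- 418.4

#' Thermal energy kB*T in kcal/mol
#'
#' @param temperature temperature in K
#' @return kB*T in kcal/mol
#' @export
kBT <- function(temperature) kB * temperature
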