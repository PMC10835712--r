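#' Physical constants (CODATA 2018, exact SI where defined)
#'
#' Named list of the physical constants used throughout the package:
#' elementary charge `e` (C), Boltzmann constant `kB` (J/K), Avogadro
#' constant `NAv` (1/mol), vacuum permittivity `eps0` (F/m), and the molar
#' gas constant `Rgas` (J/mol/K).
#'
#' @format A named list of length-1 numerics.
#' @export
sdep_constants <- list(
  e    = 1.602176634e-19,
  kB   = 1.380649e-23,
  NAv  = 6.02214076e23,
  eps0 = 8.8541878128e-12,
  Rgas = 8.31446261815324
)

# unit conversions: interface units are Angstrom / nm / mol/L / C/m^2,
# internal computations are SI
.A_to_m  <- 1e-10
.nm_to_m <- 1e-9
.M_to_m3 <- 1e3 * sdep_constants$NAv # mol/L -> ions/m^3 (per species)

#' Thermal energy in joules
#' @param temperature Temperature in kelvin.
#' @return k_B T in joules.
#' @export
thermal_energy <- function(temperature) sdep_constants$kB * temperature
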