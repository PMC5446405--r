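# Unit system: mass in Dalton, length in Angstrom, energy in kcal/mol
# (per molecule). The derived time unit [L]*sqrt([M]/[E]) is ~48.9 fs.

# CODATA-scale constants
.kB_kcal <- 1.9872e-3        # Boltzmann constant, kcal/mol/K
.kB_J <- 1.380649e-23        # J/K
.NA <- 6.02214076e23         # 1/mol
.e_C <- 1.602176634e-19      # C
.eps0 <- 8.8541878128e-12    # F/m
.Da_kg <- 1.66053906660e-27  # kg
.kcalmol_J <- 4184 / .NA     # J per molecule

#' Debye screening length
#'
#' \eqn{\kappa^{-1} = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}}
#' for a monovalent electrolyte of ionic strength I. At physiological-like
#' conditions (relative permittivity 80, 0.1 M salt, 300 K) this is about
#' 1 nm.
#'
#' @param dielectric relative permittivity (dimensionless), e.g. 80 for water.
#' @param ionic_strength molar ionic strength (mol/L) of a 1:1 electrolyte.
#' @param temperature Kelvin.
#' @return Length in Angstrom.
#' @examples
#' debye_length(80, 0.1, 300) # ~ 9.7 A, i.e. ~1 nm
#' @export
debye_length <- function(dielectric, ionic_strength, temperature = 300) {
  if (any(c(dielectric, ionic_strength, temperature) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  I_m3 <- ionic_strength * 1000  # mol/m^3
  m <- sqrt(.eps0 * dielectric * .kB_J * temperature /
              (2 * .NA * .e_C^2 * I_m3))
  m * 1e10
}

#' Bjerrum length
#'
#' Separation at which the Coulomb energy of two unit charges equals
#' \eqn{k_B T}: \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_r k_B T)};
#' about 7 A in water at 300 K.
#'
#' @inheritParams debye_length
#' @return Length in Angstrom.
#' @export
bjerrum_length <- function(dielectric = 80, temperature = 300) {
  if (dielectric <= 0 || temperature <= 0) {
    stop("all arguments must be positive", call. = FALSE)
  }
  m <- .e_C^2 / (4 * pi * .eps0 * dielectric * .kB_J * temperature)
  m * 1e10
}

#' The intrinsic time unit of the simulation, in femtoseconds
#'
#' With mass in Dalton, length in Angstrom and energy in kcal/mol per
#' molecule, the derived time unit \eqn{[T] = [L]\sqrt{[M]/[E]}} evaluates
#' to approximately 48.9 fs (commonly quoted as ~50 fs).
#'
#' @return Femtoseconds per simulation time unit.
#' @examples
#' dmd_time_unit() # ~ 48.9
#' @export
dmd_time_unit <- function() {
  1e-10 * sqrt(.Da_kg / .kcalmol_J) * 1e15
}

#' Thermal energy in simulation units
#' @param temperature Kelvin.
#' @return kcal/mol.
#' @export
kT <- function(temperature = 300) .kB_kcal * temperature
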