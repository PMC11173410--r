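# Physical constants (CODATA 2018) and the analytic electrostatics layer.
# Internal unit system: lengths in Å, energies in kBT, charges in units of e.

.const <- list(
  e  = 1.602176634e-19,   # elementary charge, C
  eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
  kB = 1.380649e-23       # Boltzmann constant, J/K
)

#' Bjerrum length of a dielectric continuum solvent
#'
#' The Bjerrum length \eqn{l_B = e^2 / (4\pi \varepsilon_0 \varepsilon_r k_B T)}
#' is the separation at which two unit charges interact with thermal energy
#' \eqn{k_B T}; it sets the strength of all Coulomb couplings in the
#' primitive model. In water (\eqn{\varepsilon_r \approx 78}) at 298 K it is
#' about 7.2 Å; in ethanol (\eqn{\varepsilon_r = 20}) about 28 Å.
#'
#' @param solvent a [solvent_spec()].
#' @return Bjerrum length in Å.
#' @examples
#' bjerrum_length(solvent_spec(78))
#' @export
bjerrum_length <- function(solvent) {
  stopifnot(inherits(solvent, "solvent_spec"))
  with(.const, e^2 / (4 * pi * eps0 * solvent$epsilon_r * kB * solvent$temperature)) * 1e10
}

#' Surface charge density of a spherical macroion
#'
#' @param macroion a [macroion_spec()].
#' @return \eqn{|Z_M| e / (4 \pi R_M^2)} in C/m².
#' @examples
#' surface_charge_density(macroion_spec(radius = 20, valence = -60)) # ~0.19 C/m2
#' @export
surface_charge_density <- function(macroion) {
  stopifnot(inherits(macroion, "macroion_spec"))
  r_m <- macroion$radius * 1e-10
  abs(macroion$valence) * .const$e / (4 * pi * r_m^2)
}

#' Counterion-counterion coupling parameter
#'
#' \eqn{\Gamma = Z^2 l_B / a_Z} measures the ratio of the Coulomb repulsion
#' between neighbouring Z-valent counterions condensed on a surface of
#' charge density \eqn{\sigma} to the thermal energy, with
#' \eqn{a_Z = \sqrt{Z e / \sigma}} the mean spacing of those counterions.
#' Ion-ion correlation effects (and with them charge inversion) set in for
#' \eqn{\Gamma \gtrsim 2}.
#'
#' @param valence positive integer counterion valence Z.
#' @param solvent a [solvent_spec()] (enters through the Bjerrum length).
#' @param sigma surface charge density in C/m², e.g. from
#'   [surface_charge_density()].
#' @return dimensionless coupling parameter.
#' @examples
#' coupling_parameter(3, solvent_spec(78), 0.19)
#' @export
coupling_parameter <- function(valence, solvent, sigma) {
  stopifnot(valence > 0, sigma > 0)
  a_z <- sqrt(valence * .const$e / sigma) * 1e10 # Å
  valence^2 * bjerrum_length(solvent) / a_z
}

#' Thermal voltage kBT/e in millivolts
#'
#' Conversion factor between the internal dimensionless potential
#' \eqn{e\varphi / k_B T} and millivolts (about 25.7 mV at 298 K).
#'
#' @param temperature kelvin.
#' @return mV per unit of \eqn{e\varphi/k_B T}.
#' @export
thermal_voltage_mV <- function(temperature = 298) {
  .const$kB * temperature / .const$e * 1000
}
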