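#' Physical constants and unit conventions
#'
#' All quantities in this package use MD units: length in nm, time in ps,
#' energy in kJ/mol, mass in amu (g/mol), temperature in K. Forces are
#' kJ mol^-1 nm^-1 and friction coefficients kJ ps mol^-1 nm^-2. In these
#' units amu * nm^2 / ps^2 = kJ/mol, so no mass conversion factor is needed
#' in the equations of motion.
#'
#' @return `kB()` returns the Boltzmann constant in kJ mol^-1 K^-1.
#' @examples
#' kB() * 300  # thermal energy at 300 K, kJ/mol
#' @export
kB <- function() 0.0083144621

#' Convert a pulling velocity from m/s to nm/ps
#'
#' Pull velocities are conventionally reported in m/s; internally the
#' package works in nm/ps (1 m/s = 1e-3 nm/ps).
#'
#' @param v velocity in m/s.
#' @return velocity in nm/ps.
#' @export
ms_to_nmps <- function(v) v * 1e-3

# ps^-1 -> s^-1
.PS_TO_S <- 1e12
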