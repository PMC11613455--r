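#' Working unit system
#'
#' All quantities in this package are carried in a single working unit
#' system: length in Angstrom (A), time in nanoseconds (ns), viscosity in
#' centipoise (cP), temperature in Kelvin (K) and pressure in bar. The
#' derived energy unit is cP * A^3 / ns, which equals 1e-24 J; with this
#' choice the Stokes-Einstein expression kB*T / (6 * pi * eta[cP] * R[A])
#' evaluates directly to A^2/ns.
#'
#' `crowd_units` collects the conversion factors between SI and working
#' units in one place so that every formula in the package documents its
#' unit handling through a single ledger.
#'
#' @format A named list of conversion factors:
#' \describe{
#'   \item{kB_SI}{Boltzmann constant, J/K (1.380649e-23).}
#'   \item{N_A}{Avogadro constant, 1/mol.}
#'   \item{temperature_default}{Default temperature, 298 K.}
#'   \item{energy_J_per_work}{Joules per working energy unit (cP A^3/ns).}
#'   \item{D_work_per_SI}{(A^2/ns) per (m^2/s), i.e. 1e11.}
#'   \item{visc_cP_per_SI}{cP per Pa s, i.e. 1e3.}
#'   \item{pressure_Pa_per_bar}{Pa per bar, 1e5.}
#'   \item{length_m_per_A}{m per Angstrom.}
#'   \item{time_s_per_ns}{s per ns.}
#' }
#' @export
crowd_units <- list(
  kB_SI               = 1.380649e-23,
  N_A                 = 6.02214076e23,
  temperature_default = 298,
  energy_J_per_work   = 1e-24,   # 1 cP A^3/ns = 1e-3 Pa s * 1e-30 m^3 / 1e-9 s
  D_work_per_SI       = 1e11,    # 1 m^2/s = 1e20 A^2 / 1e9 ns
  visc_cP_per_SI      = 1e3,
  pressure_Pa_per_bar = 1e5,
  length_m_per_A      = 1e-10,
  time_s_per_ns       = 1e-9
)

#' Thermal energy in working units
#'
#' Returns kB*T expressed in the working energy unit cP * A^3 / ns, so that
#' `thermal_energy(T) / (6 * pi * eta * R)` with `eta` in cP and `R` in
#' Angstrom is a translational diffusion coefficient in A^2/ns.
#'
#' @param temperature Temperature in K (> 0).
#' @return Thermal energy kB*T in cP A^3/ns.
#' @examples
#' thermal_energy(298) / (6 * pi * 1 * 1) # ~218.3 A^2/ns for eta=1cP, R=1A
#' @export
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0)) {
    stop("`temperature` must be a positive, finite value in K", call. = FALSE)
  }
  crowd_units$kB_SI * temperature / crowd_units$energy_J_per_work
}

#' Green-Kubo unit prefactor
#'
#' Conversion factor V/(kB*T) taking an integrated pressure-tensor
#' autocorrelation in bar^2 * ns to a viscosity in cP, for a box volume in
#' A^3 and temperature in K. Derivation: eta_SI = V_SI/(kB T) * I_SI with
#' I_SI = I[bar^2 ns] * 1e10 * 1e-9 Pa^2 s, V_SI = V[A^3] * 1e-30 m^3, and
#' 1 Pa s = 1e3 cP, giving eta[cP] = 1e-26 * V * I / (kB * T).
#'
#' @param volume Box volume in A^3.
#' @param temperature Temperature in K.
#' @return Prefactor in cP per (bar^2 ns).
#' @keywords internal
gk_prefactor <- function(volume, temperature) {
  if (volume <= 0) stop("`volume` must be positive (A^3)", call. = FALSE)
  if (temperature <= 0) stop("`temperature` must be positive (K)", call. = FALSE)
  1e-26 * volume / (crowd_units$kB_SI * temperature)
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' @param eta Viscosity in cP.
#' @param radius Hydrodynamic radius in A.
#' @param temperature Temperature in K.
#' @return Diffusion coefficient in A^2/ns.
#' @export
stokes_einstein_Dt <- function(eta, radius, temperature = crowd_units$temperature_default) {
  if (eta <= 0 || radius <= 0) {
    stop("`eta` and `radius` must be positive", call. = FALSE)
  }
  thermal_energy(temperature) / (6 * pi * eta * radius)
}
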