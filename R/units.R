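#' Internal-to-real unit conversion constants
#'
#' The molecular-dynamics engine works in internal units: bead diameter
#' d = 1 (mapped to 1 nm for the integrator, 225 nm physically), thermal
#' energy kT = 1, time in picoseconds. The mapping to real units follows
#' the mobility calibration of radiation-induced 53BP1 foci: 1 real hour
#' corresponds to 5500 ps of simulation, and one bead (100 kb of DNA)
#' has a physical size of 225 nm.
#'
#' The characteristic Lennard-Jones time is tau = d * sqrt(m / U0);
#' with m = 100 amu, d = 1 nm and U0 = kT at 300 K this gives ~6 ps,
#' and the friction coefficient Gamma = 0.5 / tau ~ 0.1 / ps.
#'
#' @param bead_mass_amu bead mass in atomic mass units.
#' @param d_internal_nm internal bead diameter in nm (MD length unit).
#' @param d_real_nm physical bead size in nm.
#' @param temperature_K temperature used to convert kT to Joules.
#' @param ps_per_real_hour internal picoseconds corresponding to one
#'   real hour.
#' @param t_max_ps default observation window of the lesion-dynamics
#'   simulations, internal ps.
#' @param dt_contact_ps interval between contact-formation checks,
#'   internal ps.
#' @return An object of class `scale_map`: a list with the above fields
#'   plus `tau_ps` (Lennard-Jones time), `gamma_per_ps` (friction) and
#'   `bead_mass_internal` (mass in kT*ps^2/d^2 units, so that
#'   d*sqrt(m/kT) = tau).
#' @examples
#' sm <- scale_map()
#' sm$tau_ps              # ~6 ps
#' real_time_conversion(18000)$hours  # ~3.3 h
#' @export
scale_map <- function(bead_mass_amu = 100, d_internal_nm = 1,
                      d_real_nm = 225, temperature_K = 300,
                      ps_per_real_hour = 5500, t_max_ps = 18000,
                      dt_contact_ps = 5) {
  amu <- 1.66053906660e-27 # kg
  kB <- 1.380649e-23       # J/K
  m_kg <- bead_mass_amu * amu
  u0_J <- kB * temperature_K
  tau_s <- (d_internal_nm * 1e-9) * sqrt(m_kg / u0_J)
  tau_ps <- tau_s * 1e12
  structure(list(
    bead_mass_amu = bead_mass_amu,
    d_internal_nm = d_internal_nm,
    d_real_nm = d_real_nm,
    temperature_K = temperature_K,
    ps_per_real_hour = ps_per_real_hour,
    t_max_ps = t_max_ps,
    dt_contact_ps = dt_contact_ps,
    tau_ps = tau_ps,
    gamma_per_ps = 0.1,
    bead_mass_internal = tau_ps^2 # m = kT * (tau/d)^2 with kT = d = 1
  ), class = "scale_map")
}

#' Convert internal simulation time to real time
#'
#' Uses the calibration 1 real hour = 5500 ps of simulation.
#'
#' @param t_ps internal time in picoseconds (non-negative).
#' @param ps_per_real_hour conversion constant.
#' @return List with `hours` and `seconds`.
#' @export
real_time_conversion <- function(t_ps, ps_per_real_hour = 5500) {
  stopifnot(all(t_ps >= 0))
  hours <- t_ps / ps_per_real_hour
  list(hours = hours, seconds = hours * 3600)
}
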