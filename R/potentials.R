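#' Excluded-volume (Weeks-Chandler-Andersen) pair energy
#'
#' `U_ev(r) = 4 u0_ev [ (d/r)^12 - (d/r)^6 + 1/4 ]` for
#' distances up to d*2^(1/6) and 0 beyond; the +1/4 shift makes the potential
#' continuous (zero) at the cutoff.
#'
#' @param r centre-to-centre distance (> 0), same units as `d`.
#' @param u0_ev energy coefficient, kT.
#' @param d bead diameter.
#' @return Energy in kT; vectorized over `r`.
#' @examples
#' excluded_volume_energy(1, 1)        # 1 kT at r = d
#' excluded_volume_energy(2^(1/6), 1)  # 0 at the cutoff
#' @export
excluded_volume_energy <- function(r, u0_ev, d = 1) {
  if (any(r <= 0)) stop("r must be positive")
  s6 <- (d / r)^6
  ifelse(r <= d * 2^(1 / 6), 4 * u0_ev * (s6^2 - s6 + 0.25), 0)
}

#' Attractive (shifted, truncated Lennard-Jones) pair energy
#'
#' Zero up to d*2^(1/6) (where excluded volume acts), the
#' Lennard-Jones form shifted so the value at `r_cut` is exactly zero
#' for `d * 2^(1/6) < r <= r_cut`, and zero beyond `r_cut`. At the
#' default `r_cut = 3 d` the unshifted tail is 0.5% of the well depth,
#' so attraction beyond the cutoff is negligible.
#'
#' @param r centre-to-centre distance (> 0).
#' @param u0_attr_ij attraction depth for the pair, kT.
#' @param r_cut cutoff distance (default 3 d).
#' @param d bead diameter.
#' @return Energy in kT; vectorized over `r`.
#' @examples
#' attraction_energy(3, 1)   # exactly 0 at the cutoff
#' attraction_energy(1.5, 1) # negative (attractive well)
#' @export
attraction_energy <- function(r, u0_attr_ij, r_cut = 3, d = 1) {
  if (any(r <= 0)) stop("r must be positive")
  s6 <- (d / r)^6
  shift <- (d / r_cut)^12 - (d / r_cut)^6
  inside <- r > d * 2^(1 / 6) & r <= r_cut
  ifelse(inside, 4 * u0_attr_ij * (s6^2 - s6 - shift), 0)
}

#' Total potential energy of a conformation
#'
#' Sum of harmonic bond, excluded-volume and attraction terms used by
#' the dynamics engine. Mainly a diagnostic.
#'
#' @param conf a conformation (N x 3 matrix).
#' @param potentials a [pair_potential_field()].
#' @param k_bond harmonic bond stiffness, kT/d^2.
#' @return Scalar energy, kT.
#' @export
total_energy <- function(conf, potentials, k_bond = 200) {
  cpp_total_energy(unclass_conf(conf), potentials$u0_attr,
                   potentials$u0_ev, potentials$diameter,
                   potentials$r_cut, k_bond)
}
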