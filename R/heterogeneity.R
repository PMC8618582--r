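#' Pair-distance distribution around an anchor locus
#'
#' For every partner locus j, the distances between the anchor and j
#' are histogrammed over the ensemble on radial bins of width `dr` and
#' normalized per chromosome and per shell volume:
#' `psi_{i,j}(r) = counts / (K * 4 pi r_mid^2 dr)`, so that
#' `integral psi 4 pi r^2 dr = 1` for every pair (midpoint rule; the
#' identity closes exactly on the histogram grid). The grid extends to
#' the chain's maximum extension; with the default `dr = 0.05 d` the
#' 1.2-d contact radius falls on a bin edge.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param anchor 1-based bead index i.
#' @param dr radial bin width, diameters.
#' @param r_max grid extent (default: chain length N in diameters,
#'   rounded up to a whole bin).
#' @return Object of class `distance_distribution`: list with `psi`
#'   (nbins x N matrix), `counts`, `r_mid`, `dr`, `anchor`, `K`.
#' @export
distance_distribution <- function(ensemble, anchor, dr = 0.05,
                                  r_max = NULL) {
  stopifnot(dr > 0)
  K <- length(ensemble)
  n <- nrow(ensemble$members[[1]])
  if (anchor < 1 || anchor > n) stop("anchor out of range")
  if (is.null(r_max)) r_max <- n
  nbins <- as.integer(ceiling(r_max / dr))
  counts <- cpp_pair_distance_counts(ensemble_positions(ensemble),
                                     anchor - 1L, dr, nbins)
  r_mid <- (seq_len(nbins) - 0.5) * dr
  psi <- counts / (K * 4 * pi * r_mid^2 * dr)
  structure(list(psi = psi, counts = counts, r_mid = r_mid, dr = dr,
                 anchor = anchor, K = K),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "<distance_distribution> anchor bead %d, %d partners, %d radial bins of %g d\n",
    x$anchor, ncol(x$psi), nrow(x$psi), x$dr))
  invisible(x)
}

#' Damage heterogeneity function
#'
#' Weights the pair-distance distribution by the damage probability of
#' the partner locus: `phi_{i,j}(r; D) = psi_{i,j}(r) * [P_DSB(D) +
#' Gamma_sp(j)]`. The per-cell variant (two homolog copies) is `2 phi`.
#'
#' @param psi a `distance_distribution`.
#' @param params an [ir_params()].
#' @param gamma_sp per-bead spontaneous DSB probabilities or NULL.
#' @param per_cell multiply by 2 for the per-cell function.
#' @return Object of class `damage_heterogeneity` with the same radial
#'   grid and a `phi` matrix.
#' @export
damage_heterogeneity <- function(psi, params, gamma_sp = NULL,
                                 per_cell = FALSE) {
  n <- ncol(psi$psi)
  pdmg <- rep(ir_damage_probability(params), n)
  if (!is.null(gamma_sp)) {
    stopifnot(length(gamma_sp) == n)
    pdmg <- pdmg + gamma_sp
  }
  phi <- sweep(psi$psi, 2, pdmg, "*")
  if (per_cell) phi <- 2 * phi
  structure(list(phi = phi, r_mid = psi$r_mid, dr = psi$dr,
                 anchor = psi$anchor, dose = params$dose,
                 per_cell = per_cell),
            class = "damage_heterogeneity")
}

#' Breakpoint profile from the damage heterogeneity function
#'
#' Distance-distribution route to the breakpoints: the expected lesion
#' contacts per cell are the radial integral of phi up to the
#' colocalization radius, `f_cont(j) = 2 * integral_0^{R_cont_CA} phi
#' 4 pi r^2 dr`, and each contact converts with probability `p_ce`:
#' `f_bp(j) = f_cont(j) * p_ce`. With `R_cont_CA` equal to the contact
#' radius used for structure simulation, this reproduces the
#' contact-route profile exactly.
#'
#' @param phi a `damage_heterogeneity` (per-chromosome, i.e. built with
#'   `per_cell = FALSE`; the factor 2 is applied here).
#' @param R_cont_CA lesion colocalization radius (default 1.2 d); must
#'   not exceed the radial grid.
#' @param p_ce contact-to-exchange probability.
#' @return Numeric vector of expected breakpoints per cell per bead
#'   (zero at the anchor).
#' @export
breakpoints_from_heterogeneity <- function(phi, R_cont_CA = 1.2, p_ce) {
  if (phi$per_cell)
    stop("supply the per-chromosome phi; the per-cell factor 2 is applied here")
  grid_max <- max(phi$r_mid) + phi$dr / 2
  if (R_cont_CA > grid_max + 1e-12)
    stop("R_cont_CA beyond the radial grid")
  sel <- phi$r_mid < R_cont_CA
  shell <- 4 * pi * phi$r_mid[sel]^2 * phi$dr
  f_cont <- 2 * as.numeric(shell %*% phi$phi[sel, , drop = FALSE])
  out <- f_cont * p_ce
  out[phi$anchor] <- 0
  out
}
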