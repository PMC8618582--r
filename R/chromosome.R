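#' Bead-chain description of one chromosome
#'
#' A chromosome is represented as a chain of `n_subunits` beads, each
#' carrying 100 kb of DNA. The first beads form the centromeric region
#' (modelled dynamically but excluded from Hi-C comparison), one bead is
#' the nuclease (I-SceI) recognition site, and an optional set of beads
#' is non-mappable in the experimental map.
#'
#' Bead indices are 1-based. Bead `b` covers the genomic half-open
#' interval `[bin_origin + (b-1)*resolution, bin_origin + b*resolution)`.
#'
#' @param label chromosome name (e.g. "chr18").
#' @param n_subunits number of beads N (>= 3).
#' @param breaksite 1-based bead index of the nuclease recognition site.
#' @param centromere integer vector of centromeric bead indices
#'   (default: the first 30 beads, i.e. 3 Mb, capped at N).
#' @param non_mappable integer vector of non-mappable bead indices; must
#'   not contain the breaksite.
#' @param diameter bead diameter in internal units (1).
#' @param cage_radius equilibration cage radius in diameters (14).
#' @param bin_origin genomic coordinate of the start of bead 1 (bp).
#' @param resolution bin size in bp (100 kb).
#' @return Object of class `chromosome_spec`.
#' @examples
#' sp <- chromosome_spec("toy", 50, breaksite = 25, centromere = 1:5)
#' sp
#' @export
chromosome_spec <- function(label, n_subunits, breaksite,
                            centromere = seq_len(min(30, n_subunits)),
                            non_mappable = integer(0),
                            diameter = 1, cage_radius = 14,
                            bin_origin = 0, resolution = 1e5) {
  n_subunits <- as.integer(n_subunits)
  breaksite <- as.integer(breaksite)
  centromere <- as.integer(centromere)
  non_mappable <- as.integer(non_mappable)
  stopifnot(n_subunits >= 3,
            breaksite >= 1, breaksite <= n_subunits,
            all(centromere >= 1), all(centromere <= n_subunits),
            all(non_mappable >= 1), all(non_mappable <= n_subunits))
  if (breaksite %in% non_mappable)
    stop("the breaksite bead cannot be non-mappable")
  structure(list(label = label, n_subunits = n_subunits,
                 breaksite = breaksite, centromere = centromere,
                 non_mappable = non_mappable, diameter = diameter,
                 cage_radius = cage_radius, bin_origin = bin_origin,
                 resolution = resolution),
            class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("<chromosome_spec> %s: N = %d beads of %g kb\n",
              x$label, x$n_subunits, x$resolution / 1e3))
  cat(sprintf("  breaksite bead %d; %d centromeric, %d non-mappable beads\n",
              x$breaksite, length(x$centromere), length(x$non_mappable)))
  invisible(x)
}

#' Bead-chain specs for the mouse chromosomes of the reference study
#'
#' Chain lengths 1818 (chr2), 1526 (chr7) and 908 (chr18) beads of
#' 100 kb; breaksite bins 180.1-180.2 Mb (chr2), 31.2-31.3 Mb (chr7)
#' and 70.6-70.7 Mb (chr18); the first 30 beads (3 Mb) are centromeric.
#'
#' @param chrom one of "chr2", "chr7", "chr18".
#' @return A `chromosome_spec`.
#' @export
mouse_chromosome_spec <- function(chrom = c("chr18", "chr7", "chr2")) {
  chrom <- match.arg(chrom)
  n <- c(chr2 = 1818L, chr7 = 1526L, chr18 = 908L)[[chrom]]
  bait_mb <- c(chr2 = 180.1, chr7 = 31.2, chr18 = 70.6)[[chrom]]
  chromosome_spec(chrom, n, breaksite = as.integer(bait_mb * 10) + 1L)
}

#' Per-pair interaction potential field
#'
#' Holds the single excluded-volume coefficient `u0_ev` (applied to all
#' pairs through the Weeks-Chandler-Andersen potential), the symmetric
#' N x N matrix of attraction depths `u0_attr` (shifted-truncated
#' Lennard-Jones), and the attraction cutoff `r_cut` (3 diameters).
#' Entries for bonded neighbours (|i-j| = 1) are ignored by the energy.
#'
#' @param u0_attr symmetric non-negative N x N matrix of attraction
#'   depths, kT units.
#' @param u0_ev excluded-volume coefficient, kT.
#' @param r_cut attraction cutoff, diameters; must exceed 2^(1/6).
#' @param diameter bead diameter (1).
#' @return Object of class `pair_potential_field`.
#' @export
pair_potential_field <- function(u0_attr, u0_ev = 1, r_cut = 3,
                                 diameter = 1) {
  u0_attr <- as.matrix(u0_attr)
  stopifnot(nrow(u0_attr) == ncol(u0_attr),
            all(u0_attr >= 0), u0_ev >= 0,
            r_cut > diameter * 2^(1 / 6))
  if (!isTRUE(all.equal(u0_attr, t(u0_attr), tolerance = 1e-12)))
    stop("u0_attr must be symmetric")
  diag(u0_attr) <- 0
  structure(list(u0_attr = u0_attr, u0_ev = u0_ev, r_cut = r_cut,
                 diameter = diameter),
            class = "pair_potential_field")
}

#' @export
print.pair_potential_field <- function(x, ...) {
  off <- x$u0_attr[upper.tri(x$u0_attr)]
  cat(sprintf(
    "<pair_potential_field> N = %d; u0_ev = %g kT; r_cut = %g d\n",
    nrow(x$u0_attr), x$u0_ev, x$r_cut))
  cat(sprintf("  u0_attr range [%.3g, %.3g] kT, mean %.3g kT\n",
              min(off), max(off), mean(off)))
  invisible(x)
}

#' Reference trial-structure potential fields
#'
#' Baseline chromosome models used for comparison with the fitted
#' heteropolymer globule: a dense homopolymer globule (uniform
#' attraction 1.57 kT for chr2, 2.33 kT for chr7, 9.34 kT for chr18), a
#' loose homopolymer globule (1.2 kT; used for chr18), a self-avoiding
#' polymer coil (no attraction), a random walk (no attraction and no
#' excluded volume), and the uniform 1.2-kT starting field of the
#' heteropolymer fit.
#'
#' @param kind one of "heteropolymer-init", "homopolymer",
#'   "loose-globule", "coil", "random-walk".
#' @param spec a [chromosome_spec()]; the `label` selects the
#'   homopolymer constant for "chr2"/"chr7"/"chr18" (other labels get
#'   the chr18 value).
#' @param u0_ev excluded-volume coefficient for kinds that use it.
#' @return A [pair_potential_field()].
#' @export
make_trial_potentials <- function(kind = c("heteropolymer-init",
                                           "homopolymer", "loose-globule",
                                           "coil", "random-walk"),
                                  spec, u0_ev = 1) {
  kind <- match.arg(kind)
  n <- spec$n_subunits
  uniform <- function(v) {
    m <- matrix(v, n, n)
    diag(m) <- 0
    m
  }
  homo_const <- switch(spec$label, chr2 = 1.57, chr7 = 2.33, 9.34)
  switch(kind,
    "heteropolymer-init" = pair_potential_field(uniform(1.2), u0_ev),
    "homopolymer" = pair_potential_field(uniform(homo_const), u0_ev),
    "loose-globule" = pair_potential_field(uniform(1.2), u0_ev),
    "coil" = pair_potential_field(uniform(0), u0_ev),
    "random-walk" = pair_potential_field(uniform(0), 0))
}

# mask of beads excluded from map comparison (centromere + non-mappable)
masked_beads <- function(spec) {
  sort(unique(c(spec$centromere, spec$non_mappable)))
}

# logical N x N matrix of pairs excluded from map comparison and
# potential updates: s <= 1 (diagonal and nearest neighbours),
# centromeric and non-mappable beads
pair_mask <- function(spec) {
  n <- spec$n_subunits
  m <- matrix(FALSE, n, n)
  bad <- masked_beads(spec)
  m[bad, ] <- TRUE
  m[, bad] <- TRUE
  idx <- seq_len(n)
  m[abs(outer(idx, idx, "-")) <= 1] <- TRUE
  m
}
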