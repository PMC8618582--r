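#' Binary contact map of a single conformation
#'
#' A contact between beads i and j is scored when their centre distance
#' does not exceed `R_cont` (inclusive); the reference radius is
#' 1.2 diameters.
#'
#' @param conf a `conformation` (N x 3 matrix).
#' @param R_cont contact radius, diameters.
#' @return Symmetric integer N x N matrix of 0/1 with zero diagonal.
#' @export
conformation_contacts <- function(conf, R_cont = 1.2) {
  stopifnot(R_cont > 0)
  cpp_contact_matrix(unclass_conf(conf), R_cont)
}

new_contact_map <- function(values, mode, spec = NULL, resolution = 1e5,
                            masked = FALSE) {
  structure(list(values = values, mode = mode, spec = spec,
                 resolution = resolution, masked = masked),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> %d x %d, mode = %s, masked = %s\n",
              nrow(x$values), ncol(x$values), x$mode, x$masked))
  invisible(x)
}

#' Aggregate an ensemble of conformations into a contact map
#'
#' Modes: `counts` is the plain sum of single-conformation binary maps
#' over the K ensemble members; `relative` divides the counts by the
#' total over unmasked pairs (contacts at genomic separation s = 1 and,
#' when a spec is given, centromeric/non-mappable pairs are excluded
#' from the total and zeroed), so unmasked entries sum to 1;
#' `per-chromosome` is counts/K (the fraction of conformations with the
#' contact); `per-cell` is counts/M with M = K/2 cells, i.e. exactly
#' twice the per-chromosome map.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param mode one of "counts", "relative", "per-chromosome",
#'   "per-cell".
#' @param spec optional [chromosome_spec()] supplying the centromere /
#'   non-mappable masks (applied in `relative` mode).
#' @param R_cont contact radius, diameters.
#' @return A `contact_map`.
#' @export
aggregate_contacts <- function(ensemble,
                               mode = c("counts", "relative",
                                        "per-chromosome", "per-cell"),
                               spec = NULL, R_cont = 1.2) {
  mode <- match.arg(mode)
  K <- length(ensemble)
  counts <- cpp_ensemble_contact_counts(ensemble_positions(ensemble),
                                        R_cont)
  if (mode == "counts")
    return(new_contact_map(counts, "counts", spec))
  if (mode == "per-chromosome")
    return(new_contact_map(counts / K, "per-chromosome", spec))
  if (mode == "per-cell") {
    if (K %% 2 != 0)
      stop("per-cell mode needs an even ensemble size (K = 2M)")
    return(new_contact_map(counts / (K / 2), "per-cell", spec))
  }
  relative_contact_map(counts, spec)
}

# normalize a counts matrix to relative frequencies per the s > 1,
# unmasked-pairs convention
relative_contact_map <- function(counts, spec = NULL) {
  n <- nrow(counts)
  mask <- if (!is.null(spec)) pair_mask(spec) else {
    idx <- seq_len(n)
    abs(outer(idx, idx, "-")) <= 1
  }
  vals <- counts
  vals[mask] <- 0
  tot <- sum(vals[upper.tri(vals)]) # total contacts over unmasked pairs
  if (tot > 0) vals <- vals / tot   # unmasked upper-triangle sums to 1
  new_contact_map(vals, "relative", spec, masked = TRUE)
}

#' Pearson correlation between two contact maps
#'
#' Computed over unmasked upper-triangle entries only (genomic
#' separation s > 1; centromeric and non-mappable beads excluded when a
#' spec is given).
#'
#' @param a,b `contact_map` objects or plain matrices of equal size.
#' @param spec optional [chromosome_spec()] for the masks.
#' @return Pearson correlation coefficient.
#' @export
map_pearson <- function(a, b, spec = NULL) {
  va <- if (inherits(a, "contact_map")) a$values else a
  vb <- if (inherits(b, "contact_map")) b$values else b
  stopifnot(all(dim(va) == dim(vb)))
  n <- nrow(va)
  mask <- if (!is.null(spec)) pair_mask(spec) else {
    idx <- seq_len(n)
    abs(outer(idx, idx, "-")) <= 1
  }
  keep <- upper.tri(va) & !mask
  stats::cor(va[keep], vb[keep])
}

#' Contact frequency versus genomic separation
#'
#' `f(s)` sums the relative contact frequencies along each
#' anti-diagonal: `f(s) = sum_i C(i, i+s)` for s = 2 .. N-1 (s = 1 is
#' excluded by the normalization convention). Centromeric and
#' non-mappable pairs are already zeroed in a masked relative map.
#'
#' @param map a `contact_map` in relative mode.
#' @return Data frame with columns `s` (bins) and `f`.
#' @export
contact_vs_separation <- function(map) {
  if (!inherits(map, "contact_map") || map$mode != "relative")
    stop("contact_vs_separation expects a relative-mode contact map")
  v <- map$values
  n <- nrow(v)
  s <- 2:(n - 1)
  f <- vapply(s, function(si) {
    i <- seq_len(n - si)
    sum(v[cbind(i, i + si)])
  }, 1.0)
  data.frame(s = s, f = f)
}

#' Power-law exponent of the contact-frequency decay
#'
#' Least-squares slope of log f versus log s over separations inside a
#' genomic range (default 0.5-5 Mb, i.e. 5-50 bins of 100 kb). Bins
#' with non-positive f are dropped; fewer than 3 usable points is an
#' error.
#'
#' @param fs data frame from [contact_vs_separation()].
#' @param s_range_mb genomic range in Mb, length 2.
#' @param resolution bin size in bp.
#' @return The exponent nu (slope; negative for decaying f).
#' @export
power_exponent <- function(fs, s_range_mb = c(0.5, 5),
                           resolution = 1e5) {
  lo <- s_range_mb[1] * 1e6 / resolution
  hi <- s_range_mb[2] * 1e6 / resolution
  sel <- fs$s >= lo & fs$s <= hi & fs$f > 0
  if (sum(sel) < 3) stop("fewer than 3 positive points in the s range")
  unname(coef(lm(log(fs$f[sel]) ~ log(fs$s[sel])))[2])
}

#' Pseudo-4C profile: one anchor row of a contact map
#'
#' Emulates a 4C experiment with the bait at `anchor`: the profile is
#' the anchor's row of the map; the anchor's own bin is flagged so
#' downstream comparisons can exclude it.
#'
#' @param map a `contact_map`.
#' @param anchor 1-based bead index; must not be masked.
#' @param spec optional [chromosome_spec()] used to reject masked
#'   anchors.
#' @return Numeric vector of length N with attribute `anchor`.
#' @export
pseudo4c_profile <- function(map, anchor, spec = map$spec) {
  v <- map$values
  if (anchor < 1 || anchor > nrow(v)) stop("anchor out of range")
  if (!is.null(spec) && anchor %in% masked_beads(spec))
    stop("anchor bead is masked (centromeric or non-mappable)")
  out <- v[anchor, ]
  attr(out, "anchor") <- anchor
  out
}

#' Single-cell contact map from two homolog conformations
#'
#' The single-cell map is the sum of the binary contact maps of the two
#' homologous chromosome copies (values 0, 1, 2).
#'
#' @param conf_a,conf_b conformations of the two homologs (same N).
#' @param R_cont contact radius.
#' @return A `contact_map` with mode "counts".
#' @export
single_cell_map <- function(conf_a, conf_b, R_cont = 1.2) {
  if (nrow(conf_a) != nrow(conf_b)) stop("homolog N mismatch")
  m <- conformation_contacts(conf_a, R_cont) +
       conformation_contacts(conf_b, R_cont)
  new_contact_map(m, "counts")
}

#' Average per-cell values over a random pool of cells
#'
#' Emulates averaging over pools of 10, 100, 1000 ... cells: a seeded
#' random subset of `m` cells is drawn without replacement and their
#' per-cell values averaged.
#'
#' @param items matrix with one row per cell (columns = bins), or a
#'   list of equal-length vectors.
#' @param m pool size (1 <= m <= number of cells).
#' @param seed integer seed.
#' @return Mean profile over the pool (numeric vector).
#' @export
pool_average <- function(items, m, seed = 1) {
  if (is.list(items)) items <- do.call(rbind, items)
  ncells <- nrow(items)
  stopifnot(m >= 1, m <= ncells)
  set.seed(seed)
  sel <- sample.int(ncells, m, replace = FALSE)
  colMeans(items[sel, , drop = FALSE])
}

#' Rebin a 100-kb profile to 200 kb and smooth with a 1-Mb window
#'
#' Adjacent 100-kb bins are summed pairwise to 200 kb, then a centred
#' boxcar mean over 1 Mb (5 bins of 200 kb) is applied, truncated at
#' the profile edges. Bins inside `exempt_region` are rebinned but not
#' smoothed (mirroring the treatment of a region where experimental
#' data exist at high resolution).
#'
#' @param values numeric vector at 100-kb resolution.
#' @param exempt_bins optional integer vector of 100-kb bin indices to
#'   exempt from smoothing.
#' @param window_bins boxcar width in 200-kb bins (default 5 = 1 Mb).
#' @return Numeric vector at 200-kb resolution with attribute
#'   `exempt_bins_200kb`.
#' @export
rebin_smooth <- function(values, exempt_bins = NULL, window_bins = 5) {
  if (window_bins < 1) stop("window smaller than one bin")
  n <- length(values)
  if (n %% 2 == 1) values <- c(values, 0)
  coarse <- values[seq(1, length(values), by = 2)] +
            values[seq(2, length(values), by = 2)]
  nc <- length(coarse)
  half <- window_bins %/% 2
  sm <- vapply(seq_len(nc), function(i) {
    w <- max(1, i - half):min(nc, i + half)
    mean(coarse[w])
  }, 1.0)
  ex200 <- integer(0)
  if (!is.null(exempt_bins)) {
    ex200 <- sort(unique((as.integer(exempt_bins) + 1L) %/% 2L))
    sm[ex200] <- coarse[ex200]
  }
  structure(sm, exempt_bins_200kb = ex200)
}

#' Empirical distribution of per-cell anchor contact counts
#'
#' Pairs consecutive ensemble members into cells (members 2k-1 and 2k
#' are the homologs of cell k) and tabulates, per cell, the number of
#' contacts between the anchor and other loci -- optionally restricted
#' to damaged loci drawn by a damage sampler.
#'
#' @param ensemble a `conformation_ensemble` with even K.
#' @param anchor 1-based bead index.
#' @param damage_sampler optional function(copy_index) returning the
#'   1-based damaged bead indices for one chromosome copy (called 2
#'   times per cell); when given, only anchor contacts with damaged
#'   partners are counted.
#' @param R_cont contact radius.
#' @return Data frame `count`, `p`: the empirical pmf (sums to 1), with
#'   attribute `samples` holding the per-cell counts.
#' @export
contact_count_pmf <- function(ensemble, anchor, damage_sampler = NULL,
                              R_cont = 1.2) {
  K <- length(ensemble)
  if (K < 2 || K %% 2 != 0) stop("ensemble must pair into cells (even K)")
  pos <- ensemble_positions(ensemble)
  per_copy <- vapply(seq_len(K), function(k) {
    p <- pos[[k]]
    dd <- sqrt(colSums((t(p) - p[anchor, ])^2))
    dd[anchor] <- Inf
    hit <- which(dd <= R_cont)
    if (!is.null(damage_sampler)) hit <- intersect(hit, damage_sampler(k))
    length(hit)
  }, 1L)
  samples <- per_copy[seq(1, K, 2)] + per_copy[seq(2, K, 2)]
  tab <- table(factor(samples, levels = 0:max(samples)))
  out <- data.frame(count = as.integer(names(tab)),
                    p = as.numeric(tab) / length(samples))
  attr(out, "samples") <- samples
  out
}
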