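#' Radiation damage parameters
#'
#' Gamma-ray double-strand-break induction with efficiency
#' `alpha = 8.2e-9 per Gy per bp`, subunit DNA content `L = 1e5 bp`,
#' dose `D` in Gy. The per-subunit mean DSB number is
#' `n = alpha * D * L = 8.2e-4 * D`, far below 1 for all doses up to
#' 15 Gy, so the probability of one DSB in a subunit is ~ n.
#'
#' @param dose absorbed dose, Gy (>= 0).
#' @param alpha DSB induction efficiency, 1/(Gy bp).
#' @param L DNA content per subunit, bp.
#' @return Object of class `ir_params`.
#' @export
ir_params <- function(dose, alpha = 8.2e-9, L = 1e5) {
  stopifnot(dose >= 0, alpha > 0, L > 0)
  structure(list(dose = dose, alpha = alpha, L = L),
            class = "ir_params")
}

#' Per-subunit probability of an IR-induced DSB
#'
#' `P_DSB = alpha * D * L`, valid in the rare-event regime
#' (`alpha * D * L << 1`). At 5 Gy this is 0.0041.
#'
#' @param params an [ir_params()].
#' @return Probability (dimensionless).
#' @examples
#' ir_damage_probability(ir_params(5))  # 0.0041
#' @export
ir_damage_probability <- function(params) {
  params$alpha * params$dose * params$L
}

new_damage_profile <- function(bead, origin) {
  structure(data.frame(bead = as.integer(bead),
                       origin = as.character(origin),
                       stringsAsFactors = FALSE),
            class = c("damage_profile", "data.frame"))
}

#' Sample the lesions of one chromosome copy
#'
#' Draws the IR lesion count from a Poisson distribution with mean
#' `N * alpha * D * L` and places the lesions uniformly over beads
#' (multiple hits in one bead collapse to a single damaged-subunit
#' flag); marks each bead independently as spontaneously damaged with
#' probability `gamma_sp[j]`; and, when nuclease damage is enabled,
#' places a lesion at the breaksite with probability 1. When one bead
#' is hit through several channels, its origin label follows the
#' priority nuclease > IR > spontaneous.
#'
#' @param spec a [chromosome_spec()].
#' @param params an [ir_params()].
#' @param gamma_sp numeric vector of per-bead spontaneous DSB
#'   probabilities (length N), or NULL for none.
#' @param nuclease logical; place the recurrent breaksite lesion?
#' @param seed optional integer seed (omit to continue the current RNG
#'   stream).
#' @return A `damage_profile`: data frame with columns `bead`, `origin`
#'   (one row per damaged subunit).
#' @export
sample_damage <- function(spec, params, gamma_sp = NULL,
                          nuclease = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subunits
  n_ir <- rpois(1, n * ir_damage_probability(params))
  ir_beads <- if (n_ir > 0) unique(sample.int(n, n_ir, replace = TRUE))
              else integer(0)
  sp_beads <- integer(0)
  if (!is.null(gamma_sp)) {
    stopifnot(length(gamma_sp) == n, all(gamma_sp >= 0), all(gamma_sp <= 1))
    sp_beads <- which(runif(n) < gamma_sp)
  }
  bead <- c(if (nuclease) spec$breaksite, ir_beads, sp_beads)
  origin <- c(if (nuclease) "nuclease",
              rep("IR", length(ir_beads)),
              rep("spontaneous", length(sp_beads)))
  keep <- !duplicated(bead)
  new_damage_profile(bead[keep], origin[keep])
}

# ---- Akima (1970) piecewise-cubic interpolation --------------------------

# local-slope cubic Hermite interpolation; smooth but overshoot-resistant,
# used for upsampling the coarse spontaneous-breakpoint profile
akima_interp <- function(x, y, xout) {
  n <- length(x)
  stopifnot(n >= 3, length(y) == n, !is.unsorted(x))
  seg <- diff(y) / diff(x)                    # n - 1 segment slopes
  S <- c(0, 0, seg, 0, 0)                     # pad two virtual slopes/side
  S[2] <- 2 * S[3] - S[4]
  S[1] <- 2 * S[2] - S[3]
  S[n + 2] <- 2 * S[n + 1] - S[n]
  S[n + 3] <- 2 * S[n + 2] - S[n + 1]
  t_i <- vapply(seq_len(n), function(i) {
    w1 <- abs(S[i + 3] - S[i + 2])
    w2 <- abs(S[i + 1] - S[i])
    if (w1 + w2 == 0) (S[i + 1] + S[i + 2]) / 2
    else (w1 * S[i + 1] + w2 * S[i + 2]) / (w1 + w2)
  }, 1.0)
  iv <- findInterval(xout, x, rightmost.closed = TRUE)
  iv[iv < 1] <- 1L
  iv[iv > n - 1] <- n - 1L
  h <- x[iv + 1] - x[iv]
  u <- (xout - x[iv]) / h
  y[iv] * (2 * u^3 - 3 * u^2 + 1) +
    h * t_i[iv] * (u^3 - 2 * u^2 + u) +
    y[iv + 1] * (-2 * u^3 + 3 * u^2) +
    h * t_i[iv + 1] * (u^3 - u^2)
}

#' Interpolate a coarse spontaneous-breakpoint profile to 100-kb bins
#'
#' The 2-Mb breakpoint profile is interpolated onto 100-kb bin centres
#' with an Akima spline, negative values are clipped to zero, and the
#' result is rescaled so the total number of breakpoints equals the
#' coarse total. When a high-resolution (25-kb) sub-profile is
#' available for an interval, it is aggregated to 100 kb and spliced in
#' place of the interpolated values there.
#'
#' @param coarse numeric vector of breakpoint counts per coarse bin.
#' @param n_out number of output 100-kb bins.
#' @param coarse_bin_bins width of a coarse bin in output bins (20 for
#'   2 Mb over 100 kb).
#' @param highres optional list with `values` (25-kb counts, length a
#'   multiple of 4) and `start_bin` (1-based first 100-kb output bin of
#'   the interval).
#' @return Numeric vector of length `n_out` (non-negative) with
#'   attribute `highres_bins`.
#' @export
interpolate_spontaneous_breakpoints <- function(coarse, n_out,
                                                coarse_bin_bins = 20,
                                                highres = NULL) {
  stopifnot(all(coarse >= 0))
  nc <- length(coarse)
  # bin centres on the output grid (units: output bins)
  xc <- (seq_len(nc) - 0.5) * coarse_bin_bins
  xo <- seq_len(n_out) - 0.5
  out <- akima_interp(xc, coarse / coarse_bin_bins, xo)
  out[out < 0] <- 0
  if (sum(out) > 0) out <- out * sum(coarse) / sum(out)
  hr_bins <- integer(0)
  if (!is.null(highres)) {
    v <- highres$values
    if (length(v) %% 4 != 0)
      stop("high-resolution values must cover whole 100-kb bins (4 x 25 kb)")
    agg <- colSums(matrix(v, nrow = 4))
    hr_bins <- highres$start_bin + seq_along(agg) - 1L
    if (min(hr_bins) < 1 || max(hr_bins) > n_out)
      stop("high-resolution interval outside the output range")
    out[hr_bins] <- agg
  }
  structure(out, highres_bins = hr_bins)
}

#' Reconstruct the spontaneous DSB profile from a breakpoint profile
#'
#' Inverse problem for unirradiated cells (D = 0): starting from a
#' uniform per-bead spontaneous DSB probability, the contact-first
#' breakpoint profile is simulated from the conformational ensemble;
#' where the simulated breakpoint frequency is below the experimental
#' one the DSB induction is increased and vice versa (multiplicative
#' update `gamma * target/sim`, clipped to the range 1e-8..1); iteration stops
#' when the Pearson correlation between the smoothed simulated and
#' experimental profiles ceases to improve. The best-Pearson profile is
#' returned.
#'
#' @param target_bp experimental breakpoint profile on the 100-kb grid
#'   (length N, breakpoints per cell).
#' @param spec a [chromosome_spec()].
#' @param ensemble optimized `conformation_ensemble`.
#' @param p_ce contact-to-exchange probability.
#' @param config list: `max_iter` (30), `patience` (3), `min_gain`
#'   (1e-3), `gamma_init` (uniform start value; default scaled to match
#'   the target total), `smooth` (logical, smooth profiles before the
#'   Pearson comparison; default TRUE).
#' @param seed integer seed (the decoupled simulator is deterministic
#'   given the ensemble; kept for interface symmetry).
#' @return List with `gamma_sp` (best profile), `pearson`, and
#'   `history` (data frame iteration/pearson/best_pearson).
#' @export
reconstruct_spontaneous_dsbs <- function(target_bp, spec, ensemble,
                                         p_ce, config = list(),
                                         seed = 1) {
  cfg <- utils::modifyList(list(max_iter = 30, patience = 3,
                                min_gain = 1e-3, gamma_init = NULL,
                                smooth = TRUE), config)
  n <- spec$n_subunits
  stopifnot(length(target_bp) == n, all(target_bp >= 0))
  q <- aggregate_contacts(ensemble, "per-chromosome")$values
  qrow <- q[spec$breaksite, ]            # contact frequency with the bait
  base <- 2 * qrow * p_ce                # f_bp = base * gamma_sp
  base[spec$breaksite] <- 0
  sim_profile <- function(g) base * g
  prep <- function(v) if (cfg$smooth) as.numeric(rebin_smooth(v)) else v
  tgt_cmp <- prep(target_bp)
  g <- rep(if (is.null(cfg$gamma_init)) {
    tot <- sum(base)
    if (tot > 0) min(1, sum(target_bp) / tot) else 1e-3
  } else cfg$gamma_init, n)
  best <- list(pearson = -Inf, g = g)
  hist <- NULL
  stall <- 0
  for (it in seq_len(cfg$max_iter)) {
    sim <- sim_profile(g)
    r <- suppressWarnings(stats::cor(prep(sim), tgt_cmp))
    if (is.na(r)) r <- 0
    improved <- r > best$pearson + cfg$min_gain
    if (r > best$pearson) best <- list(pearson = r, g = g)
    stall <- if (improved) 0 else stall + 1
    hist <- rbind(hist, data.frame(iteration = it, pearson = r,
                                   best_pearson = best$pearson))
    if (stall >= cfg$patience) break
    ratio <- ifelse(sim > 0, target_bp / sim, ifelse(target_bp > 0, 2, 1))
    g <- pmin(1, pmax(1e-8, g * ratio))
  }
  list(gamma_sp = best$g, pearson = best$pearson, history = hist)
}
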