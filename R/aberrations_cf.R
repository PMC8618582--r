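#' Contacting lesion pairs of one conformation
#'
#' A lesion contact is a contact (centre distance <= `R_cont`) between
#' two beads that both carry DSBs, of any origin combination.
#'
#' @param conf a `conformation`.
#' @param damage a `damage_profile` (see [sample_damage()]).
#' @param R_cont contact radius, diameters.
#' @return Data frame `i`, `j` (bead indices, i < j), `origin_i`,
#'   `origin_j`, `origin_pair` (alphabetical "a-b" label).
#' @export
lesion_contact_pairs <- function(conf, damage, R_cont = 1.2) {
  beads <- damage$bead
  origins <- damage$origin
  nd <- length(beads)
  empty <- data.frame(i = integer(0), j = integer(0),
                      origin_i = character(0), origin_j = character(0),
                      origin_pair = character(0),
                      stringsAsFactors = FALSE)
  if (nd < 2) return(empty)
  pos <- unclass_conf(conf)[beads, , drop = FALSE]
  dd <- as.matrix(stats::dist(pos))
  hit <- which(upper.tri(dd) & dd <= R_cont, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  a <- hit[, 1]
  b <- hit[, 2]
  op <- vapply(seq_along(a), function(k)
    paste(sort(c(origins[a[k]], origins[b[k]])), collapse = "-"),
    character(1))
  data.frame(i = pmin(beads[a], beads[b]), j = pmax(beads[a], beads[b]),
             origin_i = origins[a], origin_j = origins[b],
             origin_pair = op, stringsAsFactors = FALSE)
}

#' Convert lesion contacts into exchange aberrations
#'
#' Each contacting lesion pair converts into an exchange independently
#' with probability `p_ce`; the surviving exchanges are assigned
#' symmetric (inversion) or asymmetric (ring) type with probability 1/2
#' each. The fitted reference values of `p_ce` are 0.0035 for
#' chromosome 2 and 0.0029 for chromosomes 7 and 18.
#'
#' @param pairs data frame from [lesion_contact_pairs()].
#' @param p_ce contact-to-exchange probability between 0 and 1.
#' @param seed optional integer seed.
#' @return The surviving rows of `pairs` with a `type` column
#'   ("symmetric" or "asymmetric").
#' @export
contacts_to_exchanges <- function(pairs, p_ce, seed = NULL) {
  stopifnot(p_ce >= 0, p_ce <= 1)
  if (!is.null(seed)) set.seed(seed)
  keep <- runif(nrow(pairs)) < p_ce
  out <- pairs[keep, , drop = FALSE]
  out$type <- ifelse(runif(nrow(out)) < 0.5, "symmetric", "asymmetric")
  rownames(out) <- NULL
  out
}

#' Reference contact-to-exchange probabilities
#' @param chrom "chr2", "chr7" or "chr18".
#' @return `p_ce` fitted on the corresponding chromosome (0.0035 for
#'   chr2, 0.0029 for chr7 and chr18).
#' @export
default_pce <- function(chrom = c("chr18", "chr7", "chr2")) {
  chrom <- match.arg(chrom)
  if (chrom == "chr2") 0.0035 else 0.0029
}

new_breakpoint_distribution <- function(values, dose, mechanism, M,
                                        channels = NULL,
                                        per_cell_samples = NULL) {
  structure(list(values = values, dose = dose, mechanism = mechanism,
                 M = M, channels = channels,
                 per_cell_samples = per_cell_samples),
            class = "breakpoint_distribution")
}

#' @export
print.breakpoint_distribution <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_distribution> N = %d beads, D = %g Gy, %s, M = %g cells\n",
    length(x$values), x$dose, x$mechanism, x$M))
  cat(sprintf("  total breakpoints per cell: %.4g\n", sum(x$values)))
  invisible(x)
}

# per-bead expected damage probability (IR + spontaneous), nuclease
# handled separately
damage_prob_vector <- function(spec, params, gamma_sp) {
  p <- rep(ir_damage_probability(params), spec$n_subunits)
  if (!is.null(gamma_sp)) p <- p + gamma_sp
  p
}

#' Population breakpoint distribution under the contact-first mechanism
#'
#' Expected breakpoints per cell at each bead, for exchanges involving
#' the bait (nuclease) bead, tallied at the non-bait partner. In the
#' default decoupled mode the expectation is evaluated analytically:
#' `f_bp(j) = 2 * P_ce * q_cont(i*, j) * [P_DSB(D) + Gamma_sp(j)]`,
#' with `q_cont` the per-chromosome contact frequency of the ensemble
#' (the factor 2 counts the two homolog copies per cell); this is exact
#' in the limit of an infinite cell population over the fixed ensemble.
#' With `decoupled = FALSE` a full per-cell Monte Carlo is run: each
#' cell draws two conformations (with replacement) and independent
#' damage for each copy, scores lesion contacts, converts them with
#' probability `p_ce`, and accumulates bait-involving breakpoints.
#'
#' @param spec a [chromosome_spec()].
#' @param ensemble optimized `conformation_ensemble`.
#' @param params an [ir_params()].
#' @param gamma_sp per-bead spontaneous DSB probabilities or NULL.
#' @param p_ce contact-to-exchange probability.
#' @param M number of cells (Monte Carlo mode; informational in
#'   decoupled mode).
#' @param seed integer seed (Monte Carlo mode).
#' @param decoupled evaluate the analytic expectation (default) or run
#'   the per-cell Monte Carlo.
#' @param R_cont contact radius.
#' @param keep_cells in Monte Carlo mode, also return the per-cell
#'   total breakpoint counts.
#' @param nuclease include the recurrent breaksite lesion (disable to
#'   isolate the IR/spontaneous-only channels in Monte Carlo runs).
#' @return A `breakpoint_distribution`; `channels` holds the per-cell
#'   totals decomposed by origin pair (decoupled mode).
#' @export
population_breakpoints_cf <- function(spec, ensemble, params,
                                      gamma_sp = NULL, p_ce, M = 1e8,
                                      seed = 1, decoupled = TRUE,
                                      R_cont = 1.2, keep_cells = FALSE,
                                      nuclease = TRUE) {
  n <- spec$n_subunits
  if (decoupled) {
    q <- aggregate_contacts(ensemble, "per-chromosome",
                            R_cont = R_cont)$values
    qrow <- q[spec$breaksite, ]
    pdmg <- damage_prob_vector(spec, params, gamma_sp)
    vals <- 2 * p_ce * qrow * pdmg
    vals[spec$breaksite] <- 0
    pir <- ir_damage_probability(params)
    gs <- if (is.null(gamma_sp)) rep(0, n) else gamma_sp
    ut <- upper.tri(q)
    nb <- setdiff(seq_len(n), spec$breaksite)  # non-bait beads
    qnb <- q[nb, nb]
    utnb <- upper.tri(qnb)
    one <- rep(1, length(nb))
    channels <- c(
      `nuclease-IR` = 2 * p_ce * pir * sum(qrow[-spec$breaksite]),
      `nuclease-spontaneous` = 2 * p_ce * sum(qrow * gs),
      `IR-IR` = 2 * p_ce * pir^2 * sum(qnb[utnb]),
      `IR-spontaneous` = 2 * p_ce * pir *
        sum((outer(gs[nb], one) + outer(one, gs[nb]))[utnb] * qnb[utnb]),
      `spontaneous-spontaneous` = 2 * p_ce *
        sum((outer(gs[nb], gs[nb]) * qnb)[utnb]))
    return(new_breakpoint_distribution(vals, params$dose, "contact-first",
                                       M, channels = channels))
  }
  # full per-cell Monte Carlo; single-conformation contact maps are
  # precomputed once (pure geometry), the per-cell randomness is the
  # conformation draw, the damage draw and the conversion trials
  set.seed(seed)
  K <- length(ensemble)
  cms <- lapply(ensemble_positions(ensemble), cpp_contact_matrix,
                Rcont = R_cont)
  pir <- ir_damage_probability(params)
  bait <- spec$breaksite
  vals <- numeric(n)
  per_cell <- if (keep_cells) numeric(M) else NULL
  for (cell in seq_len(M)) {
    tot_cell <- 0
    for (copy in 1:2) {
      k <- sample.int(K, 1)
      n_ir <- rpois(1, n * pir)
      dmg <- if (n_ir > 0) unique(sample.int(n, n_ir, replace = TRUE))
             else integer(0)
      if (!is.null(gamma_sp))
        dmg <- c(dmg, which(runif(n) < gamma_sp))
      if (nuclease) dmg <- c(bait, dmg)
      dmg <- unique(dmg)
      if (length(dmg) < 2) next
      sub <- cms[[k]][dmg, dmg]
      idx <- which(upper.tri(sub) & sub == 1L, arr.ind = TRUE)
      if (nrow(idx) == 0) next
      conv <- runif(nrow(idx)) < p_ce
      if (!any(conv)) next
      ei <- dmg[idx[conv, 1]]
      ej <- dmg[idx[conv, 2]]
      hit <- ei == bait | ej == bait
      partners <- ifelse(ei[hit] == bait, ej[hit], ei[hit])
      for (p in partners) vals[p] <- vals[p] + 1
      tot_cell <- tot_cell + sum(conv)
    }
    if (keep_cells) per_cell[cell] <- tot_cell
  }
  new_breakpoint_distribution(vals / M, params$dose, "contact-first", M,
                              per_cell_samples = per_cell)
}

#' Dose response of breakpoint totals by lesion-origin channel
#'
#' Evaluates, for each dose, the expected total breakpoints per cell
#' split by the origin pair of the exchanging lesions. The
#' nuclease-spontaneous channel is dose-independent, nuclease-IR grows
#' linearly with dose, and IR-IR quadratically.
#'
#' @param spec a [chromosome_spec()].
#' @param ensemble `conformation_ensemble`.
#' @param doses numeric vector of doses, Gy.
#' @param gamma_sp spontaneous profile or NULL.
#' @param p_ce contact-to-exchange probability.
#' @param R_cont contact radius.
#' @return Data frame with `dose`, one column per channel, and `total`.
#' @export
dose_response <- function(spec, ensemble, doses, gamma_sp = NULL,
                          p_ce, R_cont = 1.2) {
  stopifnot(all(doses >= 0))
  rows <- lapply(doses, function(D) {
    bp <- population_breakpoints_cf(spec, ensemble, ir_params(D),
                                    gamma_sp, p_ce, R_cont = R_cont)
    as.data.frame(c(list(dose = D), as.list(bp$channels),
                    list(total = sum(bp$channels))),
                  check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Chi-square agreement between simulated and experimental profiles
#'
#' `chi^2 = sum_j (f_sim(j) - f_exp(j))^2 / f_sim(j)` over the compared
#' bins. Bins listed in `excluded` (e.g. the 1-Mb region around the
#' breaksite and chromosome-specific uncertain regions) are skipped;
#' remaining bins where both profiles are zero contribute nothing; a
#' zero simulated value against a nonzero experimental one is an error.
#'
#' @param sim,exp numeric profiles on a common grid (same length), or a
#'   `breakpoint_distribution` for `sim`.
#' @param excluded integer vector of bin indices to skip.
#' @return List of class `fit_quality` with `chi_square` and `n_bins`.
#' @export
chi_square <- function(sim, exp, excluded = integer(0)) {
  if (inherits(sim, "breakpoint_distribution")) sim <- sim$values
  stopifnot(length(sim) == length(exp))
  keep <- setdiff(seq_along(sim), excluded)
  s <- sim[keep]
  e <- exp[keep]
  both_zero <- s == 0 & e == 0
  s <- s[!both_zero]
  e <- e[!both_zero]
  if (any(s <= 0))
    stop("zero simulated value in the comparison set")
  structure(list(chi_square = sum((s - e)^2 / s), n_bins = length(s)),
            class = "fit_quality")
}

#' Bins excluded from breakpoint-profile comparison
#'
#' The 1-Mb region around the breaksite plus, for the reference
#' chromosomes, the uncertain digitized regions 179.6-181.2 Mb (chr2)
#' and 31.0-32.2 Mb (chr7).
#'
#' @param spec a [chromosome_spec()].
#' @param grid_kb grid resolution of the compared profiles, kb.
#' @return Integer vector of 1-based bin indices on that grid.
#' @export
excluded_comparison_bins <- function(spec, grid_kb = 200) {
  res_kb <- spec$resolution / 1e3
  bait_bp <- spec$bin_origin + (spec$breaksite - 1) * spec$resolution
  win <- c(bait_bp - 5e5, bait_bp + spec$resolution + 5e5)
  regions <- list(win)
  if (spec$label == "chr2") regions <- c(regions, list(c(179.6e6, 181.2e6)))
  if (spec$label == "chr7") regions <- c(regions, list(c(31.0e6, 32.2e6)))
  bins <- unlist(lapply(regions, function(rg) {
    lo <- floor((rg[1] - spec$bin_origin) / (grid_kb * 1e3)) + 1
    hi <- ceiling((rg[2] - spec$bin_origin) / (grid_kb * 1e3))
    seq(max(1, lo), hi)
  }))
  sort(unique(as.integer(bins)))
}

#' Fit the contact-to-exchange probability by chi-square minimization
#'
#' The simulated breakpoint profile is linear in `p_ce`, so profiles
#' for the whole candidate grid are obtained by scaling a base profile
#' computed once at `p_ce = 1`; the grid value minimizing the
#' chi-square against the experimental profile is returned. For the
#' linear model `f_sim = p * b` the continuous optimum has the closed
#' form `p* = sqrt(sum(e^2/b) / sum(b))`, reported alongside as a
#' cross-check.
#'
#' @param spec a [chromosome_spec()].
#' @param ensemble `conformation_ensemble`.
#' @param params an [ir_params()].
#' @param gamma_sp spontaneous profile or NULL.
#' @param exp_profile experimental breakpoints per cell on the 100-kb
#'   grid (length N).
#' @param grid candidate `p_ce` values.
#' @param excluded bins (100-kb grid) to skip; defaults to
#'   [excluded_comparison_bins()] on that grid.
#' @return List with `p_ce` (grid minimizer), `p_ce_closed_form`,
#'   `chi_square` (at the minimizer), and `grid` (data frame).
#' @export
fit_pce <- function(spec, ensemble, params, gamma_sp = NULL,
                    exp_profile, grid = seq(5e-4, 1e-2, by = 1e-4),
                    excluded = NULL) {
  n <- spec$n_subunits
  stopifnot(length(exp_profile) == n)
  if (is.null(excluded))
    excluded <- excluded_comparison_bins(spec, grid_kb = spec$resolution / 1e3)
  base <- population_breakpoints_cf(spec, ensemble, params, gamma_sp,
                                    p_ce = 1)$values
  keep <- setdiff(which(base > 0), excluded)
  if (length(keep) == 0 || all(exp_profile[keep] == 0))
    warning("degenerate experimental profile in the comparison set")
  b <- base[keep]
  e <- exp_profile[keep]
  chi <- vapply(grid, function(p) sum((p * b - e)^2 / (p * b)), 1.0)
  i <- which.min(chi)
  closed <- sqrt(sum(e^2 / b) / sum(b))
  list(p_ce = grid[i], p_ce_closed_form = closed, chi_square = chi[i],
       grid = data.frame(p_ce = grid, chi_square = chi))
}

#' Relative fluctuation (SD over mean) of per-cell samples
#'
#' @param x numeric vector of per-cell values (>= 2 samples, nonzero
#'   mean).
#' @return `sd(x) / mean(x)`.
#' @export
fluctuation_stats <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x)
  if (m == 0) stop("zero mean")
  stats::sd(x) / m
}

#' Per-cell samples of contact and aberration characteristics
#'
#' Draws `n_cells` cells (two conformations each, sampled with
#' replacement from the ensemble) and returns, per cell: the total
#' number of contacts in the two chromosome copies, the number of
#' contacts with the breaksite, the number of damaged-locus contacts
#' with the breaksite at the given dose, and the number of exchange
#' breakpoints. Used for the relative-fluctuation comparison across
#' these four characteristics.
#'
#' @param spec a [chromosome_spec()].
#' @param ensemble `conformation_ensemble`.
#' @param params an [ir_params()].
#' @param gamma_sp spontaneous profile or NULL.
#' @param p_ce contact-to-exchange probability.
#' @param n_cells number of cells to draw.
#' @param seed integer seed.
#' @param R_cont contact radius.
#' @return Data frame with columns `total_contacts`, `anchor_contacts`,
#'   `lesion_anchor_contacts`, `breakpoints` (one row per cell).
#' @export
cf_cell_samples <- function(spec, ensemble, params, gamma_sp = NULL,
                            p_ce, n_cells, seed = 1, R_cont = 1.2) {
  set.seed(seed)
  K <- length(ensemble)
  pos <- ensemble_positions(ensemble)
  cm <- lapply(pos, cpp_contact_matrix, Rcont = R_cont)
  tot_per_conf <- vapply(cm, function(m) sum(m) / 2, 1.0)
  anchor_sets <- lapply(cm, function(m) which(m[spec$breaksite, ] == 1))
  out <- data.frame(total_contacts = numeric(n_cells),
                    anchor_contacts = numeric(n_cells),
                    lesion_anchor_contacts = numeric(n_cells),
                    breakpoints = numeric(n_cells))
  for (cell in seq_len(n_cells)) {
    ks <- sample.int(K, 2, replace = TRUE)
    tot <- 0; anc <- 0; les <- 0; bp <- 0
    for (k in ks) {
      tot <- tot + tot_per_conf[k]
      anc <- anc + length(anchor_sets[[k]])
      dmg <- sample_damage(spec, params, gamma_sp, nuclease = TRUE)
      la <- intersect(anchor_sets[[k]], dmg$bead)
      les <- les + length(la)
      if (length(la) > 0) bp <- bp + rbinom(1, length(la), p_ce)
    }
    out[cell, ] <- c(tot, anc, les, bp)
  }
  out
}
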