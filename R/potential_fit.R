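#' Configuration of the inverse potential fit
#'
#' @param initial_u0 starting uniform attraction depth, kT (1.2).
#' @param step_size additive update per iteration, kT.
#' @param K_min,K_max ensemble size per iteration: grows linearly from
#'   `K_min` (early iterations) to `K_max` (late) for cost control.
#' @param max_iter iteration budget.
#' @param patience iterations without Pearson improvement (> `min_gain`)
#'   before stopping.
#' @param min_gain minimal Pearson improvement that counts.
#' @param stride,burn_in ensemble sampling options (see
#'   [sample_ensemble()]).
#' @param R_cont contact radius for the simulated maps.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(initial_u0 = 1.2, step_size = 0.05,
                       K_min = 200, K_max = 4000, max_iter = 30,
                       patience = 3, min_gain = 1e-3,
                       stride = 200, burn_in = 2000, R_cont = 1.2) {
  structure(list(initial_u0 = initial_u0, step_size = step_size,
                 K_min = K_min, K_max = K_max, max_iter = max_iter,
                 patience = patience, min_gain = min_gain,
                 stride = stride, burn_in = burn_in, R_cont = R_cont),
            class = "fit_config")
}

#' Sign-update of the attraction coefficients
#'
#' For each unmasked pair, the attraction depth increases by
#' `step_size` when the simulated contact frequency is below the target
#' and decreases when it is above; depths are clamped at zero
#' (a negative depth would redefine the potential) and masked pairs are
#' left unchanged. Symmetry is preserved.
#'
#' @param u0_attr current N x N depth matrix, kT.
#' @param sim_map,target_map relative contact-frequency matrices (or
#'   `contact_map` objects) of the same shape and normalization.
#' @param step_size additive step, kT.
#' @param mask logical N x N matrix of pairs to leave unchanged
#'   (default: s <= 1 only).
#' @return Updated depth matrix.
#' @export
update_potentials <- function(u0_attr, sim_map, target_map, step_size,
                              mask = NULL) {
  sim <- if (inherits(sim_map, "contact_map")) sim_map$values else sim_map
  tgt <- if (inherits(target_map, "contact_map")) target_map$values
         else target_map
  if (!all(dim(sim) == dim(tgt)) || !all(dim(sim) == dim(u0_attr)))
    stop("shape mismatch between maps and u0_attr")
  n <- nrow(u0_attr)
  if (is.null(mask)) {
    idx <- seq_len(n)
    mask <- abs(outer(idx, idx, "-")) <= 1
  }
  upd <- pmax(u0_attr + step_size * sign(tgt - sim), 0)
  upd[mask] <- u0_attr[mask]
  (upd + t(upd)) / 2
}

#' Assign potentials of non-mappable beads from flanking mappable beads
#'
#' The structure of a non-mappable region is postulated to resemble its
#' mappable neighbourhood: the attraction row (and column) of each
#' non-mappable bead is replaced by the mean of the rows of the nearest
#' mappable bead on each side (the single nearest row at a chain end,
#' where only one flank exists). Symmetry is restored afterwards.
#'
#' @param u0_attr N x N depth matrix.
#' @param spec a [chromosome_spec()] with `non_mappable` set.
#' @return Updated symmetric matrix.
#' @export
assign_nonmappable_potentials <- function(u0_attr, spec) {
  nm <- spec$non_mappable
  if (length(nm) == 0) return(u0_attr)
  n <- spec$n_subunits
  mappable <- setdiff(seq_len(n), nm)
  if (length(mappable) == 0) stop("all beads are non-mappable")
  rows <- lapply(nm, function(i) {
    lower <- mappable[mappable < i]
    upper <- mappable[mappable > i]
    src <- c(if (length(lower)) max(lower), if (length(upper)) min(upper))
    if (length(src) == 2) (u0_attr[src[1], ] + u0_attr[src[2], ]) / 2
    else u0_attr[src, ]
  })
  out <- u0_attr
  for (k in seq_along(nm)) {
    out[nm[k], ] <- rows[[k]]
    out[, nm[k]] <- rows[[k]]
  }
  # entries between two non-mappable beads get both replacements;
  # average them to restore symmetry
  if (length(nm) > 1)
    for (k1 in seq_along(nm))
      for (k2 in seq_along(nm))
        if (k1 < k2) {
          v <- (rows[[k1]][nm[k2]] + rows[[k2]][nm[k1]]) / 2
          out[nm[k1], nm[k2]] <- v
          out[nm[k2], nm[k1]] <- v
        }
  diag(out) <- 0
  out
}

#' Fit per-pair attraction potentials to a target contact map
#'
#' Iterative inverse optimization: starting from a uniform field
#' (1.2 kT), an ensemble is sampled, its relative contact map compared
#' with the target by Pearson correlation over unmasked pairs, and each
#' pair's depth nudged up or down by the sign rule
#' ([update_potentials()]). The additive step is halved whenever the
#' correlation drops below the previous iteration's value (damped sign
#' update). The loop stops when the best correlation has not improved
#' by more than `min_gain` for `patience` iterations, and the
#' best-Pearson state is returned. Each iteration uses a fresh seed
#' (independent ensembles) and warm-starts the dynamics from the last
#' conformation of the previous ensemble.
#'
#' @param spec a [chromosome_spec()].
#' @param target_map relative-mode `contact_map` (or plain matrix
#'   normalized the same way).
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return List with `potentials` (best [pair_potential_field()], with
#'   non-mappable rows filled in), `ensemble` (best iteration's
#'   `conformation_ensemble`), and `history` (data frame: iteration,
#'   pearson, best_pearson, step_size, mean_abs_delta, K).
#' @export
fit_potentials <- function(spec, target_map, config = fit_config(),
                           seed = 1) {
  tgt <- if (inherits(target_map, "contact_map")) target_map$values
         else target_map
  n <- spec$n_subunits
  stopifnot(all(dim(tgt) == c(n, n)))
  mask <- pair_mask(spec)
  u0 <- make_trial_potentials("heteropolymer-init", spec)$u0_attr
  u0[] <- config$initial_u0
  diag(u0) <- 0
  step <- config$step_size

  best <- list(pearson = -Inf, u0 = u0, ensemble = NULL)
  hist <- NULL
  stall <- 0
  prev_pearson <- -Inf
  start_conf <- NULL

  for (it in seq_len(config$max_iter)) {
    K <- round(config$K_min + (config$K_max - config$K_min) *
                 (it - 1) / max(1, config$max_iter - 1))
    field <- pair_potential_field(assign_nonmappable_potentials(u0, spec))
    ens <- sample_ensemble(spec, field, K, seed = seed + 1000L * it,
                           stride = config$stride,
                           burn_in = config$burn_in, start = start_conf)
    start_conf <- ens$members[[length(ens$members)]]
    sim <- aggregate_contacts(ens, "relative", spec = spec,
                              R_cont = config$R_cont)
    r <- map_pearson(sim, tgt, spec = spec)
    improved <- r > best$pearson + config$min_gain
    if (r > best$pearson) {
      best <- list(pearson = r, u0 = field$u0_attr, ensemble = ens)
    }
    stall <- if (improved) 0 else stall + 1
    # damp the step only on drops clearly beyond the map-noise level
    # (iteration-to-iteration Pearson scatter is ~0.015 at the default
    # ensemble sizes), otherwise sampling noise shrinks the step
    # prematurely and the fit stalls
    if (it > 1 && r < prev_pearson - 0.02) step <- step / 2
    u0_new <- update_potentials(u0, sim$values, tgt, step, mask = mask)
    hist <- rbind(hist, data.frame(
      iteration = it, pearson = r, best_pearson = best$pearson,
      step_size = step, mean_abs_delta = mean(abs(u0_new - u0)), K = K))
    u0 <- u0_new
    prev_pearson <- r
    if (stall >= config$patience) break
  }
  if (!is.finite(best$pearson))
    warning("no iteration produced a finite Pearson correlation")
  list(potentials = pair_potential_field(best$u0),
       ensemble = best$ensemble, history = hist)
}
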