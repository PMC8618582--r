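#' Breakage-first kinetics configuration
#'
#' Parameters of the lesion-dynamics simulation: the contact-exchange
#' rate `V_ce` (per real hour), the observation window `t_max`
#' (18000 internal ps = 3.3 h), the contact-check interval `dt`
#' (5 internal ps = 3.3 s of real time), and the initial-distance
#' classes used to bin contact-formation kinetics. The per-check
#' conversion probability `V_ce * dt_real` must not exceed 1.
#' Reference fitted rates: 1.54/h (chr18), 0.52/h (chr7), 0.28/h
#' (chr2).
#'
#' @param V_ce contact-to-exchange rate, 1/h (>= 0).
#' @param t_max_ps observation window, internal ps.
#' @param dt_ps contact-check interval, internal ps.
#' @param classes upper edges of the initial-distance classes in
#'   diameters (Inf-terminated); the defaults delimit the classes
#'   up to 1.2 d, 1.2-2 d, 2-3 d, 3-6 d and beyond 6 d.
#' @param scale a [scale_map()] for the ps-to-hour conversion.
#' @return List of class `kinetics_config` including the derived
#'   per-check probability `p_step`, number of checks `n_checks`, and
#'   real check interval `dt_hours`.
#' @export
kinetics_config <- function(V_ce, t_max_ps = 18000, dt_ps = 5,
                            classes = c(1.2, 2, 3, 6, Inf),
                            scale = scale_map()) {
  stopifnot(V_ce >= 0, t_max_ps >= 0, dt_ps > 0,
            !is.unsorted(classes))
  dt_hours <- dt_ps / scale$ps_per_real_hour
  p_step <- V_ce * dt_hours
  if (p_step > 1)
    stop("V_ce * dt exceeds 1; reduce the rate or the check interval")
  structure(list(V_ce = V_ce, t_max_ps = t_max_ps, dt_ps = dt_ps,
                 classes = classes, dt_hours = dt_hours,
                 p_step = p_step,
                 n_checks = as.integer(floor(t_max_ps / dt_ps)) + 1L),
            class = "kinetics_config")
}

#' Reference contact-exchange rates
#' @param chrom "chr2", "chr7" or "chr18".
#' @return `V_ce` in 1/h (1.54 for chr18, 0.52 for chr7, 0.28 for
#'   chr2).
#' @export
default_vce <- function(chrom = c("chr18", "chr7", "chr2")) {
  chrom <- match.arg(chrom)
  c(chr18 = 1.54, chr7 = 0.52, chr2 = 0.28)[[chrom]]
}

#' Simulate aberration formation by the breakage-first mechanism
#'
#' Per cell, two chromosome copies are drawn from the ensemble and
#' damaged as in the contact-first model; each copy's lesions are then
#' tracked through Langevin dynamics over the observation window. At
#' every check interval, each currently contacting damaged pair
#' converts into an exchange with probability `V_ce * dt_real`
#' (pre-existing contacts at t = 0 included, so the contact-first
#' mechanism is an integral part); a pair whose first contact episode
#' ends without conversion is retired (re-formed contacts neglected),
#' and the lesion count is constant (no repair). Lesion mobility equals
#' undamaged-locus mobility.
#'
#' @param spec a [chromosome_spec()].
#' @param ensemble equilibrated `conformation_ensemble`.
#' @param potentials the [pair_potential_field()] that generated the
#'   ensemble (drives the lesion dynamics).
#' @param params an [ir_params()].
#' @param gamma_sp spontaneous profile or NULL.
#' @param kinetics a [kinetics_config()].
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param R_cont contact radius.
#' @param frozen freeze the conformations (no dynamics; conversion
#'   kinetics only) -- the closed-form limit used for validation.
#' @param config [dynamics_config()] overrides.
#' @return List with `breakpoints` (a `breakpoint_distribution`,
#'   bait-involving breakpoints at the non-bait partner, per cell),
#'   `events` (data frame: cell, copy, i, j, r0, first_contact_ps,
#'   convert_ps -- NA when the event never happened), and `kinetics`
#'   (the configuration).
#' @export
simulate_breakage_first <- function(spec, ensemble, potentials, params,
                                    gamma_sp = NULL, kinetics,
                                    n_cells, seed = 1, R_cont = 1.2,
                                    frozen = FALSE, config = list()) {
  cfg <- utils::modifyList(dynamics_config(), config)
  set.seed(seed)
  K <- length(ensemble)
  dt <- effective_dt(cfg, potentials)
  steps_per_check <- if (frozen) 0L
                     else as.integer(round(kinetics$dt_ps / dt))
  events <- vector("list", 2 * n_cells)
  idx <- 0
  for (cell in seq_len(n_cells)) {
    for (copy in 1:2) {
      k <- sample.int(K, 1)
      dmg <- sample_damage(spec, params, gamma_sp, nuclease = TRUE)
      if (nrow(dmg) < 2) next
      res <- cpp_breakage_first(
        unclass_conf(ensemble$members[[k]]), dmg$bead - 1L,
        potentials$u0_attr, potentials$u0_ev, potentials$diameter,
        potentials$r_cut, cfg$k_bond, cfg$mass, cfg$gamma, cfg$kT,
        dt, steps_per_check, kinetics$n_checks, R_cont,
        kinetics$p_step)
      idx <- idx + 1
      events[[idx]] <- data.frame(
        cell = cell, copy = copy,
        i = res$i + 1L, j = res$j + 1L, r0 = res$r0,
        first_contact_ps = ifelse(res$first_contact < 0, NA_real_,
                                  res$first_contact * kinetics$dt_ps),
        convert_ps = ifelse(res$convert < 0, NA_real_,
                            res$convert * kinetics$dt_ps))
    }
  }
  events <- if (idx > 0) do.call(rbind, events[seq_len(idx)])
            else data.frame(cell = integer(0), copy = integer(0),
                            i = integer(0), j = integer(0),
                            r0 = numeric(0),
                            first_contact_ps = numeric(0),
                            convert_ps = numeric(0))
  vals <- numeric(spec$n_subunits)
  conv <- events[!is.na(events$convert_ps), , drop = FALSE]
  bait <- spec$breaksite
  hit <- conv[conv$i == bait | conv$j == bait, , drop = FALSE]
  if (nrow(hit) > 0) {
    partners <- ifelse(hit$i == bait, hit$j, hit$i)
    for (p in partners) vals[p] <- vals[p] + 1
  }
  bp <- new_breakpoint_distribution(vals / n_cells, params$dose,
                                    "breakage-first", n_cells)
  attr(bp, "convert_times_ps") <- conv$convert_ps
  list(breakpoints = bp, events = events, kinetics = kinetics)
}

#' Contact-formation kinetics by initial-distance class
#'
#' Tabulates the first lesion-contact events from
#' [simulate_breakage_first()] into (initial-distance class, time bin)
#' counts, with both differential and cumulative views. The t = 0
#' column counts pre-existing contacts.
#'
#' @param events event data frame from [simulate_breakage_first()].
#' @param classes upper edges of the initial-distance classes,
#'   diameters (must be increasing).
#' @param time_bins_ps upper edges of the time bins, internal ps (the
#'   first bin is t = 0 exactly).
#' @return Object of class `lesion_kinetics`: list with `differential`
#'   and `cumulative` matrices (classes x time bins), class labels and
#'   bin edges.
#' @export
contact_formation_kinetics <- function(events,
                                       classes = c(1.2, 2, 3, 6, Inf),
                                       time_bins_ps = c(0, 1000, 2000,
                                                        4000, 8000,
                                                        18000)) {
  if (is.unsorted(classes) || is.unsorted(time_bins_ps))
    stop("class and time-bin boundaries must be increasing")
  cls_lab <- paste0(c("0", head(classes, -1)), "-", classes, "d")
  cls_lab[1] <- paste0("<=", classes[1], "d")
  fc <- events$first_contact_ps[!is.na(events$first_contact_ps)]
  r0 <- events$r0[!is.na(events$first_contact_ps)]
  cls <- findInterval(r0, classes, left.open = TRUE) + 1L
  # bin 1: t = 0 exactly (pre-existing contacts); bin b > 1 covers
  # (time_bins_ps[b-1], time_bins_ps[b]]
  tb <- ifelse(fc == 0, 1L,
               findInterval(fc, time_bins_ps, left.open = TRUE) + 1L)
  nbt <- length(time_bins_ps)
  diffm <- matrix(0, length(classes), nbt,
                  dimnames = list(cls_lab, paste0("t<=", time_bins_ps)))
  ok <- tb <= nbt & cls <= length(classes)
  for (e in which(ok))
    diffm[cls[e], tb[e]] <- diffm[cls[e], tb[e]] + 1
  cum <- t(apply(diffm, 1, cumsum))
  structure(list(differential = diffm, cumulative = cum,
                 classes = classes, time_bins_ps = time_bins_ps),
            class = "lesion_kinetics")
}

#' Split a breakage-first result into contact-first and breakage-first
#' parts
#'
#' Conversions at t = 0 arise from pre-existing contacts (the
#' contact-first mechanism as an integral part of the kinetic model);
#' conversions at t > 0 are the breakage-first contribution. The two
#' per-bead profiles sum exactly to the total.
#'
#' @param result return value of [simulate_breakage_first()].
#' @param spec the [chromosome_spec()] used in the simulation.
#' @return List with `contact_first` and `breakage_first` (numeric
#'   per-bead breakpoints-per-cell profiles) and `total`.
#' @export
decompose_mechanisms <- function(result, spec) {
  conv <- result$events[!is.na(result$events$convert_ps), , drop = FALSE]
  n_cells <- result$breakpoints$M
  bait <- spec$breaksite
  prof <- function(sub) {
    v <- numeric(spec$n_subunits)
    hit <- sub[sub$i == bait | sub$j == bait, , drop = FALSE]
    if (nrow(hit) > 0) {
      partners <- ifelse(hit$i == bait, hit$j, hit$i)
      for (p in partners) v[p] <- v[p] + 1
    }
    v / n_cells
  }
  cf <- prof(conv[conv$convert_ps == 0, , drop = FALSE])
  bf <- prof(conv[conv$convert_ps > 0, , drop = FALSE])
  list(contact_first = cf, breakage_first = bf, total = cf + bf)
}

#' Breakpoint modelling with a conformational transition
#'
#' Two scenarios for a hypothetical post-irradiation conformational
#' change (implemented as altered attraction potentials on the
#' breaksite row only). In the `early-late` scenario the total profile
#' is a weighted sum of two contact-first profiles -- one from the
#' original ensemble ("early" times) and one from the altered ensemble
#' ("late" times) -- with non-negative weights fitted by chi-square
#' minimization against the experimental profile. In the
#' `transition-then-dynamics` scenario the t = 0 part forms by the
#' contact-first mechanism on the original ensemble and the t > 0 part
#' by the breakage-first mechanism on the altered ensemble.
#'
#' @param mode "early-late" or "transition-then-dynamics".
#' @param spec a [chromosome_spec()].
#' @param ensemble_original,ensemble_altered ensembles before and
#'   after the transition (same N).
#' @param params an [ir_params()].
#' @param gamma_sp spontaneous profile or NULL.
#' @param p_ce contact-first conversion probability.
#' @param exp_profile experimental profile (100-kb grid) for the
#'   weight fit (early-late mode).
#' @param kinetics a [kinetics_config()] (transition mode).
#' @param potentials_altered altered [pair_potential_field()]
#'   (transition mode).
#' @param n_cells Monte Carlo cells (transition mode).
#' @param seed integer seed.
#' @param excluded comparison bins to skip (early-late mode).
#' @return List with `values` (combined per-bead profile), `weights`
#'   (early-late mode) or the breakage-first `events`, and `chi_square`
#'   where a fit was performed.
#' @export
conformational_transition_scenario <- function(mode = c("early-late",
                                                         "transition-then-dynamics"),
                                               spec, ensemble_original,
                                               ensemble_altered,
                                               params, gamma_sp = NULL,
                                               p_ce,
                                               exp_profile = NULL,
                                               kinetics = NULL,
                                               potentials_altered = NULL,
                                               n_cells = 100, seed = 1,
                                               excluded = NULL) {
  mode <- match.arg(mode)
  if (nrow(ensemble_original$members[[1]]) !=
      nrow(ensemble_altered$members[[1]]))
    stop("ensembles of different N")
  early <- population_breakpoints_cf(spec, ensemble_original, params,
                                     gamma_sp, p_ce)$values
  if (mode == "early-late") {
    late <- population_breakpoints_cf(spec, ensemble_altered, params,
                                      gamma_sp, p_ce)$values
    stopifnot(!is.null(exp_profile))
    if (is.null(excluded))
      excluded <- excluded_comparison_bins(spec,
                                           grid_kb = spec$resolution / 1e3)
    keep <- setdiff(which(early + late > 0), excluded)
    obj <- function(w) {
      s <- pmax(1e-300, w[1] * early[keep] + w[2] * late[keep])
      sum((s - exp_profile[keep])^2 / s)
    }
    fit <- stats::optim(c(0.5, 0.5), function(lw) obj(exp(lw)),
                        method = "Nelder-Mead")
    w <- exp(fit$par)
    list(values = w[1] * early + w[2] * late, weights = w,
         chi_square = fit$value)
  } else {
    stopifnot(!is.null(kinetics), !is.null(potentials_altered))
    bf <- simulate_breakage_first(spec, ensemble_altered,
                                  potentials_altered, params, gamma_sp,
                                  kinetics, n_cells, seed = seed)
    dec <- decompose_mechanisms(bf, spec)
    list(values = early + dec$breakage_first,
         contact_first = early, breakage_first = dec$breakage_first,
         events = bf$events)
  }
}
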