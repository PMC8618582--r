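#' Dynamics engine configuration
#'
#' Numerical parameters of the BAOAB Langevin integrator. Time is in
#' internal picoseconds (see [scale_map()]); energies in kT = 1.
#'
#' @param dt integration step, ps. The default 0.2 ps keeps the
#'   combined harmonic-bond plus excluded-volume stiffness well inside
#'   the stability region of the integrator.
#' @param k_bond harmonic bond stiffness, kT/d^2; 200 keeps bond-length
#'   fluctuations below 0.1 d at kT = 1.
#' @param mass bead mass in internal units (kT ps^2 / d^2); the default
#'   reproduces the Lennard-Jones time tau = d sqrt(m/U0) ~ 6 ps of the
#'   physical mapping (100 amu, 1 nm, kT at 300 K).
#' @param gamma Langevin friction, 1/ps.
#' @param kT thermal energy, internal units.
#' @param cage_k stiffness of the confining cage wall, kT/d^2.
#' @return List of engine parameters.
#' @export
dynamics_config <- function(dt = 0.2, k_bond = 200,
                            mass = scale_map()$bead_mass_internal,
                            gamma = 0.1, kT = 1, cage_k = 100) {
  list(dt = dt, k_bond = k_bond, mass = mass, gamma = gamma, kT = kT,
       cage_k = cage_k)
}

#' Stability-limited integration step for a potential field
#'
#' The stiffest local modes are the bond spring, the excluded-volume
#' wall (curvature ~1100 u0_ev / d^2 at the thermally accessible
#' compression of the WCA potential), and the deepest attraction well
#' (57.15 u0 / d^2 at the Lennard-Jones minimum, times a conservative
#' coordination factor of 6 for a dense globule). The returned step
#' keeps `omega * dt <= 0.35`, well inside the stability region of the
#' BAOAB scheme.
#'
#' @param potentials a [pair_potential_field()].
#' @param k_bond bond stiffness, kT/d^2.
#' @param mass bead mass, internal units.
#' @return Maximum safe step, ps.
#' @export
stable_timestep <- function(potentials, k_bond = 200,
                            mass = scale_map()$bead_mass_internal) {
  u0max <- max(potentials$u0_attr)
  k_eff <- k_bond + 1100 * potentials$u0_ev + 57.15 * 6 * u0max
  0.35 / sqrt(k_eff / mass)
}

# effective step: configured dt capped at the stability limit
effective_dt <- function(cfg, potentials, attraction_on = TRUE) {
  pot <- potentials
  if (!attraction_on)
    pot <- list(u0_attr = matrix(0, 1, 1), u0_ev = potentials$u0_ev)
  min(cfg$dt, stable_timestep(pot, cfg$k_bond, cfg$mass))
}

new_conformation <- function(pos, time_stamp = NA_real_) {
  structure(pos, class = c("conformation", "matrix"),
            time_stamp = time_stamp)
}

unclass_conf <- function(conf) {
  m <- unclass(conf)
  attributes(m) <- list(dim = dim(m))
  m
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d beads; Rg = %.3f d\n",
              nrow(x), radius_of_gyration(x)))
  invisible(x)
}

#' Radius of gyration of a conformation
#'
#' @param conf N x 3 coordinate matrix.
#' @return Root-mean-square bead distance from the centre of mass, in
#'   diameters.
#' @export
radius_of_gyration <- function(conf) {
  m <- unclass_conf(conf)
  ctr <- colMeans(m)
  sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
}

#' Grow a self-avoiding initial conformation inside the cage
#'
#' The chain is grown bead by bead at bond length d in random
#' directions; a placement is rejected when any non-bonded bead lies
#' closer than d or the bead falls outside the impenetrable spherical
#' cage of radius `cage_radius` (14 d by default) used to speed up
#' equilibration. Exhausted growth restarts the whole chain; repeated
#' failure is reported as non-convergence.
#'
#' @param spec a [chromosome_spec()].
#' @param seed integer seed; the same seed always yields the same
#'   conformation.
#' @param max_tries placement attempts per bead before restart.
#' @param max_restarts whole-chain restarts before giving up.
#' @return A `conformation` (N x 3 matrix, units of d).
#' @export
build_initial_conformation <- function(spec, seed, max_tries = 1000,
                                       max_restarts = 20) {
  set.seed(seed)
  pos <- cpp_grow_saw(spec$n_subunits, spec$diameter,
                      spec$cage_radius * spec$diameter,
                      max_tries, max_restarts)
  new_conformation(pos, time_stamp = 0)
}

#' Equilibrate a conformation until the radius of gyration plateaus
#'
#' Runs cage-confined Langevin dynamics (by default with excluded
#' volume and bonds only, matching the coil-equilibration stage that
#' precedes switching on the attractions) in windows, and stops when
#' the windowed mean Rg changes by less than `rel_tol` across two
#' consecutive windows.
#'
#' @param conf starting `conformation`.
#' @param potentials a [pair_potential_field()]; attractions are
#'   ignored unless `use_attraction = TRUE`.
#' @param config list of options: `window` (steps per window, default
#'   10000), `rel_tol` (default 0.01), `max_windows` (default 50),
#'   `use_attraction` (default FALSE), `cage_radius` (default 14 d; set
#'   <= 0 to disable), `seed`, plus [dynamics_config()] overrides.
#' @return The equilibrated `conformation`, with attributes `rg_trace`
#'   (windowed mean Rg values) and `converged`. Non-convergence within
#'   `max_windows` is reported with a warning and the trace.
#' @export
equilibrate <- function(conf, potentials, config = list()) {
  cfg <- utils::modifyList(c(dynamics_config(),
                             list(window = 10000L, rel_tol = 0.01,
                                  max_windows = 50L,
                                  use_attraction = FALSE,
                                  cage_radius = 14, seed = 1L)),
                           config)
  set.seed(cfg$seed)
  u0a <- if (cfg$use_attraction) potentials$u0_attr
         else matrix(0, 0, 0)
  dt <- effective_dt(cfg, potentials, cfg$use_attraction)
  pos <- unclass_conf(conf)
  means <- numeric(0)
  converged <- FALSE
  for (w in seq_len(cfg$max_windows)) {
    res <- cpp_langevin_run(pos, u0a, potentials$u0_ev,
                            potentials$diameter, potentials$r_cut,
                            cfg$k_bond, cfg$mass, cfg$gamma, cfg$kT,
                            dt, as.integer(cfg$window), 0L,
                            max(1L, as.integer(cfg$window / 100)),
                            cfg$cage_radius * potentials$diameter,
                            cfg$cage_k)
    pos <- res$final
    means <- c(means, mean(res$rg))
    if (w >= 2 &&
        abs(means[w] - means[w - 1]) / means[w - 1] < cfg$rel_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("equilibration did not reach the Rg plateau within ",
            cfg$max_windows, " windows")
  out <- new_conformation(pos)
  attr(out, "rg_trace") <- means
  attr(out, "converged") <- converged
  out
}

#' Run Langevin dynamics and sample a trajectory
#'
#' Integrates the bead chain under the full potential field (cage
#' removed, attractions on) with the BAOAB Langevin scheme at kT = 1,
#' sampling a frame every `stride` steps.
#'
#' @param conf starting `conformation` (normally equilibrated).
#' @param potentials a [pair_potential_field()].
#' @param n_steps number of integration steps.
#' @param seed integer seed (same seed, same trajectory).
#' @param stride steps between sampled frames.
#' @param config [dynamics_config()] overrides; set `cage_radius` > 0
#'   to keep the cage.
#' @return Object of class `trajectory`: an N x 3 x F array with
#'   attributes `dt_ps` (time between frames, internal ps) and `final`.
#' @export
simulate_dynamics <- function(conf, potentials, n_steps, seed,
                              stride = 100, config = list()) {
  cfg <- utils::modifyList(c(dynamics_config(), list(cage_radius = 0)),
                           config)
  set.seed(seed)
  dt <- effective_dt(cfg, potentials)
  res <- cpp_langevin_run(unclass_conf(conf), potentials$u0_attr,
                          potentials$u0_ev, potentials$diameter,
                          potentials$r_cut, cfg$k_bond, cfg$mass,
                          cfg$gamma, cfg$kT, dt,
                          as.integer(n_steps), as.integer(stride), 0L,
                          cfg$cage_radius * potentials$diameter,
                          cfg$cage_k)
  traj <- res$frames
  structure(traj, class = "trajectory", dt_ps = dt * stride,
            final = new_conformation(res$final))
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<trajectory> %d beads, %d frames, %g ps between frames\n",
              d[1], d[3], attr(x, "dt_ps")))
  invisible(x)
}

#' Extract one frame of a trajectory as a conformation
#' @param traj a `trajectory`.
#' @param frame frame index.
#' @return A `conformation`.
#' @export
trajectory_frame <- function(traj, frame) {
  new_conformation(unclass(traj)[, , frame],
                   time_stamp = frame * attr(traj, "dt_ps"))
}

#' Ensemble of chromosome conformations
#'
#' @param members list of `conformation` objects sharing N.
#' @param provenance list recording seed, potential-field checksum and
#'   iteration index (free-form).
#' @return Object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(members, provenance = list()) {
  stopifnot(length(members) >= 1)
  n <- unique(vapply(members, nrow, 1L))
  if (length(n) != 1) stop("all members must share the same N")
  structure(list(members = members, provenance = provenance),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<conformation_ensemble> K = %d conformations of %d beads\n",
              length(x$members), nrow(x$members[[1]])))
  invisible(x)
}

#' @export
length.conformation_ensemble <- function(x) length(x$members)

ensemble_positions <- function(ensemble) {
  lapply(ensemble$members, unclass_conf)
}

#' Sample a conformational ensemble for a potential field
#'
#' Convenience pipeline: grow a self-avoiding coil in the cage,
#' equilibrate it, switch on the attractions and remove the cage, then
#' sample K conformations from one long Langevin trajectory at a fixed
#' stride (so successive members are decorrelated by `stride` steps).
#'
#' @param spec a [chromosome_spec()].
#' @param potentials a [pair_potential_field()].
#' @param K number of conformations.
#' @param seed integer seed.
#' @param stride steps between sampled conformations.
#' @param burn_in steps run after switching on attractions before
#'   sampling starts.
#' @param start optional starting `conformation` (skips coil growth and
#'   equilibration; used to warm-start successive fit iterations).
#' @param equil_config options passed to [equilibrate()].
#' @param config [dynamics_config()] overrides for the sampling run.
#' @return A `conformation_ensemble`.
#' @export
sample_ensemble <- function(spec, potentials, K, seed, stride = 200,
                            burn_in = 2000, start = NULL,
                            equil_config = list(), config = list()) {
  if (is.null(start)) {
    conf <- build_initial_conformation(spec, seed)
    conf <- equilibrate(conf, potentials,
                        utils::modifyList(list(seed = seed + 1L),
                                          equil_config))
    if (max(potentials$u0_attr) > 0) {
      # second stage: attractions on, cage off, relax to the collapsed
      # state before any sampling; the tolerance is looser than the
      # coil stage because the windowed Rg mean of a small globule
      # fluctuates by a few percent at stationarity
      conf <- suppressWarnings(
        equilibrate(conf, potentials,
                    utils::modifyList(
                      list(seed = seed + 3L,
                           use_attraction = TRUE,
                           cage_radius = 0,
                           rel_tol = 0.02,
                           max_windows = 30L),
                      equil_config)))
    }
  } else {
    conf <- start
  }
  traj <- simulate_dynamics(conf, potentials, burn_in + K * stride,
                            seed + 2L, stride = stride, config = config)
  f0 <- floor(burn_in / stride)
  members <- lapply(seq_len(K) + f0, function(f) trajectory_frame(traj, f))
  conformation_ensemble(members,
                        provenance = list(seed = seed, K = K,
                                          checksum = sum(potentials$u0_attr)))
}

#' Mean squared displacement of one locus along a trajectory
#'
#' MSD over lag times, averaged over time origins, reported in real
#' units: lag in hours (5500 ps per hour) and displacement in nm^2
#' using the physical bead size (225 nm).
#'
#' @param traj a `trajectory` (>= 2 frames).
#' @param locus 1-based bead index.
#' @param scale a [scale_map()].
#' @param max_lag maximum lag in frames (default: half the trajectory).
#' @return Data frame with `lag_ps`, `lag_hours`, `msd_internal`
#'   (d^2) and `msd_nm2`.
#' @export
msd_curve <- function(traj, locus, scale = scale_map(),
                      max_lag = NULL) {
  d <- dim(traj)
  if (d[3] < 2) stop("trajectory needs at least 2 frames")
  if (locus < 1 || locus > d[1]) stop("locus out of range")
  xyz <- t(unclass(traj)[locus, , ])   # F x 3
  nf <- nrow(xyz)
  if (is.null(max_lag)) max_lag <- max(1L, nf %/% 2L)
  lags <- seq_len(max_lag)
  msd <- vapply(lags, function(L) {
    dd <- xyz[(1 + L):nf, , drop = FALSE] - xyz[1:(nf - L), , drop = FALSE]
    mean(rowSums(dd^2))
  }, 1.0)
  lag_ps <- lags * attr(traj, "dt_ps")
  data.frame(lag_ps = lag_ps,
             lag_hours = lag_ps / scale$ps_per_real_hour,
             msd_internal = msd,
             msd_nm2 = msd * (scale$d_real_nm / scale$d_internal_nm)^2)
}
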