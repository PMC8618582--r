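# Pair potentials, chain construction, dynamics and unit conversion

test_that("excluded-volume potential matches the closed form and is
           continuous at its cutoff", {
  # hand evaluation at r = 0.9 d
  expect_equal(excluded_volume_energy(0.9, 1),
               4 * ((1 / 0.9)^12 - (1 / 0.9)^6 + 0.25))
  expect_equal(excluded_volume_energy(1, 1), 1)          # 4(1-1+1/4)
  expect_equal(excluded_volume_energy(2^(1 / 6), 5), 0)  # shift forces 0
  eps <- 1e-9
  expect_lt(abs(excluded_volume_energy(2^(1 / 6) - eps, 3)), 1e-6)
  expect_identical(excluded_volume_energy(2, 1), 0)
  expect_error(excluded_volume_energy(0, 1), "positive")
  expect_error(excluded_volume_energy(-1, 1), "positive")
})

test_that("attraction potential is zero at and beyond the cutoff,
           continuous there, and its unshifted tail is 0.5% of the well", {
  expect_identical(attraction_energy(3, 2), 0)      # exactly 0 at r_cut
  expect_identical(attraction_energy(4, 2), 0)      # beyond r_cut
  eps <- 1e-9
  expect_lt(abs(attraction_energy(3 - eps, 2)), 1e-6)
  expect_identical(attraction_energy(1.0, 2), 0)    # WCA region
  # well depth is u0; unshifted magnitude at r_cut = 3d relative to it
  tail_pct <- abs(4 * ((1 / 3)^12 - (1 / 3)^6)) / 1 * 100
  expect_equal(round(tail_pct, 1), 0.5)
  expect_lt(attraction_energy(1.5, 1), 0)           # attractive well
  expect_error(attraction_energy(-0.1, 1), "positive")
})

test_that("pair energy is invariant under chain relabeling i <-> j", {
  conf <- random_conformation(12, seed = 5)
  set.seed(9)
  a <- matrix(runif(144, 0, 2), 12, 12)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  pot <- pair_potential_field(a)
  rev_idx <- 12:1
  pot_rev <- pair_potential_field(a[rev_idx, rev_idx])
  conf_rev <- chromoCA:::new_conformation(unclass(conf)[rev_idx, ])
  expect_equal(total_energy(conf, pot), total_energy(conf_rev, pot_rev))
})

test_that("trial-structure potential fields carry the reference constants", {
  sp18 <- mouse_chromosome_spec("chr18")
  hp <- make_trial_potentials("homopolymer", sp18)
  off <- hp$u0_attr[upper.tri(hp$u0_attr)]
  expect_true(all(off == 9.34))
  sp2 <- chromosome_spec("chr2", 60, 40)
  expect_true(all(make_trial_potentials("homopolymer", sp2)$u0_attr[
    upper.tri(diag(60))] == 1.57))
  sp7 <- chromosome_spec("chr7", 60, 40)
  expect_true(all(make_trial_potentials("homopolymer", sp7)$u0_attr[
    upper.tri(diag(60))] == 2.33))
  coil <- make_trial_potentials("coil", sp18)
  expect_true(all(coil$u0_attr == 0))
  expect_gt(coil$u0_ev, 0)
  rw <- make_trial_potentials("random-walk", sp18)
  expect_true(all(rw$u0_attr == 0) && rw$u0_ev == 0)
  init <- make_trial_potentials("heteropolymer-init", sp18)
  expect_true(all(init$u0_attr[upper.tri(diag(908))] == 1.2))
  expect_error(make_trial_potentials("bogus", sp18))
})

test_that("self-avoiding growth yields a valid seeded conformation
           inside the cage", {
  sp3 <- chromosome_spec("t3", 3, 2, centromere = 1L)
  c3 <- build_initial_conformation(sp3, seed = 4)
  bonds <- sqrt(rowSums(diff(unclass(c3))^2))
  expect_equal(bonds, c(1, 1), tolerance = 1e-8)
  expect_gte(sqrt(sum((unclass(c3)[1, ] - unclass(c3)[3, ])^2)),
             1 - 1e-6)

  sp <- mouse_chromosome_spec("chr18")      # N = 908
  conf <- build_initial_conformation(sp, seed = 2)
  expect_equal(nrow(conf), 908)
  expect_true(all(sqrt(rowSums(unclass(conf)^2)) <= 14 + 1e-9))
  # non-bonded minimum distance >= d
  d <- as.matrix(stats::dist(unclass(conf)[1:80, ]))
  d[abs(row(d) - col(d)) <= 1] <- Inf
  expect_gte(min(d), 1 - 1e-6)
  # seeded determinism
  conf2 <- build_initial_conformation(sp, seed = 2)
  expect_identical(unclass(conf)[, ], unclass(conf2)[, ])
})

test_that("equilibration reaches an Rg plateau and is idempotent under
           the plateau criterion", {
  sp <- chromosome_spec("t50", 50, 30, centromere = 1:3)
  conf <- build_initial_conformation(sp, seed = 1)
  pot <- make_trial_potentials("coil", sp)
  eq <- equilibrate(conf, pot, list(seed = 2, window = 4000))
  expect_true(attr(eq, "converged"))
  trace <- attr(eq, "rg_trace")
  expect_gte(length(trace), 2)
  n <- length(trace)
  expect_lt(abs(trace[n] - trace[n - 1]) / trace[n - 1], 0.01)
  # re-equilibrating an equilibrated conformation converges again and
  # stays at the same plateau (idempotence up to Rg fluctuations, which
  # are sizeable for a 50-bead coil)
  eq2 <- equilibrate(eq, pot, list(seed = 3))
  expect_true(attr(eq2, "converged"))
  expect_equal(mean(attr(eq2, "rg_trace")), mean(attr(eq, "rg_trace")),
               tolerance = 0.15)
})

test_that("a force-free dimer at zero temperature is static", {
  sp <- chromosome_spec("dimer", 3, 2, centromere = 1L)
  pos <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  conf <- chromoCA:::new_conformation(pos)
  pot <- make_trial_potentials("coil", sp)
  traj <- simulate_dynamics(conf, pot, 500, seed = 1, stride = 100,
                            config = list(kT = 0))
  final <- unclass(attr(traj, "final"))[, ]
  expect_equal(final, pos, tolerance = 1e-8)
})

test_that("seeded dynamics are bit-reproducible and uniform attraction
           collapses the chain relative to the coil", {
  sp <- chromosome_spec("t50", 50, 30, centromere = 1:3)
  conf <- build_initial_conformation(sp, seed = 1)
  pot <- make_trial_potentials("coil", sp)
  eq <- equilibrate(conf, pot, list(seed = 2, window = 4000))
  t1 <- simulate_dynamics(eq, pot, 3000, seed = 7, stride = 300)
  t2 <- simulate_dynamics(eq, pot, 3000, seed = 7, stride = 300)
  expect_identical(unclass(t1)[, , ], unclass(t2)[, , ])

  hp <- make_trial_potentials("homopolymer", sp)   # 9.34 kT globule
  eqh <- equilibrate(conf, hp, list(seed = 2, window = 4000))
  th <- simulate_dynamics(eqh, hp, 40000, seed = 8, stride = 1000)
  tc <- simulate_dynamics(eq, pot, 20000, seed = 8, stride = 1000)
  rg_h <- mean(sapply(seq_len(dim(th)[3]),
                      function(f) radius_of_gyration(trajectory_frame(th, f))))
  rg_c <- mean(sapply(seq_len(dim(tc)[3]),
                      function(f) radius_of_gyration(trajectory_frame(tc, f))))
  expect_lt(rg_h, rg_c)
})

test_that("MSD is zero for a static trajectory, reports lags in real
           hours, and grows diffusively for a free chain", {
  sp <- chromosome_spec("dimer", 3, 2, centromere = 1L)
  pos <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  conf <- chromoCA:::new_conformation(pos)
  pot <- make_trial_potentials("coil", sp)
  static <- simulate_dynamics(conf, pot, 500, seed = 1, stride = 100,
                              config = list(kT = 0))
  m0 <- msd_curve(static, locus = 2)
  expect_true(all(m0$msd_internal < 1e-12))
  # lag bookkeeping: internal lag of 5500 ps reads as 1 hour
  expect_equal(m0$lag_hours, m0$lag_ps / 5500)

  rw <- make_trial_potentials("random-walk", sp)
  traj <- simulate_dynamics(conf, rw, 40000, seed = 3, stride = 400)
  m <- msd_curve(traj, locus = 1)
  fitslope <- unname(coef(lm(log(m$msd_internal) ~ log(m$lag_ps)))[2])
  expect_gt(fitslope, 0.6)   # diffusive, not trapped
  expect_lt(fitslope, 1.4)
  expect_equal(m$msd_nm2, m$msd_internal * 225^2)
  expect_error(msd_curve(traj, locus = 99), "range")
})

test_that("unit conversions reproduce the physical mapping", {
  sm <- scale_map()
  expect_equal(round(sm$tau_ps), 6)           # d sqrt(m/kT) at 300 K
  expect_equal(round(real_time_conversion(18000)$hours, 1), 3.3)
  expect_equal(round(real_time_conversion(5)$seconds, 1), 3.3)
  expect_identical(real_time_conversion(0)$hours, 0)
  expect_error(real_time_conversion(-1))
})
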