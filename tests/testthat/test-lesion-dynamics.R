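# Breakage-first mechanism: lesion tracking, conversion kinetics,
# mechanism decomposition and conformational-transition scenarios

test_that("kinetics configuration derives the per-check probability and
           rejects super-unit conversion probabilities", {
  kc <- kinetics_config(V_ce = 1.54)
  expect_equal(kc$dt_hours, 5 / 5500)
  expect_equal(kc$p_step, 1.54 * 5 / 5500)
  expect_identical(kc$n_checks, 3601L)
  expect_error(kinetics_config(V_ce = 2000), "exceeds 1")
  expect_equal(default_vce("chr18"), 1.54)
  expect_equal(default_vce("chr7"), 0.52)
  expect_equal(default_vce("chr2"), 0.28)
})

test_that("a zero conversion rate yields no breakpoints regardless of
           the dynamics", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  kc <- kinetics_config(V_ce = 0, t_max_ps = 200)
  res <- simulate_breakage_first(sp, ens, toy_potentials(), ir_params(5),
                                 gamma_sp = rep(0.2, 40), kinetics = kc,
                                 n_cells = 5, seed = 1)
  expect_true(all(res$breakpoints$values == 0))
  expect_true(all(is.na(res$events$convert_ps)))
})

test_that("frozen dynamics match the closed-form geometric conversion
           oracle within three standard errors", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  g <- rep(1, sp$n_subunits)      # every bead damaged, deterministic
  kc <- kinetics_config(V_ce = 50, t_max_ps = 500)   # p_step = 0.0455
  n_cells <- 40
  res <- simulate_breakage_first(sp, ens, toy_potentials(), ir_params(0),
                                 gamma_sp = g, kinetics = kc,
                                 n_cells = n_cells, seed = 3,
                                 frozen = TRUE)
  # oracle: each initially contacting pair converts with
  # p_eff = 1 - (1 - p_step)^n_checks; no new contacts ever form
  expect_true(all(is.na(res$events$first_contact_ps) |
                    res$events$first_contact_ps == 0))
  n_contact0 <- sum(res$events$r0 <= 1.2)
  p_eff <- 1 - (1 - kc$p_step)^kc$n_checks
  conv <- sum(!is.na(res$events$convert_ps))
  se <- sqrt(n_contact0 * p_eff * (1 - p_eff))
  expect_lt(abs(conv - n_contact0 * p_eff), 3 * se)
})

test_that("cumulative kinetics integrate the differential view, are
           non-decreasing, and start from the pre-existing contacts", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  g <- rep(0.3, sp$n_subunits)
  kc <- kinetics_config(V_ce = 1.54, t_max_ps = 400)
  res <- simulate_breakage_first(sp, ens, toy_potentials(), ir_params(5),
                                 gamma_sp = g, kinetics = kc,
                                 n_cells = 6, seed = 9)
  kin <- contact_formation_kinetics(res$events,
                                    time_bins_ps = c(0, 100, 200, 400))
  expect_equal(kin$cumulative,
               t(apply(kin$differential, 1, cumsum)))
  expect_true(all(apply(kin$cumulative, 1, function(r) all(diff(r) >= 0))))
  # t = 0 column counts exactly the initially contacting lesion pairs
  expect_equal(sum(kin$differential[, 1]),
               sum(res$events$first_contact_ps == 0, na.rm = TRUE))
  expect_equal(sum(kin$differential),
               sum(!is.na(res$events$first_contact_ps)))
  expect_error(contact_formation_kinetics(res$events,
                                          classes = c(2, 1)), "increasing")
})

test_that("mechanism decomposition splits at t = 0 and the parts sum to
           the total profile exactly", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  g <- rep(0.3, sp$n_subunits)
  kc <- kinetics_config(V_ce = 300, t_max_ps = 300)
  res <- simulate_breakage_first(sp, ens, toy_potentials(), ir_params(5),
                                 gamma_sp = g, kinetics = kc,
                                 n_cells = 8, seed = 2)
  dec <- decompose_mechanisms(res, sp)
  expect_equal(dec$contact_first + dec$breakage_first,
               res$breakpoints$values)
  expect_equal(dec$total, res$breakpoints$values)
  # frozen limit: nothing forms after t = 0, so the late part comes
  # only from still-lasting initial contacts
  resf <- simulate_breakage_first(sp, ens, toy_potentials(), ir_params(5),
                                  gamma_sp = g, kinetics = kc,
                                  n_cells = 8, seed = 2, frozen = TRUE)
  decf <- decompose_mechanisms(resf, sp)
  late_conv <- resf$events$convert_ps[!is.na(resf$events$convert_ps)]
  expect_true(all(resf$events$first_contact_ps %in% c(0, NA)))
  expect_equal(sum(decf$contact_first) + sum(decf$breakage_first),
               sum(resf$breakpoints$values))
})

test_that("in a dense globule, lesion pairs starting beyond two
           diameters almost never meet, while a loose coil gains
           contacts after t = 0", {
  n <- 30
  sp <- chromosome_spec("kin", n, breaksite = 18, centromere = 1:3)
  dense_pot <- pair_potential_field({
    m <- matrix(9.34, n, n); diag(m) <- 0; m
  })
  coil_pot <- make_trial_potentials("coil", sp)
  dense_ens <- cached("kin_dense",
                      sample_ensemble(sp, dense_pot, 20, seed = 21,
                                      stride = 400))
  coil_ens <- cached("kin_coil",
                     sample_ensemble(sp, coil_pot, 20, seed = 22,
                                     stride = 400))
  g <- rep(1, n)
  kc <- kinetics_config(V_ce = 0, t_max_ps = 3000)
  run <- function(ens, pot, seed)
    simulate_breakage_first(sp, ens, pot, ir_params(0), gamma_sp = g,
                            kinetics = kc, n_cells = 4, seed = seed)
  dense <- run(dense_ens, dense_pot, 31)
  coil <- run(coil_ens, coil_pot, 32)
  far_formed <- function(ev)
    mean(!is.na(ev$first_contact_ps[ev$r0 > 2]) &
           ev$first_contact_ps[ev$r0 > 2] > 0, na.rm = TRUE)
  expect_lt(far_formed(dense$events), 0.05)
  # loose chain: contacts formed after t = 0 in the 1.2-3 d classes
  # exceed the initial-contact count
  ev <- coil$events
  post <- sum(ev$r0 > 1.2 & ev$r0 <= 3 &
                !is.na(ev$first_contact_ps) & ev$first_contact_ps > 0)
  init <- sum(ev$first_contact_ps == 0, na.rm = TRUE)
  expect_gt(post, init)
})

test_that("conformational-transition scenarios recover degenerate
           weights and reduce to plain contact-first", {
  fx <- tiny_bp_fixture()
  sp <- fx$spec
  params <- ir_params(fx$truth$dose)
  # altered = original: any weight pair summing to one reproduces the
  # profile; the fitted combination must match the target profile
  res <- conformational_transition_scenario(
    "early-late", sp, fx$ensemble, fx$ensemble, params,
    fx$truth$gamma_sp, fx$truth$p_ce,
    exp_profile = fx$breakpoint_profile)
  expect_equal(sum(res$weights), 1, tolerance = 0.05)
  expect_lt(res$chi_square, 1e-10)
  # an injected transition: target built from a half-half mixture of
  # original and altered ensembles is fit better with both weights free
  alt_ens <- conformation_ensemble(rev(fx$ensemble$members[1:100]))
  early <- population_breakpoints_cf(sp, fx$ensemble, params,
                                     fx$truth$gamma_sp,
                                     fx$truth$p_ce)$values
  late <- population_breakpoints_cf(sp, alt_ens, params,
                                    fx$truth$gamma_sp,
                                    fx$truth$p_ce)$values
  mix <- 0.3 * early + 0.7 * late
  res2 <- conformational_transition_scenario(
    "early-late", sp, fx$ensemble, alt_ens, params,
    fx$truth$gamma_sp, fx$truth$p_ce, exp_profile = mix)
  only_early <- chi_square(early, mix,
                           excluded = excluded_comparison_bins(sp, 100))
  expect_lt(res2$chi_square, only_early$chi_square)
  expect_error(conformational_transition_scenario(
    "early-late", sp, fx$ensemble,
    conformation_ensemble(list(chromoCA:::new_conformation(
      matrix(0, 5, 3)))), params, NULL, 0.003,
    exp_profile = fx$breakpoint_profile), "different N")
})
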