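# Contact-first aberration simulation and its statistics

test_that("lesion contact pairs are the brute-force damaged-pair filter
           of the full contact set", {
  conf <- random_conformation(20, 3)
  dmg <- chromoCA:::new_damage_profile(c(2L, 5L, 11L, 17L),
                                       c("nuclease", "IR", "IR",
                                         "spontaneous"))
  got <- lesion_contact_pairs(conf, dmg, R_cont = 2.5)
  cm <- conformation_contacts(conf, R_cont = 2.5)
  want <- which(cm[dmg$bead, dmg$bead] == 1 &
                  upper.tri(cm[dmg$bead, dmg$bead]), arr.ind = TRUE)
  expect_equal(nrow(got), nrow(want))
  for (r in seq_len(nrow(want))) {
    i <- dmg$bead[want[r, 1]]; j <- dmg$bead[want[r, 2]]
    expect_true(any(got$i == min(i, j) & got$j == max(i, j)))
  }
  # no lesions / one lesion: empty set
  expect_identical(nrow(lesion_contact_pairs(
    conf, chromoCA:::new_damage_profile(integer(0), character(0)))), 0L)
  # two lesions at distance 1.0 d form one pair under R_cont = 1.2 d
  pos <- matrix(c(0, 0, 0, 5, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE)
  c3 <- chromoCA:::new_conformation(pos)
  d3 <- chromoCA:::new_damage_profile(c(1L, 3L), c("nuclease", "IR"))
  p3 <- lesion_contact_pairs(c3, d3)
  expect_identical(nrow(p3), 1L)
  expect_identical(p3$origin_pair, "IR-nuclease")
})

test_that("contact-to-exchange conversion is Bernoulli with the two
           exchange types equally likely", {
  pairs <- data.frame(i = 1:200, j = 201:400,
                      origin_i = "IR", origin_j = "nuclease",
                      origin_pair = "IR-nuclease")
  expect_identical(nrow(contacts_to_exchanges(pairs, 0, seed = 1)), 0L)
  all_in <- contacts_to_exchanges(pairs, 1, seed = 1)
  expect_identical(nrow(all_in), 200L)
  frac_sym <- mean(all_in$type == "symmetric")
  expect_gt(frac_sym, 0.35); expect_lt(frac_sym, 0.65)
  expect_error(contacts_to_exchanges(pairs, 1.5))
  expect_equal(default_pce("chr2"), 0.0035)
  expect_equal(default_pce("chr7"), 0.0029)
  expect_equal(default_pce("chr18"), 0.0029)
})

test_that("the decoupled expectation agrees with the full per-cell
           Monte Carlo within three standard errors", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  params <- ir_params(15)
  g <- rep(0.02, sp$n_subunits)
  p_ce <- 0.5                       # inflated so events are frequent
  dec <- population_breakpoints_cf(sp, ens, params, g, p_ce)
  expected_total <- sum(dec$channels)
  M <- 1500
  mc <- population_breakpoints_cf(sp, ens, params, g, p_ce, M = M,
                                  seed = 5, decoupled = FALSE,
                                  keep_cells = TRUE)
  per_cell <- mc$per_cell_samples
  se <- stats::sd(per_cell) / sqrt(M)
  expect_lt(abs(mean(per_cell) - expected_total), 3 * se)
  # bait-channel profile agreement (summed over beads)
  dec_bait <- sum(dec$values)
  mc_bait <- sum(mc$values)
  expect_lt(abs(mc_bait - dec_bait),
            3 * sqrt(dec_bait / M) + 3 * se)
  # p_ce = 0 silences everything
  z <- population_breakpoints_cf(sp, ens, params, g, p_ce = 0)
  expect_true(all(z$values == 0))
})

test_that("origin channels scale with dose as constant, linear and
           quadratic terms", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  g <- rep(0.01, sp$n_subunits)
  dr <- dose_response(sp, ens, doses = c(1, 2, 4), gamma_sp = g,
                      p_ce = 0.0029)
  expect_equal(dr$`nuclease-IR` / dr$`nuclease-IR`[1], c(1, 2, 4))
  expect_equal(dr$`IR-IR` / dr$`IR-IR`[1], c(1, 4, 16))
  expect_equal(dr$`nuclease-spontaneous`,
               rep(dr$`nuclease-spontaneous`[1], 3))
  d0 <- dose_response(sp, ens, doses = 0, gamma_sp = g, p_ce = 0.0029)
  expect_identical(d0$`nuclease-IR`, 0)
  expect_identical(d0$`IR-IR`, 0)
  expect_gt(d0$`nuclease-spontaneous`, 0)
  expect_gt(d0$`spontaneous-spontaneous`, 0)
})

test_that("chi-square follows its defining sum and honors exclusions", {
  expect_equal(chi_square(c(1, 1), c(2, 0))$chi_square, 2)
  expect_equal(chi_square(c(3, 4, 5), c(3, 4, 5))$chi_square, 0)
  # excluded bins do not contribute, however perturbed
  a <- chi_square(c(1, 1, 1), c(2, 0, 99), excluded = 3)$chi_square
  b <- chi_square(c(1, 1, 1), c(2, 0, -7), excluded = 3)$chi_square
  expect_equal(a, b)
  expect_equal(a, 2)
  expect_error(chi_square(c(0, 1), c(1, 1)), "zero simulated")
})

test_that("p_ce is recovered from a forward-generated profile, matching
           the closed-form optimum of the linear model", {
  fx <- tiny_bp_fixture()
  params <- ir_params(fx$truth$dose)
  fit <- fit_pce(fx$spec, fx$ensemble, params, fx$truth$gamma_sp,
                 exp_profile = fx$breakpoint_profile,
                 grid = seq(5e-4, 1e-2, by = 5e-4))
  expect_equal(fit$p_ce, fx$truth$p_ce, tolerance = 1e-9)
  expect_equal(fit$p_ce_closed_form, fx$truth$p_ce, tolerance = 1e-6)
  # degenerate target pushes to the smallest grid value
  fit0 <- suppressWarnings(fit_pce(fx$spec, fx$ensemble, params,
                                   fx$truth$gamma_sp,
                                   exp_profile = numeric(fx$spec$n_subunits),
                                   grid = c(1e-4, 1e-3, 1e-2)))
  expect_equal(fit0$p_ce, 1e-4)
})

test_that("relative fluctuation behaves as the SD/mean estimator", {
  expect_identical(fluctuation_stats(rep(4, 10)), 0)
  set.seed(6)
  lam <- 50
  x <- rpois(20000, lam)
  expect_equal(fluctuation_stats(x), 1 / sqrt(lam), tolerance = 0.05)
  expect_error(fluctuation_stats(c(0, 0)), "zero mean")
  expect_error(fluctuation_stats(3))
})

test_that("relative fluctuations increase from total contacts through
           anchor and lesion contacts to breakpoints", {
  ens <- toy_ensemble()
  sp <- toy_spec()
  g <- rep(0.02, sp$n_subunits)
  cells <- cf_cell_samples(sp, ens, ir_params(5), g, p_ce = 0.3,
                           n_cells = 600, seed = 12)
  f <- vapply(cells, fluctuation_stats, 1.0)
  expect_lt(f["total_contacts"], f["anchor_contacts"])
  expect_lt(f["anchor_contacts"], f["lesion_anchor_contacts"])
  expect_lt(f["lesion_anchor_contacts"], f["breakpoints"])
})
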