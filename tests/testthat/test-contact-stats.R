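# Contact detection, map aggregation, f(s), pseudo-4C, pooling,
# smoothing and count distributions

test_that("contact detection agrees with the all-pairs brute-force
           oracle and treats the radius inclusively", {
  for (seed in 1:5) {
    conf <- random_conformation(10, seed)
    got <- conformation_contacts(conf, R_cont = 1.2)
    dd <- as.matrix(stats::dist(unclass(conf)[, ]))
    want <- (dd <= 1.2) * 1L
    diag(want) <- 0L
    expect_identical(unname(got[, ]), unname(want))
  }
  # boundary: exactly at R_cont is a contact, just outside is not
  pos <- matrix(c(0, 0, 0, 1.2, 0, 0, 0, 1.21, 0), 3, 3, byrow = TRUE)
  conf <- chromoCA:::new_conformation(pos)
  m <- conformation_contacts(conf, 1.2)
  expect_identical(m[1, 2], 1L)
  expect_identical(m[1, 3], 0L)
})

test_that("aggregation modes are exact rational multiples of the counts
           map and relative maps sum to one", {
  ens <- toy_ensemble()
  K <- length(ens)
  counts <- aggregate_contacts(ens, "counts")
  single <- conformation_contacts(ens$members[[1]])
  one <- aggregate_contacts(conformation_ensemble(ens$members[1]), "counts")
  expect_identical(one$values[, ], matrix(as.numeric(single), 40, 40))

  per_chr <- aggregate_contacts(ens, "per-chromosome")
  per_cell <- aggregate_contacts(ens, "per-cell")
  expect_equal(per_chr$values * K, counts$values)
  expect_equal(per_cell$values, 2 * per_chr$values)  # M = K/2
  expect_error(aggregate_contacts(
    conformation_ensemble(ens$members[1:3]), "per-cell"), "even")

  rel <- aggregate_contacts(ens, "relative", spec = toy_spec())
  expect_equal(sum(rel$values[upper.tri(rel$values)]), 1)
  # masked entries are zeroed: s = 1 band, centromere, breaksite is kept
  expect_true(all(rel$values[cbind(1:39, 2:40)] == 0))
  expect_true(all(rel$values[1:4, ] == 0))
})

test_that("f(s) matches hand summation over anti-diagonals and its sum
           recovers the relative-map total", {
  set.seed(3)
  n <- 10
  v <- matrix(0, n, n)
  v[2, 7] <- 0.4; v[7, 2] <- 0.4
  v[3, 5] <- 0.6; v[5, 3] <- 0.6
  map <- chromoCA:::new_contact_map(v, "relative")
  fs <- contact_vs_separation(map)
  expect_equal(fs$f[fs$s == 5], 0.4)
  expect_equal(fs$f[fs$s == 2], 0.6)
  expect_equal(sum(fs$f), 1)
  # brute-force oracle on a dense random symmetric map
  w <- matrix(runif(n * n), n, n); w <- w + t(w)
  w[abs(row(w) - col(w)) <= 1] <- 0
  w <- w / sum(w[upper.tri(w)])
  fs2 <- contact_vs_separation(chromoCA:::new_contact_map(w, "relative"))
  for (s in c(2, 4, 9)) {
    i <- seq_len(n - s)
    expect_equal(fs2$f[fs2$s == s], sum(w[cbind(i, i + s)]))
  }
  expect_error(contact_vs_separation(chromoCA:::new_contact_map(w, "counts")),
               "relative")
})

test_that("power exponent recovers exact power laws and matches an
           independent log-log regression", {
  s <- 2:80
  fs <- data.frame(s = s, f = s^(-1))
  expect_equal(power_exponent(fs), -1)
  fs2 <- data.frame(s = s, f = 3.7 * s^(-0.9))
  expect_equal(power_exponent(fs2), -0.9)
  # independent regression oracle on noisy data
  set.seed(4)
  fs3 <- data.frame(s = s, f = exp(log(2 * s^(-1.1)) + rnorm(length(s), 0, 0.05)))
  sel <- fs3$s >= 5 & fs3$s <= 50
  want <- unname(coef(lm(log(fs3$f[sel]) ~ log(fs3$s[sel])))[2])
  expect_equal(power_exponent(fs3), want)
  expect_error(power_exponent(data.frame(s = c(5, 6), f = c(1, 1))),
               "fewer than 3")
})

test_that("pseudo-4C extracts the anchor row and rejects masked anchors", {
  ens <- toy_ensemble()
  map <- aggregate_contacts(ens, "per-chromosome")
  pr <- pseudo4c_profile(map, anchor = 25)
  expect_equal(as.numeric(pr), map$values[25, ])
  expect_identical(attr(pr, "anchor"), 25)
  expect_error(pseudo4c_profile(map, 2, spec = toy_spec()), "masked")
  zero <- chromoCA:::new_contact_map(matrix(0, 6, 6), "counts")
  expect_true(all(pseudo4c_profile(zero, 3) == 0))
})

test_that("single-cell maps sum the two homolog maps", {
  a <- random_conformation(15, 1)
  b <- random_conformation(15, 2)
  sc <- single_cell_map(a, b)
  expect_equal(sc$values[, ],
               (conformation_contacts(a) + conformation_contacts(b))[, ])
  same <- single_cell_map(a, a)
  expect_true(all(same$values %in% c(0, 2)))
  expect_error(single_cell_map(a, random_conformation(9, 3)), "mismatch")
})

test_that("pool averaging is seeded, exact at full pool size, and its
           variance shrinks roughly as one over the pool size", {
  set.seed(8)
  cells <- matrix(rpois(2000 * 5, 4), nrow = 2000)
  expect_equal(pool_average(cells, m = 2000, seed = 1), colMeans(cells))
  one <- pool_average(cells, m = 1, seed = 3)
  expect_true(all(one == round(one)))
  expect_identical(pool_average(cells, 10, seed = 5),
                   pool_average(cells, 10, seed = 5))
  v_of_pool <- function(m) {
    stats::var(vapply(1:300, function(s)
      pool_average(cells, m, seed = s)[1], 1.0))
  }
  v10 <- v_of_pool(10); v100 <- v_of_pool(100)
  expect_gt(v10 / v100, 4)   # ~10 expected; loose law-of-large-numbers
  expect_lt(v10 / v100, 25)
  expect_error(pool_average(cells, 0))
})

test_that("rebinning to 200 kb conserves totals and the 1-Mb boxcar
           passes constants and exempt regions through unchanged", {
  const <- rep(2, 40)
  out <- rebin_smooth(const)
  expect_equal(as.numeric(out), rep(4, 20))  # pairwise sum, smoothing no-op
  spike <- numeric(40); spike[21] <- 10
  sm <- rebin_smooth(spike)
  expect_equal(sum(sm), 10)                  # interior spike conserved
  expect_true(sum(sm > 0) >= 5)              # spread over the window
  # exempt region: rebinned but not smoothed
  ex <- rebin_smooth(spike, exempt_bins = 21:22)
  expect_equal(ex[11], 10)
  expect_error(rebin_smooth(const, window_bins = 0), "window")
})

test_that("anchor contact-count pmf is a normalized tally of per-cell
           counts", {
  ens <- toy_ensemble()
  pmf <- contact_count_pmf(ens, anchor = 25)
  expect_equal(sum(pmf$p), 1)
  samples <- attr(pmf, "samples")
  expect_length(samples, length(ens) / 2)
  # direct tally oracle for cell 1 (members 1 and 2)
  cnt <- sum(conformation_contacts(ens$members[[1]])[25, ]) +
         sum(conformation_contacts(ens$members[[2]])[25, ])
  expect_identical(samples[1], as.integer(cnt))
  expect_identical(sum(pmf$p[pmf$count == samples[1]] > 0), 1L)
})
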