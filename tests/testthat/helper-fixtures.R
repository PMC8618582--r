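# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 40-bead dense globule ensemble: fast, compact, used for contact and
# aberration statistics
toy_spec <- function() {
  chromosome_spec("toy", 40, breaksite = 25, centromere = 1:4)
}

toy_potentials <- function() {
  pair_potential_field({
    n <- 40
    m <- matrix(1.5, n, n)
    diag(m) <- 0
    m
  })
}

toy_ensemble <- function(K = 60) {
  cached(paste0("toy_ens_", K),
         sample_ensemble(toy_spec(), toy_potentials(), K, seed = 11))
}

tiny_fixture <- function() {
  cached("tiny_fx", generate_fixture("contact-map", "tiny", seed = 101))
}

tiny_bp_fixture <- function() {
  cached("tiny_bp",
         generate_fixture("breakpoint-profile", "tiny", seed = 101))
}

# random self-avoiding conformations for oracle comparisons
random_conformation <- function(n, seed) {
  sp <- chromosome_spec("rnd", n, breaksite = max(2, n %/% 2),
                        centromere = 1:2)
  build_initial_conformation(sp, seed)
}
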