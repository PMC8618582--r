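#' Forward-generate a synthetic test dataset with known ground truth
#'
#' Stands in for external Hi-C / translocation-sequencing inputs: a
#' small chromosome spec is built, a block-structured heteropolymer
#' potential field (within-block attraction enhanced over a uniform
#' baseline, plus smooth noise) is drawn, an ensemble is simulated and
#' aggregated into a target contact map. The "breakpoint-profile" and
#' "full-pipeline" kinds continue through damage and contact-first
#' simulation with a known spontaneous profile and conversion
#' probability, producing a breakpoint profile whose generating truth
#' is recorded.
#'
#' @param kind "contact-map", "breakpoint-profile" or "full-pipeline".
#' @param scale "tiny" (N = 50, K = 200) or "small" (N = 150, K = 300).
#' @param seed integer seed; the same seed reproduces the fixture
#'   bit-exactly.
#' @param dose IR dose for the breakpoint stages, Gy.
#' @param n,K override the chain length / ensemble size of the chosen
#'   scale.
#' @param stride steps between sampled target-ensemble conformations;
#'   larger strides decorrelate the ensemble and sharpen the target
#'   map at linear cost.
#' @return List with `spec`, `target_map` (relative `contact_map`),
#'   `ensemble`, and for the breakpoint kinds `breakpoint_profile`
#'   (per-cell, 100-kb grid); `truth` records the generating
#'   `potentials`, `gamma_sp`, `p_ce` and `seed`.
#' @export
generate_fixture <- function(kind = c("contact-map", "breakpoint-profile",
                                      "full-pipeline"),
                             scale = c("tiny", "small"), seed = 1,
                             dose = 5, n = NULL, K = NULL,
                             stride = 200) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  if (is.null(n)) n <- if (scale == "tiny") 50L else 150L
  if (is.null(K)) K <- if (scale == "tiny") 200L else 300L
  n <- as.integer(n)
  K <- as.integer(K)
  spec <- chromosome_spec(paste0("fix", n), n,
                          breaksite = as.integer(n * 0.6),
                          centromere = seq_len(max(3L, n %/% 16L)))
  set.seed(seed)
  # block-structured attractions: uniform baseline + within-block bonus
  n_blocks <- 3L
  edges <- round(seq(1, n + 1, length.out = n_blocks + 1))
  block <- findInterval(seq_len(n), edges, rightmost.closed = TRUE)
  u0 <- matrix(0.6, n, n)
  bonus <- runif(n_blocks, 0.8, 1.6)
  for (b in seq_len(n_blocks)) {
    sel <- block == b
    u0[sel, sel] <- u0[sel, sel] + bonus[b]
  }
  noise <- matrix(runif(n * n, -0.1, 0.1), n, n)
  u0 <- u0 + (noise + t(noise)) / 2
  u0[u0 < 0] <- 0
  diag(u0) <- 0
  potentials <- pair_potential_field(u0)
  ensemble <- sample_ensemble(spec, potentials, K, seed = seed + 7L,
                              stride = stride)
  target <- aggregate_contacts(ensemble, "relative", spec = spec)
  truth <- list(potentials = potentials, seed = seed,
                block_bonus = bonus)
  out <- list(spec = spec, target_map = target, ensemble = ensemble,
              truth = truth)
  if (kind == "contact-map") return(out)

  gamma_sp <- 0.002 * (1 + sin(seq_len(n) / n * 2 * pi))^2
  p_ce <- 0.003
  params <- ir_params(dose)
  bp <- population_breakpoints_cf(spec, ensemble, params, gamma_sp,
                                  p_ce = p_ce)
  out$breakpoint_profile <- bp$values
  out$truth$gamma_sp <- gamma_sp
  out$truth$p_ce <- p_ce
  out$truth$dose <- dose
  out
}
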