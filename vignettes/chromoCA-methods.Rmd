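---
title: "Modelling chromosome folding and cis-translocation formation with chromoCA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chromosome folding and cis-translocation formation with chromoCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chromoCA)
```

## The model

chromoCA treats an interphase chromosome as a coarse-grained polymer:
a chain of N spherical subunits, each carrying 100 kb of DNA. Two
subunits interact through a Weeks-Chandler-Andersen excluded-volume
term (one coefficient `u0_ev` for all pairs) plus a shifted, truncated
Lennard-Jones attraction whose depth `u0_attr(i, j)` is specific to
the pair. The attraction cutoff is 3 diameters, where the unshifted
potential is 0.5% of the well depth, so longer-range attraction is
neglected. A contact between subunits is scored when their centres
come within `R_cont = 1.2` diameters.

The pair-specific depths are what make the model a *heteropolymer
globule*: they are not imposed, but fitted so that the thermodynamic
ensemble of chain conformations reproduces a target (Hi-C) contact
map. The fit is a plain sign-following inverse iteration: simulate an
ensemble, compare its contact map with the target by Pearson
correlation over unmasked pairs, then raise the depth of every pair
whose simulated contact frequency is too low and lower it where it is
too high, and repeat until the correlation stops improving.

On top of the structural ensemble sit two mechanisms of
intrachromosomal exchange-aberration (cis-translocation) formation:

* **contact-first** — damage strikes an existing conformation; every
  pair of damaged subunits currently in contact converts into an
  exchange with probability `P_c-e`;
* **breakage-first** — lesions move with the chain after damage; every
  contact episode between damaged subunits converts at rate `V_c-e`
  per unit real time (the t = 0 conversions reproduce the
  contact-first channel as an integral part).

Damage itself has three origins: the recurrent nuclease (I-SceI)
lesion placed at the breaksite bead with probability 1; IR-induced
lesions whose per-chain count is Poisson with mean `N * alpha * D * L`
(`alpha = 8.2e-9 /Gy/bp`, `L = 1e5 bp`, dose `D` in Gy — 0.0041 per
subunit at 5 Gy); and spontaneous lesions drawn per bead from a
phenomenological profile `Gamma_sp` that can be reconstructed from an
experimental breakpoint profile by a multiplicative inverse iteration.

The package reports breakpoint profiles as HTGTS-comparable
bait-involving exchanges tallied at the non-bait partner bead, in
breakpoints per cell (two chromosome copies per cell).

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `u0_ev` | 1 | kT | excluded-volume strength; ~1 kT is the scale used in the Lennard-Jones time estimate |
| `u0_attr` | fitted (init 1.2) | kT | per-pair attraction depth |
| `r_cut` | 3 | d | attraction cutoff |
| `R_cont` | 1.2 | d | contact radius (structure and aberrations) |
| `alpha` | 8.2e-9 | 1/(Gy bp) | IR DSB induction efficiency |
| `P_c-e` | 0.0029 / 0.0035 | — | contact-to-exchange probability (chr7/18, chr2) |
| `V_c-e` | 1.54 / 0.52 / 0.28 | 1/h | contact-to-exchange rate (chr18 / chr7 / chr2) |
| `t_max` | 18000 | ps | observation window (3.3 h of real time) |
| `dt_contact` | 5 | ps | contact-check interval (3.3 s of real time) |

The internal-to-real mapping follows the mobility calibration of
damaged chromatin loci: one bead is physically 225 nm, and 1 real hour
corresponds to 5500 ps of simulation. For the integrator the bead is
1 nm and 100 amu, which gives the Lennard-Jones time
`tau = d sqrt(m/U0) ~ 6 ps` and friction `Gamma = 0.1 /ps`.

## Numerical choices

Several ingredients are genuinely open at the level of the published
model description; the package's choices are:

* **Bonded interaction.** Harmonic bond with rest length d and
  stiffness 200 kT/d^2, which keeps bond-length fluctuations near
  0.07 d at kT = 1 — stiff enough for connectivity, soft enough to
  integrate.
* **Integrator and step.** BAOAB Langevin splitting at kT = 1. The
  step is capped by a stability bound derived from the stiffest local
  mode (bond spring + WCA wall + deepest attraction well with a
  coordination factor of 6), keeping `omega * dt <= 0.35`; for a coil
  this gives ~0.06 ps, for the 9.34-kT dense globule ~0.03 ps. A
  nominal `dt = 0.2` ps is used whenever the bound allows it.
* **Energy junction of the two pair terms.** Read literally, the
  total pair energy jumps by about the well depth at `r = d 2^(1/6)`
  where the attraction switches on. Forces are taken as the piecewise
  analytic derivatives inside each branch; the measure-zero
  discontinuity exerts no impulsive force. This matches the published
  equations at the cost of a formally discontinuous energy.
* **Equilibration criterion.** The initial self-avoiding coil is
  grown inside an impenetrable spherical cage of radius 14 d (growth
  retries capped at 1000 per bead, with whole-chain restarts) and
  equilibrated with excluded volume only; the plateau criterion is a
  relative change of the windowed mean radius of gyration below 1%
  across two consecutive 10^4-step windows. For very short test
  chains the windowed mean itself fluctuates by a few percent, so
  convergence there certifies stationarity rather than a tight
  plateau.
* **Fit update.** The published rule fixes only the direction of each
  coefficient update. The package uses a fixed additive step of
  0.05 kT, halved when the Pearson correlation drops more than 0.02
  below the previous iteration's value (drops smaller than the
  iteration-to-iteration sampling scatter of the map correlation,
  about 0.015 at the default ensemble sizes, are not treated as
  overshoot), with depths clamped at zero. Stopping: `patience`
  iterations (default three) without a 10^-3 improvement in the best
  correlation; noisy small-ensemble fits benefit from a larger
  patience so that a chance dip does not end the optimization. Ensembles are resampled independently each iteration
  (fresh seeds), growing from `K_min` to `K_max` conformations for
  cost control, warm-starting the dynamics from the previous
  iteration's last conformation.
* **Non-mappable beads.** Their attraction rows are the mean of the
  nearest mappable row on each side (the single nearest row at a
  chain end); one row per side, since the number of "closest" mappable
  neighbours is not specified anywhere.
* **Spontaneous-profile reconstruction.** The update is
  multiplicative, `Gamma' = Gamma * target/sim`, clipped to
  [1e-8, 1], with profiles smoothed (200-kb rebin, 1-Mb boxcar)
  before the Pearson comparison. `Gamma_sp` is a probability per
  chromosome per exposure snapshot; its time basis is left
  phenomenological.
* **Radial grid.** Pair-distance distributions use `dr = 0.05 d` with
  midpoint shell volumes, so the contact radius 1.2 d falls on a bin
  edge and the identity between the radial integral of psi up to
  `R_cont` and the contact frequency `q_cont` closes exactly on the
  grid.
* **Smoothing.** Breakpoint profiles are rebinned 100 kb -> 200 kb by
  pairwise summation and smoothed with a centred 5-bin (1 Mb) boxcar,
  truncated at the edges; bins of a declared high-resolution region
  are rebinned but not smoothed.
* **Conversion trials.** In the breakage-first simulator a pair in
  contact undergoes one Bernoulli trial per 5-ps check while the
  contact lasts (rate semantics), and a pair whose first contact
  episode ends without conversion is retired — re-formed contacts are
  neglected, as in the published approximation. A lesion may
  participate in several exchanges; at the fitted conversion
  probabilities double use is vanishingly rare.
* **Bead indexing.** The R interface is 1-based throughout; genomic
  intervals are 0-based half-open 100-kb bins at the I/O boundary
  (bedGraph convention).

## What the synthetic generator emulates

`generate_fixture()` forward-generates everything the pipeline needs:
a block-structured heteropolymer field (three blocks of enhanced
within-block attraction over a uniform baseline, plus smooth noise)
stands in for the compartment-like structure of a real contact map; a
smooth sinusoidal `Gamma_sp` and a known `P_c-e = 0.003` generate
breakpoint profiles with known truth. Two scales are built in: tiny
(N = 50 beads, K = 200 conformations) and small (N = 150, K = 300).

What this does **not** emulate: experimental coverage biases and their
correction, non-mappable gaps of realistic size and placement,
locus-specific contact features (loops, TADs at sub-block scale), or
the sheer size of real chromosomes (N = 908-1818 at 100 kb). Passing
the recovery tests therefore demonstrates that the inverse machinery
is consistent — forward-generated data are recovered — not that any
particular biological structure is correct. Full-scale refits of real
Hi-C maps use the same code path but need cluster-scale time and the
external data themselves.

## Problem sizes used by the tests

The test-suite simulations are deliberately small: a 40-bead uniform
globule with 60 conformations for contact and aberration statistics,
N = 50 fixtures for the conversion-probability and
spontaneous-profile recoveries, an N = 100 / K = 300 fixture for the
contact-map refit (target Pearson >= 0.9), 10^5 sampled cells for the
dose-scaling checks, and a few dozen cells for the lesion-dynamics
checks with shortened observation windows. Because the contact map of
a short chain is noise-limited when sampled from one trajectory at a
modest stride (two independent ensembles of the *same* potentials
correlate at only ~0.85-0.93), the refit target and the final
evaluation ensemble are sampled at a long stride (1500 steps), while
the fit iterations themselves use cheap ensembles whose noise only
perturbs the update direction. Monte Carlo assertions use
three-standard-error bands. Conversion probabilities are sometimes
inflated (e.g. 0.5 instead of 0.003) in scaling tests so that event
counts resolve the dose law; the laws themselves (linear for
nuclease-IR, quadratic for IR-IR) are unaffected by the scale factor.

## Known limitations

* Single chromosomes only: no interchromosomal exchanges, no nuclear
  environment (lamina, nucleolus, other chromosomes).
* No DSB repair during the observation window (appropriate for
  repair-deficient cells; for wild-type cells the conversion
  parameters would absorb repair implicitly).
* Damaged loci move like undamaged ones; no mobility enhancement.
* The sign-update inverse fit is the published algorithm; no
  maximum-entropy or gradient alternative is provided.
* The conformational-transition scenarios alter potentials only on
  the breaksite row and are samples from many possible variants, not
  unique reconstructions.
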