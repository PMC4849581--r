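---
title: "Evolution of epistasis on noisy fitness ridges: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolution of epistasis on noisy fitness ridges: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgesim)
```

# The model

ridgesim simulates the evolution of a quantitative trait controlled by a
small number of interacting loci, with the aim of understanding when common,
deleterious phenotypes ("disease", prevalence on the order of 1%) are
explained by *synergistic epistasis* rather than by additive allele effects.

## Genotype to phenotype

Each diploid individual carries two positive allele values at each of `d`
loci; the *input value* of a locus is the sum of its two allele values. A
landscape maps the inputs to a phenotype `z`. The central family is the
limiting-pathway (LP) map

$$z = \tfrac12\left(k + x + y - \sqrt{(k + x + y)^2 - 4xy}\right),$$

which interpolates between the hard minimum `z = min(x, y)` at `k = 0`
(e.g. the abundance of a two-subunit complex under tight binding, with `k` a
dissociation constant) and nearly additive behaviour at large `k`. Solving
`z(x, x) = 1` gives the *corner* of the optimal ridge at
`x = 1 + sqrt(k)`. For more than two inputs the package supports the
minimum map `z = min(x_1, ..., x_d)`. Smooth alternatives with the same
ridge topology are available (`landscape_poly()`, `landscape_product()`,
`landscape_saturable()`), plus completely arbitrary ridge shapes built from
a parametric optimal-phenotype curve and a gridded lookup table
(`curve_ridge()` + `build_lookup()`, bilinearly interpolated), and rotations
of any two-input landscape in `(ln x, ln y)` about its corner
(`landscape_rotate()`).

## Phenotype to fitness

The trait is under stabilizing selection,
$w(z) = \exp\!\left(-s \ln^2 (z/z_{opt})\right)$, so the set `z = z_opt`
is an optimal-fitness ridge: an L-shaped pair of arms meeting at the corner
for the LP map. `w` is symmetric in `ln z` and satisfies
`w(z; s') = w(z; s)^(s'/s)`, which lets a transient selection shift be
assessed without re-simulating.

## Phenotypic noise

Noise perturbs the *inputs* on the log scale, turning nominal inputs (from
the genotype) into effective inputs that produce the observed phenotype:

* **Developmental noise** — independent per individual and per input,
  `ln x_e = ln x + N(0, sigma_dev^2)`, not inherited.
* **Environmental noise** — one shared perturbation per input for the whole
  population, evolving across generations by a Metropolis–Hastings chain
  with stationary law `N(0, sigma_env^2)` and proposal sd `sigma_step`
  (default `0.25 * sigma_env`).

The order of application is environment first, then development. The
*heritable phenotype* `z_H` of an individual is the phenotype computed from
its environment-adjusted (but not developmentally noised) inputs:
genetically identical individuals share `z_H` even under environmental
noise, so only developmental noise reduces heritability.

With the default ratio 0.25 the environmental chain has an autocorrelation
time of about 27 generations. A note on conventions: `autocorr_time()`
defaults to the ACF *half-life* (the lag at which the autocorrelation first
drops below 1/2, linearly interpolated). The chain's empirical ACF is close
to exponential with e-folding time ~38 generations; the half-life
(`38 * ln 2 ≈ 26.5`) is the convention under which the quoted "27
generations" is exact, and both the e-folding (`method = "exponential"`) and
integrated (`method = "integrated"`) estimators are provided. The
acceptance tolerance for this quantity is ±20%.

# The simulator

`run_simulation()` advances a Wright–Fisher population of `N` diploids in
non-overlapping generations (compiled core):

1. one MH update of the environmental perturbation per input;
2. phenotype and fitness realization for every individual (allele sums →
   environmental shift → developmental noise → landscape → fitness);
3. scheduled population snapshot (after `burn_in`, every `sample_every`);
4. parent selection by rejection sampling — a uniformly drawn candidate is
   accepted if its fitness exceeds a uniform draw on `(0, max w)` — with
   the two parents of an offspring required to be distinct. The rejection
   scheme is retained (rather than replaced by weighted sampling) to
   preserve the exact stochastic process; a test verifies the marginals
   match weighted sampling;
5. transmission: one chromosome chosen uniformly at the first locus,
   switching between successive loci with probability `recomb`
   (0.5 = free recombination);
6. mutation: each allele independently with probability `mu`; a mutation
   adds `N(0, sigma_mu^2)` to the log allele value, keeping values
   positive; proposals at or above `allele_cap` (default 100) are rejected
   and the allele kept. The cap is also enforced at initialization.

Every founding allele and every accepted mutation carries a unique lineage
identifier, so population frequencies of the alleles carried by any
individual are exact (`rarest_allele_frequency()`, and the `rarest_freq`
snapshot column).

Populations start homozygous at the corner (allele value
`(1 + sqrt(k))/2` per locus for the LP map) unless explicit
`start_inputs` are given (required for rotated and lookup landscapes, which
have no diagonal corner solution). All randomness derives from the single
`seed`; identical seeds give identical snapshot streams.

Full-scale defaults follow the study conditions (`N = 5000`, `mu = 1e-4`,
cap 100, 10^7 generations with 10^6 burn-in, sampling every 10^4
generations).

# Case–control sampling and the epistasis decomposition

At each sampled time point, *cases* are the top `case_fraction` (default
1%) of phenotype values and *controls* a uniform sample (default 500) from
the 25th–75th phenotype percentiles. The control reference point is the
coordinate-wise median of the controls' *effective* inputs (a
nominal-input variant exists but is off by default, matching the
definition of the reference as the typical observed, i.e. noised, healthy
genotype). For each case,

$$H_{ind} = \frac{z_H - z_{controls}}{z_{case} - z_{controls}}, \qquad
  h_{ind} = \frac{\sum_i (z_i - z_{controls})}{z_{case} - z_{controls}},$$

where `z_i` substitutes the case's i-th heritable input into the control
reference coordinates (one locus at a time — the natural d-locus reading of
the single-mutant construction). `H_ind` is the heritable fraction of the
case's phenotypic deviation, `h_ind` its additive fraction, and
`H_ind - h_ind` the *epistatic fraction*. With developmental noise off,
`H_ind = 1` exactly and `h_ind` reduces to the purely functional `h*` of
`functional_epistasis()` (`h* < 1` synergistic, `h* > 1` antagonistic).
Cases with `|z_case - z_controls|` below tolerance are flagged degenerate,
excluded and counted. Relative fitness is case fitness over mean control
fitness, and may exceed 1 under environmental noise (the population can sit
below the optimum while the top-phenotype class is nearer to it).

`statistical_heritability()` is the population-level counterpart: the R²
of a least-squares regression of phenotype on the input values
(`1 - h²` is statistical epistasis when non-genetic variance is absent).
`case_enriched_heritability()` reweights the sample so the top-phenotype
class carries a target share (default 50%) of the regression weight, as in
a balanced case-control study; the weights are importance ratios
(target share over observed share), which matches the described
construction of the reweighted design. Regression uses input values
(allele sums), the same coordinates in which the landscapes are defined,
not individual alleles.

# Effective fitness and the random-walk picture

When noise is fast relative to selection-driven genetic change, selection
feels a locally averaged landscape. `effective_fitness()` computes
`w_e = E[w]` under an isotropic Gaussian kernel on the log inputs by
tensor-product Gauss–Hermite quadrature (21 nodes per axis by default,
spanning roughly ±5 sd; convergence is checked by node doubling — the
`k = 0` integrand is kinked at the ridge, so its convergence is slower than
for smooth landscapes but still monotone under refinement).

`arm_profile()` projects the grid onto the x-axis, taking for each `ln x`
the ridge-top value (max over `ln y`) so the profile follows the arm even
where the optimal contour curves, and normalizes at the corner.
`build_chain()` places the weak-mutation (origin-fixation) walk on that
profile: proposals from a discretized Gaussian mutation kernel (log-scale
sd `sigma_mu`), accepted with a fixation probability computed from the
effective selection coefficient `s_e = ln(w_e(x)/w_e(x'))`. The exact
fixation form used in the original supplementary treatment is not
available; the package defaults to the diffusion-limit expression
`rho = (1 - e^{-2 s_e})/(1 - e^{-4 N s_e})` (neutral limit `1/(2N)`), with
a Metropolis-like alternative `min(1, e^{4 N s_e})/(2N)` switchable for
sensitivity analysis. `stationary_distribution()` solves the left
unit-eigenvector; `exceedance()` gives `P(distance from corner >= d)`;
`simulate_chain()` cross-checks the eigen solution by Monte-Carlo.

## What the averaging theory does and does not capture

Two structural facts about this construction are worth knowing.

First, for the exact minimum map (`k = 0`) the effective fitness at the
corner *equals* the far-arm plateau identically: with an even fitness
kernel `f(ln z)` and `ln z = min(U, V)` at the corner,
`min(U, V) ~ -max(U, V)` implies `E f(min) = E f(U)`. The corner's
advantage instead appears as a peak slightly up the diagonal (nominal
inputs a little above the corner compensate the downward bias of the
noised minimum). The chain built on such profiles localizes near — not
exactly at — the corner.

Second, because of this cancellation the *degree* of chain localization is
not monotone in `k` under this construction: the sharpest corners do not
have the largest smoothed-fitness advantage. The full simulator, which
makes no averaging approximation, does show the strongest corner retention
at the smallest `k`, and that is what the package's simulation tests
assert. Chain-level tests are therefore property-based: neutral limit,
stationary-law/Monte-Carlo agreement (total variation < 0.02), linear
exceedance decay on flat profiles, and noise-monotone localization.
Relatedly, for *environmental* noise the averaging premise itself fails
(the perturbation is shared and autocorrelated), which is why simulated
localization is non-monotone in `sigma_env` while any averaging theory is
monotone; only the simulator captures that.

# Problem sizes and scaling

The headline equilibrium analyses in tests and in `scripts/acceptance.R`
use the full population size `N = 5000` with the run length reduced to
5×10^5 generations (burn-in 10^5, sampling every 2000), about nine minutes
of compute. The population size is deliberately *not* scaled down: the
force holding a population at the corner is the fixation bias `~2 N s_e`
of a weak effective-fitness advantage (`s_e ~ 10^-3` at noise level 0.05),
so corner trapping weakens linearly with `N`. At `N = 1000` with the same
noise and selection, simulated populations escape the corner for most of a
5×10^5-generation run (localized fraction 0–0.5 across seeds, against 1.0
at `N = 5000`), which changes the scientific regime, not just the noise of
the estimate. Run *length* is safe to scale because a corner-started
run at `N = 5000` is already stationary within the burn-in.

The noise-sweep analysis (optimum of unfit-case epistasis near
`s sigma^2 = 0.005`) uses `N = 3000` and 2×10^5 generations per noise
level — the largest population the sweep's time budget allows. Shrinking
`N` further visibly shifts the apparent optimum to higher noise, for the
same trapping-bias reason as above, so sweep results at small `N` should
be read as direction, not location.

# Other numerical choices

* Curve-ridge lookup tables default to the 2100 × 1800 grid over
  `ln x ∈ [-3.5, 3.5]`, `ln y ∈ [-2, 4]`; the parametric curve is sampled
  at ≥10^4 points (2×10^4 default) and nearest points found by a
  coarse-plus-window scan, with inside/outside signing by a per-column
  crossing test. Doubling the curve sampling changes log-phenotypes by
  under 10^-4 on smooth curves.
* Out-of-bounds lookup queries raise an error by default (`clamp = TRUE`
  opts into edge clamping, which the simulation presets use since mutation
  can carry genotypes to the allele cap).
* Contour orientation and curvature use central finite differences of
  `ln z` (step 10^-3); points with vanishing gradient are flagged, not
  silently filled.
* `max_epistasis_map()` enumerates the eight signed ±step perturbation
  pairs per grid point (default step 0.3) and reports the largest
  `|1 - h*|`; directions with phenotype changes below tolerance are
  skipped. This is a documented approximation of a closed-form bound whose
  exact expression is not available; it reproduces the qualitative pattern
  (maxima at corners, minima where the contour runs axis-parallel).
* The environmental chain's stationary law is verified by a KS test on a
  chain thinned to near-independence (every 200 steps); testing the raw
  autocorrelated series would reject by construction at any sample size.
* Tie-breaks: case selection orders by phenotype then stable index; the
  folded input ratio (`max/min` of population-mean inputs) is used for
  corner localization so it is invariant to relabelling loci.

# What the generator emulates, and limits

The simulator *is* the data generator: every analysis in the package runs
on its output, and the study conditions (population size, mutation rate
and step, allele cap, noise levels, sampling cadence) are the defaults
stated above. It emulates a finite panmictic diploid population with free
(or reduced) recombination, stabilizing selection on a single trait, and
the two noise channels. It does not emulate: linkage maps beyond a single
switch probability, dominance at a locus (allele values are additive
within a locus), overlapping generations, population structure, or
sequence-level variation — so passing tests support conclusions about the
model's regime, not about any particular organism's genetic architecture.
Case-control analyses here have direct access to true phenotypes,
fitnesses and lineages; real studies observe none of these directly.
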