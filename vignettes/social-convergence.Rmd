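---
title: "Measuring morphological convergence in social lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring morphological convergence in social lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(socioconv)
```

## The question and the shape of the analysis

Some bird clades — swallows and martins are the motivating example — span the
full range of social organisation: species breed alone or in colonies of
thousands of pairs, and forage alone, in pairs, or in dense flocks. If social
life imposes its own aerodynamic and foraging demands (collision avoidance in
flocks, exploitation of small swarming insects), lineages that become social
should be pushed toward a shared region of morphological space, repeatedly
and from different starting points. That is convergent evolution, and it
needs more than a group-mean comparison to demonstrate: close relatives
resemble each other for purely genealogical reasons, so every statistic in
this package is referred to a null model of undirected trait evolution on the
phylogeny.

`socioconv` implements the full chain of that argument:

1. **Trait preparation** — specimen-level measurements (wing length, outer
   tail length, middle tail length, tarsus length, bill length, bill width,
   in mm) are side-averaged per specimen, tail-fork depth is derived per
   specimen as mean outer tail minus middle tail, species means pool sexes
   with equal weight per specimen, and all traits except tarsus are divided
   by tarsus length to control for body size.
2. **Behaviour coding** — breeding is social when a species has been
   documented nesting in groups of five or more pairs (with an override for
   cavity-reusing taxa that aggregate without social cohesion); foraging is
   "groups" when a species forages beyond the breeding pair.
3. **Ancestral social states** — a Bayesian liability threshold model
   reconstructs where in the tree each social behaviour was gained and lost.
4. **Convergence metrics** — Stayton's C1–C4 trajectory indices with
   Brownian-motion simulation nulls, and the Wheatsheaf index with
   permutation nulls.
5. **Group comparisons** — phylogenetic two-sample t-tests per trait with
   Holm correction, and Pagel's correlated-evolution test between the two
   behaviours.

A synthetic-data generator emulates the whole study system so each stage is
testable end to end without any external data.

## The liability threshold model

The observed social state of a tip is modelled as the sign of an unobserved
continuous *liability* that evolves by Brownian motion on the tree. The model
is attractive here precisely because different subclades can be more or less
labile: a genus that flickers between social and solitary and a genus that is
uniformly social are both consistent with one liability process, whereas a
single transition-rate matrix must average over them.

With only two states, the liability scale, the Brownian rate, and the
threshold location are jointly unidentifiable, so the rate is fixed at 1 and
the threshold at 0; state 1 corresponds to liability > 0. Only the node and
tip liabilities are sampled. The sampler is a single-site random-scan
Metropolis chain: the joint density factorises into Gaussian increments
along edges, so updating one node touches only its parent and child edges
and a full sweep costs O(n). One **generation** is one full sweep with the
node order re-randomised; the defaults (2,000,000 generations, sampled every
2,000, first 10% of samples discarded) give 900 retained, nearly independent
samples. Tip proposals that would flip the observed sign are rejected, which
is the Metropolis kernel of the sign-constrained posterior. Per-node step
sizes are Robbins–Monro tuned toward 0.3 acceptance during burn-in and then
frozen, keeping the realised acceptance rate in a healthy band from 10-tip
to 100-tip trees. Initial liabilities are ±1 at tips and descendant-average
at internal nodes. Effective sample size and split-R̂ of the root liability
are reported but not enforced. Posterior state probabilities are the
fraction of retained samples with liability above 0; doubling all branch
lengths only rescales liabilities, leaving these probabilities unchanged.

## Stayton's convergence indices

For a focal pair of tips (a, b) with multivariate phenotypes, let `Dtip` be
their present Euclidean distance and `Dmax` the maximum distance between any
ancestor on a's root-path and any ancestor on b's root-path (paths truncated
at, and including, their most recent common ancestor; the tips themselves
count as path members). Ancestors are maximum-likelihood Brownian-motion
estimates (the GLS conditional mean, computed through a precomputed linear
operator so the same estimator is applied to observed data and to every null
replicate). Then

* `C1 = 1 − Dtip/Dmax` — the fraction of the maximal ancestral dissimilarity
  that evolution has closed (0 = none, 1 = complete);
* `C2 = Dmax − Dtip` — the same quantity in raw trait-distance units;
* `C3 = C2 / (total evolution along both lineages from the MRCA)`;
* `C4 = C2 / (total evolution over every edge of the tree)`.

"Total evolution" sums Euclidean ancestor-to-descendant step lengths along
edges; a squared-step variant is available behind a flag because verbal
descriptions of these denominators vary between sources. Values are averaged
over all focal pairs. The search for `Dmax` considers *all* ancestor pairs on
the two paths, not only contemporaneous ones. Traits are z-scored by default
before distances are taken so that no single trait dominates.

Significance: rates and the full trait evolutionary covariance are estimated
from the observed data by GLS (jointly, preserving trait correlations; a
flag simulates traits independently), `n_sims` Brownian datasets are
simulated, ancestors re-estimated, and indices recomputed for the same focal
set; `p = (#{sim ≥ obs} + 1)/(n_sims + 1)`, which can never be exactly zero.

## The Wheatsheaf index

The Wheatsheaf index asks a complementary question that needs no ancestral
reconstruction: are the focal species more tightly packed in phenotype space
than the clade as a whole, beyond what their relatedness explains? Traits
are z-scored, pairwise Euclidean distances computed, and each distance is
penalised for shared ancestry: `d'(i,j) = d(i,j) × (1 + v(i,j)/max depth)`,
where `v(i,j)` is the shared root-path length from the phylogenetic
covariance matrix. Close relatives thus have their distances inflated, so
similarity that merely reflects common descent earns less convergence
credit. The index is `w = mean(d' over all pairs) / mean(d' over focal
pairs)`; `w > 1` indicates focal clustering, and `w = 1` exactly when the
focal set is the whole clade. The penalty's published form is described only
verbally in the literature this package follows; the formula above is this
package's explicit, documented choice, kept behind a stable interface so an
alternative penalty can be swapped in without touching callers. Significance
comes from permuting which taxa carry the focal label (focal-set size
fixed), with the same +1-smoothed p-value estimator.

## Phylogenetic t-tests and Pagel's test

The two-group trait tests use the pooled-variance two-sample t statistic,
but its null distribution is built by simulating the trait under Brownian
motion on the tree (rate estimated from the full trait vector by GLS) with
the group labels fixed — on a star phylogeny this reproduces the classical
t distribution, and on a structured tree it properly discounts differences
that track deep splits. Holm's step-down correction is applied across the
six traits within each behaviour. Raw-mm species means feed these tests by
default (the descriptive-table analogue); tarsus-scaled values feed the
convergence metrics. Both choices are switchable in `analysis_config()`.

Pagel's test compares a 4-rate model in which each behaviour's gain/loss
rates ignore the other behaviour against an 8-rate model in which they may
depend on it. Likelihoods come from Felsenstein pruning over the joint
4-state chain; transition probabilities use one eigendecomposition of the
rate matrix per likelihood evaluation with a scaling-and-squaring series as
a fallback near defective matrices. The independent model factorises into
two 2-state fits (with closed-form transition probabilities), and the
dependent optimisation always starts from the independent solution plus
random restarts, so the likelihood ratio is non-negative by construction.
Root state frequencies default to the stationary distribution of the fitted
matrix (uniform available). Significance is a parametric bootstrap:
characters are resimulated under the fitted independent model, both models
refitted, and the LR compared. Null replicates are conditioned on both
characters being variable — exactly the condition imposed on observed data
(a constant character is an error) — because an unconditioned null is
polluted by uninformative replicates and the p-value becomes
anti-conservative.

## The synthetic study system

`synthetic_config()` / `make_dataset()` generate: a Yule tree (default 73
species, unit birth rate, grown until the moment the (n+1)-th speciation
would occur); two social characters from a *bivariate* liability Brownian
motion with correlation ρ (default 0.6) and a socially inclined root
(liability +0.5), thresholded at zero at every node — so the characters are
correlated through their evolution, not coupled after the fact; species
trait means by Brownian motion with per-trait rates `sd²/tree height`, the
mean/SD anchors taken from the familiar mm scale of swallow morphometrics
(wing 110.73 ± 13.15 mm, and so on); optionally an exact
Ornstein–Uhlenbeck transition toward a social optimum on every edge whose
child node's true foraging state is social (pull `α = alpha_height/height`,
default `alpha_height = 3`); and specimen records (default 5 males + 5
females per species) with per-specimen Gaussian noise on the scale of the
measuring instruments (≈2 mm for ruler traits, ≈0.2–0.3 mm for caliper
traits), left/right side jitter for the bilateral traits, and the middle
tail derived from outer tail minus fork depth. Specimen measurements are
floored at 0.1 mm so records remain physically valid. Maximum breeding group
sizes are drawn consistently with the true breeding state (solitary 1–4
pairs; social 5 pairs and up, capped at 6,000), and one species by default
lacks breeding data so the per-behaviour pruning path is always exercised.
Generation is a pure function of the configuration: one master seed, one
stream, bit-identical datasets on regeneration.

What the generator does *not* emulate: trait measurement error correlated
within specimens, sexual dimorphism (sexes share the species mean),
non-ultrametric trees, and any coupling between group size magnitude and
morphology beyond the binary state. Passing tests therefore demonstrate
correctness of the machinery under the stated forward models, not
distributional fidelity to any particular empirical dataset.

## Numerical and design choices

* **Seeds and streams.** Every stochastic operation takes one explicit seed
  and draws all replicates from that single stream, because replicates are
  generated vectorised (one preorder pass over edges serves all Brownian
  replicates at once). Same seed, same output, byte for byte; per-replicate
  seed derivation was rejected as it would preclude the vectorised path and
  nothing here runs in parallel.
* **Degenerate covariances.** Zero-length terminal branches are allowed (with
  a warning) but make the phylogenetic covariance singular; a Cholesky
  failure triggers an epsilon of `1e-8 × max depth` added only inside the
  inversion, never to the stored tree.
* **Optimisation.** Pagel fits run Nelder–Mead on log-rates (box
  `e^-18`–`e^9` via a soft penalty), multi-start, with a final polish from
  the best start; `n_starts` and `maxit` are exposed and the same settings
  are used for observed data and null replicates, preserving estimator
  consistency inside the bootstrap.
* **Monte-Carlo p-values** all use `(r + 1)/(n + 1)`.
* **Dmax ties and skipped pairs.** A focal pair whose two paths are
  phenotypically identical everywhere (`Dmax = 0`) is skipped with a
  warning rather than contributing an undefined ratio.
* **Calibration regimes and problem sizes.** The test suite verifies type-I
  error of every simulation/permutation p-value at desk scale: 1,000 null
  datasets for the t-test and Wheatsheaf tests (15-tip trees), 500 for the
  Stayton indices (40-tip trees, two traits, eight focal taxa), and 500 for
  Pagel's bootstrap (20-tip trees, gain/loss rate 0.6, 199 null simulations
  each), alongside power checks (10 focal lineages pulled to a shared
  optimum one Brownian SD away at `α·height = 3` on 50-tip trees) and
  recovery checks for the threshold model. Each null dataset for the
  Brownian-based tests draws a fresh tree, because the small-sample bias of
  a parametric bootstrap varies with tree shape; calibration is a property
  of the procedure averaged over the study design, not of one topology. A
  larger-scale version lives in `scripts/calibration.R`. Two caveats are
  worth knowing: the Stayton bootstrap is mildly conservative on very small
  trees (the estimated trait covariance feeding the null acquires spurious
  correlations), and Pagel's bootstrap LR is not pivotal at very low
  information (few expected state changes) — its rejection rate stays near
  nominal but the bulk of its p-value distribution sits slightly below
  uniform; both effects shrink as trees and transition counts grow toward
  the study scale of ~70 taxa.
* **Paper-scale defaults.** The pipeline defaults follow the study design
  this package reimplements: 10,000 t-test simulations, 1,000 convergence
  simulations, 1,000 Pagel simulations, threshold MCMC of 2,000,000
  generations thinned every 2,000 with 10% burn-in. The Wheatsheaf default
  is 10,000 permutations (`full_perms = TRUE` restores 1,000,000); at
  10,000 permutations the Monte-Carlo standard error of a p-value near 0.05
  is ~0.002, far below any decision threshold used here.
* **Phylomorphospace.** Coordinates only (tips at observed values, internal
  nodes at ML ancestral estimates, parent–child edges); the breeding-size
  axis uses log10 maximum breeding pairs, since group sizes span three
  orders of magnitude. No statistics are computed on these projections.

## Limitations

The threshold sampler fixes the liability rate, so only two-state characters
are supported (no ordered multi-state thresholds, and no joint
liability–trait correlation model). The convergence indices inherit the
assumptions of Brownian ancestral reconstruction; under strong directional
regimes the reconstructed ancestors are pulled toward the tips, which makes
C1 conservative rather than inflated. The Wheatsheaf penalty is a documented
package choice (see above). Rate-shift *detection* (painting a tree with
selective regimes) is deliberately out of scope; the generator can impose a
known regime, which is what the power tests use.
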