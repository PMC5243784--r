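# socioconv

Comparative phylogenetic analysis of **morphological convergence in social
lineages**. The motivating system is a swallow-like clade in which species
breed and forage anywhere from solitarily to in groups of thousands: if
social life imposes its own aerodynamic and foraging demands, lineages that
become social should repeatedly evolve toward the same region of
morphological space. Because close relatives resemble each other for purely
genealogical reasons, every statistic here is referred to a null model of
trait evolution on the phylogeny rather than to classical sampling theory.

The package takes a rooted phylogeny (Newick), specimen-level morphometrics
(CSV), and literature-derived behaviour records (CSV), and runs the full
chain of analyses:

* **Threshold-model ancestral states** — each binary social behaviour is the
  sign of an unobserved liability evolving by Brownian motion; a single-site
  Metropolis sampler (compiled) yields posterior state probabilities
  P(social) at every node.
* **Stayton's convergence indices** — for focal pairs (a, b),
  `C1 = 1 − Dtip/Dmax` where `Dtip` is the present phenotypic distance and
  `Dmax` the maximal distance between their reconstructed ancestors;
  `C2 = Dmax − Dtip`; `C3`, `C4` scale `C2` by the total evolution along the
  two lineages and over the whole tree. Significance by Brownian-motion
  simulation with rates estimated from the data.
* **Wheatsheaf index** — `w = mean(d') / mean(d' | focal pairs)` with
  distances penalised for shared ancestry,
  `d'(i,j) = d(i,j)(1 + v(i,j)/max depth)`; significance by permuting the
  focal labels.
* **Phylogenetic t-tests** — pooled-variance t per trait between behavioural
  groups, null distribution from Brownian simulation on the tree, Holm
  correction across traits.
* **Pagel's correlated-evolution test** — 4-rate independent vs 8-rate
  dependent Markov models for the two behaviours (pruning likelihood,
  compiled), with a parametric-bootstrap p-value.
* **Phylomorphospace coordinates** and a **synthetic-data generator** that
  emulates the whole study system (Yule tree, correlated threshold
  liabilities, Brownian or convergent Ornstein–Uhlenbeck trait regimes,
  specimen noise), so the pipeline runs end to end with no external data.

See `vignettes/social-convergence.Rmd` for the models, assumptions, and
design choices in full.

## Worked example

```r
library(socioconv)

# a synthetic swallow-like dataset with a pronounced convergent regime:
# group-foraging lineages are pulled toward a shared small-bodied optimum
means <- c(wing = 110.73, outer_tail = 61.25, tail_fork = 16.94,
           tarsus = 8.16, bill_length = 6.93, bill_width = 5.23)
sds   <- c(wing = 13.15, outer_tail = 21.70, tail_fork = 19.85,
           tarsus = 1.77, bill_length = 1.61, bill_width = 1.09)
cfg <- synthetic_config(n_species = 40, theta_social = means - 1.5 * sds,
                        root_liability = c(0.3, -0.6), seed = 11)
ds <- make_dataset(cfg)
write_fixture(ds, "demo_data")

report <- run_analysis(
  "demo_data/tree.nwk", "demo_data/specimens.csv", "demo_data/behavior.csv",
  out_dir = "demo_out",
  config = analysis_config(n_sims_ttest = 1000, n_sims_conv = 500,
                           n_sims_pagel = 200, n_perm = 5000,
                           mcmc_gen = 2e5, mcmc_thin = 200, seed = 11))
print(report)
```

which prints (exact output of the code above):

```
socioconv analysis report (status: complete )
breeding: 39 taxa (10 solitary / 29 social)
  C1 = 0.153 (p = 0.0419), w = 1.006 (p = 0.384), P(root social) = 0.953
foraging: 40 taxa (14 pairs / 26 groups)
  C1 = 0.194 (p = 0.00599), w = 1.158 (p = 0.0038), P(root groups) = 0.544
Pagel correlation: LR = 3.234, p = 0.353
```

Reading it: the breeding and foraging analyses run on their own pruned
taxon sets (one species lacks breeding data, hence 39 vs 40). Group-foraging
species have closed about 19% of their maximal ancestral dissimilarity
(`C1 = 0.194`), far more than Brownian evolution produces on this tree
(`p = 0.006`), and they cluster in morphospace beyond what their relatedness
explains (`w = 1.158`, permutation `p = 0.004`) — the convergent regime this
dataset was generated with acts on foraging lineages, and the analysis
recovers that. The breeding signal is weaker (`C1` significant at 0.042,
Wheatsheaf not), and the threshold model is confident the ancestral species
bred socially (`P = 0.953`). `demo_out/` holds `report.json`, per-behaviour
t-test tables, posterior node-state CSVs, and phylomorphospace coordinates.

A thin command-line wrapper is installed at `exec/socioconv`
(`socioconv run --tree ... --specimens ... --behavior ... --out report/`,
`socioconv synth --out dir/`).

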