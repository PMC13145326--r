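# modnest

Structural analysis of weighted ecological networks: modularity, WNODA
nestedness, bespoke null models, and module-level trait-assembly inference.

`modnest` is aimed at community ecologists asking *why* a consumer
assemblage is organized the way it is. It takes two kinds of weighted
matrices over the same consumers — an **occurrence network** (community
samples × consumers, cells = abundance) and a **food web** (prey items ×
predators, cells = frequency of occurrence in stomachs) — and separates
the signatures of *abundance-based* (neutral encounter) and *niche-based*
(trait filtering) assembly.

## What it computes

* **Weighted modularity** `Q_w`: bipartite (Barber-type) and directed
  unipartite objectives,
  `Q = (1/W) Σ_{ij same module} (A_ij − r_i c_j / W)`,
  optimized by simulated annealing (Rcpp engine) with a 100-restart
  retention policy and deterministic tie-breaking; normalized `Q/Q_max`
  against an idealized fully modular matrix.
* **WNODA** (Weighted Nestedness based on Overlap and Decreasing
  Abundance, 0–100) for whole matrices, same-module areas (compound
  topology) and individual module blocks.
* **Null models**: a connectance-preserving randomization that keeps the
  number of links exact while maintaining the degree distribution
  probabilistically; a module-membership-constrained variant that
  randomizes only within module blocks; and Monte Carlo null modules built
  by resampling interaction events while fixing events per module.
* **Trait assembly**: Gower distance over mixed traits → principal
  coordinates (Cailliez correction) → functional dispersion (FDis) of the
  consumers using each module's resources, community-weighted means (CWM)
  per quantitative trait, and chi-square contingency tests for categorical
  traits and habitat / prey-category composition.
* **z-scores** `z = (X_obs − X̄)/Sd_X` with the |z| > 2 rule and the
  standard interpretation grid (nested / anti-nested, modular /
  anti-modular, limiting similarity / niche filtering, trait matching /
  trait barrier).
* **Abundance–degree regressions** (degree ~ log10 abundance), the
  neutral-assembly diagnostic.
* **Synthetic generators** that plant modules, within-module nestedness,
  trait convergence and neutral abundance structure at the scale of a real
  riverine piscivore system (149×17 and 113×17 matrices), so every stage
  is testable without field data.

Results come back as tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(modnest)

# a 40 x 12 occurrence network with 3 planted modules, weak mixing,
# moderate within-module nestedness, lognormal abundances
g    <- generate_modular_network(synthetic_spec(
          n_resources = 40, n_consumers = 12, n_modules = 3,
          mixing = 0.1, nestedness = 0.5, total_events = 600, seed = 42))
m    <- g$matrix
mods <- find_modules(m, n_restarts = 50, seed = 1)
mods
#> <module_partition> 3 modules over 52 nodes, Qw = 0.4071 (bipartite, 50 restarts)

q_zscore(m, n_null = 100, n_restarts = 50, seed = 1, partition = mods)$z
#>   metric     x_obs null_mean null_sd     z n_reps interpretation
#> 1 modularity 0.407     0.174 0.00980  23.7    100 modular

wnoda_zscore(m, n_null = 200, seed = 1)$z
#>   metric x_obs null_mean null_sd     z n_reps interpretation
#> 1 wnoda   26.2      46.5    3.09 -6.59    200 anti-nested

tr  <- generate_traits(g$partition, convergence = 0.8, seed = 2)
module_assembly(m, mods, tr, n_null = 500, seed = 3)$fdis
#>   module  fdis null_mean null_sd      z interpretation
#> 1      1 0.285     0.542  0.0104 -24.7  niche filtering
#> 2      2 0.503     0.540  0.0254  -1.48 non-significant
#> 3      3 0.502     0.539  0.0238  -1.54 non-significant
```

Read: the network is far more modular than its degree-constrained null
(z = 23.7) and less nested than expected (z = −6.6) — niche-type structure
dominates the whole-network topology. Module 1's consumers are much more
functionally similar than random resampling predicts (FDis z = −24.7,
niche filtering); the planted trait convergence is recovered. The
abundance–degree regression on the same data
(`abundance_degree_regression()`) returns R² = 0.95 with a positive slope:
abundant consumers occupy more communities, the neutral signal operating
alongside the niche one.

`run_full_analysis(config)` chains all of the above for one or two
networks (modularity and nestedness z-scores, per-module WNODA / FDis /
CWM / composition tests, regressions) into a single deterministic report.

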