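---
title: "Modularity, nestedness and assembly rules in weighted ecological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modularity, nestedness and assembly rules in weighted ecological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Consumer assemblages organize along two complementary network dimensions.
An **occurrence network** links community samples (site by date) to the
consumer species recorded there, weighted by abundance; its modules are
groups of consumers that co-occur in space and time. A **food web** links
prey items to the predators whose stomachs they appear in, weighted by
frequency of occurrence; its modules are groups of predators sharing prey.
Two families of mechanism can generate structure in both: *abundance-based*
(neutral) processes, where interaction probability scales with encounter
rates and hence with the abundance of both parties, and *niche-based*
processes, where traits gate which resources a consumer can use. Neutral
assembly favours nested networks whose degree gradients follow abundance;
trait filters in heterogeneous resource landscapes favour modules, either
internally convergent (strong filters) or divergent (weak filters plus
competition).

`modnest` implements the full inferential pipeline for separating these
signals in weighted networks: modularity and nestedness against tailored
null models, module-level functional diversity and trait means against
Monte Carlo null modules, trait/habitat/prey contingency tests, and
abundance–degree regressions — plus synthetic generators that plant each
kind of structure so every stage can be validated end to end.

# Models and statistics

## Weighted modularity

For a weighted matrix $A$ with row (resource) totals $r_i$, column
(consumer) totals $c_j$ and total weight $W$, the bipartite weighted
modularity of a partition assigning every node to a module is

$$Q = \frac{1}{W}\sum_{ij:\,\text{same module}}\left(A_{ij} - \frac{r_i c_j}{W}\right).$$

Food webs are viewed as directed prey-to-predator graphs and scored with
the directed unipartite form
$Q = \sum_s \left[ W_{ss}/W - (W^{out}_s/W)(W^{in}_s/W) \right]$.
On a bipartite carrier the two expressions coincide algebraically (a
prey node's out-strength is its row total, a predator's in-strength its
column total), so one optimization engine serves both; both evaluation
functions are exposed and their equality on the shared carrier is part of
the test suite.

Optimization uses simulated annealing with a fixed, documented schedule:
initial temperature calibrated as twice the mean absolute $\Delta Q$ of
random single-node moves from the singleton start; geometric cooling
(factor 0.995 per sweep of $n$ proposals); proposals mixing single-node
moves (10% of them towards an empty module, which implements splits) with
module merges (10% of proposals); stop after $n^2$ consecutive rejections.
Each restart ends with a greedy hill-climb over best single-node moves and
best pairwise merges, which makes the search exact on small instances (the
suite checks equality with exhaustive enumeration over all partitions on
matrices up to 4x4). The search is restarted `n_restarts` times (default
100) and the best configuration kept; ties go to the lexicographically
smallest canonical relabelling so runs are reproducible bit for bit given
a seed. A faster `weighted_label_propagation` method (random initial
grouping + the same greedy hill-climb) is available where thousands of
null-replicate detections are needed; on the small matrices involved it
reaches the same optima.

Raw $Q_w$ depends on size and connectance, so `normalize_q()` reports
$Q/Q_{max}$, with $Q_{max}$ the modularity of an idealized fully modular
matrix built by moving every row's inter-module weight inside its module
proportionally to its existing within-module cells (rows whose module has
no consumers keep their cells; the degenerate $Q_{max}=0$ case returns
`NA` with a warning).

## WNODA nestedness

Weighted Nestedness based on Overlap and Decreasing Abundance scores every
same-side node pair, ordered by marginal total with the larger first: the
pair score is the percentage of the smaller-total node's nonzero cells
whose value is *strictly* lower than the corresponding nonzero cell of the
larger-total node. Equal-marginal-total pairs score 0 (the
decreasing-abundance requirement), as do equal cell values — the
conservative tie rule of the weighted-NODF lineage; the index is the mean
over all row pairs and column pairs jointly, 0 for perfectly non-nested
and 100 for perfectly nested matrices. It is invariant to row/column
permutation, transposition and positive rescaling (all comparisons are
ordinal); these are property tests in the suite, alongside equality with
an independently coded pair-enumeration oracle.

`wnoda_sm()` restricts the computation to same-module areas (each module's
resource-by-consumer block) and aggregates modules weighted by
contributing pair count (a simple module mean is also reported). High
same-module WNODA together with high modularity indicates a *compound
topology* — a modular network with internally nested modules.
`module_wnoda()` scores one module's block; modules with at most one
consumer are skipped with an explicit `NA`, matching the convention of
comparing nestedness only where more than one predator is present.

## Null models

Three randomization schemes, all operating on integer interaction events
(non-integer matrices are rescaled with a documented factor):

* **vaznull** — preserves the number of nonzero cells exactly and the
  degree distribution probabilistically. A binary skeleton of exactly $C$
  cells is drawn with probability proportional to $r_i c_j$, coverage
  first (every interacting row draws one column proportional to column
  totals, then every still-uncovered column draws a row proportional to
  row totals, with redraws if coverage overruns $C$), then the remaining
  $W - C$ events are distributed multinomially over the skeleton with the
  same probabilities. Every replicate conserves $W$ and $C$ exactly and
  covers every row and column.
* **module-constrained** — the same procedure applied independently inside
  each module's diagonal block, inter-module cells copied unchanged, so
  module membership is held constant; per-block $W$ and $C$ are preserved.
  Block coverage is enforced only for rows/columns that interact within
  the observed block (a module may contain a resource whose events all lie
  outside it).
* **module resampling** — draws a fixed number of events from the whole
  network's event multiset, without replacement by default (null modules
  are then sub-multisets of the observed network, so consumers from other
  modules can enter — the stated purpose of the design); sampling with
  replacement is available behind a flag.

Ensembles derive per-replicate seeds deterministically from a base seed,
so `build_ensemble()` is reproducible end to end.

## z-scores and their reading

Every metric is standardized as $z = (X_{obs} - \bar X)/\mathrm{Sd}_X$
over its null ensemble, with $|z| > 2$ read as significant. The
interpretation grid: WNODA and same-module WNODA high/low = nested /
anti-nested; modularity high/low = modular / anti-modular; FDis high/low =
limiting similarity / niche filtering; CWM high/low = trait matching /
trait barrier; everything else non-significant.

## Module-level trait assembly

Traits live in a mixed table (quantitative and categorical; per-individual
measurement lists are collapsed to means for the distance space, with raw
values retained). The trait space is a hand-computed Gower distance
(range-normalized quantitative differences, simple matching for
categories, equal weights; zero-range traits are excluded with a warning)
embedded by principal coordinates with a Cailliez additive correction when
the matrix is not Euclidean; *all* axes with positive corrected
eigenvalues are kept, because FDis is distance-based and truncation would
silently change values. Functional dispersion is the weighted mean
distance to the weighted centroid,

$$c = \frac{\sum_i w_i x_i}{\sum_i w_i}, \qquad
\mathrm{FDis} = \frac{\sum_i w_i \lVert x_i - c\rVert}{\sum_i w_i}.$$

For a module, the consumer set is **all** consumers interacting with the
module's resources — not only module members — each weighted by its total
interaction weight with those resources. This makes FDis defined for every
module including monospecific ones, and lets consumers from other modules
enter where the module's resources impose weak barriers. Global-abundance
weighting is available behind a flag (`weighting = "global_abundance"`)
since the definitional phrase "weighted by consumer relative abundances"
admits both readings; module-interaction weighting is the default because
it is the quantity the resampling null reproduces.

CWM is the analogous weighted mean of one quantitative trait. Both are
compared to 2000 (configurable) null modules from the module-resampling
scheme, sharing one ensemble per module. Categorical traits and the
habitat/prey-category composition of a module's resources are tested with
Pearson chi-square goodness-of-fit tests against whole-network
proportions: species-weighted proportions for traits by default
(abundance-weighted behind a flag; the "proportion of traits in the whole
network" phrase is ambiguous and species-weighting is the simpler
reading), occurrence-weighted proportions for habitat/prey composition.

## Abundance–degree regression

Ordinary least squares of degree (count of nonzero cells per consumer) on
$\log_{10}$ abundance. The direction — degree as response, log-abundance
as predictor — follows the axis layout of the standard diagnostic plot;
$R^2$, $F$ and $p$ are base-invariant, only the slope depends on the log
base (10, documented).

# The synthetic generators

`generate_modular_network()` plants all the structure the pipeline is
meant to detect. Consumers and resources are assigned round-robin to
modules; consumer abundances are lognormal; each event's consumer is drawn
proportional to abundance; with probability `mixing` the event lands
uniformly in a random *other* module. Within modules, `nestedness`
controls two things at once: *containment* (consumers lower in the
module's abundance ranking are restricted, with that probability, to the
top-ranked resources of the module, so specialists' resource sets nest
inside generalists') and *smoothness* (that fraction of each consumer's
events is placed by largest-remainder rounding of the expected decay
profile rather than multinomially). Both are needed because a
degree-proportional null is itself near-ideally nested given decaying
margins: a planted block can only exceed the null by having either
beyond-margin containment structure or less cell-level noise than a
multinomial realization — which is precisely how empirically nested
modules exceed it. Every node is guaranteed at least one event by moving
events out of the fullest cells, keeping $W$ exact.

`generate_traits()` draws quantitative traits as
`convergence * module_mean + N(0, 1 - convergence)` with module means from
$N(0, 1.5)$, and categorical traits from module-biased category
distributions; convergence 0 decouples traits from modules entirely,
convergence 1 removes within-module variance.

`generate_neutral_network()` is the abundance-only baseline: consumer
drawn proportional to abundance and resource uniformly, or — via
`resource_abundances` — proportional to resource abundance, making the
cell probabilities bilinear in both sides' abundances as the
encounter-probability mechanism implies.

Default dimensions mirror the empirical system the package is designed
around: 149 samples x 17 predators with 3010 events for the
occurrence-network scale, 113 prey x 17 predators with 1271 events for the
food-web scale, 7 and 6 modules, lognormal abundances
(meanlog log 50, sdlog 1.2). Mixing 0.15, nestedness 0.3 and convergence
0.7 are the package's reference settings for a clearly but not trivially
structured system.

What the generator does *not* emulate: spatial autocorrelation among
samples, seasonal/hydrological turnover, ontogenetic diet shifts,
taxonomic resolution differences among prey, and trait covariance
structure. Tests passing on synthetic data therefore demonstrate that the
machinery detects the planted mechanism classes at realistic scale — not
that any particular empirical system is driven by them.

# Calibration: what the null models do and do not control

Two properties of the design deserve explicit statement; both are verified
empirically in the acceptance suite.

**Generator–null alignment.** The connectance-preserving null places cells
and events proportional to $r_i c_j$. A neutral process that is bilinear
in both sides' abundances is well calibrated against it (type-I rate near
the nominal ~5% at the $|z|>2$ rule, and 4–5% for vaznull-generated data
against vaznull ensembles). A neutral process with *uniform* resource use
is systematically less nested than this null (anti-nested bias of roughly
one z-unit at the scales tested) — a genuine model mismatch, not an
implementation artifact. The calibration experiments therefore use the
bilinear variant.

**Selection effects at module level.** FDis and CWM nulls resample events
from the whole network; the observed module, however, is usually the
output of modularity *optimization*, which concentrates interaction weight
on the module's consumers by construction. Under pure neutrality this
selection alone drives observed FDis below the resampling null (median z
near -3 in our experiments). The type-I property is therefore stated — and
tested — for a data-independent partition, where the observed module's
events are exactly a random sub-multiset and calibration is structural.
Interpreting FDis/CWM z-scores on optimized modules is conditional on that
selection, a caveat shared with the published design rather than
introduced by this implementation.

# Numerical and procedural choices

* Optimizer determinism: all randomness flows through R's RNG (the C++
  engine uses R's uniform generator), so a single seed fixes the entire
  analysis; restart ties break to the lexicographically smallest canonical
  assignment; module ids are relabelled 1..k by descending module weight.
* Null-replicate module detection uses a reduced restart count (default
  20 vs 100 for the observed network) as a tractability knob; at null-
  matrix sizes the optimizer converges well before that, and the type-I
  experiments use equal budgets on both sides.
* Replicate counts: network-level nulls default to 100 in
  `run_full_analysis()` (1000-scale runs are configurable; the acceptance
  script uses 200), module-level nulls to 500 (2000 in the acceptance
  script, matching the reference design). The test suite uses smaller
  counts chosen so the full run completes in minutes on one CPU.
* Degenerate inputs: single-cell matrices are their own vaznull replicate;
  matrices with no partition beating $Q = 0$ return the single-module
  partition; WNODA is undefined (error) for a 1x1 matrix and same-module
  WNODA when no module has more than one node on a side; zero null
  standard deviation raises a degenerate-null error rather than an
  infinite z.
* All-zero rows/columns are rejected at construction (optionally dropped
  with a warning): they carry no events and break degree-probabilistic
  nulls.

# Known limitations

* The annealing schedule is fixed rather than adaptive; pathological
  near-degenerate modularity landscapes may need more restarts.
* WNODA here is one frozen, fully documented variant of the
  overlap-and-decreasing-fill family (strict inequalities, ties score 0,
  joint row/column average); published variants differ in tie handling,
  and cross-package numerical comparisons should expect small systematic
  differences.
* FDis/CWM inference on optimized modules carries the selection effect
  described above; treat those z-scores as descriptive of module
  distinctiveness rather than exact hypothesis tests.
* The chi-square composition tests use asymptotic p-values; very small
  modules can have sparse expected counts.
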