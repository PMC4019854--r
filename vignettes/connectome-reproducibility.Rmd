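---
title: "Reproducibility analysis of structural brain networks with connrepro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproducibility analysis of structural brain networks with connrepro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connrepro)
```

## The problem

Structural brain networks are commonly built by counting tractography
streamlines between pairs of anatomically labeled regions, thresholding the
resulting weighted connectivity matrix to a fixed graph density, binarizing,
and summarizing the binary graph with network metrics. Every step of that
chain — and in particular the choice of fiber-tracking algorithm — can change
the result. connrepro implements the downstream analysis as a reusable,
seeded pipeline: given one connectivity matrix per subject × session ×
group, it quantifies (i) how topologically similar repeated measurements
are (edge-wise Dice), (ii) how reliable each network metric is across
test–retest sessions (ICC as a function of density), and (iii) whether two
groups — e.g. two tracking algorithms — produce systematically different
metric curves (a permutation test on the area between group mean curves).

Because the upstream imaging steps are out of scope, the package includes a
synthetic test–retest connectome generator so that the entire pipeline can
be exercised, calibrated and tested without any imaging data.

## Density thresholding

For an undirected graph we define density with the ordered-pair convention

$$D(G) = \frac{2\,\lVert E(G)\rVert}{\lVert N(G)\rVert(\lVert N(G)\rVert-1)},$$

so that $D$ spans $[0,1]$ and a complete graph has density 1. (The same
quantity is sometimes written without the factor 2, with edges counted once;
that variant only reaches 0.5. We state our convention prominently because
published density ranges are consistent with either reading.)

`threshold_to_density()` keeps the top-weighted edges until the edge budget
$\mathrm{round}\!\left(d\cdot\tfrac{N(N-1)}{2}\right)$ is met (half-up
rounding, so grids are bit-reproducible), then sets the surviving weights
to 1. Two numerical choices matter and are deliberately fixed:

* **Tie-breaking.** Streamline counts are small integers, so ties at the
  threshold weight are common. Edges are ordered by weight descending, then
  by (row, column) index pair ascending. This total order makes
  thresholding deterministic and makes the edge sets *nested* across any
  increasing density grid — a property the Dice and curve machinery relies
  on and that the test suite checks on random matrices.
* **Zero-weight pairs are never edges.** If the requested density exceeds
  the density of the positive-support graph (`max_density()`), the call
  fails with the achievable maximum rather than padding with
  zero-weight edges.

## The seven network metrics

All metrics operate on binary undirected graphs (`binary_graph`); weighted
and directed variants are out of scope.

* **Mean clustering coefficient** — per node,
  $C_i = 2e_i/(k_i(k_i-1))$ with $e_i$ the edges among $i$'s neighbors;
  averaged over all $N$ nodes. Nodes of degree $<2$ have a vanishing
  denominator; we use the common binary-graph convention $C_i = 0$.
* **Characteristic path length** — mean hop count over all pairs. It is
  only defined for connected graphs, so the largest connected component is
  extracted first (ties between equal-size components go to the one
  containing the smallest node index). If the largest component has fewer
  than two nodes the value is undefined (`NA`).
* **Largest connected component size** — node count of the largest
  component, also reported as a fraction of $N$; curves use the fraction so
  cohorts with different parcellations remain comparable.
* **Assortativity** — the Pearson correlation of degrees across edge
  endpoints, evaluated in its edge-sum form. For any regular graph (all
  endpoint degrees equal) the denominator vanishes; we return a typed
  undefined value (`NA`) rather than letting NaN propagate into curves.
* **Global efficiency** — mean of $1/L_{ij}$ over all pairs with
  $1/\infty = 0$; defined for disconnected graphs, no component extraction.
* **Local efficiency** — for each node, the global efficiency of the
  subgraph induced on its *neighbors* (nodes of degree $<2$ contribute 0),
  averaged over all nodes. Two readings of the local-efficiency subgraph
  circulate: "the graph with node $i$ removed" and "the subgraph induced on
  the neighbors of $i$". We implement the neighbor-induced form: it is the
  definition in the efficiency literature, it matches the intuition of
  fault tolerance (how well $i$'s neighbors communicate if $i$ fails), it
  keeps the metric in $[0,1]$, and the removal reading would make the
  measure an $N$-fold repetition of global efficiency.
* **Rich-club coefficient** — with $N(G,k)$ the nodes of degree $\ge k$ in
  the full graph, $R(G,k)$ is the density of the subgraph induced on
  $N(G,k)$ (again with the factor 2, so $R(G,0) = D(G)$ exactly — an
  identity the tests assert for every random graph). Fewer than two
  qualifying nodes leaves the value undefined.

Each metric is checked against an independent exhaustive implementation
(triangle enumeration, Floyd–Warshall distances, direct formula evaluation)
on hundreds of random graphs to $10^{-12}$, and cross-checked against
igraph where igraph implements the same quantity.

## Graph curves

Binary graphs at a single density are hard to compare; curves of metric
versus density retain the continuous structure of the weighted matrix.
`common_density_range()` builds the shared grid: from `step` up to the
*minimum* over the dataset of each matrix's maximum density, so every graph
can be thresholded at every grid point. The grid step defaults to 0.01;
it is a sampling choice, not a statistical one, and results that are
sensitive to it should be treated with suspicion (undefined points are
carried as `NA`, never interpolated).

The rich-club coefficient depends on two parameters, so its curve is taken
over degree level $k$ at one fixed density — 0.15 by default, with
`"common"` (the highest density shared by all graphs) as the alternative
mode.

## Dice similarity and ICC

Edge-wise Dice,
$\mathrm{Dice}(x,y) = 2\lVert E(x)\cap E(y)\rVert/(\lVert E(x)\rVert+\lVert E(y)\rVert)$,
measures topological overlap of two constant-density graphs over the same
nodes. `dice_curves()` reports, per density, the mean over each subject's
session pair (intra-subject) and the mean over all cross-subject pairs
(inter-subject, all four session combinations per subject pair — the
pairing scheme is a package choice, stated here because conventions vary).
Two empty edge sets are defined to overlap perfectly (Dice 1), a degenerate
case that real densities never reach.

Reliability of a scalar metric across sessions is the intraclass
correlation coefficient

$$\mathrm{ICC} = \frac{\sigma^2_{bs}}{\sigma^2_{bs}+\sigma^2_{ws}},$$

estimated by the one-way random-effects ANOVA method of moments:
$\hat\sigma^2_{ws} = \mathrm{MSW}$ and
$\hat\sigma^2_{bs} = \max\{0, (\mathrm{MSB}-\mathrm{MSW})/k\}$ for $k$
sessions, so the reported ICC lies in $[0,1]$ (the unclamped between-subject
component is returned alongside for transparency). Where a metric carries
little to no variance the estimator is unstable; points with
$\mathrm{MSB}+\mathrm{MSW} < 10^{-10}$ are flagged invalid and no ICC is
reported there. `icc_curve()` applies the estimator per grid point, skipping
points where any subject's curve is undefined. `icc_category()` maps values
onto the usual agreement labels (below 0.2 poor, up to 0.40 fair, 0.60
moderate, 0.80 strong, above 0.8 near-perfect; the published guideline list
leaves (0.2, 0.21) unassigned and we resolve that gap into "fair").

The estimator's sampling spread is worth keeping in mind: for $n$ subjects
and 2 sessions its standard deviation is approximately
$(1-\rho^2)/\sqrt{n-1}$, i.e. about 0.067 at $\rho = 0.25$ even with 200
subjects. Pointwise ICC values from 21-subject cohorts therefore carry
substantial uncertainty, which is why the pipeline reports whole curves
rather than single values.

## Permutation test on the area between mean curves

To compare two groups of curves we use the simplest functional-data-analysis
device: average each group into a mean curve, measure the area between the
two mean curves (trapezoidal integral of the absolute difference, restricted
once to the grid points where every curve is defined), and build the null by
re-assigning the group labels at random without replacement (group sizes
preserved), `n_iterations` = 10000 times by default. The p-value is $x/i$
where $x$ counts permuted areas **greater than or equal to** the observed
area. Counting ties as extreme is the conservative convention: with strict
"greater than" counting, two identical groups (all areas zero) would get
p = 0 instead of p = 1. The unit of permutation is the individual curve;
in a test–retest design one could instead permute subjects as pairs, which
we do not do — with one curve per subject × session and group sizes equal,
curve-level permutation is the direct reading of "permuting individual group
assignments", and the choice is stated rather than hidden.

The test is exactly invariant to swapping the two group labels (the null is
drawn by sampling the smaller group), reproducible given its seed, and its
type-I error is checked by Monte-Carlo calibration in the test suite.

## The synthetic cohort generator

`generate_testretest_dataset()` emulates the study design the pipeline is
meant for: $S$ subjects × 2 sessions × $G$ groups of $N$-node streamline
count matrices. The generative model is deliberately simple:

1. **Population backbone per group.** A modular random graph — edges within
   a module with probability `p_in` (scaled by the group's effect
   multiplier), between modules with probability `p_out` — with expected
   edge weights `weight_scale` × log-normal(0, 1). Modularity gives the
   heavy-tailed, community-structured weight distribution that makes
   constant-density thresholding non-trivial.
2. **Subject and session effects.** Per-edge Gaussian effects on the
   log-weight scale: $b_s \sim N(0, \sigma^2_{between})$ per subject and
   $e_{st} \sim N(0, \sigma^2_{within})$ per session.
3. **Counts.** Observed entries are Poisson draws around the subject- and
   session-adjusted expectation — streamline counts are nonnegative
   integers with multiplicative variability, which log-normal × Poisson
   captures with few parameters.

Defaults are fixed once, as the study conditions the package targets:
21 subjects × 2 sessions (a standard public test–retest cohort size),
78 nodes (approximately a masked AAL cortical + deep-gray parcellation;
exact masked-label counts vary, so this is configurable and labeled
approximate), 6 modules, `p_in` = 0.8, `p_out` = 0.15 (expected backbone
density ≈ 0.25, inside the 0.17–0.41 range typical of deterministic-DTI
count matrices), `weight_scale` = 50, and
`sigma_between` = 0.5 > `sigma_within` = 0.1 — test–retest noise well below
between-subject differences, the regime in which intra-subject overlap
should exceed inter-subject overlap at every density. A `deterministic`
mode replaces the Poisson draw by its mean so that exact invariants
(e.g. "zero session noise ⇒ identical sessions ⇒ intra-subject Dice = 1")
can be tested without tolerance.

What the generator does **not** emulate: spatial geometry and distance
dependence of connections, hemispheric symmetry, label-volume effects,
tractography-specific biases (curvature/FA stopping rules), or any
systematic session effect such as scanner drift. Passing tests on synthetic
cohorts therefore demonstrate that the *pipeline* is correct and calibrated,
not that any particular empirical finding generalizes.

`generate_gaussian_repeated_measures()` is the scalar analogue with known
true ICC, used for parameter-recovery checks of the estimator.

## Pipeline and problem sizes

`run_pipeline()` chains everything: common grid → per-matrix metric curves
and rich-club curves → per-group Dice and ICC → all pairwise-group
permutation tests (for each metric curve family, the rich-club curves, and
the per-subject intra-subject Dice curves). Outputs are tidy long-format
CSV tables plus the resolved configuration and a log; with a fixed seed,
reruns are byte-identical (the log carries no timestamps for exactly this
reason). Stage errors name the offending (subject, session, group).

The test suite exercises the metric oracles on 200 random graphs of up to
10 nodes, the thresholding contract on 100 random matrices, permutation
calibration on 500 null datasets of 200 iterations each, and ICC recovery
at five true ratios × 100 seeds — sizes chosen so the whole suite runs in
about a minute on one core while keeping Monte-Carlo noise well below the
asserted tolerances. The acceptance script runs the full pipeline at the
default cohort scale (84 matrices of 78 nodes, density step 0.01, 10000
permutation iterations).

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_subjects = 8, n_nodes = 40, n_modules = 4,
                        groups = c(FACT = 1.0, TEND = 1.3), seed = 42)
ds <- generate_testretest_dataset(cfg)
res <- run_pipeline(ds, "connrepro_out", density_step = 0.02,
                    rich_club_density = "common",
                    n_iterations = 2000, seed = 42)
subset(res$dice, group == "FACT")[1:3, ]
subset(res$icc, metric == "global_efficiency" & valid)[1:3, ]
res$fda
```

## Known limitations

* Only binary, undirected graphs; no weighted or directed metric variants,
  and no betweenness/modularity/small-worldness.
* The one-way ICC has no confidence intervals here, and no two-way or
  consistency-type variants are offered.
* The FDA comparison is the raw mean-curve area with a global permutation
  p-value; there is no basis-function smoothing and no pointwise
  multiple-testing machinery, and only two-group comparisons are supported
  (run pairwise for more groups, as the pipeline does).
* The synthetic generator is a stand-in for imaging-derived data, adequate
  for correctness and calibration testing, not for effect-size realism.
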