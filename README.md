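# connrepro

Test–retest reproducibility analysis for structural brain networks built
from streamline-count connectivity matrices.

Graph-theoretical summaries of white-matter connectivity — built by counting
tractography streamlines between labeled brain regions, thresholding the
count matrix to a fixed graph density, binarizing, and computing network
metrics — are sensitive to every processing choice upstream, most notably
the fiber-tracking algorithm. `connrepro` implements the downstream
analysis as a seeded, reusable pipeline for anyone who has (or simulates)
one connectivity matrix per subject × session × group and wants to know:

* how topologically reproducible the thresholded graphs are, within and
  between subjects (edge-wise Dice similarity over a density range);
* how reliable each network metric is across repeated sessions
  (intraclass correlation, ICC, as a function of graph density);
* whether two groups — e.g. two tracking algorithms — produce
  systematically different metric curves (a permutation test on the area
  between group mean curves, in the style of functional data analysis).

## The model in brief

Density is defined with the ordered-pair convention
`D(G) = 2‖E(G)‖ / (‖N(G)‖(‖N(G)‖−1))`, so it spans [0, 1]. *Cumulative
density thresholding* keeps the `round(D·N(N−1)/2)` top-weighted edges
(ties broken deterministically by index, so edge sets are nested across
densities) and binarizes. Seven binary undirected metrics are provided:
mean clustering coefficient, characteristic path length (on the largest
connected component), largest-component size, degree assortativity, global
efficiency, local efficiency, and the rich-club coefficient
`R(G,k) = 2‖E(G,k)‖ / (‖N(G,k)‖(‖N(G,k)‖−1))` with `R(G,0) = D(G)`.

Reliability per grid point is the one-way random-effects ICC,
`σ²bs / (σ²bs + σ²ws)`, estimated by ANOVA method of moments with the
between-subject component clamped at zero; points with essentially no
variance are flagged invalid instead of reported. Group differences are
tested by permuting curve labels without replacement (default 10000
iterations) and counting permuted between-mean-curve areas ≥ the observed
area.

A synthetic test–retest connectome generator (modular log-normal backbone,
per-subject and per-session log-weight effects, Poisson counts) stands in
for the imaging pipeline, so the whole analysis is testable end to end
without data. See `vignettes/connectome-reproducibility.Rmd` for the full
account of conventions, estimators and limitations.

## Worked example

```r
library(connrepro)

cfg <- synthetic_config(n_subjects = 8, n_nodes = 40, n_modules = 4,
                        groups = c(FACT = 1.0, TEND = 1.3), seed = 42)
ds  <- generate_testretest_dataset(cfg)      # 8 subjects x 2 sessions x 2 groups
res <- run_pipeline(ds, "connrepro_out", density_step = 0.02,
                    rich_club_density = "common",
                    n_iterations = 2000, seed = 42)

subset(res$dice, group == "FACT")[1:3, ]
#>        group parameter intra_mean inter_mean
#> FACT.1  FACT      0.02  0.9062500  0.5223214
#> FACT.2  FACT      0.04  0.9032258  0.5535714
#> FACT.3  FACT      0.06  0.8989362  0.5887158
```

Within-subject topology reproduces far better than between-subject topology
(Dice ≈ 0.90 vs ≈ 0.52–0.59 at low densities): session noise is small
relative to stable subject differences.

```r
subset(res$icc, metric == "global_efficiency" & valid)[1:3, ]
#>    group            metric parameter       icc valid     category
#> 57  FACT global_efficiency      0.02 0.4318145  TRUE     moderate
#> 58  FACT global_efficiency      0.04 0.8855351  TRUE near-perfect
#> 59  FACT global_efficiency      0.06 0.3867183  TRUE         fair
```

Pointwise ICC is noisy with 8 subjects — exactly why the pipeline reports
curves, not single values.

```r
res$fda[, c("comparison", "observed_area", "p_value")]
#>               comparison observed_area p_value
#> 1             clustering  0.0079470302  0.0000
#> 2       char_path_length  0.0133123329  0.2220
#> 3 largest_component_size  0.0031250000  0.0370
#> 4          assortativity  0.0093782872  0.0640
#> 5      global_efficiency  0.0009132407  0.0525
#> 6       local_efficiency  0.0081746434  0.0000
#> 7              rich_club  0.2054273682  0.0005
#> 8     intra_subject_dice  0.0028058557  0.0920
```

The injected group effect (TEND's within-module edge probability × 1.3)
is detected in the clustering, local-efficiency and rich-club curves
(p ≤ 0.0005); global efficiency is the most robust to it — p-values are
`x / i` with `x` the permuted areas at least as large as the observed one.

A thin command-line wrapper with subcommands `simulate`, `metrics`,
`curves`, `dice`, `icc`, `fda` and `run-all` is installed at
`inst/cli/connrepro.R`:

```sh
Rscript inst/cli/connrepro.R simulate --out-dir demo --n-subjects 4 --seed 7
Rscript inst/cli/connrepro.R run-all --manifest demo/manifest.csv \
    --out-dir demo_results --density-step 0.02 --iterations 2000 --seed 7
```

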