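# wetnet

Temporal dynamics and co-occurrence networks of wetland soil microbiomes.

`wetnet` is for microbial ecologists studying how soil communities turn
over through time and how their interaction structure responds to an
experimental treatment — the motivating design is a warming experiment in
two coastal wetlands: 2 sites × 2 treatments (control/warming) × 9
seasonal dates × 3 plots, 27 samples per site-by-treatment group. From an
OTU count table, sample metadata and (optionally) a phylogeny and
environmental variables, the package computes:

* **Diversity** — rarefaction to even depth, observed richness, Shannon
  index (nats), Bray-Curtis and unweighted UniFrac distance matrices.
* **Community statistics** — PCoA; seeded permutation tests (one-factor
  PERMANOVA/Adonis, ANOSIM, Mantel) with the add-one p-rule
  `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`.
* **Temporal turnover** — time-decay relationships (TDR): OLS of
  community similarity on time interval in days; the turnover rate
  `v = |slope|` (similarity·day⁻¹).
* **Co-occurrence networks** — per-group prevalence filter (> 75% of
  samples, i.e. 21 of 27), Spearman correlations with t-approximation
  p-values, edges where `|r| ≥ 0.820` and `p < 0.001` (signs retained),
  or a threshold chosen by random-matrix theory: the smallest cut-off
  where the eigenvalue nearest-neighbour spacing distribution of the
  thresholded matrix becomes Poisson and stops being GOE (Wigner).
* **Node roles** — within-module degree z-score Zi and participation
  coefficient `Pi = 1 − Σ_s (k_is/k_i)²`; module hubs (Zi > 2.5),
  connectors (Pi > 0.62), network hubs (both), peripherals; keystones =
  non-peripherals, with Jaccard overlap between treatments.
* **Robustness** — proportion of taxa remaining after removing 50% of
  nodes (random) or keystones (targeted, degree-ordered), followed by
  secondary extinction of newly isolated nodes; rank-sum comparison of
  robustness distributions.
* **Synthetic data** — a generator with planted correlation modules,
  treatment-specific AR(1) temporal drift and multinomial counts, which
  reproduces the study design's statistical shape so the whole pipeline
  is testable offline.

## Worked example

```r
library(wetnet)

cfg <- synthetic_config(n_sites = 1, n_treatments = 2, n_otus = 120,
                        depth = 10000, seed = 7)
ds <- simulate_dataset(cfg)
ds
#> Synthetic dataset: 1 sites x 2 treatments x 9 times x 3 plots = 54 samples
#>   120 OTUs at depth 10000; 3 planted modules

bc <- bray_curtis(ds$table)
m <- ds$metadata
ids <- m$sample_id[m$treatment == "warming"]
tdr_fit(bc[ids, ids], m)
#> Time-decay relationship (plot pairs, n = 108)
#>   v = 0.0005323 similarity/day  (slope -0.0005323)
#>   R2 = 0.3431, p = 2.768e-11
```

The warming group's turnover rate (v ≈ 5.3·10⁻⁴ similarity per day) is
about 2.6× the control group's (2.1·10⁻⁴, not shown): community
similarity between repeat visits of the same plot erodes faster under the
higher configured drift. The regression uses the 108 within-plot pairs
with positive time interval.

```r
nets <- make_group_networks(ds$table, m)   # one network per site x treatment
net <- nets[["siteA.warming"]]
net
#> Co-occurrence network: 12 nodes, 9 edges
#>   thresholds: |r| >= 0.82 , p < 0.001 ( 27 samples )
#>   negative edges: 11.1 %

mods <- detect_modules(net)
topology_metrics(net, mods)
#> Network topology
#>    n_nodes                            12
#>    n_links                             9
#>    average_connectivity              1.5
#>    average_path_distance          1.9333
#>    average_clustering_coefficient 0.13889
#>    modularity                     0.57511
#>    n_modules                           5
#>    scale_free_r2                  0.86683
#>    pct_negative_edges             11.111

roles <- classify_roles(zipi(net, mods$membership))
simulate_removal(net, "random", 0.5, n_trials = 100, seed = 1)
#> Robustness (random removal of 50%): 0.2933 +/- 0.1036 over 100 trials
```

Of the 27-sample warming group's 120 OTUs, 12 survive the prevalence
filter *and* keep a correlation ≥ 0.82 with some partner; the resulting
sparse network fragments into 5 modules (Q = 0.58). Removing half its
nodes at random leaves on average 29% of taxa connected once secondarily
isolated nodes are pruned.

The full study design runs through one call:

```r
report <- run_pipeline(run_config(simulation = synthetic_config(),
                                  seed = 1, outdir = "run1"))
```

which writes all stage artifacts (tables, distance matrix, PCoA
coordinates, GraphML networks, role tables) plus `report.json` /
`report.txt`, every file stamped with the seed and a configuration hash;
re-running with the same seed reproduces the report byte for byte.

A thin command-line wrapper with `simulate`, `diversity`, `network` and
`run` subcommands is installed at `inst/cli/wetnet.R`.

## Vignette

`vignettes/wetnet-methods.Rmd` documents the generative model and every
estimator's conventions (tie handling, thresholds, unfolding and
goodness-of-fit choices of the RMT scan, role cut-offs, removal bases),
the design decisions behind them, and known limitations.
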