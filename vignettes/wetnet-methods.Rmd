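---
title: "Methods: temporal turnover and co-occurrence networks of wetland soil microbiomes"
author: "wetnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal turnover and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetnet)
```

## What the package computes

`wetnet` analyses the temporal dynamics and interaction structure of soil
microbial communities sampled repeatedly from a factorial field design:
two wetland sites, a warming and a control treatment, nine seasonal
sampling dates, three replicate plots — 108 samples in all, 27 per
site-by-treatment group. From an OTU count table and its sample metadata
it derives:

1. alpha diversity (observed richness, Shannon index) and beta-diversity
   distances (Bray-Curtis, unweighted UniFrac);
2. principal coordinates, PERMANOVA, ANOSIM and Mantel permutation tests;
3. time-decay relationships (TDR): the ordinary least-squares slope of
   community similarity against time interval, whose absolute value *v*
   (similarity day⁻¹) is the temporal turnover rate;
4. co-occurrence networks per site-by-treatment group: prevalence
   filtering, Spearman correlations, fixed or random-matrix-theory (RMT)
   thresholds, topology metrics, greedy modularity modules;
5. Zi-Pi node roles, keystone sets and their overlap between treatments;
6. network robustness under random or keystone-targeted species loss with
   secondary extinction.

Because the motivating study's sequencing data live in external archives,
the package ships a synthetic generator that reproduces the *statistical
shape* of such data, so every downstream stage can be validated without a
download.

## The synthetic community model

For OTU $j$ in sample $s$ (site $g$, treatment $w$, time $t$, plot $p$)
the latent log-abundance is

$$x_{js} = b_j + u_{gj} + \sqrt{\rho_P}\,\sigma f_{m(j),s}
          + z_{gwjt} + a_{gwpj} + \varepsilon_{js},$$

with

* $b_j$ — baseline: background OTUs draw from
  $\mathcal N(0, \texttt{base\_log\_sd}^2)$ (default sd 1.5, giving the
  usual steep abundance spectrum); OTUs planted into correlation modules
  draw from $\mathcal N(1, 0.5^2)$ so that the planted associations are
  carried by prevalent taxa — mirroring the fact that the network stage
  only ever sees taxa that pass the prevalence filter;
* $u_{gj} \sim \mathcal N(0, \texttt{site\_effect\_scale}^2)$ — a per-site
  shift (default sd 1) creating the strong between-site compositional
  contrast;
* $f_{m,s} \sim \mathcal N(0,1)$ — one shared factor per planted module.
  A module OTU splits its stochastic variance between the shared factor
  ($\rho_P$) and its own noise ($1-\rho_P$), so the pairwise latent
  correlation is $\rho_P$ while the marginal variance matches background
  OTUs. The target is specified as a Spearman correlation $\rho_S$ and
  converted through the Gaussian-copula relation
  $\rho_P = 2\sin(\pi\rho_S/6)$;
* $z_{gwjt}$ — temporal drift: an AR(1) recursion per site-treatment group
  and OTU, $z_t = \phi\, z_{t-1} + r_w \sqrt{\Delta_t}\,\eta$, with
  $\phi = 1$ by default (pure accumulation) and innovation scale $r_w$ per
  treatment in log-abundance units per $\sqrt{\text{day}}$. Scaling
  innovations with the square root of the days elapsed makes the
  accumulated drift variance proportional to calendar time, which yields
  the near-linear decay of Bray-Curtis similarity that the TDR stage
  assumes. Warming is encoded **only** through a larger innovation scale
  (defaults 0.04 control, 0.10 warming) — it accelerates succession
  without shifting mean composition;
* $a_{gwpj}$ — optional plot-level random effect, default scale 0 (the
  emulated design gives no basis for a plot variance component, so it is
  exposed but off);
* $\varepsilon_{js} \sim \mathcal N(0, \texttt{noise\_scale}^2)$ —
  independent noise, default sd 1.

Counts are multinomial draws of `depth` reads (default 28,500, a typical
16S rarefaction depth) from the softmax composition of each sample's
latent vector. Environmental covariates are built as
$\rho\,\text{PC}_k + \sqrt{1-\rho^2}\,\mathcal N(0,1)$ from the leading
principal components of the latent matrix (default target correlation
0.7); the achieved correlation is verified post hoc rather than solved
exactly.

The drift defaults were fixed once, during design, so that the generator
reproduces two qualitative field findings at the default problem size:
sampling time explains roughly 20% of community variance within a site,
and the warming turnover rate clearly exceeds the control rate. One
consequence of drift-only warming worth knowing: because each treatment
group follows its own drift realisation, a PERMANOVA on *treatment* within
a site will eventually detect the accumulated divergence even though the
generating model contains no systematic treatment shift — composition
tests on drifting communities conflate divergence with effect.

What the generator deliberately does **not** emulate: compositional
(negative-sum) coupling beyond the softmax, phylogenetic signal in
abundances, seasonally cyclic dynamics, plot-level spatial structure, and
sequencing artefacts (chimeras, contamination). Passing tests therefore
demonstrate correctness of the estimators on data with planted known
structure, not robustness to every failure mode of real amplicon data.

A single master seed is expanded into independent per-stage stream seeds
(`split_seed`): seeding R's RNG once with the master seed and drawing one
integer per stream. Fixed seed means bit-identical tables, TSVs and
reports.

## Diversity and distances

Rarefaction subsamples each sample uniformly without replacement to a
fixed depth (`vegan::rrarefy` behind the interface); samples below depth
are dropped with a message, never up-sampled. Shannon diversity uses
natural logarithms (nats), computed on positive proportions; alpha
diversity is reported post-rarefaction by default. Bray-Curtis follows
$1 - 2\sum_i \min(x_i, y_i)/(\sum x + \sum y)$. Unweighted UniFrac
classifies every tree edge by whether any leaf below it is present
(count ≥ 1) in each community, and divides the branch length unique to
one community by the branch length reachable from either; edges with no
observed leaf below them are ignored, and OTUs missing from the tree are
a hard error listing the offending ids.

## Ordination and permutation tests

PCoA double-centres $-d^2/2$ (Gower) and eigendecomposes; coordinates are
eigenvectors scaled by $\sqrt{\lambda}$ for positive eigenvalues only,
negative eigenvalues are counted and reported but carry no axes, and
proportions explained are taken over the positive part of the spectrum.

PERMANOVA (one factor), ANOSIM and the Mantel test are implemented
in-package so that every permutation p-value obeys the add-one rule
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$,
one-sided towards separation/association, with an explicit seed; p is
never reported as 0 and defaults to 999 permutations. Spearman Mantel
rank-transforms both matrices once up front — a simultaneous row/column
permutation permutes the pairwise values bijectively, so Pearson on the
rank matrices equals Spearman for every permutation. The test suite
cross-checks all three statistics against vegan and against brute-force
enumeration of all label splits at small n, and verifies nominal type-I
error (0.05 ± 0.02 over 1000 null simulations).

## Time-decay relationships

Similarity ($1 -$ Bray-Curtis) is regressed by OLS on the time interval
in days, over pairs with a positive interval. The default pairing scope is
within-plot (pairs of the same site, treatment and plot across dates);
a within-group scope (all cross-time pairs of a site-treatment group) is
available, since field studies differ in whether they pool plots.
Regression is on raw similarity and raw days by default; a log-log option
exists but is off. Constant similarity returns $v = 0$, $R^2 = 0$ with an
undefined slope p-value rather than an error.

## Co-occurrence networks

Per site-by-treatment group (27 samples each in the default design), OTUs
must be present in more than 75% of the group's samples — the cut is the
smallest integer strictly greater than $0.75\,n$, i.e. 21 of 27. Spearman
correlations (average ranks on ties) are computed on the rarefied counts;
at even depth this equals correlating relative abundances. Two-sided
p-values use the t approximation with $n-2$ degrees of freedom. An edge
joins two OTUs when $|r| \ge r_\text{min}$ (inclusive, default 0.820) and
$p < p_\text{max}$ (strict, default 0.001); thresholding on $|r|$ keeps
negative associations, whose sign and percentage are tracked because the
balance of negative links is itself an ecological readout. Isolated nodes
are dropped.

### RMT threshold selection

The scan thresholds the correlation matrix over a grid (0.30–0.95, step
0.01). At each candidate, rows with no surviving off-diagonal entry are
removed and the eigenvalue spectrum of the thresholded matrix is unfolded
by fitting a smoothing spline to the cumulative spectral function
(numerically equal eigenvalues deduplicated first); the nearest-neighbour
spacing distribution of the unfolded spectrum is then tested by
chi-squared goodness of fit with equal-probability bins against the
Poisson law $e^{-s}$ and the GOE Wigner surmise
$\tfrac{\pi}{2} s\, e^{-\pi s^2/4}$. The chosen threshold is the smallest
candidate where Poisson is not rejected and GOE is rejected at
$\alpha = 0.05$; if no candidate qualifies the scan returns `NA` with the
full table and the caller falls back to a fixed threshold. Unfolding
method, binning, grid and $\alpha$ are all arguments, as conventions vary
across the molecular-ecological-network literature.

A structural caveat worth stating: on a pure-noise correlation matrix the
Poisson transition tracks the percolation of the thresholded graph, which
occurs at edge density $\approx 1/(n-1)$. For 60 OTUs that is ~1.7%,
slightly *denser* than the 1% tail of null correlations, so on noise the
scan settles a few hundredths below the 99th percentile of null $|r|$ —
the spacing statistics there are genuinely Poisson, and no goodness-of-fit
choice we examined (chi-squared or Kolmogorov-Smirnov) distinguishes them.
On block-structured (modular) matrices the scan brackets the planted
structure as intended.

### Topology, modules, roles

Topology metrics: node and link counts, average connectivity $2L/N$,
average path distance over the largest connected component (networks may
be disconnected), mean local clustering with nodes of degree < 2
contributing 0, modularity $Q$ of the detected partition, the scale-free
index (OLS $R^2$ of $\log_{10} P(k)$ on $\log_{10} k$ over unbinned
nonzero degree frequencies, `NA` below 3 distinct degrees), and the
percentage of negative edges.

Modules come from fast-greedy modularity maximisation on the unsigned
weighted graph; $Q$ is evaluated with the definitional formula
$\sum_m (e_m/E - (d_m/2E)^2)$ (weighted). On very small graphs the greedy
cut can land below the trivial single-module partition, in which case the
trivial partition is returned — this also guarantees
$Q \ge Q_\text{trivial}$.

Zi (within-module degree z-score) and Pi (participation coefficient,
$1 - \sum_s (k_{is}/k_i)^2$) use unweighted degrees. If every node of a
module has the same within-module degree, Zi is defined as 0 for those
nodes — none is unusually connected, and the z-score denominator would
otherwise blow up. Roles follow the conventional thresholds, both
configurable: module hub Zi > 2.5, connector Pi > 0.62, network hub both,
peripheral neither; keystones are all non-peripherals, and keystone
overlap between two networks is the Jaccard percentage of the keystone
sets.

## Robustness

Each trial removes nodes, then prunes secondarily extinct nodes (those
left without any edge; pruning is iterated although a single pass is
already a fixed point), and reports the fraction of the original nodes
remaining. Random mode removes $\lceil fN \rceil$ nodes uniformly.
Targeted mode reads "remove 50% of the keystone nodes" literally by
default: $\lceil fK \rceil$ keystones, highest degree first, degree ties
broken once by a seeded shuffle so the targeted set — and hence every
trial — is identical (sd 0). Because removing half the keystones deletes
far fewer nodes than removing half the network, targeted and random modes
are only comparable at an equal budget; `basis = "all_nodes"` removes
$\lceil fN \rceil$ nodes keystones-first for that purpose, and the
package's targeted-vs-random contrasts use it. Robustness distributions
are compared with a two-sided Wilcoxon rank-sum test on per-trial values
(identical constant vectors return p = 1 by convention).

## Pipeline and reproducibility

`run_pipeline` chains the stages under one master seed, writes every
stage artifact (input TSVs when simulated, distance matrix, PCoA
coordinates, GraphML + edge lists + role tables per network, a JSON and a
text report), and embeds the package version, seed and an MD5 hash of the
analysis configuration (excluding the output directory) in the report and
in the `#`-comment header of every pipeline TSV. Re-running the same
configuration and seed reproduces `report.json` byte for byte. Targeted
robustness is reported per network only when the network has at least one
keystone; dense planted modules often have none, which is itself a
finding the report keeps visible.

## Problem sizes used by the test suite

The shipped tests validate against scaled-down generations chosen as the
smallest sizes at which each property is comfortably identifiable: 27-
sample single-group tables with 40–80 OTUs at depths 2,000–6,000 for
generator and TDR properties, the full 108-sample default design (300
OTUs, depth 28,500) for the end-to-end and reproducibility checks, and
1000-replicate null simulations at n = 10–12 samples for calibration of
the permutation tests. The acceptance script re-runs the full default
design from scratch.

## Known limitations

* Spearman co-occurrence on compositional counts is not corrected for
  spurious negative coupling (SparCC/SPIEC-EASI-style corrections are out
  of scope); the softmax generator shares this compositional geometry, so
  planted-structure recovery is tested under, not despite, it.
* One-factor PERMANOVA only; the interaction structure of the original
  field design calls for mixed models that are outside this package.
* The RMT scan's behaviour on noise-dominated matrices is bounded by the
  percolation argument above; it is a threshold *selector*, not a test of
  whether structure exists.
* Weighted UniFrac, functional annotation and abundance-weighted
  extinction cascades are not implemented.
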