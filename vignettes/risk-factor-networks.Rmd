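---
title: "Risk-factor networks: model, estimation and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-factor networks: model, estimation and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(risknet)
```

## The model

`risknet` analyses cohorts of already-scored questionnaire variables —
demographics, symptom scales (PHQ-9, SDQ, BIS-11, CTQ-SF), binary
diagnostic indicators, and suicide-attempt characteristics — as a weighted
undirected network. Nodes are variables; the edge between two variables
carries their Spearman rank correlation $r_s$, estimated as the Pearson
correlation of average-ranked values. Binary, ordinal and count variables
enter as numeric ranks, producing a single mixed correlation matrix; this
is a marginal-association network, not a partial-correlation (conditional
independence) model, and no regularised estimation is attempted.

Two networks are inspected side by side: the complete graph over all
pairwise correlations, and a filtered graph keeping only edges with
$|r_s| \ge 0.2$, the conventional boundary below which a rank correlation
is considered weak. The retention rule is inclusive, so an edge at exactly
0.2 stays.

## Centrality

Three node-importance measures are computed, each on the absolute edge
weights:

* **Strength** — $s(v) = \sum_{u} |w_{uv}|$ over incident edges.
* **Closeness** — geodesic distances are computed with edge length
  $1/|w|$, so strongly correlated variables are close; closeness is the
  inverse of the summed distances to all other nodes.
* **Betweenness** — for every pair of other nodes, $v$ accumulates the
  fraction of geodesics through it (fractional counting when geodesics
  tie; with continuous weights ties essentially never occur).

Distances come from a per-source Dijkstra sweep and betweenness from the
standard dependency-accumulation recursion over the resulting shortest-path
DAG, with a $10^{-12}$ tolerance for declaring two path lengths equal.
Zero-weight edges carry no path (their length would be infinite) but still
count as edges of the complete graph.

Conventions that matter on thresholded networks:

* Filtering at 0.2 can disconnect the graph. Closeness is then computed
  within each node's connected component; isolated nodes score 0. The
  alternative — treating any unreachable node as making closeness zero —
  zeroes the entire panel as soon as a single variable is isolated, which
  discards all ordering information. The component-restricted rule has its
  own artefact (a two-node component with one strong edge gets a very
  small distance sum, hence inflated closeness); this is visible in the
  packaged matrix, where a two-variable component outranks the giant
  component's hub at the 0.2 cutoff. Ranks on disconnected networks should
  therefore be read per component.
* Closeness and betweenness are reported raw, not normalised by network
  size: every reported quantity downstream (descending competition ranks
  and percentile ranks) is invariant to common rescaling.
* Percentile ranks use $\lfloor 100 \cdot \#\{u : x_u < x_v\} / N \rfloor$,
  so the maximum of 34 distinct values sits at the 97th percentile and the
  minimum at the 0th.

## The packaged correlation matrix

The package ships a transcription of the published 34-variable Spearman
matrix (`table3_fixture()`), printed to three decimals, together with the
variable roster and instrument groups (`fixture_variables()`). A
transcription audit is part of the test suite: symmetry of every pair, a
frozen file checksum, and spot values. One printed cell pair disagrees in
sign between its two occurrences; the fixture fixes it to the negative
value, which is irrelevant for all absolute-value-based computations (see
`inst/extdata/table3_notes.md`).

A caveat that the package makes explicit rather than hiding: at three
printed decimals, the full-network closeness values of the nodes ranked
2nd–9th differ by less than $5\times10^{-4}$ — below the perturbation that
rounding each coefficient by up to $5\times10^{-4}$ can induce on distance
sums. Orderings and percentiles computed from the printed matrix are
therefore faithful to the printed matrix but can disagree by a few rank
positions with analyses of the underlying raw data. Strength, which sums
a whole row, is far more robust to this; all strength-based rankings
reproduce exactly.

## Bootstrap stability

Edge-weight precision is assessed by a non-parametric bootstrap: rows are
resampled with replacement $B = 1000$ times (default), the full Spearman
matrix recomputed each time, and every edge summarised by its bootstrap
mean and a nearest-rank percentile interval at 95% coverage. Imputation
(below) happens once, before resampling, matching the original single-shot
treatment of the data.

Centrality stability uses the case-dropping bootstrap: with the
full-sample centrality vector as reference, subsamples without replacement
of size $\mathrm{round}((1-p)\,n)$ are drawn at each drop proportion
$p \in \{0.1,\dots,0.9\}$ ($m = 100$ per level by default), centrality is
recomputed on each subsample's network, and the Pearson correlation with
the reference vector recorded. The CS-coefficient at $r_{\min} = 0.5$ and
95% confidence is the largest $p$ such that every level up to $p$ has at
least 95% of its correlations at or above 0.5. Requiring *every* smaller
level to pass keeps the coefficient monotone when sampling noise makes a
single level dip. Nodes isolated in a subsample network contribute
centrality 0, keeping vectors aligned; a replicate whose centrality vector
is constant yields an undefined correlation and counts as failing.

Columns that become constant in a resample (easily triggered by
low-prevalence binaries such as a 1-in-267 indicator) degrade to $r = 0$
with a warning instead of aborting the resampling run.

## Missing data

Missingness is profiled per variable; imputation is single-shot and
unconditional: observed-value mean for numeric variables, observed mode
for binary and ordinal variables (ties broken by the smallest value, so
the result is deterministic), and the mean rounded half-up for count
variables, which are numeric-like but integer-valued (configurable to
mode). No multiple imputation or MAR/MNAR modelling is attempted — the
average missingness this pipeline targets is ~1.3%, where the choice of
single-shot scheme is immaterial.

## Layout

The Fruchterman–Reingold implementation follows the classical scheme:
optimal spacing $k = \sqrt{\text{area}/N}$, repulsion $k^2/d$ between all
pairs, attraction $(d^2/k)\,|w|$ along edges — attraction scaled by the
absolute weight so strongly correlated nodes land together regardless of
sign (signs affect edge colour only) — and displacements capped by a
temperature cooled linearly from $0.1\sqrt{\text{area}}$ over 500
iterations (default). Initial positions are uniform in the unit square
from a user seed, making layouts exactly reproducible. Area defaults to
$N$. The circular layout places nodes clockwise from the top of the unit
circle in input order.

## The synthetic cohort generator

Because no participant-level data are distributable, the generator
produces cohorts whose *rank dependence* targets a given Spearman matrix
via a Gaussian copula: the target is mapped elementwise to the latent
Pearson scale by $\rho = 2\sin(\pi r_s/6)$ (exact for continuous
marginals), repaired to the nearest positive-semidefinite correlation
matrix by Higham's alternating projections (`Matrix::nearPD`; the rounded
transcription is indefinite, so repair is genuinely needed), factorised
once by Cholesky, and pushed through each variable's quantile function:

* numeric — truncated normal with stated mean, SD and bounds;
* binary — indicator of the upper prevalence tail;
* ordinal — thresholds at cumulative category probabilities;
* count — negative binomial moment-matched to the stated mean and SD,
  shifted to the stated minimum (Poisson when the variance does not
  exceed the mean).

MCAR missingness is injected cell-wise at a configurable rate.
`survive_like_spec()` bundles the study calibration: $n = 267$; the
packaged matrix as target; age 15.0 ± 1.52 truncated to 12–17; 87.4%
female; PHQ-9 17.97 ± 5.58 on 0–27; attempt count mean 2.54, SD 2.39,
minimum 1 (negative binomial, size ≈ 0.57 after moment matching);
diagnosis, substance-use and migrant prevalences as printed; lethality
category probabilities renormalised from printed percentages summing to
100.1%; ideation-intensity probabilities renormalised over the 255
respondents with available data; missingness 1.27%. The BIS-11, CTQ-SF
and SDQ scores have no printed moments, so the generator uses typical
clinical-adolescent values (e.g. CTQ subscales on 5–25 with means 8–12,
SDQ total 19.5 ± 6 on 0–40, BIS-11 total 72 ± 11 on 30–120); these affect
only the marginal scale of those columns, not the rank structure that the
network stages consume.

Known limitation, deliberate: discretising a latent normal (binary and
ordinal margins) attenuates the realised Spearman correlation toward zero
relative to the target. The generator does not iterate a correction — the
pipeline needs realistic, not exact, discrete dependence — and the test
suite asserts attenuation as an inequality rather than equality. For
continuous pairs the copula map is exact and recovery within
$3/\sqrt{n}$ is asserted directly.

## Numerical and design choices

* Inclusive threshold ($|r| \ge t$ retained).
* Average ranks for ties — the standard Spearman convention.
* Zero-variance columns degrade to $r = 0$ with a warning, never an error.
* Nearest-rank (type 1) empirical quantiles for bootstrap intervals:
  distribution-free and reproducible.
* Geodesic tie tolerance $10^{-12}$ on path lengths.
* PSD repair tolerance $10^{-8}$, with a diagonal jitter only if the
  smallest eigenvalue is still below $10^{-10}$, so Cholesky never fails.
* All stochastic stages take explicit integer seeds and are bit-exactly
  reproducible; seeds never leak into the caller's RNG state.

## Problem sizes

The shipped tests exercise exhaustive path-enumeration oracles on 50+
random graphs of up to 6 nodes, copula recovery at $n = 5000$,
bootstrap-interval coverage with 200 replicate cohorts of $n = 500$ at
$B = 500$, and reduced bootstrap budgets ($B \le 50$, $m \le 25$)
elsewhere; the analysis scripts run the full study-scale budgets
($B = 1000$, $m = 100$). These sizes are the package's chosen balance of
statistical resolution against desk-scale runtime.

## What passing tests do and do not show

The synthetic cohort emulates marginals and rank dependence, with MCAR
missingness only. It does not emulate item-level response processes,
informative missingness, clustered recruitment, or measurement error, so
agreement of pipeline output on synthetic data demonstrates correctness
of the computations, not clinical validity of the network on new
populations. Reproduction of the published centrality results is exact
for strength-based rankings and subject to the printed-precision caveat
above for closeness/betweenness orderings on the thresholded network.
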