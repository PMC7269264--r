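---
title: "Estimating partial-correlation networks from mixed questionnaire data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating partial-correlation networks from mixed questionnaire data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panet)
```

## The model

`panet` estimates Gaussian graphical models (GGMs) from questionnaire data
with mixed variable types. A GGM represents a set of variables as nodes and
their *conditional* associations as edges: the edge weight between nodes
$i$ and $j$ is the partial correlation

$$ w_{ij} = -\frac{\kappa_{ij}}{\sqrt{\kappa_{ii}\,\kappa_{jj}}}, $$

where $\kappa$ are entries of the precision (inverse covariance) matrix
$K$. A zero entry in $K$ means conditional independence given all other
nodes, so the sparsity pattern of $K$ *is* the network.

Questionnaire items are ordinal, which breaks the Gaussian assumption at
the margins. Two correlation front-ends deal with this:

* **Nonparanormal SKEPTIC** (default). Kendall's tie-corrected $\tau_b$ is
  computed for every pair and mapped to the latent Gaussian correlation by
  $\hat\rho = \sin(\pi \tau_b / 2)$. This is consistent whenever the data
  are a monotone transform of a latent Gaussian, and it needs no
  per-variable type declarations.
* **Automatic mixed correlations** (`correlation = "auto_mixed"`). Pearson
  for continuous pairs, polychoric for ordinal/binary pairs (two-step:
  thresholds from the margins via $\Phi^{-1}$, then the latent correlation
  by maximizing the bivariate-normal contingency likelihood), polyserial
  for mixed pairs.

Both front-ends can yield an indefinite matrix when assembled pairwise, so
the result passes through an eigenvalue-clipping repair (`nearest_pd()`)
that guarantees a minimum eigenvalue of at least $10^{-8}$ while keeping a
unit diagonal. Which front-end fed the published analyses this package
generalizes is ambiguous in the literature that motivated it; both are
first-class here, and SKEPTIC is the default because it makes the weakest
distributional assumptions.

## Regularization and model selection

With dozens of nodes and a few hundred participants, the saturated GGM is
noise. The graphical lasso maximizes the $\ell_1$-penalized likelihood

$$ \log\det K - \mathrm{tr}(RK) - \lambda \sum_{i \ne j} |\kappa_{ij}|, $$

with the diagonal unpenalized. The solver is a Friedman-style blockwise
coordinate descent written in C++; every fit is checked against the KKT
conditions (residual $\le 10^{-4}$) so a silent non-convergence cannot
propagate. Fits run along a descending path of 100 penalties, log-spaced
from $\lambda_{\max}$ (the largest absolute off-diagonal correlation, at
which the network is empty) down to $0.01\,\lambda_{\max}$, with warm
starts.

The penalty is selected by the Extended Bayesian Information Criterion,

$$ \mathrm{EBIC}_\gamma = -n\left[\log\det K - \mathrm{tr}(RK)\right]
   + E \log n + 4 E \gamma \log p, $$

with $E$ the number of selected edges and $\gamma = 0.5$ by default — the
conservative convention in psychometric network analysis. $\gamma = 0$
recovers the BIC; raising $\gamma$ never adds edges on a fixed path (a
property the tests assert). Edges are defined by the support of $K$ after
optimization; no extra threshold is applied. The plotting cutoffs
(`display_min = 0.04`, `display_max = 0.76`) affect visualization and
export metadata only, never estimation or metrics.

## Centrality, clustering and their conventions

Networks estimated from psychological scales contain negative edges.
All distance-based and clustering computations here use absolute weights —
the conventional treatment when strength, closeness, betweenness and
weighted clustering are reported for signed networks — with edge length
$1/|w_{ij}|$ for shortest paths, so stronger edges are shorter. Specific
conventions, each of which matters in corner cases:

* closeness sums distances over *reachable* nodes only; a fully isolated
  node gets 0;
* betweenness gives fractional credit to tied shortest paths (Brandes);
  ties have probability zero for continuous weights but arise in fixtures;
* local clustering (Watts–Strogatz, Barrat, Zhang, Onnela) returns 0 for
  nodes with fewer than two neighbours; with 0/1 weights all four variants
  coincide, which the tests use as a reduction check;
* global clustering uses the minimum method: each triplet contributes the
  smaller of its two spoke weights, and the coefficient is the closed-to-
  total ratio of that mass;
* z-standardisation of centralities is per network, across nodes, with the
  sample standard deviation; a constant index returns zeros and a
  degeneracy flag rather than `NaN`.

Every metric is validated against brute-force oracles (exhaustive
simple-path enumeration, triple loops over the formulas) on random graphs
of up to 8 nodes.

## Stability, accuracy and group comparison

*Case-dropping bootstrap.* For drop proportions
$\{0.05, 0.15, \dots, 0.75\}$ the pipeline is re-estimated on subsamples
and each centrality vector is correlated with its full-sample counterpart.
The CS-coefficient is the largest proportion such that, at it and at every
smaller grid value, the empirical 5% quantile of those correlations stays
at or above 0.7. The prefix rule is deliberate: a grid point that fails
ends the scan even if a later one passes, so CS is conservative and
grid-valued (no interpolation). Below 0.25 an index should not be
interpreted; above 0.5 is good.

*Edge accuracy.* A nonparametric bootstrap (rows resampled with
replacement, full pipeline re-run) yields 2.5/97.5 percentile intervals
per edge. Because the lasso shrinks, these intervals are biased toward
zero for strong edges; they order edges usefully but should not be read
as exact frequentist coverage.

*Network comparison test.* Two groups — in the canonical analysis, a
median split of the item total score, ties going to the low group — are
compared by re-estimating both networks under label permutations that
preserve group sizes. Test statistics are $M$, the maximum absolute edge
difference (structure invariance), and $S$, the absolute global-strength
difference; p-values use the add-one convention $p = (1 + \#\{\text{perm}
\ge \text{obs}\})/(1 + P)$, so they are bounded below by $1/(P+1)$.
Optional per-edge tests cover edges present in either observed network and
are Holm-adjusted.

## The synthetic-data generator

No public dataset accompanies the design this package emulates, so
validation rests on a generator with known truth. Ground truth is declared
in partial-correlation space: requested partials go into a unit-diagonal
precision matrix as $-\pi_{ij}$, which reproduces them exactly and leaves
every unrequested pair at exactly zero — making recovery tests direct. If
the requested values are jointly incompatible with positive definiteness
the constructor refuses and asks for weaker values; it never repairs the
matrix silently, because any repair would distort the requested truth.

The default design emulates a 14-item oral-health-literacy questionnaire:
7 two-item domains with within-domain partials spanning 0.54–0.89, a
handful of weaker cross-domain links including two negative ones, 5-level
items cut at thresholds $(-1.2, -0.4, 0.4, 1.2)$ — chosen so no category
falls under 5%, which keeps polychoric estimation stable — and 1.1%
item-level MCAR missingness. `study_spec()` adds 10 covariates (4
continuous totals, 4 five-level ordinal, 2 binary) and a two-group
contrast for comparison testing. One seed governs the latent draws and
then the MCAR mask, in that order, so tables are bit-reproducible.

What the generator does *not* emulate: missing-not-at-random mechanisms,
non-Gaussian copulas, nominal covariates (users must encode those as
binary/ordinal themselves), and realistic total-score reliability — the
default truth has sparse between-domain structure, so Cronbach's alpha on
synthetic items (≈0.46 at defaults) is well below what a real scale of
this kind shows (≈0.8). Passing tests therefore demonstrate that the
estimators recover known conditional-dependence structure under realistic
marginals and sample sizes, not that any substantive conclusion about real
populations follows.

## Missing data

The default imputer is an iterative random-forest scheme in the missForest
mould: initialize by column mode/median, revisit columns in order of
increasing missingness, regress or classify each on all others with a
forest (100 trees, single-threaded, seeded), and stop when the change
criterion — scaled squared change for continuous columns plus disagreement
fraction for ordinal ones — rises, returning the previous iteration. On
MCAR synthetic data its ordinal error is at or below mode imputation's
(tested over 10 seeds). kNN and mode/median fallbacks exist for speed and
for degenerate cases; imputation never touches observed cells and always
returns valid codes. Single imputation is intentional — the downstream
pipeline re-estimates everything under resampling anyway, which is where
its uncertainty honesty comes from.

## Numerical choices and problem sizes

Tolerances: glasso KKT residual $\le 10^{-4}$; path convergence $10^{-7}$;
numerical zero for edges $10^{-10}$; PD floor $10^{-8}$; polychoric and
polyserial optimized on $(-0.999, 0.999)$ to keep likelihoods finite, with
zero-count cells contributing nothing. Degenerate inputs fail loudly:
constant columns, fully missing columns, all-identical split scores and
asymmetric weight matrices are errors, not warnings.

The validation suite runs at deliberately moderate sizes — e.g. 50
generator seeds at $n = 400$ for recovery, 100 null repetitions with
$P = 200$ permutations on 6-node designs for test calibration, bootstrap
$B = 25$–50 — which keeps the full suite in a few minutes while leaving
every check comfortably away from its acceptance margin. Re-running with
larger $n$, $B$ or $P$ only sharpens the same conclusions.

## Known limitations

* The EBIC-glasso is biased toward zero; bootstrap CIs inherit that bias.
* The NCT permutation scheme assumes exchangeability of participants under
  the null; covariate-stratified permutation is not implemented.
* Binary variables are treated as 2-level ordinal throughout; nominal
  variables with more than two categories are out of scope.
* CS-coefficients are grid-valued; with the default grid the smallest
  nonzero value is 0.05 and the largest 0.75.
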