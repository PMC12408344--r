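---
title: "Methods: fermentation kinetics, flavour linkage and minimal community design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fermentation kinetics, flavour linkage and minimal community design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermentome)
```

# Overview

Spontaneous cocoa-bean fermentation is a short, hot, microbially driven
process: yeasts liquefy the sugary pulp and produce ethanol, lactic acid
bacteria take over mid-fermentation, and acetic acid bacteria oxidize
ethanol exothermically, driving bean temperature from ambient towards
45--50 °C while acids move into the cotyledon. The flavour of the
resulting chocolate is widely believed to be set during this week.
`fermentome` implements a computational chain that (i) condenses
fermentation temperature/pH curves and microbial abundance trajectories
into interpretable kinetic features, (ii) ranks those features by their
association with sensory panel scores using random forests, and (iii)
reduces a fermentation microbiome, represented as per-organism metabolic
networks, to a minimal defined community with equivalent metabolic
capabilities — the computational step behind designing defined starter
cultures.

Because farm measurements and genome collections are not shippable inside
a package, every pipeline input can be simulated with known ground truth
(`sim_config()` and the `simulate_*()` generators), and every stage of the
chain is tested against that ground truth or against independent oracles.

# The five-parameter kinetic model

Temperature and pH series are modelled with the generalized
(Richards-type) logistic

$$y(t) = y_0 + \frac{y_f - y_0}{\left(1 + e^{-k (t - t_i)}\right)^{1/\nu}},$$

with lower/upper asymptotes $y_0, y_f$ (native units), rate $k$ (h$^{-1}$),
inflection-locating time $t_i$ (h) and asymmetry $\nu > 0$. We use this
form as our convention for a "five-parameter general model": it is
sigmoidal, admits asymmetric approach to the asymptotes, and collapses to
the symmetric logistic at $\nu = 1$. Falling curves (cotyledon pH) are
handled by reflecting the series about its maximum
(`invert_series()`, $y \mapsto \max(y) - y$, an involution via the
recorded offset) rather than by a reciprocal, so the same sigmoid family
applies; the reflection preserves times and shape.

Closed forms used throughout: the inflection lies at
$t^\* = t_i - \ln(\nu)/k$, where the curve value is
$y_0 + (y_f - y_0)(1+\nu)^{-1/\nu}$ and the rate peaks at
$|y_f - y_0|\, k \,(1+\nu)^{-(1+\nu)/\nu}$ (i.e. $k\,\Delta/4$ at
$\nu = 1$). The "kinetic energy" of a curve is defined as proportional to
the squared rate of change, so its maximum coincides with the maximum
rate; `time_to_max_ke` is nevertheless computed by numeric grid
maximization of the analytic derivative (2001-point scan, polished with
`optimize()` to square-root machine tolerance) so the implementation does
not assume the coincidence.

## Fitting

`fit_five_param()` performs bounded Levenberg--Marquardt least squares
(`minpack.lm::nlsLM`, $k > 0$, $\nu \in [10^{-3}, 10^{3}]$) from a
deterministic multi-start grid: asymptotes from the data extremes oriented
by the empirical trend, $t_i$ at the steepest observed slope, $k$ from
that slope via the symmetric-logistic relation, $\nu \in \{0.3, 1, 3\}$,
plus seeded jittered restarts (7 starts total by default). The
best-residual solution wins; failure to converge is recorded
(`converged = FALSE`) rather than raised, so batch fitting over a farm's
worth of series degrades gracefully. Fitting requires at least 15 points
(the design minimum for these fermentation series) and a data span above
0.5 native units; flatter series are declared non-kinetic and rejected.

A known limitation, documented deliberately: around $\nu = 1$ the
asymmetry parameter is near-unidentifiable at realistic noise levels. With
20 points and noise at 2 % of span, the least-squares optimum is found
reliably (refitting from the truth reproduces it, and the fitted residual
never exceeds the truth's), but the sampling spread of $\hat\nu$ is large
— its median relative error is roughly a quarter, while $y_0, y_f, k, t_i$
are recovered within a few percent. Downstream features are only mildly
affected because they depend on the curve shape, which is well determined,
rather than on $\nu$ in isolation.

## The thirteen abiotic features

From a converged fit, `extract_abiotic_features()` derives: maximum growth
rate; time to maximum kinetic energy and the curve value there; the
exponential, linear and decay phase durations; the value change (delta)
per phase; the rates of change in the exponential and linear phases; and
the inflection time and value. Phase boundaries use the classical
inflection-tangent construction: the tangent at the inflection is
intersected with the two asymptotes; the exponential phase runs from the
curve start to the lower intersection, the linear phase between the
intersections, and the decay phase from the upper intersection until the
curve reaches $y_0 + 0.95\,(y_f - y_0)$ (the 0.95 cutoff is the
`decay_frac` argument). Boundaries are clamped to be contiguous and
non-decreasing from the curve start, so durations are non-negative and sum
exactly to (decay end − curve start); rates equal delta/duration whenever
the duration is positive.

Bean colour is summarised by the two standard RGB reductions, greyscale
$(R+G+B)/3$ and luminance $0.299R + 0.587G + 0.114B$
(`colour_metrics()`).

# Growth features of abundance trajectories

Marker taxa are chosen by `select_markers()` with inclusive per-kingdom
PERMANOVA-coefficient thresholds (bacteria ≥ 10, fungi ≥ 5 by default).
For each marker trajectory `growth_features()` computes seven summaries:
first local maximum, initial density (earliest local minimum), trapezoidal
area under the curve, maximum density, time to maximum density, midpoint
(first time the piecewise-linear interpolant reaches half the observed
maximum — half of the *observed* maximum, not of a fitted carrying
capacity), and inflection point (time of the largest forward-difference
slope). Conventions, all configurable or stated: an optional centered
moving average (default window 3 points, shrunk at the edges; window 1
reproduces raw data exactly) precedes everything; endpoint extrema count
via one-sided comparison, because trajectories truncated at fermentation
start or end routinely peak at a boundary; and all argmax/argmin ties
resolve to the earliest time, matching the "time to" semantics. A
constant trajectory therefore has its midpoint at the first time point.

# Linking features to flavour

Feature matrices (instances × features) are min-max normalized per column
(`rescale01()`; constant columns map to 0, and the map is idempotent).
Redundancy is removed by `cluster_features()`: pairwise Pearson
correlations with two-sided p-values from the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, then Ward
(`ward.D2`) clustering on Euclidean distances between feature-wise
correlation vectors. Where no cluster count is supplied, the tree is cut
at the $k \in [2, p-1]$ maximizing the mean silhouette width — a
reproducible stand-in for visual dendrogram inspection. Each cluster is
represented by its member with the highest coefficient of variation
(sd/mean), computed on the **raw** pre-normalization values, since min-max
scaling distorts sd/mean arbitrarily; ties break to the lexicographically
first name and zero-mean features (undefined CV) are deprioritized.

Per sensory attribute (0--10 panel scores), `rf_importance()` fits a
regression random forest (500 trees by default, bootstrap resampling,
`mtry = max(p/3, 1)`) and computes permutation importance as the literal
percentage increase in mean squared error:

$$\%\mathrm{IncMSE}_j = 100 \cdot
  \frac{\overline{\mathrm{MSE}^{\mathrm{perm}_j}_t - \mathrm{MSE}_t}}
       {\mathrm{MSE}_{\mathrm{OOB}}},$$

averaging over trees $t$ with non-empty out-of-bag sets, where feature $j$
is permuted within each tree's out-of-bag rows and the denominator is the
forest's baseline out-of-bag MSE. This normalization follows the name
literally; it differs from the sd-scaled z-score that `randomForest`'s
`importance()` reports under the same label, which is why the statistic is
computed here from recorded per-tree permutations (replayable exactly — a
test re-derives every reported value from the recorded permutations and
in-bag matrix). A constant response yields all-zero importances with a
warning. All randomness is governed by one seed fanned out through named
sub-streams, so a fixed seed gives a byte-identical importance map.

# Metabolic networks, scopes and minimal communities

Per-organism networks are qualitative reaction sets (substrates →
products, optionally reversible). The *scope* of a seed set is computed by
network expansion to fixpoint: a reaction fires once all its substrates
are reachable, adding its products; reversible reactions may fire in both
directions independently. There is no stoichiometry, no flux balance and
no special-casing of currency metabolites (no built-in H₂O/ATP filtering;
a user can simply omit such species or restrict the target set). The
result is order-independent, idempotent and monotone in both seeds and
reactions — each property is asserted over hundreds of random instances
against a separately implemented naive re-scan oracle.

Community scopes use the union of all members' reactions, i.e. free
exchange of every metabolite. The *added value of cooperation* is the
community scope minus the union of individual scopes: the metabolites no
member reaches alone. The default seed set, `cocoa_pulp_seeds()`, names
the components of (artificial) cocoa pulp: sucrose, glucose, fructose,
citric acid, pectin, high- and low-viscosity carboxymethyl cellulose,
yeast extract and peptone (complex nitrogen proxies), calcium lactate,
Tween 80, and magnesium/manganese sulfate.

`minimal_communities()` finds the minimum cardinality $m$ such that some
$m$-subset of organisms covers a metabolite target set, and enumerates
*all* covering $m$-subsets (minimality of each solution is automatic at
the minimum cardinality, and verified in tests by single-member deletion).
"Equivalent metabolic capabilities" is under-specified in general, so two
target modes are provided: the default `"full"` targets everything the
full community can produce beyond the seeds (the union of individual
production plus the added value), while `"added_value"` targets the
cooperative gain only. Enumeration is exhaustive up to 20 organisms;
larger pools use a seeded greedy search (best-gain insertion, reverse
deletion pruning, 100 restarts) and the result is flagged non-exhaustive.
Key species are the union over minimal communities, essential species the
intersection, alternative species the difference. `coverage_stats()`
reports Venn-style overlaps between metabolite sets, as counts and as
percentages of both the union and the reference set, since both
conventions appear in community-reduction summaries.

# The synthetic study

The generators emulate the *shape* of a multi-farm fermentation study,
not its chemistry:

* `simulate_kinetics()` — per replicate, four series (temperature at two
  box depths, pH of testa/pulp and cotyledon) drawn from the
  five-parameter model plus iid Gaussian noise on the measurement scale.
  Defaults: 15 time points over 168 h; temperature 25 → 46--48 °C with
  mid-box slightly hotter and earlier; testa/pulp pH 3.5 → 4.6; cotyledon
  pH 6.5 → 4.8; noise sd 0.5 °C and 0.05 pH units (measurement-error
  magnitudes are free parameters chosen as plausible instrument/replicate
  scatter; no published values exist for them); between-replicate
  parameter jitter of 2 %. Additive Gaussian noise is the simplest model
  consistent with replicate scatter bands around such curves.
* `simulate_taxa()` — latent taxon densities with shapes rise, fall,
  rise--fall (product of an increasing and a decreasing logistic, giving
  the single interior peak that "first local maximum" semantics need) or
  flat, plus truncated noise, closed to relative abundances summing to 1.
  The default six-taxon succession (early *Hanseniaspora* and
  *Saccharomyces*, mid *Lactiplantibacillus*, late *Acetobacter* and
  *Bacillus*, flat unclassified remainder) mimics the canonical
  yeast → LAB → AAB succession. A synthetic coefficient table marks
  non-flat taxa above, and flat taxa below, the kingdom thresholds.
* `simulate_sensory()` — 0--10 scores as clipped linear combinations of
  normalized features plus noise; the non-zero coefficients are the
  planted informative features.
* `simulate_networks()` — a pool of random decoy networks plus a planted
  cross-feeding chain split across exactly the planted organisms, whose
  last link produces the planted target metabolites; decoy reactions never
  produce chain or target metabolites, making the planted set the unique
  minimum community for those targets. The instance is verified by
  `minimal_communities()` before it is returned.

What the generators do **not** emulate — and hence what passing tests do
not show about real data: compositional noise from sequencing depth,
taxon misclassification, non-sigmoidal (multi-peak) temperature curves
from bean turning, panelist effects and score discretization, genome-scale
network reconstruction error, and any real biochemistry in the random
decoy reactions. Recovery rates on synthetic data are upper bounds on what
field data would give.

# Determinism and numerical choices

Every source of randomness flows from a single integer seed through named
sub-streams (a small string-hash derivation, kept below $2^{31}$), so
generators, forests and the full pipeline are reproducible to the byte;
run manifests record md5 hashes of every output file and the
configuration. Other numerical choices: derivative maximization uses a
2001-point grid plus `optimize()` polish over a window guaranteed to
contain the analytic inflection; trapezoidal integration for AUC;
phase-boundary clamping via a running maximum; p-values floor $1 - r^2$
at machine epsilon so perfect correlations give 0 rather than NaN;
instances with missing features are dropped by default (median imputation
would be the alternative); and zero-variance features are excluded from
clustering with a warning.

The test suite exercises the documented study conditions at sizes chosen
to keep a full run in tens of seconds: 100-curve recovery experiments,
1,000-trajectory oracle comparisons, 500-network scope checks, 50-seed
forest recovery with 100 trees, and 10-replicate end-to-end runs. The same
experiments, re-derived from scratch, constitute `scripts/acceptance.R`.
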