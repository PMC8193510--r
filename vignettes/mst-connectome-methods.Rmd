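---
title: "MST connectome analysis: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MST connectome analysis: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstnet)
```

## Why minimum spanning trees

Comparing weighted brain graphs across subjects usually requires choosing an
edge-density threshold, and most group differences are not robust to that
choice. The MST removes the dial: with unique weights it is the unique
acyclic subgraph connecting all `n` nodes through the strongest
connections, so every subject contributes exactly `n - 1` edges. The cost
is that density-dependent quantities (clustering, modularity, rich-club
coefficients) are meaningless on a tree; the analysis instead characterizes
where a tree sits between two extremes — a path (maximal segregation) and a
star (maximal integration).

## The pipeline model, stage by stage

**Connectivity.** Edges are Fisher-z transformed Pearson correlations of
ROI time series. The z transform stabilizes variance so that matrices can
be averaged across subjects for group-representative trees. Exact |r| = 1
off-diagonals (duplicated series) are clamped to 1 − 1e−7 with a warning
rather than propagating infinities.

**Distances.** Since the MST algorithm minimizes, weights are inverted,
`d = 1/w`, after removing non-positive edges. Zero weights are treated like
negative ones (1/0 is undefined, and a zero correlation carries no
connection evidence). If the positive graph is disconnected the default is
a hard error: 164-ROI correlation networks are essentially always
positively connected, so disconnection signals a data problem and should be
loud. An opt-in `repair` flag reconnects components through the
largest-|z| removed edges at tiny weight, for exploratory use.

**MST.** Kruskal's algorithm with union–find. Ties in `d` are broken by
edge index after a stable sort, making degenerate inputs deterministic; a
warning notes that uniqueness is then not guaranteed. Tests verify
optimality against exhaustive enumeration of all labeled spanning trees
(via Prüfer sequences) and agreement with an independent Prim
implementation and with igraph.

**Global metrics.** Path length uses hop counts, not summed `1/w`
distances: hop-`L` is scale-free across subjects and is what makes the
star/path closed forms (`2(n−1)/n` and `(n+1)/3`) exact. Tree hierarchy is
`Th = L_leaf / (2 m BC_max)` with betweenness normalized by the
`(n−1)(n−2)/2` node pairs. No closed formula for `Th` is universally
printed in the MST literature's summary tables; this normalization is the
one under which a star scores exactly 0.5 at every `n ≥ 3` — the anchor the
configuration-space interpretation relies on — while a path tends to 0 as
`2/(n−1)`. A convention in which a line scores 1 instead is sometimes
described; no standard formula satisfies both anchors simultaneously, and
we follow the star anchor. Degree divergence is `κ = Σk²/Σk`, the standard
second-over-first moment ratio; assortativity is Newman's degree
correlation over both orientations of each edge and is reported as `NA`
(and excluded from group tests) when endpoint degrees have zero variance.

**Nodal roles.** Local importance `li(v) = |A|/|Adj(v)| + 1/n` counts the
neighbors with degree *not exceeding* `v`'s (the inclusive comparison
matters: equal-degree neighbors count). Its bounds `1/n` and `1 + 1/n` are
attained by a leaf under a hub and by a star center. The connector index
`ci = BC/li` then separates two kinds of high-traffic nodes: hubs (high
`BC`, high `li`, moderate `ci`) and low-degree bridges between hubs (high
`BC`, minimal `li`, maximal `ci`). Betweenness is pair-normalized so `ci`
is comparable across network sizes; only relative comparisons are used
downstream, which are invariant to this choice. Hub and connector calls use
mean + 2 SD thresholds with the *population* SD — the threshold is over a
fixed finite node set, and at `n = 164` the sample/population difference is
negligible. Nodes passing both thresholds are reported as
`hub+connector` rather than silently assigned one role.

**Similarity.** Tree overlap `σ = |E_a ∩ E_b|/(n−1)` is a bounded
similarity kernel. The two-group test statistic is the unweighted mean of
the two within-group mean overlaps (with a size-weighted option; the two
coincide for equal groups). The null permutes group labels with sizes
fixed, and the one-sided p-value divides the count of permutations with
statistic *not less than* observed by exactly the number of permutations —
the observed arrangement is deliberately not added to the null here, to
match the historical convention for this test; the covariate-adjusted tests
below use the smoothed `(1+k)/(1+B)` estimate instead, and the discrepancy
is intentional and documented.

**Degree fits.** Three families are fitted to the group-representative
tree's degree histogram: `P(k) ∝ k^(−α)`, `∝ e^(−αk)`, and the
exponentially truncated power law `∝ k^(α−1) e^(−k/k_c)`. The truncated
form is implemented with a *decaying* exponential: the positive-exponent
variant sometimes printed is non-normalizable, and reported parameter
values in this literature (α around 1.3–2.4, k_c around 1.3–2.3) only make
sense for a decaying tail. On the default log scale all three families are
linear in their parameters, so the fit is exact least squares on
`log P(k)` with a free proportionality constant, and R² is computed on
that scale; a linear-scale `nls` mode is available because third-party
toolboxes differ in convention. `k_c` is unconstrained: on small noisy
histograms the best in-sample fit can have a negative `k_c` (a growing
exponent), which is reported as found rather than clipped. Model selection
takes the highest R² with a parsimony tie-break, because the truncated
family nests both one-parameter families and would otherwise tie them
exactly on exactly-generated data. MST degrees are small integers, so no
binning or CCDF transform is applied by default.

**Group inference.** The covariate-adjusted permutation test uses the
Freedman–Lane scheme: regress the metric on covariates alone, permute the
reduced-model residuals, add them back to the reduced fit, and recompute
the covariate-adjusted group mean difference. This is the standard choice
for permutation inference with nuisance covariates; the mechanism behind
published "covariate-controlled" permutation tests is often unstated, so
this is a package design choice, with a raw-label permutation fallback.
Two-sided p-values use `(1 + #{|null| ≥ |obs|})/(1 + B)`. Comparisons are
made with a relative tolerance of 1e−8 so exact ties (discrete metrics,
mirrored permutations) are counted despite floating-point noise. BH-FDR is
applied once per family — the six global metrics, or all regions × 2 nodal
metrics. Cohort matching solves, within each gender stratum, the optimal
assignment minimizing total |age difference| (Hungarian algorithm via
`clue::solve_LSAP`).

**Mediation and moderation.** The published analysis this design follows
used Bayesian SEM in commercial software with latent outcome variables and
a posterior-predictive fit index. We deliberately do not reproduce that
machinery: paths are estimated by OLS product-of-coefficients on
standardized variables — `a` from `mediator ~ x + covariates`, `b` and `c′`
from `y ~ mediator + x + covariates` — with percentile bootstrap CIs over
resampled subjects, which matches the inferential behavior asymptotically
and is fully open. Significance is "CI excludes 0", the criterion
appropriate for the asymmetric intervals the product statistic produces; a
significant indirect effect can coexist with a null total effect (the
total effect is not a gatekeeper), which the test suite demonstrates on a
suppression scenario. Latent outcomes are replaced by composite scores
(standardized means of assigned tests) or ML factor scores with promax
rotation; a first-principal-component option stands in for a latent
"network structure" variable over the six global metrics. In the
no-covariate case `c = c′ + a·b` holds to machine precision and is
asserted as such. Medication enters only the patient-only model (model 3):
controls have structurally zero dose, which would make the covariate
group-confounded in mixed models.

## The synthetic cohort: what it emulates and what it does not

The generator exists so that every downstream stage has a ground truth.
Its defaults are fixed once, as the study conditions they emulate: two
groups of 40, 164 nodes, 150 timepoints, ages uniform in 21–55, 29:11
male:female per group, lognormal head motion with a ×1.43 patient offset,
and a patient shift of +0.15 toward star-like topology.

**Trees** grow by sequential attachment: each new node attaches to the
current maximum-degree node with probability `star_bias` and to the most
recently added node otherwise. This realizes both limits exactly — a pure
path at 0, a pure star at 1 — with expected leaf fraction monotone in
between, which is the property the tests rely on. (A uniform-attachment
mixture was considered and rejected: uniform attachment yields a random
recursive tree with leaf fraction near 0.5 at the path end, not a path.)

**Connectivity** embeds the planted tree in a correlation matrix: unit
diagonal, `edge_strength = 0.6` on tree edges, `baseline = 0.1` elsewhere,
shrunk toward the identity in 10% off-diagonal steps until positive
definite. Shrinkage preserves the edge ordering, so the noise-free matrix's
MST is exactly the planted tree, and long sampled series recover it (the
suite checks overlap ≥ 0.9 at 5,000 timepoints). Time series are zero-mean
multivariate Gaussian with no temporal autocorrelation, because the
pipeline consumes only zero-lag correlations.

**Phenotypes** carry the planted chain: per-subject
`star_bias = base + offset·patient + a·z(age) + ε`, clipped to [0, 1] with
clipping recorded so linearity checks can exclude clipped subjects, and
`negative symptom = b·z(Lf) + c′·z(age) + ε`. Age is standardized against
the uniform population moments of the age range so the planted paths do
not depend on the realized sample. Default paths (`a = 0.03` in star-bias
units against total topology noise of comparable size, `b = 0.4`,
`c′ = 0.15`, symptom noise 0.9) put the standardized a path near 0.3–0.4
and the standardized b path near 0.4 — mid-sized effects of the order
reported for age–integration–symptom chains. Cognitive tests load 0.75 on
latent working-memory and executive-function factors with mild age decline
and a 1 SD patient deficit.

What the generator does *not* emulate: hemodynamics, temporal
autocorrelation, head-motion artifacts (motion is generated as a covariate
but does not corrupt the signal), atlas geometry, negative-correlation
structure, or between-site variance. Passing tests therefore show that the
statistical machinery is correct and calibrated under a faithful generative
model of the *topology and path structure* — not that the pipeline is
robust to fMRI artifacts.

## Numerical choices and degenerate inputs

- Exact |r| = 1 off-diagonals: clamped with a warning. Zero-variance
  series: an error naming the nodes.
- Tied MST distances: deterministic index order plus a warning.
- Assortativity with degenerate degree variance, constant metric columns,
  EFA non-convergence, collinear covariates, infeasible matching strata:
  explicit `NA`-with-exclusion or named errors, never silent.
- Permutation tie comparisons use a 1e−8 relative tolerance; overlap ties
  a 1e−12 absolute one (overlaps are exact rationals).
- All pipeline randomness derives from one root seed with fixed per-stage
  offsets, and reruns are bit-identical; derived seeds stay far below
  2³¹.

## Problem sizes used in the test suite

The suite scales simulations to what the checks need rather than to the
full study size: calibration uses 400 replicate null datasets at 500
permutations (rather than 5,000–10,000), mediation coverage uses 200
replicates of n = 2000 with 500 bootstrap resamples, power checks use 50
replicates at the reference 40 + 40 sample size, and the end-to-end run
uses 20 + 20 subjects on 40-node networks at 400 timepoints with a strong
planted effect. These sizes were chosen so that Monte-Carlo error is small
relative to each acceptance band.

## Known limitations

- `Th`'s value for intermediate topologies depends on the betweenness
  normalization; only the star anchor and ordering are interpretable.
- R² values from log-scale least squares are not comparable to R² from
  other toolboxes' conventions (probability vs count, linear vs log), so
  published degree-fit R² values cannot be compared digit for digit.
- Bootstrap mediation is not Bayesian SEM: no posterior-predictive fit
  index is produced, and latent-variable measurement error is not
  propagated.
- The similarity test assumes exchangeability of subjects under the null;
  it does not model within-group heterogeneity of sub-cohorts.
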