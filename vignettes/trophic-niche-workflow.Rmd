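---
title: "Models and methods behind trophicniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trophicniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophicniche)
```

# Overview

`trophicniche` implements a complete trophic-niche workflow for
communities of coexisting consumers sampled in two currencies: fecal
contents (items counted and measured volumetrically per sample) and
whole-blood stable isotopes (δ¹³C, δ¹⁵N).  This vignette documents the
models, the defaults and why they were chosen, the numerical decisions,
and — just as important — what the synthetic validation suite does and
does not demonstrate about real field data.

All randomness flows from one run seed.  Each stage (simulation,
bootstrap, MCMC, null models) derives its own child stream with
`child_seed()`, so re-ordering stages never changes any stage's result,
and two runs with the same configuration are bit-identical.

# Diet composition from fecal samples

For each species and food item we report frequency of occurrence (FO,
FO%), numeric contributions (N, N%), volumetric contributions (V, V%),
and the *prey-specific* contributions PN% and PV%: the mean of the
item's per-sample proportion taken **only over samples that contain the
item**.  These feed the prey-specific index of relative importance,

$$\mathrm{PSIRI\%} = \frac{(\mathrm{PN\%} + \mathrm{PV\%})\,
\mathrm{FO\%}}{2}\Big/100 .$$

Prey-specific averaging (per-sample proportions, not pooled ratios) is
what makes the index internally consistent: because
$\mathrm{FO\%}\times\mathrm{PN\%}/100$ is the mean per-sample numeric
proportion over *all* samples, PSIRI% sums to exactly 100 over a
species' items.  The test suite asserts this identity, together with
$\mathrm{PSIRI\%} \le \max(\mathrm{PN\%}, \mathrm{PV\%})$, on every
synthetic diet.  Note that the pooled N% column (total counts of the
item over total counts) is *not* generally equal to
$\mathrm{FO\%}\times\mathrm{PN\%}/100$; both are reported because both
are standard.

Degenerate inputs are handled explicitly: a record with zero count and
zero volume is rejected at input; a sample whose total volume (or
count) is zero has undefined per-sample proportions and is excluded
from the PV% (PN%) averages with a warning.  Volumes are taken as given
reals in mm³ — the upstream volumetric bench method is outside the
package's scope.

Trophic guilds are classified from pooled volume shares: the
predominant diet type is the guild exceeding 35% of the species' total
volume; any other guild between 10% and 35% is a secondary type (e.g.
`FR_IN`, frugivorous secondarily insectivorous).  The thresholds are
arguments, defaulting to the values conventional in Neotropical bird
diet studies.  If no guild clears the threshold the classification is
"indeterminate" — logged, not fatal.

# Dietary niche breadth and overlap

Levins' breadth $B = 1/\sum_i p_i^2$ and its standardization
$\hat B_A = (B-1)/(n-1)$, and Pianka's overlap
$O_{kj} = \sum_i p_{ij}p_{ik}\big/\sqrt{\sum_i p_{ij}^2\sum_i
p_{ik}^2}$, operate on diet-proportion vectors aligned on the union of
items (absent items are structural zeros; appending shared zeros is a
tested invariance).

**Which proportions?**  Composition can be quantified numerically (N%),
volumetrically (V%) or by PSIRI%.  Published community studies often do
not state the basis.  The package therefore makes it a switch
(`diet_proportions(basis = ...)`) with PSIRI% as default — it is the
headline composition index, it sums to 100 by construction, and it
balances count-inflated small items against volume-inflated large ones.
The other bases exist precisely for sensitivity analysis.

# The Bayesian stable-isotope mixing model

Per consumer species, blood values are modelled as (elements
$j \in \{\delta^{13}\mathrm{C}, \delta^{15}\mathrm{N}\}$, sources
$k = 1,\dots,K$):

$$x_{ij} \sim \mathcal N\!\Big(\sum_k p_k(\mu_{jk} + \lambda_{jk}),\;
\sum_k p_k^2(\omega_{jk}^2 + \tau_{jk}^2) + \sigma_j^2\Big),$$

with source means/SDs $(\mu, \omega)$, trophic discrimination factors
(TDFs) $(\lambda, \tau)$ — defaults 2.2 ± 0.1‰ for δ¹³C and
2.6 ± 0.2‰ for δ¹⁵N, blood values for an omnivorous passerine — a flat
Dirichlet prior on the contribution vector $p$, and a weakly
informative half-normal(0, 5‰) prior on each residual scale
$\sigma_j$.  Source grouping into ecologically coherent categories is
an input decision, not something the model infers; `pool_sources()`
merely aggregates labelled specimens.

**Sampling.**  The posterior is explored by random-walk Metropolis on
additive-log-ratio coordinates of $p$ (with the log-simplex Jacobian)
and on $\log\sigma_j$.  Step sizes adapt during burn-in, and from a
quarter of burn-in onward the proportion block proposes from a
covariance estimated on the chain's own burn-in history (adaptive
Metropolis, scaled by $2.38/\sqrt{d}$).  Adaptation stops at the end of
burn-in, so retained draws come from a fixed kernel.  Defaults are 4
chains × 20 000 iterations, 50% burn-in, thinning 10; convergence is
summarized by across-chain $\hat R$ per source (a warning and a
`converged = FALSE` flag above 1.1 — results are returned regardless)
and a crude autocorrelation-based effective sample size.

With 7 sources and 2 elements the system is under-determined; the
posterior is proper but wide, and the package says so once per fit.
Equal-tailed credible intervals, their midpoints (the isotope-network
weights) and posterior means come from `credible_intervals()`; interval
midpoints are marginal summaries and need not sum to 1 across sources,
even though every retained draw lies exactly on the simplex.

**A non-obvious property of the TDF sensitivity run.**  Because the
mixture variance weights source and TDF spread by $p_k^2$, inflating
the TDF SDs (the standard sensitivity variant, e.g. to 0.9/1.0‰) does
*not* uniformly widen the marginal intervals: a concentrated diet
implies a large likelihood variance, so wider source spread actively
favours even mixtures and can tighten several marginals while shifting
mass toward the simplex centre.  What the sensitivity run does
guarantee — and what the test suite asserts — is stability: wide-TDF
posterior means fall inside the narrow-TDF credible intervals, and the
diet-concentration statistic $\sum_k p_k^2$ does not increase.

# Isotopic niche: SEAc and ellipse overlap

The standard ellipse of a species' (δ¹³C, δ¹⁵N) cloud is the 1-SD
contour of the fitted bivariate normal; its area is
$\mathrm{SEA} = \pi\sqrt{\det\hat\Sigma}$ and the small-sample
correction multiplies by $(n-1)/(n-2)$, applied geometrically as a
uniform radial scaling of the boundary.  Fewer than 3 points, or a
(nearly) collinear cloud — determinant below $10^{-12}$ times the
squared mean variance — is a degeneracy error, not a silent answer.

Overlap between two SEAc ellipses is computed by discretizing each
boundary into a convex polygon (720 vertices by default; inscribed
polygon area converges quadratically, so the error is $\sim 10^{-5}$
relative) and clipping one against the other (Sutherland–Hodgman).  The
test suite pins the routine against the closed-form circular-lens area
to 0.5%.  The overlap percentage divides by the **union** of the two
areas by default — the symmetric, Jaccard-style choice; dividing by the
smaller ellipse is available via `denominator = "smaller"` because the
literature uses both and rarely says which.

Unequal field samples are bootstrap-standardized to a common size
(default n = 50, resampling with replacement, deterministic per seed)
before ellipses, mixing models or networks, mirroring standard practice
when one species is badly under-sampled.  Whether to fit on raw or
bootstrapped values is the caller's choice; both paths are plain
function composition.

# Weighted bipartite networks

Two consumers × resources matrices put excreted and assimilated diets
in the same currency:

* the **diet matrix**: summed PSIRI% of each species' items per
  resource category (rows sum to 100);
* the **isotope matrix**: the 95% credible-interval midpoint
  $(\ell + u)/2$ per species × source — the default because it is what
  a reader can rebuild from a printed CI table; the posterior mean is a
  switch (`statistic = "mean"`).

**WNODF.**  Weighted nestedness based on overlap and decreasing fill:
rows and columns are sorted by decreasing fill (number of non-zero
cells), ties broken by decreasing marginal totals; an ordered pair
scores 0 unless fill strictly decreases, otherwise the percentage of
the poorer line's non-zero cells that are *strictly* smaller than their
counterparts; WNODF is the mean over all row and column pairs.  Strict
inequalities and the fill-first sort follow the metric's canonical
implementation; equal marginal totals are handled by the fill rule
alone and the metric is tested to be invariant to input permutations
(sorting is internal).  The implementation is verified cell-for-cell
against an independent naive oracle on all random matrices up to 5 × 8
and against `vegan::nestednodf(weighted = TRUE)` to 12 decimal places.

**d′.**  For consumer $i$ with use proportions $p'_j = a_{ij}/A_i$ and
availabilities $q_j = A_j/m$, the Kullback–Leibler distance
$d_i = \sum_j p'_j\ln(p'_j/q_j)$ is standardized to
$d' = (d - d_{\min})/(d_{\max} - d_{\min})$.  The upper bound is the
exclusive-specialist bound $d_{\max} = \ln(m/A_i)$: cell-wise
$p'_j/q_j \le m/A_i$, so it dominates every matrix with the same
marginals and guarantees $d' \in [0,1]$.  For continuous weights
proportional use is feasible, so $d_{\min} = 0$; for integer count
matrices the integer-constrained minimum is found by placing units on
the smallest marginal cost (exact for this separable convex objective,
and cross-checked by brute-force enumeration in the tests).  When
$d_{\max} = d_{\min}$ — a single effective resource, or marginals that
force every allocation — $d'$ is defined as 0 with a warning.

**vaznull.**  The null model randomizes interactions while conserving
matrix dimensions, connectance (number of filled cells), total
interaction events and no-empty-row/column coverage, with cell
probabilities proportional to the product of the original marginal
totals.  It is defined on countable interaction events, so continuous
weights are first quantized to `round(weight × scale)` events
(default `scale = 100`, i.e. PSIRI percentage points and CI midpoints
are resolved to 0.01); the quantization is explicit, testable, and
conservation laws are asserted exactly on every generated null.
Nestedness is significant when observed WNODF exceeds the upper bound
of the null 2.5–97.5% band (default 1000 randomizations).

# The synthetic-data generator

`scenario_config()` encodes the study conditions the package is
validated under, mirroring the scale of the motivating field study:

* 3 consumer species over 7 resource groups (5 arthropod guilds, C3
  fruits, C4/CAM fruits); true diet proportions default to a
  fruit-dominated pair plus a predator-leaning specialist, i.e. the
  estimated assimilated diets of the thrush community;
* source δ-positions chosen so every pair is ≥ 2‰ apart on at least
  one element (C4/CAM fruits isolated high in δ¹³C, C3 fruits low on
  both axes, predators high in δ¹⁵N); coincident sources are allowed
  but flagged non-identifiable;
* TDFs 2.2 ± 0.1 / 2.6 ± 0.2‰, residual σ = 0.5‰ per element;
* blood samples (20, 15, 8) per species — bootstrap-standardized to 50
  — and fecal samples (26, 20, 4), with 1 + Poisson(3.3) items per
  sample (≈ 4.3 items per sample, ~217 items across 50 samples);
* volumes are count × per-category unit volume (fruits bulkier than
  arthropod fragments) × log-normal noise (sdlog 0.3);
* an optional per-category *detectability* multiplier down-weights
  soft items in feces but not in blood, reproducing the classic
  discordance between excreted and assimilated diets.

Blood values are drawn from **exactly the likelihood the mixing model
assumes**.  That is deliberate — it makes parameter-recovery coverage a
clean test of the sampler and interval construction — and it is also
the key caveat: passing recovery tests shows the inference machinery is
correct *under the model*, not that real blood values follow it.  The
generator likewise collapses taxonomic granularity (taxa = categories),
has no seasonality, no individual specialization, and no
concentration-dependent routing.  Conclusions about field data inherit
all the usual caveats of the SIAR model class.

# Problem sizes and test design

The validation suite runs, among others: parameter recovery over 20
seeded scenarios (3 species × 7 sources, 50 consumers each; ≥ 90% of
the 420 true source contributions must fall inside their 95% credible
intervals), a monotonicity check that posterior-mean error shrinks as
source SDs shrink, exact WNODF/d′ oracle equivalences, and null-model
comparisons at 100 randomizations.  Test fits use 2–3 chains of
6 000–12 000 iterations — shorter than the 4 × 20 000 default, chosen
so the whole suite completes in a few minutes while leaving the checked
properties unchanged; occasional marginal $\hat R$ flags over these 60
automated short fits are expected and the coverage assertion is the
operative quality gate there.

# Known limitations

* Only two isotope elements are wired into the data model, though the
  likelihood code is written for J elements.
* No concentration-dependence or elemental routing in the mixing
  model; no individual-level random effects (species-level pooling
  matches the CI tables the networks consume).
* The Bayesian ellipse posterior (credible intervals on SEA) is out of
  scope; SEAc is reported as a point estimate.
* d′ bounds follow the exclusive-specialist convention; other
  published variants constrain $d_{\max}$ by partner capacities and
  give systematically different (larger) d′ for consumers that cannot
  monopolize a partner.
* The vaznull quantization step means extremely small continuous
  weights (< half a quantum) vanish from the null structure; the
  package errors rather than silently dropping a row or column.
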