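# trophicniche

Quantifying the trophic niches of sympatric consumers from fecal
contents, blood stable isotopes, and weighted bipartite networks.

## The problem

When several closely related, morphologically similar species coexist
(the motivating system is three sympatric *Turdus* thrushes in a
subtropical forest mosaic in southern Brazil), how much of their trophic
niche do they actually share, and which resources drive partitioning?
Two complementary data streams answer this at different time scales:

* **Fecal contents** record what was eaten in the last hour or so, item
  by item, but over-represent hard, poorly digestible remains.
* **Whole-blood stable isotopes** (δ¹³C, δ¹⁵N) integrate what was
  *assimilated* over weeks, but only resolve resources to isotopically
  distinct groups.

`trophicniche` implements the full analysis chain for both streams and
joins them in a common consumer–resource network currency, so that
excreted and assimilated diets can be compared directly.

## Methods at the core

* **Diet composition** (`tabulate_diet()`): per food item, FO, FO%, N,
  N%, V, V% and the prey-specific contributions PN% and PV% (mean
  per-sample proportion over the samples containing the item), combined
  into the prey-specific index of relative importance
  `PSIRI% = (PN% + PV%) × FO% / 2 / 100`, which sums to 100 per species.
  Trophic-guild classification (`classify_guild()`) by volume
  thresholds (predominant > 35%, secondary 10–35%).
* **Dietary niche** (`levins_breadth()`, `pianka_overlap()`): Levins'
  `B = 1/Σpᵢ²` with standardized `B̂_A = (B−1)/(n−1)`, and Pianka's
  symmetric overlap `O_kj = Σpᵢⱼpᵢₖ / √(Σpᵢⱼ² Σpᵢₖ²)`.
* **Bayesian mixing model** (`fit_mixing_model()`): consumer values are
  normal mixtures of TDF-corrected sources,
  `x_ij ~ N(Σₖ pₖ(μ_jk+λ_jk), Σₖ pₖ²(ω_jk²+τ_jk²) + σ_j²)`, flat
  Dirichlet prior on `p`, half-normal(0, 5‰) prior on σ, sampled by
  adaptive random-walk Metropolis on additive-log-ratio coordinates;
  `credible_intervals()` summarizes per-source contributions.
* **Isotopic niche** (`standard_ellipse()`, `ellipse_overlap()`): the
  standard ellipse area `SEA = π√det(Σ̂)` with small-sample correction
  `SEAc = SEA·(n−1)/(n−2)`, pairwise ellipse overlap by convex polygon
  clipping, and bootstrap standardization of unequal samples to a common
  n (`bootstrap_standardize()`).
* **Bipartite networks** (`build_diet_matrix()`,
  `build_isotope_matrix()`): weighted consumers × resources matrices
  from summed PSIRI% and from 95% credible-interval midpoints; weighted
  nestedness **WNODF** (`wnodf()`), standardized Kullback–Leibler
  specialization **d′** (`dprime()`), and significance against
  **vaznull**-style null models that conserve marginal structure,
  connectance and total interaction events (`vaznull()`,
  `nestedness_test()`).
* **Synthetic studies** (`scenario_config()`, `simulate_study()`):
  generate sources, blood values and fecal samples from known true diet
  proportions, so every stage of the pipeline can be validated
  end-to-end without field data.

## Worked example

```r
library(trophicniche)

## a complete synthetic study with known ground truth
study <- simulate_study(scenario_config(rng_seed = 1))
diet  <- tabulate_diet(study$feces)
P     <- diet_proportions(diet, basis = "psiri", level = "category")
breadth_table(P)
#>     species    b  b_std n_items
#> 1  thrush_A 3.01 0.3354       7
#> 2  thrush_B 3.57 0.4281       7
#> 3  thrush_C 1.51 0.0852       7
round(pianka_matrix(P), 2)
#>          thrush_A thrush_B thrush_C
#> thrush_A     1.00     0.98     0.60
#> thrush_B     0.98     1.00     0.49
#> thrush_C     0.60     0.49     1.00
```

The two fruit-dominated species (A, B) overlap almost completely
(O = 0.98) while the arthropod-specialist C overlaps far less and has
the narrowest standardized breadth (B̂_A = 0.09) — the qualitative
pattern the generator encodes.

The isotope-side network uses the credible intervals of a published
field study of the three thrushes (shipped with the package):

```r
m <- build_isotope_matrix(thrush_isotope_ci())
wnodf(m)
#> [1] 31.94444
dprime(m)
#>           consumer     d d_min d_max d_prime
#> 1 T_amaurochalinus 0.025     0   1.1   0.023
#> 2     T_albicollis 0.116     0   1.1   0.107
#> 3    T_rufiventris 0.154     0   1.1   0.137
nestedness_test(m, n_rand = 100, seed = 5)
#> WNODF = 31.9 | null 95% CI [16.3, 31.6] (100 randomizations) | significantly nested
```

WNODF ≈ 31.9 with d′ near 0 for every consumer: the assimilated-diet
network is weakly but significantly nested and all three thrushes are
trophic generalists, the least so the predator-leaning
*T. rufiventris*.

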