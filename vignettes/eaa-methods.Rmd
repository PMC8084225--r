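---
title: "The Equal-Area Annulus method: models, null designs and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Equal-Area Annulus method: models, null designs and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the neighborhood statistic, the Monte Carlo null models, the smoothing
layer, the synthetic-plot generator, and the numerical and design choices
made where the method leaves room. The companion README shows a worked
example; the test suite and `scripts/acceptance.R` compute every empirical
claim referenced here.

## The statistic

For every *focal* tree the neighborhood is divided into `n_annuli`
concentric rings of exactly equal area (`total_area` 500 m² by default;
ring boundaries `r_k = sqrt(k·A/(nπ))`), so each physical-distance band
contains, in expectation, the same amount of data and therefore carries the
same statistical power. Within an annulus, focal–annular pairs are further
classified by the phylogenetic distance between their species — millions of
years back to the last common ancestor — cut into equal-count quantiles
over the species-pair list, with conspecific (0 Ma) pairs anchored in the
first bin. Focal trees are classified into within-species size quartiles
(quintiles for the growth analysis), and summed annular basal areas into
quintiles.

Six tests compare an observed per-cell statistic (cell = annulus ×
phylogenetic bin × focal group) against a null distribution generated by
shuffling exactly one focal attribute **within species**, leaving all
positions, species identities and neighborhood structure untouched:
annular survivor basal area, recruit fraction and mortality fraction
against focal-size shuffles (Tests 1–3); normalized focal growth against
within-species growth shuffles (Test 4); and annular recruit/death
fractions around focal recruits/deaths against within-species fate
shuffles (Tests 5–6). Each cell's significance is a z-score against the
null mean and SD; two-sided normal p-values are Benjamini–Hochberg
adjusted within a (test × census interval) family.

Because the shuffle conserves the within-species composition of every
quartile, any positive deviation in one focal-size quartile is balanced by
negative deviations in others for Tests 1–3; the growth statistic (a
difference against a comparison group of focal trees with no qualifying
neighbors in the cell) carries no such constraint. The within-species
design is also what makes the method robust to storage-effect clustering:
conspecific clusters are identical in the real and shuffled data, so
clustering alone cannot produce significance (verified on clustered
no-effect plots in the test suite).

## Tunable parameters

* `total_area` (m², default 500) and `n_annuli` (default 10, sensible range
  5–20): more annuli resolve the distance axis more finely but thin each
  ring; match to stem density.
* `n_phylo_bins` (default 8, range 5–20): equal-count bins over species
  pairs. Because many pairs share a distance, every analysis is repeated
  over `replicates` (default 10) tie-shuffles of the quantile assignment,
  each with `iterations` (default 100) null draws; per-replicate z uses its
  own 100-draw null, while the headline table pools all 1,000 draws per
  cell label.
* `n_size_bins` (4) and `n_biomass_bins` (5): focal-size and
  annular-biomass classes.
* `edge_mode`: `"weight"` (default) multiplies neighbor counts and basal
  areas by the reciprocal of the ring fraction inside the plot; `"drop"`
  discards focal trees whose outermost ring fraction falls below
  `drop_threshold`.
* `alpha` (0.05): BH level.
* `seed` and `tie_seed`: the permutation stream and the tie-shuffle stream.
  Identical seeds reproduce results bit for bit; changing only `tie_seed`
  moves cell z-scores within Monte Carlo error (checked in the acceptance
  suite as a 95th-percentile scaled difference below 3).

## Null-model details and two deliberate deviations from naive shuffling

**Tests 5–6 move the fate with the tree.** A tree's fate (recruit,
survivor, died) appears twice in these statistics: as the focal group label
and as the annular numerator flag of its neighbors. Shuffling only the
focal labels while freezing the annular flags ignores the reciprocity of
neighbor pairs and is measurably anticonservative on provably null plots
(|z| > 1.96 in 10–17 % of cells). The implementation therefore permutes the
fate as a property of the tree — it moves with the tree in both roles, and
the small/large split of the dead is recomputed for each shuffled dead set.
Under within-species exchangeability this null is exact, and the
calibration checks confirm it. `null_shuffle(..., what = "fate")` applies
the same semantics at the plot level.

**Test 4 is mildly conservative by construction.** Growth rates are
standardized to mean 0, SD 1 within species × census × start-size decile
strata. Standardization imposes an exact zero-sum constraint per stratum,
so the smallest-quintile focal trees (which concentrate in the lowest
strata) carry slight negative dependence that the within-species shuffle
(which mixes all strata) does not reproduce; the null SD is a few percent
wide and the |z| > 1.96 rate sits near 3–4 % instead of 5 %. This is the
price of the size/species/trend-free growth scale and errs in the safe
direction; the calibration check holds Test 4 to the upper band only.

Two further approximations worth knowing about. First, per-replicate
z-scores are computed against a 100-draw Monte Carlo null, so they are
t-distributed rather than normal; the nominal |z| > 1.96 exceedance under
the null is 5.4 %, and the far tail of the normal p-values is optimistic —
family-wise procedures should therefore be read off the pooled
(1,000-draw) table, which is what `pooled_results()` returns and what the
BH/FDR acceptance check uses. Second, cells whose null SD is zero (constant
statistic) get `NA` z-scores and are excluded from the BH family rather
than silently dropped.

## Geometry and edge correction

The circle–rectangle intersection area is computed by piecewise adaptive
quadrature of the chord length with analytic breakpoints at the tangency
abscissae (relative error far below the 1e-3 at which it is verified
against a rejection-sampling Monte Carlo oracle); ring fractions follow by
differencing. Distances are Euclidean, annulus bins are half-open
`[r_{k-1}, r_k)` with distance 0 in annulus 1, and the plot is the
half-open rectangle `[0, W) × [0, H)` so containment is unambiguous.
Inverse-area weighting was chosen as the default edge correction because it
keeps every focal tree and is unbiased under homogeneity (checked by the
zero-slope property of weighted annular densities on Poisson plots).

## Binning choices and degenerate inputs

Equal-count bins assign by sorted position, so occupancies differ by at
most one; ties are broken by input order where determinism matters
(focal-size quartiles) and by the replicate RNG where the tie ambiguity is
part of the method (phylogenetic quantiles, biomass quintiles). Species
with fewer trees than bins fall back to rank assignment with ties sharing
the lower bin. Conspecific pairs are always anchored in phylogenetic bin 1;
when a plot has more conspecific pairs than one bin's nominal occupancy the
equal-count property is deliberately relaxed for that bin. Growth strata
nominally use ten start-size deciles per species but collapse to
`floor(n/10)` classes so each keeps about ten trees; strata of size one or
zero spread standardize to 0. Odd counts in the small/large split of the
dead put the median tree in "small". Empty comparison groups (Test 4) and
empty denominators flag the cell `NA`.

For phylogenies, `"strict_ultrametric"` mode (MRCA depth) requires leaf
depths equal to a relative 1e-6 and coincides with `"half_patristic"` mode
on ultrametric trees; only the latter is defined after distance
manipulation, which deliberately breaks ultrametricity. Species placed only
to genus can be assigned within-genus distances drawn uniformly from the
present back to the genus crown, reproducibly under a seed.

## Smoothing

Curves are penalized cubic regression splines (`y ~ s(x, k)`, REML by
default, GCV and an unpenalized fallback for degenerate responses);
surfaces are tensor-product smooths over (annulus area-weighted mean
radius × phylogenetic distance). The basis dimension is chosen as the
smallest candidate passing two diagnostics — effective degrees of freedom
below `0.9(k−1)` and no residual-vs-predictor pattern at p > 0.05 — run
under a fixed local seed so the choice is deterministic; this
operationalizes an otherwise interactive check. Significance masks color
grid points whose fitted value leaves the null band [−1.96, 1.96]. Peaks
and valleys are reported only when the 95 % band at the extremum excludes
the neighboring shoulder values. One caution: quantile bins are evenly
populated but not evenly spaced in Ma — under a Yule tree most pairs
diverge near the crown — and a spline over Ma can oscillate in the
unsupported gap; feature-location checks in the acceptance suite therefore
fit over the quantile index, where support is even.

## What the simulator emulates — and what it does not

`simulate_fdp()` generates a rectangular plot with log-series-like
abundances, Thomas-cluster conspecific spatial structure (optionally shared
parents for declared co-occurring species groups), an ultrametric Yule
phylogeny scaled to a chosen crown age, and per-interval demography:
baseline mortality ~12 % per 5-year interval, spatially explicit
recruitment (propagules dispersed around conspecific adults, establishing
with a baseline probability, entering the census at 1 cm dbh), and growth
increments of 0.6 ± 0.4 cm per interval. Defaults give ~0.2 stems/m²,
inside the range spanned by real mapped plots. Planted effects modulate
the log-odds of the targeted rate (or the growth mean, in SD units) by
`strength ×` a standardized neighbor pressure: summed neighbor basal area ×
an exponential spatial kernel × a phylogenetic weight (`exp(−Ma/λ)`, an
explicit pair matrix, or donor-specific allelopathy with an immune set).
Pressure is standardized by its mean positive value per interval so
`strength` has a portable meaning; probabilities are clamped to
`[1e-6, 1−1e-6]` with a count of clamps. A `strength` of zero is exactly
null.

Passing tests on these plots shows the statistics recover what was planted
under known, favorable conditions; it does not show the generator captures
real forests. In particular: demography is memoryless between intervals
(no individual growth autocorrelation, no light competition), dispersal
and kernels are isotropic and stationary, there is no habitat
heterogeneity, disturbance, or measurement error, and multi-stem dynamics
are not simulated (multi-stem records are supported at the data layer).
Two subtleties discovered while calibrating are worth flagging because
they are ecologically real: establishment filtering writes interaction
history into the size–location association of *surviving* small trees, so
"no effect" at the attribute level requires neighborhood-independent
recruitment (the `dispersal = "uniform"`, unclustered null configuration);
and mechanistic effects on recruitment/mortality perturb the denominators
of other tests, so direction-recovery conditions plant growth-mediated NDD
for the clustering signature rather than thinning alone.

## Protocols

`manipulate_distances()` rewrites selected species-pair distances (both
triangle mirrors) without touching anything else; re-running the analysis
then moves those pairs' contributions into the quantile containing the new
distance — the sensitivity protocol. `subset_run()` filters the focal and
annular sides independently (a species dropped as focal still appears as a
neighbor unless also dropped as annular) and recomputes all quantile
schemes on the subset; quantile *boundaries* over species pairs are kept
from the full distance matrix so bins remain comparable across subset runs
(a frozen-versus-recomputed choice the method leaves open; passing
`pair_bins` to `build_neighborhood()` gives full control). Ready-made
study conditions for the null-calibration, direction-recovery, decay,
valley and allelopathy scenarios ship as `demo_*_config()` constructors;
their problem sizes (150 × 150 m, ~4,500 stems, 2–3 censuses, 10 × 100
null draws) were chosen once as the smallest plots on which the planted
signals are comfortably detectable.

## Known limitations

* Tests 5–6 examine small subsets of trees (recruits and deaths) and are
  correspondingly noisy; the package reports their "other" groups so the
  balance can be inspected.
* Per-replicate normal p-values are approximate in the far tail (see
  above); use the pooled table for familywise claims.
* The BH adjustment assumes independent-ish cells; quartile balance makes
  cells within a cell-quartet negatively dependent, which is conservative
  for FDR in the pooled checks performed here but is not a formal
  guarantee.
* No toroidal wrapping or irregular plot boundaries; no seedling censuses
  (recruitment is proxied by stems reaching 1 cm dbh, as in the census
  protocol); no regression-based effect-size estimates by design.
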