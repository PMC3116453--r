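---
title: "Population-weighted distance to parks: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-weighted distance to parks: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkaccess)
```

## The measure

`parkaccess` quantifies the potential spatial accessibility of parks for
residential populations. Three families of measures dominate this
literature: travel-cost measures (distance to the nearest park), container
measures (park count or area within a unit or buffer), and
spatial-interaction (gravity) indices. Each has a known pathology: the
nearest-park distance assumes residents use exactly one park; containers are
hostage to the unit definition (the modifiable areal unit problem) and to
edge effects; raw gravity scores have no intuitive unit.

The population-weighted distance (PWD) combines the three. For a census
block $i$ and park $j$ with park area $S_j$ (mi²) and centroid-to-centroid
distance $d_{ij}$ (miles):

$$A_{ij} = \frac{S_j^{\alpha}}{d_{ij}^{\beta}}, \qquad
  A_i = \sum_{j \in N_k(i)} A_{ij}, \qquad
  P_{ij} = \frac{A_{ij}}{A_i}, \qquad
  B_i = \sum_{j \in N_k(i)} P_{ij}\, d_{ij},$$

where $N_k(i)$ is the choice set of the $k$ nearest parks. $B_i$ is an
expected travel distance in miles: a convex combination of the choice-set
distances weighted by Huff visit probabilities, so it is always at least the
nearest-park distance and never exceeds the farthest choice-set distance.
Aggregation to any unit $u$ of a nesting geographic hierarchy is the
population-weighted mean

$$T_u = \frac{\sum_{i \in u} \mathrm{Pop}_i\, B_i}{\sum_{i \in u}
  \mathrm{Pop}_i},$$

which makes roll-ups exactly consistent across levels (the weighted mean of
state values, weighted by state populations, equals the national value
computed directly from blocks) and lets subgroup populations re-weight the
same block-level $B_i$.

### Assumptions

* Residents evaluate a bounded set of nearby parks, not all parks in the
  study area. The choice-set size follows the information-processing limit
  of roughly seven simultaneously compared alternatives.
* Visit propensity scales with park size and decays with distance as a
  power law; park service capacity is not limiting (unlike healthcare
  accessibility, where supply-demand ratios matter).
* Block populations are concentrated at interior centroids, and
  straight-line (Euclidean/great-circle) distance is an acceptable proxy
  for travel cost. Attractiveness attributes (facilities, safety, quality)
  are out of scope, though `gravity_accessibility()` accepts an optional
  multiplicative per-park weight as a forward-compatible hook.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.85 | — | exponent on park area; the empirical public-open-space value |
| `beta` | 1.91 | — | distance decay (friction); the empirical estimate for public open space, close to the conventional 2.0 |
| `k` | 7 | parks | choice-set size; all parks are used when fewer than `k` exist |
| `d_floor` | 0.05 | miles | lower clamp on distances entering the model |
| `metric` | geodesic | — | great-circle on lon/lat, or planar on projected mile coordinates |
| min park size | 0.1/640 | mi² | parks under 0.1 acres (4000 ft²) are filtered out |

Raising `beta` shifts probability toward nearer parks, so the PWD is
strictly decreasing in `beta` whenever the choice set has two distinct
distances; at `alpha = beta = 0` the probabilities are uniform and the PWD
is the arithmetic mean of the choice-set distances. Because
$2\alpha - \beta \ne 0$, the accessibility score $A_{ij}$ carries a physical
dimension; it is treated as a dimensionless relative weight, and only
probabilities and the PWD (miles) are reported as interpretable outputs.

### Degenerate inputs and numerical choices

* **Zero distance.** A block centroid can coincide with a park centroid,
  which makes $d^{-\beta}$ singular. All distances are clamped below at
  `d_floor` (default 0.05 miles, configurable) *after* nearest-neighbour
  selection, so rankings use true distances while the model stays finite.
  The clamped distance is used consistently in both the PWD and the
  nearest-park baseline, preserving the dominance identity
  $B_i \ge d_{i,(1)}$ with equality for single-park choice sets.
* **Fewer than `k` parks.** The choice set is simply smaller; an empty park
  universe is an error.
* **Overflow guard.** Computations are in double precision with no
  log-domain transform; over the supported magnitudes (distances 0.05–10³
  miles, sizes 10⁻⁴–10⁴ mi²) this is safe for `beta` up to 50, and larger
  values are rejected.
* **Ties.** Equal-distance parks at the choice-set boundary are broken by
  ascending `park_id` (byte order), making selection deterministic. The k-d
  tree (Rcpp) compares `(squared distance, park index)` lexicographically;
  under the geodesic metric points are embedded on a sphere of radius
  3958.8 miles so chord ordering equals great-circle ordering.
* **Quantiles.** The within-stratum quintile classification uses
  linear-interpolation quantiles (R type 7) cut at the 20/40/60/80th
  percentiles; values equal to a boundary take the lower class, so a
  stratum of identical PWDs is all class 1. Strata with fewer than 5
  defined units are flagged rather than classified.
* **Zero-population units.** Aggregated units with zero population are
  reported with an `NA` PWD and an explicit `zero_population` flag, never
  silently dropped or zeroed.

### Open design choices

Where the method's definition is genuinely open we fixed the following, for
determinism and reproducibility rather than fidelity to any one historical
computation:

* $d_{ij}$ is the block-to-park centroid distance for *every* park in the
  choice set (the per-park generalisation of the nearest-park wording).
* The default metric is geodesic on lon/lat, the reproducible national-scale
  choice; planar mode serves projected inputs and small-region equivalence
  testing (the two agree in rank order for point sets spanning under 0.1°).
* The nearest-vs-PWD Pearson correlation is computed across unweighted
  block-level observations by default; `r_level` switches to aggregated
  units. Reported correlations from national studies do not state their
  observation level, so none is asserted as canonical.
* Poverty is inherited by blocks from their block group (a prefix level of
  the ID), classified low (< 10%), medium (≥ 10% and < 20%), high (≥ 20%).

## The synthetic landscape generator

National park layers and block population files are proprietary or bulky,
so all testing runs on seeded synthetic landscapes
(`generate_landscape()`). The generator emulates the structure the method
assumes:

* **Urban-rural gradient.** Blocks scatter around `n_centers = 3` urban
  cores on a 160 × 160-mile plane with exponentially decaying density
  (mean radius 12 miles) over a uniform rural background; six ordered
  urban-rural classes are assigned by distance bands from the nearest core
  (breaks at 4, 10, 18, 30, 48 miles). Parks follow the same radial process
  (mean radius 8 miles, 85% clustered), so park density falls — and
  nearest-park distance rises — monotonically along the continuum. That
  makes the qualitative access gradient an emergent, structural property
  rather than a hard-coded output.
* **Park sizes** are lognormal (median 0.03 mi² in the most urban band,
  log-sd 1.2), with the log-mean increasing by 0.5 per band toward rural —
  rural parks are sparser but larger — truncated below at the 0.1-acre
  floor by redraw.
* **Populations** are lognormal per block (log-mean 4, log-sd 1, ≈ 55
  people at the median, right-skewed like real block populations), rounded
  to counts. Subgroup counts are a multinomial split of the block total
  with Dirichlet-drawn shares whose concentration interpolates from a
  diverse urban profile to a homogeneous rural one, so subgroup counts are
  an exact partition of the total.
* **Poverty** is one Beta(2, 8) draw per block group (mean 20%, spanning
  all three classes), inherited by member blocks.
* **Hierarchical IDs** come from nested spatial tiles (2×2 states, 3×3
  counties, 4×4 tracts, 2×2 block groups), so ID prefixes correspond to
  spatial containment exactly as FIPS codes do.
* **Degenerate paths** are exercised deliberately: each default landscape
  contains a block placed exactly on a park centroid and a zero-population
  block.

One pseudorandom stream is used per run, seeded once, so identical
seed-plus-configuration is bit-identical.

These defaults were chosen once as a realistic stylised region and then
frozen; the band-wise population-weighted PWD was monotone non-decreasing
across the six classes in 20 of 20 generated landscapes at design time.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: real street networks (all distances are
straight-line), true FIPS geography and county shapes, the empirical size
distribution of any national park layer, spatial autocorrelation of poverty
beyond block-group constancy, and any correlation between subgroup
composition and park placement. Results on synthetic landscapes validate
the measure's mathematics and invariants, not any substantive claim about
actual park equity.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes, chosen to exercise every code path while keeping the default run
fast: landscapes of 660 blocks and 150 parks, brute-force
nearest-neighbour verification on 50 random landscapes of up to 500 × 500
points, 1000-instance property sweeps, and 20-landscape replications of the
gradient check. The implementation itself is vectorised and k-d-tree-backed,
and scales to national inputs (millions of blocks) in memory-bounded
batches of the same operations.

## Known limitations

* Euclidean distance understates travel cost increasingly from urban to
  rural settings; the measure is comparably biased where street density is
  low.
* The choice set is the same size everywhere; behaviourally, rural
  residents may consider fewer, farther destinations.
* Park attractiveness, safety and facility quality are not modelled; the
  hook exists but no default data feed it.
* `alpha` and `beta` come from a single empirical study of public open
  space; context-specific recalibration is advisable when linking to
  outcomes.
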