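# parkaccess

Population-weighted distance (PWD) measures of potential spatial
accessibility to parks, for health-geography and built-environment research.

The classic measures of neighbourhood park access are either a shortest
distance to the single nearest park (unrealistically exclusive) or a count or
area of parks inside a fixed container (sensitive to the unit definition —
the modifiable areal unit problem). `parkaccess` implements a gravity-model
alternative that keeps the intuitiveness of a distance while borrowing the
realism of spatial-interaction models: each census block interacts with a
bounded choice set of its *k* nearest parks, with visit probabilities from
the Huff trade-area model, and its expected travel distance is reported in
miles.

## The model

For block *i* and park *j* with park size *S<sub>j</sub>* (mi²) and
block-to-park centroid distance *d<sub>ij</sub>* (miles):

- gravity accessibility: *A<sub>ij</sub> = S<sub>j</sub><sup>α</sup> /
  d<sub>ij</sub><sup>β</sup>*
- total accessibility over the *k* nearest parks:
  *A<sub>i</sub> = Σ<sub>j</sub> A<sub>ij</sub>*
- Huff visit probability: *P<sub>ij</sub> = A<sub>ij</sub> / A<sub>i</sub>*
- block PWD: *B<sub>i</sub> = Σ<sub>j</sub> P<sub>ij</sub> d<sub>ij</sub>*
- roll-up to any unit *k* of a nesting hierarchy (tract, county, state,
  nation): *T<sub>k</sub> = Σ<sub>i</sub> Pop<sub>i</sub> B<sub>i</sub> /
  Pop<sub>k</sub>*

Defaults are the empirical public-open-space parameters *α* = 0.85,
*β* = 1.91, and *k* = 7 — the information-processing limit of roughly seven
alternatives in destination choice. Parks below 0.1 acres are filtered out.
Distances are Euclidean (great-circle on lon/lat input, straight-line on
projected mile coordinates), with near-zero distances clamped to a 0.05-mile
floor so a block sitting on a park centroid stays finite.

Around the core model the package provides population-weighted aggregation
to any prefix-coded (FIPS-like) hierarchy level, subgroup and
poverty/urban-rural stratified reporting, a nearest-park baseline comparison
(difference and Pearson correlation), within-stratum quintile classification
of relative access, a seeded synthetic-landscape generator, CSV/GeoJSON
readers, a pipeline runner with a reproducibility manifest, and a CLI
(`inst/cli/parkaccess`).

## Worked example

One block with two 1-mi² parks at exactly 1 and 2 miles:

```r
library(parkaccess)
ex <- worked_example_fixture()
params <- access_params(metric = "planar")

cs <- choice_sets(ex$blocks, ex$parks, params)
huff_probabilities(cs, ex$parks, params)[, c("park_id", "distance",
                                             "accessibility", "prob")]
#>   park_id distance accessibility      prob
#> 1  PARK_A        1     1.0000000 0.7898317
#> 2  PARK_B        2     0.2660925 0.2101683

compute_access(ex$blocks, ex$parks, params)
#>          block_id  a_total      pwd nearest_distance
#> 1 010010001001001 1.266093 1.210168                1
```

The nearer park captures 79% of expected visits
(1 / (1 + 2<sup>−1.91</sup>)), so the expected travel distance is 1.21
miles — above the nearest-park distance of 1 mile, below the 1.5-mile naive
average.

On a full synthetic landscape:

```r
land <- generate_landscape(landscape_config(seed = 7))
acc <- compute_access(land$blocks, filter_parks(land$parks),
                      access_params(metric = "planar"))
aggregate_pwd(acc, land$blocks, "nation")
#>    level unit_id n_blocks   pop      pwd flag
#> 1 nation     ALL      660 57276 8.207402

comparison_report(acc, land$blocks, stratum = "urban_rural")[1:3, 1:5]
#>               geography nearest_miles pwd_miles difference_miles pearson_r
#> 1                   ALL     6.0439387  8.207402        2.1634628 0.9697317
#> 2 1_large_central_metro     0.8164331  1.230468        0.4140348 0.9364699
#> 3  2_large_fringe_metro     1.7151393  2.989791        1.2746522 0.8518102
```

Residents of this landscape are expected to travel 8.2 miles to their local
parks; access worsens monotonically from the large-central-metro band (1.2
miles) outward, and the PWD correlates strongly (r ≈ 0.97) with the
nearest-park baseline while exceeding it everywhere by construction.

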