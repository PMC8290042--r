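# placeconn

Measure how strongly places are connected by the people who move between
them, using nothing more than geotagged point events (user id, timestamp,
longitude, latitude) and a polygon place layer.

The core statistic is a shared-user connectivity index. Over an analysis
period *T* (typically a calendar year), let *S&#x2071;* be the number of
unique users observed (≥ 1 geotagged event) in place *i*, and *S&#x2071;&#x02B2;*
the number of users observed in both *i* and *j*. The index is

```
PCI_ij = S_ij / sqrt(S_i * S_j)
```

— the shared-user count normalized by the geometric mean of the two
places' user counts, giving a value in [0, 1] that is comparable across
places of very different sizes. A directional variant `S_ij / S_i` (the
share of *i*'s users also seen in *j*) is available; its geometric mean
over the two directions reproduces the symmetric index exactly. Around
this core the package provides:

* point-in-polygon assignment of events to places and re-keying across
  hierarchy levels (county → state → country), with unique users recounted
  at each level rather than summed;
* person-day movement matrices (home-to-destination or same-day
  co-presence), the quantity mobility panels report;
* pairwise comparison tools: base-10 log transforms (the index is scaled
  by 1000 before logging), matrix and per-origin Pearson correlations and
  slopes;
* distance-decay power-law fits `y = a * d^(-b)` by raw-scale nonlinear
  least squares on great-circle centroid distances (statute miles);
* boundary-effect regression: connectivity on a same-state indicator plus
  distance, with conventional OLS errors and significance stars;
* focal-place association models (e.g. outcome rates against each
  county's connectivity to one focal county);
* regionalization: average-linkage agglomerative clustering of places on
  inverse-connectivity dissimilarities, cut at any set of community
  counts;
* a gravity-model synthetic event generator so the whole pipeline can be
  exercised offline with known ground truth.

All user-facing functions take and return tibbles, chain with the pipe,
and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(placeconn)
library(dplyr)

# a synthetic world: 6x6 grid of ~69-mile cells in 4 states, and a year of
# gravity-model mobility (decay exponent 1.7, same-state boost 3)
world <- make_world(grid_rows = 6, grid_cols = 6, states = 4, seed = 7)
sim   <- simulate_events(world, n_users = 400, seed = 7)

period <- as.Date(c("2019-01-01", "2020-01-01"))
pci <- sim$events |>
  assign_points(world$layer) |>
  build_incidence(period) |>
  compute_pci() |>
  filter_min_users(5)
pci
#> <pci_matrix> 36 places, 617 connected pairs
#>   pci range: 0.01316 (median 0.1397) to 0.6607

dist <- centroid_distance(world$layer)
tab  <- pair_edges(pci$pci, pci$pci, distances = dist,
                   parent_map = world$parent_map)

boundary_regression(tab)
#> Linear model: y
#>   (Intercept)    0.28309***  (SE 0.0092062)
#>   same_parent    0.20037***  (SE 0.0078869)
#>   distance      -0.00063156***  (SE 3.5156e-05)
#>   Adjusted R-squared: 0.79   Observations: 617
#>   *p<0.1, **p<0.05, ***p<0.01
```

The same-state coefficient is strongly positive at fixed distance — the
planted boundary effect — and the distance term is negative. Fitting the
decay curve and regionalizing:

```r
fit_distance_decay(tab)
#> <decay_fit> y = a * d^(-b)
#>   a = 27.4157, b = 0.9633, R^2 (raw scale) = 0.617, n = 617

regions <- cluster_regions(pci_to_distance(pci), k_list = 4)
head(region_assignment(regions, 4))
```

Note the index's fitted exponent (0.96) is shallower than the planted
movement exponent (1.7): the index counts unique shared users, which
saturates for busy nearby pairs. The movement-based estimate recovers the
planted value (see the methods vignette).

A command-line interface wraps the same functions
(`inst/cli/placeconn.R`): `simulate`, `compute`, `decay`, `boundary`,
`regionalize`, `focal`, `compare`.

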