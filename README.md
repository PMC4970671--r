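# ohigapfill

Gapfilling, provenance tracking and uncertainty propagation for
hierarchical composite indicators in the style of the Ocean Health Index
(OHI).

Composite marine assessments score every country and territorial
jurisdiction on a set of goals, but the underlying data layers are never
complete: values for small territories, remote islands or data-poor
commodities must be estimated ("gapfilled") before anything can be scored.
`ohigapfill` is an engine for doing that transparently. It

- fills missing observations with a library of estimators: regional means
  or medians with hierarchical fallback (neighbors → higher-resolution
  geopolitical region → lower-resolution region → global), territorial
  disaggregation, zero-filling, per-entity temporal regression, covariate
  (OLS) models, taxonomic nearest-ancestor averaging, and nearest-donor
  grid interpolation;
- records every decision in a per-observation **gapfilling ledger**
  (gapfilled yes/no, method token, error place-holder) that round-trips
  through CSV;
- selects among candidate imputation models by **leave-one-out
  cross-validation**, cascading country → geopolitical region → global as
  data availability allows, with parsimony tie-breaks;
- propagates the **percent contribution of gapfilled data** through the
  exact weight tree used to aggregate scores, so every status, trend,
  pressure, resilience, goal, region-index and global score carries its own
  gapfill percentage.

## The model in brief

Each goal score for a region is the average of current status `x` and the
projected future state

```
x_future = x * (1 + beta * T + (1 - beta) * (R - P)),     score = (x + x_future) / 2
```

with trend `T` (the OLS slope of the five most recent years of status,
times five, clamped to [-1, 1]), pressure `P` and resilience `R`, and
`beta = 0.67`. Goal scores average (optionally weighted) into a region
index, and region indices average, weighted by EEZ area `A_r`, into the
global score `sum(A_r * I_r) / sum(A_r)`.

Gapfill percentages flow through the *same* weighted means. A single
primitive (`propagate_gapfill(fractions, weights)`) serves every level;
dimension fractions enter the goal with component attribution weights
`(0.883, 0.0784, 0.0193, 0.0193)` for (status, trend, pressure,
resilience) — status carries 88.3% of the index-level attribution.

## Worked example

```r
library(ohigapfill)

cfg <- synth_config(seed = 42, n_regions = 60, n_georegions_l2 = 6,
                    n_georegions_l1 = 3)
reg <- make_registry(cfg)                       # seeded region registry
ly  <- make_layer(reg, cfg, layer_id = "tourism_index")  # masked layer + truth

fr <- regional_stat_fill(ly$masked, reg, min_n = 3)
fr
#> <fill_result> layer 'tourism_index': 60 obs, 15 flagged gapfilled
head(fr$diagnostics$fills, 3)
#>            key        level n_donors  estimate
#> 1  region_id=6 georegion_l2        6 0.3393358
#> 2  region_id=7 georegion_l2        8 0.5966776
#> 3 region_id=13 georegion_l2       10 0.2390310
```

Fifteen of sixty regions were missing; each was filled with the mean of
the valued regions in its own geopolitical region (6–10 donors), and the
ledger records `regional_mean:georegion_l2` for every one of them. A full
assessment-scale run (220 regions, 9 goals, territory-biased missingness):

```r
a <- synthetic_assessment(synth_config(seed = 42))
head(a$summary_table, 4)
#>   goal mean_pct sd_pct wmean_pct wsd_pct
#>  Index     21.7   18.8      11.1     9.2
#>     AO     22.2   28.6      13.2    21.3
#>     BD     23.6   29.3       6.5    17.0
#>     CP     20.0   29.6      14.2    22.0
a$global
#> global index 49.7, gapfilled 11.1%
```

The Index row says: on average a region's index score rests on 21.7%
gapfilled data, but only 11.1% after EEZ-area weighting — large countries
are better observed, exactly the pattern the territory-biased missingness
mechanism generates. The predictor regression makes that explicit:

```r
a$regression$full
#> territory effect +36.3 pct points (p = 1.1e-74), R2 = 0.83
```

A thin command-line front end over the same functions lives in
`inst/cli/ohigf.R` (`synth`, `calc`, `report` verbs).

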