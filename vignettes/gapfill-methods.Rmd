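---
title: "Gapfilling methods and uncertainty propagation for composite ocean indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gapfilling methods and uncertainty propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ohigapfill)
```

## The problem

Composite marine assessments such as the Ocean Health Index score every
reporting region — countries and the territories they administer — on a set
of goals, each assembled from data layers through a fixed weight tree.
Real layers are incomplete, and the regions most often missing are exactly
the small, territorial jurisdictions whose scores are least certain. Two
things are therefore needed beyond the score calculator itself: principled
estimators for the missing values, and an explicit account of *how much* of
every published score rests on estimated data. `ohigapfill` provides both,
organized around one discipline: gapfill provenance is stored and
aggregated in precisely the structures used for the data and scores
themselves.

## Scores

For one goal in one region, with status $x \in [0,1]$, trend
$T \in [-1,1]$, pressure $P \in [0,1]$ and resilience $R \in [0,1]$:

$$x_{future} = x\,[1 + \beta T + (1-\beta)(R - P)], \qquad
  \text{score} = \tfrac{1}{2}(x + x_{future}),$$

with $\beta = 0.67$ by default (configurable per goal). The trend is the
ordinary-least-squares slope of the five most recent years of status,
multiplied by five. Goal scores combine into a region index by a weighted
mean (equal weights by default; a goal excluded from an assessment gets
weight zero and drops out of both the score and the gapfill average), and
region indices combine into the global score by an EEZ-area-weighted mean.
Scores are held on the 0–1 scale internally — the trend multiplication and
future-state formula are naturally proportional — and multiplied by 100
only at the reporting boundary.

Numerical choices: the trend regressor is calendar year centered on its
mean (slope-identical, better conditioned); future state and score are
clamped to $[0,1]$ and trend to $[-1,1]$, preserving each quantity's
declared range when extreme inputs would otherwise leave it.

## Tracking gapfilling

Every layer is paired with a ledger holding one record per observation:
whether the value was gapfilled, the method (from a closed vocabulary,
with a `:detail` suffix recording e.g. the fallback level used), and a
numeric place-holder for the estimated error, kept empty until error
models are attached. Confident zero assumptions (`assumed_zero`) carry
`gapfilled = 0`: absence of a report is taken as evidence of absence, not
as missingness. Because that judgement is contestable,
`collapse_layer(count_assumed_zero = TRUE)` reclassifies such records for
sensitivity analysis.

## Gapfilling estimators

*Regional statistics with fallback* (`regional_stat_fill`). Each missing
value is filled with the mean (or median) of valued donor regions sharing
its non-region keys (category, year), walking an ordered chain of registry
groupings — typically neighbors, then the 22-class geopolitical region,
then the 7-class one, then global — and stopping at the first level with
at least `min_n` donors. `min_n` defaults to 3, the smallest donor count
with a defined dispersion; the global level is terminal and accepts any
donor rather than failing a region outright. Optional per-region weights
(e.g. habitat area) turn the mean into a weighted mean. Donor pools are
fully configurable through `donor_filter` — whether, say, sibling
territories of the same administrative country should donate is a
judgement the caller owns, not a rule the engine imposes. A target is
never its own donor.

*Territorial disaggregation* (`disaggregate_group`): a group value is
copied to each member, or a group total is split proportionally to EEZ
area. EEZ area is used because it is the only area the registry carries;
where a different basis (coastal area, habitat area) is appropriate it can
be passed as the group total basis.

*Zero fill* (`zero_fill`): missing values become 0, flagged either as
gapfilling or as assumed zeros; the operation refuses to overwrite
non-missing data.

*Temporal* (`temporal_fill`): per entity, an OLS fit of value on year
predicts missing years; extrapolation beyond the observed span requires
explicit permission, and skipped out-of-span targets are reported rather
than silently filled. Predictions are clamped to the layer's declared
value range — the data's stated bounds are taken as harder information
than a regression line's excursion beyond them.

*Taxonomic* (`taxonomic_fill`): a tip with missing data takes the
unweighted mean of valued tips under its nearest ancestor with any valued
descendant — conspecific populations first, then congeners, and so on.
Averaging is unweighted at each rank; fills are computed from original
values only, so results are independent of target order.

*Covariate* (`covariate_fill`): OLS on correlated predictors, optionally
with a categorical group term. The fit must be full rank, must have at
least 4 complete training rows per parameter (and never fewer than
parameters + 2), and refuses to predict factor levels absent from
training; all three refusals are signalled as typed conditions so a caller
can fall back to a coarser method.

*Grid interpolation* (`grid_fill`): each missing cell takes the value of
the nearest valued cell by Euclidean distance on cell indices, ties broken
by row-major donor order — the simplest fully deterministic rule — and the
share of filled cells is reported per region.

*The commodity recipe* (`fao_commodity_fill`) composes the above for
paired tonnes/value trade data: tonnes missing with value present is
predicted by the cross-validated model cascade below; both missing becomes
an explicit zero fill.

## Cross-validated model selection

Where several regression models could fill the same gaps,
`select_gapfill_model` walks a fallback chain of spatial scales per entity
(country → geopolitical region → global). A candidate is eligible at a
scale when the entity's scale unit has at least `min_n` complete rows;
among eligible candidates at the finest usable scale, the one with the
lowest leave-one-out RMSE wins, with ties broken by fewest parameters and
then candidate order, so the simplest adequate model is preferred and
selection is deterministic. The winning candidate's LOOCV RMSE is kept as
the entity's error estimate. Raising `min_n` can only push entities to
coarser scales, never finer.

`loocv_rmse` computes the leave-one-out residuals exactly from the single
full OLS fit via $e_i/(1-h_{ii})$, where $h_{ii}$ is the hat-matrix
diagonal — algebraically identical to refitting $n$ times (the test suite
checks this against a literal $n$-refit oracle) at a fraction of the cost.
A leverage of 1 means the model is unidentifiable without that case, and
is reported as an error naming it. Responses are modelled on their natural
scale by default; any transformation is the caller's, applied before the
data enter the engine.

Before regional means are used at all, `group_signal_test` runs a
fixed-effects one-way ANOVA across the candidate donor groups and flags
`use_global_mean` when $p \ge \alpha$ (default 0.05): if the groups are
statistically indistinguishable, a grand mean is the more defensible
donor pool.

## Propagating the gapfill percentage

One primitive, `propagate_gapfill(fractions, weights)` — a
normalized-weight mean — serves every aggregation level: observations into
a region's layer value (`collapse_layer`), layers into a dimension,
dimensions into a goal, goals into the index, regions into the globe.
Staged propagation through the tree equals a single pass with product
weights, the result always stays in $[0,1]$, and flipping any single
ledger flag from clean to gapfilled can never decrease a downstream
percentage. Applying the same primitive to the scores themselves
reproduces the score aggregation, which the tests assert directly: scores
and their provenance travel on one code path.

The only place the score and gapfill trees differ is the dimension-to-goal
step, where the score formula is not a weighted mean. Attribution there
uses the component weights $(0.883, 0.0784, 0.0193, 0.0193)$ for (status,
trend, pressure, resilience): the status share is fixed at 88.3%, and the
remaining 11.7% is split trend : pressure : resilience as
$\beta : (1-\beta)/2 : (1-\beta)/2$, mirroring how the future-state
formula weighs its own inputs. This split is a declared design choice —
the framework pins down only the status share — and the vector is fully
overridable per goal.

Category-keyed layers are collapsed to one value per region before
scoring by a weighted mean over categories (equal weights unless declared)
at the most recent valued year; this collapse rule is likewise a package
decision, made explicit so alternative collapses can replace it.

## Synthetic data

The generators exist so that every estimator can be validated against
known ground truth without any external download. `synth_config` fixes the
study shape: 220 regions in 22 higher- / 7 lower-resolution geopolitical
regions with about 40% territories — the scale of the global assessment —
log-normal EEZ areas (meanlog 11, sdlog 1.8, in km²; territories shifted
2.5 log-units smaller, matching the observation that territories are
systematically small), georegion-level layer means (SD 0.15 around 0.5)
with observation noise (SD 0.05), and three missingness mechanisms:
completely at random, territory-biased (default rates 0.5 vs 0.1), and
size-biased (logistic in standardized log area). Time series use 6 years
with yearly slopes drawn N(0, 0.02); covariate datasets use 20 entities ×
12 rows with slopes N(1.5, 0.5) and response noise SD 0.3 — well under 10%
of the covariate signal, so scale-recovery behavior is attributable to the
selection rule rather than to noise.

One root seed fans out into named substreams (stable string hashing), so
adding a generator never perturbs existing draws, and every generator
returns the unmasked truth beside the masked data.

What the generator deliberately does **not** emulate: spatial
autocorrelation beyond georegion membership, heavy-tailed or heteroscedastic
layer noise, missingness that depends on the unobserved value itself
(MNAR), correlated missingness across layers, and any attempt at the real
2015 layer values. Passing tests therefore demonstrate that the machinery
is correct under the declared statistical structure, not that real-world
gapfilling error is small.

## Problem sizes and runtime choices

The test suite validates the LOOCV identity on 100 random datasets of up
to 50 rows against the brute-force oracle, the trend closed form on 1,000
random 5-year windows, propagation algebra on 100 random weight trees plus
1,000 flag-flip perturbations, selection recovery on 25 entities × 12
rows, the ANOVA flag's type-I calibration on 1,000 null simulations, and
one full 220-region, 9-goal assessment. These sizes give stable pass/fail
behavior with a suite that runs in well under a minute on a single core.

## Known limitations

- The error field of the ledger is a place-holder: percentages of
  gapfilled data quantify exposure to estimation, not the error itself, so
  equal percentages do not imply equal uncertainty; no confidence
  intervals are produced.
- All regression estimators are ordinary least squares; count-like or
  bounded responses are handled by clamping rather than by link functions.
- Grid interpolation is nearest-donor only; no kriging or splines, and no
  raster file formats (grids enter as in-memory matrices).
- EEZ areas are inputs; nothing geodesic is computed.
- The engine trusts its registry: adjacency lists, georegion membership
  and administrative links are data, and the quality of neighbor-based
  fills is bounded by the quality of the declared adjacency.
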