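---
title: "Methods: ecohydrological metrics for synoptic river-network surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ecohydrological metrics for synoptic river-network surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A synoptic survey samples many stream-network locations nearly
simultaneously, giving a spatial snapshot of water chemistry with minimal
temporal confounding. Repeated snapshots (here: Spring, Summer, Fall)
support three questions that routine monitoring cannot answer:

1. **Where is solute flux generated or removed?** — subwatershed *leverage*.
2. **At what spatial scale does among-site variability collapse as
   tributaries mix?** — *variance changepoints* over subwatershed area.
3. **Are the spatial patterns stable enough that one snapshot
   characterises the system?** — *spatial persistence* of rankings.

`synopticr` implements all three on a common long-format site table
(site x season rows; areas in km², concentrations in mg/L for DOC, TDN,
DIN, PO4, Cl, SO4), plus the comparison layer (ANOVA/Tukey, AICc
all-subsets regression) and a synthetic watershed generator so that the
whole pipeline can be exercised against known ground truth.

## Scaled concentration and variance changepoints

For each solute the retained concentrations are z-scored (mean
subtracted, sample-sd divided) and ordered by subwatershed area; ties in
area break by site id so results are deterministic, and point sources
encoded with `area_km2 = 0` sort first. Because the series is z-scored,
the segment mean is fixed at zero and a variance change is the only
alternative considered. Each segment's cost is twice the negative
log-likelihood of a zero-mean normal at the segment's maximum-likelihood
variance,

    C(seg) = m * (log(2*pi) + log(max(mean(x^2), 1e-8)) + 1),

with the `1e-8` floor keeping all-zero segments finite. The optimal
segmentation minimises total cost plus a penalty `beta` per changepoint,
found by PELT: the `O(n)`-amortised pruned dynamic program. Pruning is
exact for this cost family; with a minimum segment length `min_seg > 1`
a candidate marked prunable at time `t` is removed only from times
`t + min_seg` onward, because the domination argument routes through `t`
as a changepoint and needs a whole segment after it. An exhaustive
optimal-partitioning oracle (`brute_force_changepoints()`, dynamic
programming with no pruning, guarded to `n <= 40`) verifies exact
equivalence in the test suite across hundreds of seeded series.

Tunables, with defaults and reasoning:

* `penalty`: `"bic"` (default) is `2 * log(n)` per changepoint — two
  parameters per added segment (its variance and its location).
  `"mbic"` adds `1.5 * log(n)` per changepoint plus a
  `log(segment length / n)` term per segment (the modified-BIC family).
  A manual numeric penalty is accepted; every output records the penalty
  used, since reported thresholds are only meaningful alongside it.
* `min_seg = 2`: a variance needs at least two points.
* Scaling group: pooled across seasons and networks by default (one
  threshold set per solute); per-season or per-network series are
  available through `order_by_area()` arguments.
* Boundary convention: a changepoint is the **last index of the left
  segment** (1-based), and its "area" is the subwatershed area at that
  index. The convention is recorded in every result object because the
  area axis is irregular and the choice matters near ties.

## Subwatershed leverage

With uniform specific discharge assumed across the watershed,

    leverage_conc = (c_sub - c_out) * (a_sub / a_out)        [mg/L]
    leverage_pct  = 100 * leverage_conc / c_out              [% of outlet flux]

measures how much of the outlet flux a subwatershed accounts for.
Classes use strict thresholds: `|pct| < 25` low/moderate, `pct > 100`
highly influential (critical source area), `pct < -100` the symmetric
sink case (an extension, clearly labelled — the source-only reading is
the conventional one), boundaries inclusive to `intermediate`. Values
above 100% are possible only because material is retained or removed in
transit; on an exactly conservative network the leaf leverages sum to
zero and no site can exceed +100%, a fact the test suite exploits as a
mass-balance oracle.

The outlet is the flagged `is_outlet` site; a `max_area` fallback exists
for tables without flags. Valley-tributary sites are rejected by name —
they do not converge to a single network outlet — unless explicitly
allowed; `exclude_valley_tributaries()` is the standard upstream filter.

Group means of `leverage_pct` are reported with a direction label under
the convention that a **positive mean implies net removal** within the
surface-water network (tributaries carry more solute than the outlet
accounts for) and a negative mean implies net production. The survey
literature contains both this wording and its mirror image; the package
follows the methods-text convention and records the discrepancy here
rather than silently reconciling it.

## Spatial persistence

For each (category, solute, season pair) the package computes Spearman's
rank correlation over sites observed in both seasons; ties receive
average ranks. Pairing is strictly by `site_id`, so replicate volunteer
samples must be aggregated at read time (`aggregate_duplicates =
"mean"`). Groups with fewer than `min_overlap = 5` overlapping sites are
reported as `NA` with a reason instead of being dropped: a rank
correlation on fewer points is uninformative and would distort the
mean-and-range summaries. The 0.7 level is a useful reading anchor: above
it, the majority of the spatial pattern is retained between samplings.

## The comparison layer

* `solute_anova()`: fixed-effects linear model, Type-II sums of squares
  (via `car::Anova`), optional interaction. A constant response returns
  `F = 0, p = 1` rather than failing on a zero residual sum of squares.
* `tukey_hsd()`: studentized-range adjusted pairwise comparisons.
* `best_subset()`: OLS for every subset of {season, forest, developed,
  impervious, herbaceous} (`2^p` fits including intercept-only), ranked
  by AICc `= -2 logL + 2k + 2k(k+1)/(n-k-1)` with `k` counting the
  residual variance. Ties break toward fewer predictors, then
  lexicographically, making selection deterministic and invariant to
  candidate order. Collinear subsets are skipped with a warning. The
  survey methodology names generalized least squares without specifying
  a correlation or variance structure; OLS is the identity-structure
  special case and the only determinate reading, so it is what the
  package fits. Whether to log-transform concentrations is likewise
  unstated; `log_response = TRUE` is provided and is advisable whenever
  point-source spikes dominate the concentration scale.

A note on what AICc selection can and cannot do: AICc is an *efficient*
criterion, not a *consistent* one. Adding a spurious predictor costs
only ~2 penalty units, which a chi-squared(1) noise improvement beats
about 15% of the time regardless of sample size or noise level. Exact
recovery of a planted single-predictor subset therefore plateaus near
50% with five candidates, even though the planted predictor itself is
recovered with the correct sign essentially always. The test suite
asserts both facts; the exact-recovery assertion documents the gap
between the efficient and consistent selection regimes.

## The synthetic watershed generator

`simulate_watershed()` emulates the statistical structure of a semiarid
synoptic survey so every stage has a no-download test surface:

* **Topology.** Each non-valley network (one or two per category) is a
  random recursive bifurcation tree; leaf areas are log-uniform up to
  1/8 of the upper area bound, internal areas are exactly the sums of
  their children, and the root is the flagged outlet. Valley-tributary
  networks are small disjoint site sets with no shared outlet, so the
  leverage stage fails on them by construction, mirroring the standard
  exclusion. Land-cover fractions are Dirichlet-like draws around
  category profiles (valley sites the most developed/impervious).
* **Concentrations.** Leaf concentration is `baseline * season_factor *
  exp(coef . land_cover) * exp(eta) * exp(eps)` with a site-level random
  effect `eta` and season-level noise `eps`; their variance ratio sets
  each solute's persistence tier (Cl/SO4 ~0.94, TDN/DIN intermediate,
  DOC/PO4 lowest). Routing mixes children flux-weighted under uniform
  specific discharge. The **diffuse** signal mixes conservatively —
  lateral inputs keep ambient concentrations stationary downstream —
  while point-source **excess** decays at a per-node rate derived from
  the solute's total path retention and the network's mean leaf depth.
  This separation is what makes >100% leverage attainable at all: a
  fully conservative network bounds every site at +100%. Per-node
  retention applied to the whole signal was tried and rejected — it
  makes outlet concentrations depth-dependent and inflates the leverage
  of every large tributary.
* **Point sources** are planted on deeper-than-median leaves
  (wastewater-like outfalls on headwater tributaries) for the N and P
  species, with load `point_source_strength` times the network's
  expected baseline flux. The default strength 1.5 was calibrated once
  so that the planted sites land well above the 100% threshold while
  the overall highly-influential fraction for TDN/PO4 tracks the
  planted fraction (default 0.12). Planting at `area_km2 = 0` — the
  field convention for recording point sources — is deliberately *not*
  used for the planted critical sources, because leverage is
  identically zero at zero area; zero-area rows remain fully supported
  by the reader and the ordering stage.
* **Hourglass variance** injects site-level (season-stable) extra
  variance below 1 km² (headwater heterogeneity, point-source-adjacent
  scatter) and above 200 km² at non-outlet sites (return flows, losing
  reaches, diversions in the tailwaters). The outlet itself is never
  perturbed: it is the reference for every leverage value.
* **Persistence modes.** `"persistent"` keeps all site-level structure
  fixed across seasons. `"scrambled"` permutes each season's finished
  concentrations across sites within their network — a true rank-null.
  Merely redrawing `eta` per season was tried and rejected: the fixed
  land-cover term, tree attenuation and planted sources keep
  cross-season rank correlation near 0.4, which is not a null.
* **Conservative mode** (`conservative_routing = TRUE`) forces zero
  retention, disables planting and post-routing perturbations, and
  yields exact mass balance: the leaf leverages of every network, solute
  and season sum to zero to floating-point precision.

Determinism: every draw flows from `config$seed` (topology) and
`config$seed + 1` (concentrations); repeated calls are identical, and
changing the seed changes values but never the schema.

What the generator does **not** emulate: discharge variation (uniform
specific discharge is exact, not approximate, here), correlated
land-cover along flow paths (an internal site's own covariates are drawn
independently of its upstream mix, which deliberately weakens land-cover
regressions toward the modest R² typical of such surveys), gauge or
laboratory error structure, and in-lake processes. Passing tests
therefore demonstrate the *statistical machinery* — not that real
watersheds satisfy the generator's assumptions.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random series of
`n <= 30` for PELT-oracle equivalence; 200 seeded replicates at `n = 100`
for boundary recovery (sd ratio 10, tolerance ±3 positions) and false
positives on constant variance; 50 generator seeds (~200 sites each) for
the critical-source fraction; 20 seeds per persistence mode; and 100
replicates for the regression-selection rates. These sizes give stable
rates (binomial standard errors of a few percent) while keeping the
default run in the low minutes on one core.

Other fixed choices: variance floor `1e-8`; DP ties resolved toward the
smallest candidate start; area ties toward the lexicographically smaller
site id; AICc ties toward parsimony; all thresholds (±25%, ±100%, rho
0.7) strict as documented above.

## Known limitations

* Changepoint "areas" inherit the irregular area axis; two adjacent
  indices can differ by orders of magnitude in km², so report indices
  alongside areas.
* Leverage assumes uniform specific discharge; in strongly losing or
  regulated reaches the flux interpretation degrades to a qualitative
  index.
* The persistence matrix treats seasons as exchangeable snapshots; it
  models no temporal autocorrelation beyond the three pairwise
  comparisons.
* Best-subset selection inherits AICc's overfitting tail (see above);
  interpret selected models as predictive summaries, not causal ones.
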