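# synopticr

Analysis of synoptic (snapshot) stream-network water-chemistry surveys:
many sites sampled nearly simultaneously, repeated across seasons, used to
locate solute sources and sinks in a river network. The package targets
the long-format site table such surveys produce — one row per site and
season, with subwatershed area (km²), land-use category, land-cover
fractions, and dissolved concentrations (mg/L) of DOC, TDN, DIN, PO4, Cl
and SO4 — and computes the three ecohydrological metrics built on it:

* **Subwatershed leverage** — the share of outlet flux a subwatershed
  accounts for under uniform specific discharge:
  `leverage = (C_sub − C_out) · (A_sub / A_out)`, reported both in mg/L
  and as % of outlet flux. Sites above +100% are *critical source areas*:
  they deliver more solute than leaves the outlet altogether, possible
  only because material is removed in transit.
* **Spatial-variance changepoints** — each solute is z-scored, ordered by
  subwatershed area, and segmented by a from-scratch PELT dynamic program
  with a zero-mean Gaussian variance cost, locating the watershed scales
  where among-site variability collapses (or, in semiarid networks,
  re-expands into an "hourglass"). An exhaustive optimal-partitioning
  oracle verifies the search exactly.
* **Spatial persistence** — Spearman rank correlation of site
  concentrations between season pairs, per category and solute: high ρ
  means sources and sinks are spatially stable, so one snapshot
  characterises the system.

Around these sit a comparison layer (Type-II ANOVA, Tukey HSD, and
all-subsets OLS regression selected by small-sample AICc), a synthetic
watershed generator with known ground truth (nested bifurcation-tree
subwatersheds, planted point sources, hourglass variance, tunable rank
persistence), and a pipeline runner with a reproducibility manifest.

## Worked example

```r
library(synopticr)

sim <- simulate_watershed(watershed_config(seed = 1))
sim$table
#> <site_table> 609 observations, 203 sites, 8 network(s), 6 solute(s)

# Variance changepoints for PO4 over subwatershed area
cp <- pelt_changepoints(order_by_area(sim$table, "PO4"), penalty = "bic")
cp
#> <changepoint_result> PO4: n = 609, penalty = bic (12.82), 16 changepoint(s)
#>   indices: 48, 51, 81, 84, 114, 117, 135, 138, 153, 156, 162, 165, 186, 189, 234, 261
#>   areas (km2): 0.4256, 0.4293, 0.8091, 0.8286, 1.38, 1.403, 1.992, 2.051, ...
```

Most PO4 changepoints sit at sub-km² areas: planted point sources create
narrow high-variance pockets among the smallest subwatersheds, exactly the
behaviour that makes small-area variance thresholds a point-source
signature in real surveys.

```r
# Leverage of every subwatershed on its network outlet (TDN, Spring)
lev <- leverage_table(exclude_valley_tributaries(sim$table), solutes = "TDN")
subset(summarize_leverage(lev), season == "Spring")
#>   category                mean_leverage_pct fraction_highly_influential direction
#> 1 AgriculturalUnregulated              19.7                      0.0588 removal
#> 2 MixedDammed                          33.7                      0.102  removal
#> 3 MountainUrban                        15.4                      0.0833 removal
```

Positive mean leverage reads as net removal within the surface-water
network (the tributaries carry more TDN than the outlet accounts for);
roughly a tenth of subwatersheds are highly influential (>100%), i.e. the
planted critical source areas.

```r
# Rank persistence per solute (mean rho over categories and season pairs)
pers <- persistence_summary(persistence_matrix(sim$table))
aggregate(mean_rho ~ solute, pers, function(x) round(mean(x), 2))
#>   solute mean_rho    # Cl 0.95, SO4 0.96 (conservative ions)
#>                      # TDN 0.94, DIN 0.90, PO4 0.87, DOC 0.77

# AICc all-subsets regression of Cl on season and land cover
best_subset(sim$table, "Cl", log_response = TRUE)
#> <model_fit> Cl ~ -forest +herbaceous +impervious +season
#>   R^2 = 0.145, AICc = 732.28, n = 609
```

Conservative ions persist most strongly; the Cl model recovers the
planted land-cover drivers (herbaceous and impervious positive) at the
modest R² typical of concentration–land-use regressions.

The same stages run end to end with
`run_pipeline(watershed_config(seed = 1), "out/")` (tidy CSVs plus a
`manifest.json` with seed, options and penalty formula), or from a shell
via `inst/scripts/watershed-pipeline.R`.

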