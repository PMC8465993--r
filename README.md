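# ecoclues

Land-use change simulation and ecosystem-service importance assessment for a
six-class ecosystem map (forest, grassland, wetland, cultivated, artificial,
other), in the CLUE-S tradition: a non-spatial Markov demand module coupled to
a spatial allocator driven by logistic suitability surfaces, validated with
ROC and Cohen's kappa, followed by four ecosystem-service calculators whose
graded importance maps feed an urban-encroachment accounting table.

The package is written for landscape ecologists and regional planners who
want the *mechanism* of this kind of analysis as tested, scriptable code:
every stage — from transfer-matrix accounting to the encroachment overlay —
is an exported function with tibble outputs, broom-style `tidy()`/`glance()`
methods for fitted models, and `autoplot()` quick-looks. A synthetic
landscape generator with known logistic coefficients makes the whole chain
verifiable end to end without any external rasters.

## The model

**Demand (non-spatial).** From a class-to-class area transfer matrix $T$
between two dates, transition probabilities are the row-normalization
$P_{ij} = T_{ij}/\sum_j T_{ij}$; per-class area demand propagates by
$a_{t+1} = a_t P$ per observation step, with per-class outflow/inflow
scenario modifiers and linear interpolation to yearly values. Total area is
conserved exactly.

**Suitability (spatial).** For each class, a stepwise binary logistic
regression (Wald entry p < 0.05, removal p > 0.10) of class presence on
standardized drivers (elevation, slope, climate normals, distances to road,
river and settlement, population density). Admission requires ROC > 0.70
(Mann–Whitney AUC, ties one half).

**Allocation.** Each cell takes the admissible class maximizing
`TPROP = P + ELAS·[incumbent] + ITER`, where ELAS is the per-class conversion
elasticity in [0, 1] (1 = never converts away) and ITER a per-class balancing
variable adjusted iteratively until every class's allocated area matches its
demand within tolerance. Simulated maps are compared with observed ones by
Cohen's kappa.

**Services.** Water conservation `TQ = Σ (P − R − ET) × A` (1 mm over 1 km² =
1000 m³); soil conservation `A_c = R·K·L·S·(1 − C)`; sandstorm-prevention
capacity `S_WS = NPP·K·F_q·D` with the wind-erosion climate factor
`F_q = (1/100) Σ u³ max(0, (ETP − P)/ETP) d`,
`ETP = 0.19(20 + T)²(1 − r)`, the 1/7-power wind profile and roughness
`D = 1/cos θ`; biodiversity by percentile-envelope species distribution
scores. Each service raster is graded into Very Important / Important /
Moderate / Common by a cumulative-contribution prefix rule, services combine
by per-cell maximum level, and newly urbanized cells are tallied per invaded
service combination.

## Worked example

```r
library(ecoclues)

spec  <- scene_spec(80, 80, seed = 2024)   # 80 x 80 km synthetic scene
scene <- generate_scene(spec)

models <- fit_all_classes(scene$landuse, scene$drivers)
purrr::map_dfr(models, glance)[, c("class_name", "n_drivers", "roc")]
#>   class_name n_drivers   roc
#> 1 forest             5 0.868
#> 2 grassland          6 0.869
#> 3 wetland            6 0.829
#> 4 cultivated         8 0.804
#> 5 artificial         5 0.857
#> 6 other              6 0.878
```

All six class models clear the ROC > 0.70 admission bound on this scene. The
fitted artificial-surface model recovers the generator's truth (people and
proximity to settlements attract construction):

```r
tidy(models$artificial)
#>   term            estimate    p.value
#> 1 (Intercept)       -2.38  NA
#> 2 pop_density        1.48   1.79e-212
#> 3 dist_settlement   -1.49   9.34e-129
#> 4 slope             -0.294  4.58e- 11
#> 5 dist_river         0.418  1.76e- 12
#> 6 rainfall          -0.207  5.01e-  6
```

The scene was sampled with true coefficients +1.5 on `pop_density` and −1.5
on `dist_settlement`; both are recovered to two decimals here. Downstream,
the water-balance service and its importance grading:

```r
water <- water_conservation(
  P   = scene$drivers$layers$rainfall,
  R   = estimate_runoff(scene$drivers$layers$rainfall, scene$landuse,
                        spec$runoff_coefficients),
  ET  = annual_evapotranspiration(scene$climate),
  map = scene$landuse)
grade_stats(grade(water$per_cell))
#>   level          acreage_km2 area_ratio_pct
#> 1 Very Important          20           0.31
#> 2 Important               31           0.48
#> 3 Moderate                42           0.66
#> 4 Common                6307          98.6
```

On this semi-arid synthetic scene most cells have a negative annual water
balance (floored at zero for grading), so the conserving area is small and
concentrated — 20 km² of cells carry the top 35% of the total service.

The whole pipeline — historical change, Markov demand, simulation to a
horizon year, all four services, grading and the encroachment table — runs
from one call:

```r
cfg <- validate_config(list(scene = list(n_rows = 80, n_cols = 80), seed = 2024))
res <- run_scene_report(cfg, output_dir = "out/")
res$encroachment_totals   # km2 of new urban land on graded service areas
```

A thin command-line wrapper with `synth`, `transfer`, `demand`, `fit`,
`grade` and `report` subcommands is installed at
`system.file("cli", "ecoclues.R", package = "ecoclues")`.

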