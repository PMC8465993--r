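---
title: "Methods: land-use change simulation and ecosystem-service importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use change simulation and ecosystem-service importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclues)
```

## Overview

`ecoclues` implements a complete CLUE-S-style land-use change analysis for a
six-class ecosystem map (forest, grassland, wetland, cultivated, artificial,
other) together with four ecosystem-service importance assessments and an
urban-encroachment overlay. The pipeline has five stages:

1. **Accounting** — class-to-class transfer matrices between two dates and
   Cohen's kappa map agreement.
2. **Demand** (non-spatial) — a Markov chain on the row-normalized transfer
   matrix projects per-class area demand to a horizon year, with per-class
   scenario modifiers.
3. **Suitability** (spatial) — per-class binary stepwise logistic regressions
   of class presence on standardized drivers, validated by the area under the
   ROC curve.
4. **Allocation** — an iterative competitive allocator converts yearly demand
   into maps, driven by the suitability surfaces, per-class conversion
   elasticities and conversion rules.
5. **Services and grading** — water conservation (water balance), soil
   conservation (universal soil loss equation), sandstorm-prevention capacity
   (wind-erosion climate factor) and biodiversity habitat suitability
   (occurrence envelopes) are each graded into four ordinal importance levels;
   newly urbanized cells are tallied against the graded services.

Everything runs on synthetic landscapes produced by the package's own
generator, so the full chain is testable without external data.

## The demand model

Given a transfer matrix $T$ (areas in km^2^, rows = class at $t_0$), the
transition matrix is the row-normalization $P_{ij} = T_{ij} / \sum_j T_{ij}$.
A class absent at $t_0$ receives an identity row. Demand propagates by left
multiplication, one application per observation interval (default 5 years,
matching typical land-use map revision cycles), and is interpolated linearly
to yearly values for the allocator. Left multiplication by a stochastic matrix
conserves the total area exactly, and the projection equals an explicit
matrix power — both are asserted in the test suite.

Scenario adjustments are multiplicative factors on the off-diagonal
probabilities: an *outflow* modifier on a class's row encodes protection
(0 = the class never leaves) or accelerated loss, an *inflow* modifier on its
column damps or accelerates growth. Rows are re-normalized through the
diagonal; a modifier combination that would require a negative staying
probability is rejected rather than silently clipped. The default pipeline
scenario sets the wetland outflow to 0 (strictly protected water bodies),
which also keeps the allocator's wetland elasticity of 1 feasible.

## Suitability models

For each class $k$ the package fits a binary logistic regression of the
indicator "cell is class $k$" on the drivers, standardized to zero mean and
unit variance over unmasked cells. Selection is stepwise: the candidate with
the smallest Wald p-value enters while $p < 0.05$; any selected driver with
$p > 0.10$ is removed; the cycle repeats to a fixpoint. The entry/removal
thresholds are the common defaults of desktop statistics packages. ROC is
computed in-sample by the Mann–Whitney formulation (ties count one half),
which is invariant under monotone transforms of the score.

Degenerate inputs are handled explicitly: a class occupying less than 1% or
more than 99% of cells is refused (no stable regression exists); perfect
separation triggers a ridge-penalized fall-back fit (penalty $10^{-6}$ on the
slopes, intercept unpenalized). Under separation the penalized Wald statistic
degenerates, so a separating driver is treated as carrying overwhelming
evidence and retained rather than assessed by its meaningless p-value.

## The allocator

Each unmasked, unrestricted cell is assigned the admissible class maximizing

$$\mathrm{TPROP}_u \;=\; P_u \;+\; \mathrm{ELAS}_u\,[u = \text{current class}] \;+\; \mathrm{ITER}_u,$$

where $P_u$ is the suitability surface, ELAS is the per-class conversion
elasticity in $[0,1]$ (1 = the class never converts away; the elasticity
rewards incumbency additively for the current class only), and ITER is a
per-class balancing variable adjusted until allocated areas match demand.
Admissibility combines the conversion matrix (rows = current class) with the
elasticity-1 lock; ties break towards the lowest class code, which makes the
allocator fully deterministic.

**Numerical choice.** ITER starts at 0 each year and is updated additively,
$\mathrm{ITER}_u \mathrel{+}= \eta\, g_u\, r_u / \max(d_u, a)$, where
$r_u$ is the area residual (demand minus allocated), $d_u$ the class demand,
$a$ one cell area and $\eta = 0.05$. Normalizing by the class's own demand —
rather than the total study area — is essential: for a minority class a
total-area-normalized step is $O(10^{-4})$ per iteration and cannot close a
typical suitability gap within any reasonable iteration budget. The per-class
gain $g_u$ starts at 1, halves when the residual changes sign (damping
oscillation around a discrete cell flip) and grows by 10% under a persistent
one-sided residual, bounded in $[0.01, 20]$. Convergence requires every class
within `tolerance_frac` (default 0.001) of the total area; non-convergence
after `max_iterations` (default 1000) is an error carrying the last
residuals, never a silently degraded map.

Default elasticities (wetland 1.0, artificial 0.9, forest/grassland 0.6,
cultivated 0.4, other 0.3) encode strict protection of water bodies, the
practical irreversibility of built land, and the relative mobility of
cultivated and unused land. They are configuration with a documented
rationale, not estimates.

## Service calculators

* **Water conservation**: per-cell $(P - R - ET)$ in mm, converted with
  1 mm over 1 km^2^ = 1000 m^3^; totals aggregate by ecosystem class. The
  runoff term $R$ is modelled as a per-class fraction of rainfall (defaults
  0.05 wetland … 0.6 artificial) because no runoff observations accompany the
  other inputs. Annual actual evapotranspiration is aggregated
  supply-limited from monthly values, $\sum_m \min(\mathrm{ETP}_m, P_m)$.
  Negative balances are legitimate (semi-arid cells) and are floored at zero
  only when grading.
* **Soil conservation**: $A_c = A_p - A_r = R\,K\,L\,S\,(1 - C)$ with
  $A_p = R K L S$ the potential and $A_r = A_p C$ the actual erosion. The
  slope-length factor $L$ defaults to 1 (unit plot) with a user override —
  flow-path tracing is out of scope — and the steepness factor $S$ can be
  derived from slope via McCool's relation as a convenience helper.
* **Sandstorm prevention**: $S_{WS} = \mathrm{NPP}_{mean} \times K \times
  F_q \times D$, a dimensionless capacity index. The wind-erosion climate
  factor is $F_q = \tfrac{1}{100}\sum_m u^3 \max\!\big(0, \tfrac{\mathrm{ETP}_m - P_m}{\mathrm{ETP}_m}\big)\, d_m$
  with $u$ the monthly wind speed at 2 m (converted from the measurement
  height by the one-seventh power profile $u_2 = u_1 (z_2/z_1)^{1/7}$),
  $\mathrm{ETP}_m = 0.19\,(20 + T_m)^2 (1 - r_m)$ the monthly potential
  evapotranspiration (clamped to 0 at $T \le -20$ °C, below which the
  quadratic would rise again), and $d_m$ the days in the month. Months wetter
  than their evaporative demand contribute nothing — wind erosion is inactive
  in humid months. Surface roughness is $D = 1/\cos\theta$.
* **Biodiversity**: a rectilinear-envelope species distribution model. Each
  species with at least five occurrences contributes an envelope per driver
  (5th–95th percentile of the driver at its points); a cell's species score
  is the fraction of drivers inside the envelope, and the surface is the
  protection-weighted species mean, which lies in $[0,1]$ by construction.

Slope is derived from the DEM by Horn's 3×3 operator with replicated borders.
All calculators are cell-local and deterministic; nodata propagates (a cell
masked in any input is masked in the result).

## Importance grading and the encroachment overlay

Grading ranks cells by their contribution to the service total: after
flooring negatives at zero, cells are sorted descending (ties by row-major
index) and the minimal prefix reaching a cumulative share of 0.35 is graded
Very Important; the prefixes to 0.65 and 0.85 bound Important and Moderate;
the remainder is Common. The three cut points are configuration — the
published grading scheme delegates them to planning guidelines without
printing values — and the four-level scale follows the published statistical
tables (their accompanying text names only three levels; the tables are taken
as defining). The combined importance of several services is the per-cell
maximum level.

Encroachment accounting scans the cells newly converted to artificial
surface: the invaded set at a cell is the services graded Moderate or higher
there, and severity is the overlap cardinality — one service is a Moderate
encroachment (keyed by that service), two an Important one (keyed by the
pair), three or more a Very Important one. This cardinality reading is the
only one that produces the single/pair/triple row labels of the published
overlay table; severity totals are exact sums of their combination rows.

## The synthetic landscape generator

The generator emulates the statistical structure the analysis assumes:
spatially autocorrelated drivers and a categorical land-use map sampled from
*known* logistic coefficients, so that estimator recovery is a testable
property rather than an assumption.

* The DEM is white noise (sd 200 m) convolved with a Gaussian kernel (radius
  4 cells by default), so its variance falls monotonically with the
  smoothness radius.
* Temperature follows the standard environmental lapse rate (−0.0065 °C/m)
  plus smooth noise (sd 1.2 °C); rainfall is elevation-coupled
  (+0.1 mm per m) plus smooth noise (sd 30 mm); distances to a random road
  line, river line and settlement points are exact Euclidean distance
  transforms; population density clusters around its *own* random centres.
* Land use is sampled per cell from a multinomial logit over the true
  coefficients applied to standardized drivers — a multinomial rather than
  six independent binaries guarantees a valid categorical partition.
* Monthly climate follows sinusoidal seasonal cycles (July peak) with
  clipped humidity; species occurrences are drawn proportional to a
  suitability surface.

All generators are deterministic given the scene seed (each consumes an
offset sub-seed, so stages can be regenerated independently).

**Why the coefficient design is sparse.** The default "true" coefficients
give every class at least two strong (|β| ≥ 1) drivers, with each strong
driver loading on at most two classes and the driver fields kept only weakly
collinear. This is deliberate: the suitability module fits one-vs-rest
*binary* logistic models (the standard practice this pipeline reproduces),
which are approximately unbiased for a multinomial-logit truth only for
drivers not shared by several classes and not collinear with other drivers.
Under this design, empirical checks across seeded 100×100 scenes recover all
strong-coefficient signs and almost all magnitudes within ±0.5; a small
misspecification tail (roughly one scene in twenty places a single
coefficient just outside the band) is inherent to the binary-fit-of-a-
multinomial set-up, not an estimation bug.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: realistic geomorphology or hydrology (the DEM is
smoothed noise, rivers are random walks), spatial autocorrelation in the
land-use residual beyond what the smooth drivers induce, class-contiguity
(real parcels are contiguous; sampled cells are conditionally independent),
observation error in the maps, and temporally varying drivers.

## Problem sizes and determinism

The shipped tests run the estimation stages at 100×100 cells (10^4^
observations per logistic fit) and the allocator at 50×50, sizes at which the
statistical properties under test (coefficient recovery, ROC admission,
convergence, conservation) are already stable; the published study operates
on a ~37,000 km^2^ region at finer resolution, and those map-specific results
(its transfer areas, per-class ROC of 0.76–0.87, kappa of 0.84, the
226.1 km^2^ simulated expansion) depend on the original rasters and are
explicitly not reproduced here. Every random quantity flows from a single
integer seed; repeated runs are byte-identical, which the CLI tests assert on
the emitted CSV files.

## Known limitations

* Binary one-vs-rest suitability fits are a pragmatic approximation to the
  multinomial truth; coefficient recovery has the tail described above.
* ROC is computed in-sample (no holdout protocol is defined for the method
  being reproduced); with strong drivers this is mildly optimistic.
* The runoff coefficients, cover factors and grading cut points are
  documented configuration, not fitted quantities.
* Raster I/O is limited to the plain-text ESRI ASCII grid; no coordinate
  reference system handling or reprojection is attempted.
* The allocator treats suitability surfaces as static within a simulation;
  year-varying drivers would require refitting per year.
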