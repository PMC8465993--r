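#' Water conservation by water balance
#'
#' Per-cell water retention is the water-balance residual
#' `(P - R - ET)` in mm, converted to volume with the cell area
#' (1 mm over 1 km^2 = 1000 m^3). Class totals aggregate cells by ecosystem
#' type and the total `TQ` (m^3) is their sum. Negative cell values are
#' permitted in the balance (and in `TQ`); grading floors them at zero.
#'
#' @param P Rainfall [grid_raster] (mm/yr).
#' @param R Surface runoff [grid_raster] (mm/yr); see [estimate_runoff()].
#' @param ET Evapotranspiration [grid_raster] (mm/yr).
#' @param map A [land_use_map] aligned with the rasters.
#' @return A list: `per_cell` ([grid_raster], m^3), `by_class` (tibble
#'   `class_code`, `class_name`, `area_km2`, `volume_m3`), `TQ` (m^3).
#' @export
water_conservation <- function(P, R, ET, map) {
  stopifnot(inherits(map, "land_use_map"))
  check_aligned(P, R); check_aligned(P, ET); check_aligned(P, map)
  cell_area <- map$cell_size_km^2
  depth <- P$values - R$values - ET$values            # mm
  vol <- depth * cell_area * 1000                     # m^3 per cell
  vol[map$mask] <- NA_real_
  per_cell <- grid_raster(vol, map$cell_size_km, map$mask)
  keep <- !map$mask
  by_class <- tibble::tibble(
    class_code = unname(landuse_classes),
    class_name = landuse_labels,
    area_km2 = tabulate(map$codes[keep], 6L) * cell_area,
    volume_m3 = vapply(landuse_classes, function(k)
      sum(vol[keep & map$codes == k]), numeric(1))
  )
  list(per_cell = per_cell, by_class = by_class, TQ = sum(vol[keep]))
}

#' Estimate surface runoff from per-class coefficients
#'
#' The water balance needs a runoff term the source data do not provide
#' directly; the package models it as a fixed per-class fraction of rainfall,
#' `R = c[class] * P`.
#'
#' @param P Rainfall [grid_raster] (mm/yr).
#' @param map A [land_use_map].
#' @param runoff_coefficients Named per-class fractions in `[0, 1]`.
#' @return A [grid_raster] of runoff (mm/yr).
#' @export
estimate_runoff <- function(P, map, runoff_coefficients) {
  stopifnot(inherits(map, "land_use_map"))
  check_aligned(P, map)
  miss <- setdiff(landuse_labels[sort(unique(map$codes[!map$mask]))],
                  names(runoff_coefficients))
  if (length(miss))
    stop("runoff coefficient missing for class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(runoff_coefficients < 0 | runoff_coefficients > 1))
    stop("runoff coefficients must lie in [0, 1]", call. = FALSE)
  cvec <- setNames(rep(NA_real_, 6), landuse_labels)
  cvec[names(runoff_coefficients)] <- runoff_coefficients
  r <- cvec[map$codes] * P$values
  r[map$mask] <- NA_real_
  grid_raster(matrix(r, nrow(P$values), ncol(P$values)),
              map$cell_size_km, map$mask)
}

#' Soil conservation by the universal soil loss equation
#'
#' Soil conservation is potential minus actual erosion:
#' `A_c = A_p - A_r = R * K * L * S * (1 - C)`, with potential erosion
#' `A_p = R * K * L * S` (bare-soil) and actual erosion `A_r = A_p * C`.
#' All factors are per-cell rasters; `C` is the vegetation cover factor in
#' `[0, 1]`.
#'
#' @param r_f Rainfall erosivity (MJ mm / hm^2 h a).
#' @param k_f Soil erodibility (t hm^2 h / hm^2 MJ mm).
#' @param l_f Slope-length factor (dimensionless; default 1, the unit plot).
#' @param s_f Slope-steepness factor (dimensionless); see [slope_s_factor()].
#' @param c_f Vegetation cover factor in `[0, 1]`.
#' @return A list of [grid_raster]s: `a_c` (conservation, t/hm^2 a),
#'   `a_p` (potential erosion), `a_r` (actual erosion).
#' @export
soil_conservation <- function(r_f, k_f, l_f, s_f, c_f) {
  check_aligned(r_f, k_f); check_aligned(r_f, s_f); check_aligned(r_f, c_f)
  if (is.numeric(l_f) && length(l_f) == 1)
    l_f <- grid_raster(matrix(l_f, nrow(r_f$values), ncol(r_f$values)),
                       r_f$cell_size_km, r_f$mask)
  check_aligned(r_f, l_f)
  cv <- c_f$values[!c_f$mask]
  if (any(cv < 0 | cv > 1))
    stop("cover factor C must lie in [0, 1]", call. = FALSE)
  a_p <- combine_rasters(function(r, k, l, s) r * k * l * s, r_f, k_f, l_f, s_f)
  a_r <- combine_rasters(`*`, a_p, c_f)
  a_c <- combine_rasters(`-`, a_p, a_r)
  list(a_c = a_c, a_p = a_p, a_r = a_r)
}

#' Slope-steepness factor from slope angle
#'
#' Convenience helper using McCool's relation: `S = 10.8 sin(theta) + 0.03`
#' below 9% slope, `16.8 sin(theta) - 0.5` above. Offered because the source
#' method names the S factor without a sub-formula; it is a standard choice,
#' not part of the core equations.
#'
#' @param slope A [grid_raster] of slope angles (radians).
#' @return A [grid_raster] of dimensionless S factors.
#' @export
slope_s_factor <- function(slope) {
  s <- sin(slope$values)
  f <- ifelse(s < 0.09, 10.8 * s + 0.03, 16.8 * s - 0.5)
  f[slope$mask] <- NA_real_
  grid_raster(f, slope$cell_size_km, slope$mask)
}

#' Monthly potential evapotranspiration
#'
#' `ETP = 0.19 * (20 + T)^2 * (1 - r)` (mm), where `T` is the monthly mean
#' temperature (deg C) and `r` the relative humidity as a fraction. Clamped to
#' zero at `T <= -20` deg C, where the quadratic would otherwise rise again.
#'
#' @param T_c Temperature in degrees C (vectorized).
#' @param r Relative humidity fraction in `[0, 1]` (vectorized).
#' @return Potential evapotranspiration (mm).
#' @export
potential_evapotranspiration <- function(T_c, r) {
  if (any(r < 0 | r > 1, na.rm = TRUE))
    stop("relative humidity must lie in [0, 1]", call. = FALSE)
  ifelse(T_c <= -20, 0, 0.19 * (20 + T_c)^2 * (1 - r))
}

#' Wind speed at another height (1/7-power profile)
#'
#' `u2 = u1 * (z2 / z1)^(1/7)` — the empirical one-seventh power-law wind
#' profile over open terrain.
#'
#' @param u1 Wind speed (m/s) at height `z1`.
#' @param z1,z2 Heights (m), both positive.
#' @return Wind speed (m/s) at `z2`.
#' @export
wind_at_height <- function(u1, z1, z2) {
  if (any(z1 <= 0) || any(z2 <= 0))
    stop("heights must be positive", call. = FALSE)
  u1 * (z2 / z1)^(1 / 7)
}

#' Wind-erosion climate factor
#'
#' `F_q = (1/100) * sum over months of u^3 * max(0, (ETP - P) / ETP) * d`,
#' where `u` is the monthly mean wind speed at 2 m, `ETP` the monthly
#' potential evapotranspiration, `P` the monthly precipitation and `d` the
#' days in the month. Months wetter than their evaporative demand (P >= ETP)
#' contribute nothing — wind erosion is inactive in humid months — as do
#' months with non-positive ETP.
#'
#' @param climate A [climate_stack]; wind is converted from its stated
#'   measurement height to `target_height_m` by [wind_at_height()].
#' @param target_height_m Height (m) the erosivity formula expects (default 2).
#' @return A [grid_raster] of `F_q` values.
#' @export
climate_erosivity <- function(climate, target_height_m = 2) {
  stopifnot(inherits(climate, "climate_stack"))
  acc <- NULL
  for (m in seq_len(12)) {
    Tm <- climate$temp[[m]]$values
    rm_ <- climate$rh[[m]]$values
    Pm <- climate$precip[[m]]$values
    um <- wind_at_height(climate$wind[[m]]$values, climate$wind_height_m,
                         target_height_m)
    etp <- potential_evapotranspiration(Tm, rm_)
    frac <- ifelse(etp > 0, pmax(0, (etp - Pm) / etp), 0)
    contrib <- um^3 * frac * climate$days[m]
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  ref <- climate$precip[[1]]
  fq <- acc / 100
  fq[ref$mask] <- NA_real_
  grid_raster(fq, ref$cell_size_km, ref$mask)
}

#' Surface roughness factor from slope
#'
#' `D = 1 / cos(theta)`; strictly increasing on `[0, pi/2)`.
#'
#' @param slope A [grid_raster] of slope angles (radians) in `[0, pi/2)`.
#' @return A [grid_raster] of roughness factors (>= 1).
#' @export
surface_roughness <- function(slope) {
  th <- slope$values[!slope$mask]
  if (any(th < 0 | th >= pi / 2))
    stop("slope must lie in [0, pi/2)", call. = FALSE)
  d <- 1 / cos(slope$values)
  d[slope$mask] <- NA_real_
  grid_raster(d, slope$cell_size_km, slope$mask)
}

#' Sandstorm-prevention (sand-fixation) capacity index
#'
#' `S_WS = NPP_mean * K * F_q * D`: the product of mean net primary
#' productivity, the wind-erosion soil factor, the wind-erosion climate factor
#' and the surface roughness factor, per cell. A dimensionless capacity index.
#'
#' @param npp Mean NPP [grid_raster].
#' @param soil_k Wind-erosion soil factor [grid_raster] (>= 0).
#' @param fq Climate erosivity [grid_raster]; see [climate_erosivity()].
#' @param roughness Surface roughness [grid_raster]; see [surface_roughness()].
#' @return A [grid_raster] of capacity indices.
#' @export
sand_fixation <- function(npp, soil_k, fq, roughness) {
  check_aligned(npp, soil_k); check_aligned(npp, fq); check_aligned(npp, roughness)
  combine_rasters(function(a, b, cc, d) a * b * cc * d, npp, soil_k, fq, roughness)
}

#' Biodiversity habitat suitability from occurrence envelopes
#'
#' A rectilinear-envelope species distribution model: for each species with at
#' least `min_occurrences` points, the envelope of each driver is the 5th-95th
#' percentile of the driver's values at the occurrence cells; a cell's species
#' score is the fraction of drivers whose value there falls inside the
#' envelope, and the output is the protection-weighted mean over species
#' (weights normalized to sum 1, so the surface lies in `[0, 1]`).
#'
#' @param occ A [species_occurrences()] object.
#' @param drivers A [driver_stack].
#' @param min_occurrences Minimum points per species (default 5); species
#'   below it are skipped with a warning, and an error is raised if none
#'   remain.
#' @param envelope_probs Lower/upper envelope percentiles.
#' @return A [grid_raster] of suitabilities in `[0, 1]`.
#' @export
biodiversity_suitability <- function(occ, drivers, min_occurrences = 5L,
                                     envelope_probs = c(0.05, 0.95)) {
  stopifnot(inherits(occ, "species_occurrences"),
            inherits(drivers, "driver_stack"))
  nr <- nrow(drivers$mask); nc <- ncol(drivers$mask)
  if (any(occ$row < 1 | occ$row > nr | occ$col < 1 | occ$col > nc))
    stop("occurrence coordinates fall outside the grid", call. = FALSE)
  w <- attr(occ, "protection_weight")
  counts <- table(occ$species_id)
  ids <- names(counts)[counts >= min_occurrences]
  skipped <- setdiff(names(counts), ids)
  if (length(skipped))
    warning("species with < ", min_occurrences, " occurrences skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(ids))
    stop("no species has enough occurrences", call. = FALSE)
  dnames <- names(drivers$layers)
  acc <- matrix(0, nr, nc)
  wsum <- 0
  for (s in ids) {
    pts <- occ[occ$species_id == s, ]
    cells <- cbind(pts$row, pts$col)
    inside <- matrix(0, nr, nc)
    for (d in dnames) {
      v <- drivers$layers[[d]]$values
      env <- quantile(v[cells], probs = envelope_probs, na.rm = TRUE,
                      names = FALSE)
      inside <- inside + (v >= env[1] & v <= env[2])
    }
    ws <- unname(w[as.character(s)]) %|NA|% 1
    acc <- acc + ws * inside / length(dnames)
    wsum <- wsum + ws
  }
  out <- acc / wsum
  out[drivers$mask] <- NA_real_
  grid_raster(out, drivers$cell_size_km, drivers$mask)
}

#' Annual actual evapotranspiration and precipitation from a climate stack
#'
#' Annual actual evapotranspiration is approximated supply-limited as the sum
#' over months of `min(ETP_i, P_i)`; annual precipitation is the plain monthly
#' sum. Both are package conveniences for feeding the annual water balance
#' from monthly climate layers.
#'
#' @param climate A [climate_stack].
#' @return A [grid_raster] (mm/yr).
#' @export
annual_evapotranspiration <- function(climate) {
  stopifnot(inherits(climate, "climate_stack"))
  acc <- NULL
  for (m in seq_len(12)) {
    etp <- potential_evapotranspiration(climate$temp[[m]]$values,
                                        climate$rh[[m]]$values)
    aet <- pmin(etp, climate$precip[[m]]$values)
    acc <- if (is.null(acc)) aet else acc + aet
  }
  ref <- climate$precip[[1]]
  acc[ref$mask] <- NA_real_
  grid_raster(acc, ref$cell_size_km, ref$mask)
}

#' @rdname annual_evapotranspiration
#' @export
annual_precipitation <- function(climate) {
  stopifnot(inherits(climate, "climate_stack"))
  acc <- Reduce(`+`, lapply(climate$precip, `[[`, "values"))
  ref <- climate$precip[[1]]
  acc[ref$mask] <- NA_real_
  grid_raster(acc, ref$cell_size_km, ref$mask)
}
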