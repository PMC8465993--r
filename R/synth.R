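#' Default "true" suitability coefficients for synthetic landscapes
#'
#' Per-class multinomial-logit coefficients on standardized drivers used by
#' [generate_landuse()]. The design is sparse: each class is driven strongly
#' (|beta| >= 1) by at least two drivers, and each strong driver loads mainly
#' on one class, so one-vs-rest logistic refits can recover sign and magnitude.
#'
#' @return Named list (one element per class name) of named coefficient vectors.
#' @export
default_true_coefficients <- function() {
  list(
    forest     = c(dem = 1.5, slope = 1.0),
    grassland  = c(dem = -1.5, temperature = -1.2),
    wetland    = c(dist_river = -1.5, rainfall = 1.2),
    cultivated = c(temperature = 1.2, dist_road = -1.0),
    artificial = c(dist_settlement = -1.5, pop_density = 1.5),
    other      = c(rainfall = -1.2, dist_settlement = 1.0)
  )
}

#' Specify a synthetic scene
#'
#' A scene spec fixes everything the synthetic generators need: grid size,
#' random seed, the "true" per-class logistic coefficients the land-use map is
#' sampled from, the spatial smoothness of the driver fields (Gaussian kernel
#' radius in cells), and per-class runoff coefficients for the water-balance
#' stage.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param seed Integer random seed; every generator is deterministic given it.
#' @param logistic_coefficients Named list of per-class named coefficient
#'   vectors on the standardized driver scale. Must cover all six classes.
#' @param spatial_smoothness Gaussian smoothing radius in cells (> 0).
#' @param runoff_coefficients Per-class runoff fractions in `[0, 1]`.
#' @param cell_size_km Cell edge length in km.
#' @param noise List of noise amplitudes: `dem_sd` (m), `temp_sd` (deg C),
#'   `rain_sd` (mm).
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_rows, n_cols, seed = 1L,
                       logistic_coefficients = default_true_coefficients(),
                       spatial_smoothness = 4,
                       runoff_coefficients = c(forest = 0.15, grassland = 0.25,
                                               wetland = 0.05, cultivated = 0.35,
                                               artificial = 0.6, other = 0.45),
                       cell_size_km = 1,
                       noise = list(dem_sd = 200, temp_sd = 1.2, rain_sd = 30)) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be positive", call. = FALSE)
  if (spatial_smoothness <= 0) stop("`spatial_smoothness` must be > 0", call. = FALSE)
  miss <- setdiff(landuse_labels, names(logistic_coefficients))
  if (length(miss))
    stop("`logistic_coefficients` missing class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(landuse_labels, names(runoff_coefficients))
  if (length(miss))
    stop("`runoff_coefficients` missing class(es): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(runoff_coefficients < 0 | runoff_coefficients > 1))
    stop("runoff coefficients must lie in [0, 1]", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, seed = as.integer(seed),
         logistic_coefficients = logistic_coefficients,
         spatial_smoothness = spatial_smoothness,
         runoff_coefficients = runoff_coefficients,
         cell_size_km = cell_size_km,
         noise = modifyList(list(dem_sd = 200, temp_sd = 1.2, rain_sd = 30),
                            noise)),
    class = "scene_spec"
  )
}

# internal: separable Gaussian smoothing with replicated borders
gaussian_smooth <- function(m, sigma) {
  hw <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-hw, hw), sd = sigma)
  k <- k / sum(k)
  pad_conv_rows <- function(x) {
    nr <- nrow(x)
    xp <- x[c(rep(1L, hw), seq_len(nr), rep(nr, hw)), , drop = FALSE]
    out <- matrix(0, nr, ncol(x))
    for (j in seq_along(k))
      out <- out + k[j] * xp[j:(j + nr - 1L), , drop = FALSE]
    out
  }
  t(pad_conv_rows(t(pad_conv_rows(m))))
}

# internal: smoothed standard-normal field (unit variance after rescaling)
smooth_field <- function(nr, nc, sigma) {
  f <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), sigma)
  s <- stats::sd(f)
  if (s > 0) f / s else f
}

#' Generate a synthetic elevation field
#'
#' Smoothed Gaussian-noise elevation (metres), deterministic given the scene
#' seed: white noise of amplitude `dem_sd` convolved with a Gaussian kernel of
#' radius `spatial_smoothness` cells. Smoothing averages the noise, so the
#' field's variance decreases monotonically with the smoothness radius,
#' approaching a constant plain in the limit.
#'
#' @param spec A [scene_spec].
#' @return A [grid_raster] of elevations (m).
#' @export
generate_dem <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed + 1L, {
    f <- gaussian_smooth(matrix(rnorm(spec$n_rows * spec$n_cols),
                                spec$n_rows, spec$n_cols),
                         spec$spatial_smoothness)
    grid_raster(1000 + spec$noise$dem_sd * f, spec$cell_size_km)
  })
}

# internal: Euclidean distance (km) from every cell to the nearest feature cell
distance_raster <- function(nr, nc, feat_rc, cell_size_km) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d2 <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(feat_rc)))
    d2 <- pmin(d2, (rows - feat_rc[k, 1])^2 + (cols - feat_rc[k, 2])^2)
  grid_raster(sqrt(d2) * cell_size_km, cell_size_km)
}

# internal: random left-to-right polyline as a set of (row, col) cells
random_polyline <- function(nr, nc) {
  r <- numeric(nc)
  r[1] <- runif(1, 0.2 * nr, 0.8 * nr)
  for (j in seq_len(nc - 1))
    r[j + 1] <- min(max(r[j] + rnorm(1, sd = max(1, nr / 40)), 1), nr)
  cbind(round(r), seq_len(nc))
}

#' Generate driver surfaces from a DEM
#'
#' Builds the eight standard driver rasters: elevation (`dem`, m), `slope`
#' (rad), annual `rainfall` (mm, positively correlated with elevation),
#' annual mean `temperature` (deg C, lapse rate -0.0065 deg C/m plus noise),
#' Euclidean distances (km) to a random road line, river line and settlement
#' points, and `pop_density` (persons/km^2, decaying with settlement distance).
#' Deterministic given the scene seed.
#'
#' @param dem A [grid_raster] from [generate_dem()].
#' @param spec The [scene_spec].
#' @param n_settlements Number of settlement seed points.
#' @return A [driver_stack] with layers `dem`, `slope`, `rainfall`,
#'   `temperature`, `dist_road`, `dist_river`, `dist_settlement`,
#'   `pop_density`.
#' @export
generate_drivers <- function(dem, spec, n_settlements = 3L) {
  stopifnot(inherits(dem, "grid_raster"), inherits(spec, "scene_spec"))
  nr <- nrow(dem$values); nc <- ncol(dem$values)
  withr::with_seed(spec$seed + 2L, {
    temperature <- 15 - 0.0065 * dem$values +
      spec$noise$temp_sd * smooth_field(nr, nc, spec$spatial_smoothness)
    rainfall <- 400 + 0.1 * (dem$values - 1000) +
      spec$noise$rain_sd * smooth_field(nr, nc, spec$spatial_smoothness)
    rainfall <- pmax(rainfall, 10)
    road <- random_polyline(nr, nc)
    river <- random_polyline(nr, nc)
    setl <- cbind(sample.int(nr, n_settlements, replace = TRUE),
                  sample.int(nc, n_settlements, replace = TRUE))
    d_road <- distance_raster(nr, nc, road, spec$cell_size_km)
    d_river <- distance_raster(nr, nc, river, spec$cell_size_km)
    d_setl <- distance_raster(nr, nc, setl, spec$cell_size_km)
    # population clusters around its own centres (market towns etc.), not the
    # settlement points used for the distance driver, so the two surfaces are
    # correlated only weakly and both remain identifiable in regression
    pop_centres <- cbind(sample.int(nr, n_settlements + 2L, replace = TRUE),
                         sample.int(nc, n_settlements + 2L, replace = TRUE))
    d_pop <- distance_raster(nr, nc, pop_centres, spec$cell_size_km)
    pop <- 500 * exp(-d_pop$values / (0.15 * max(nr, nc) * spec$cell_size_km)) +
      20 * abs(smooth_field(nr, nc, spec$spatial_smoothness))
    driver_stack(list(
      dem = dem,
      slope = if (nr >= 3 && nc >= 3) slope_from_dem(dem)
              else grid_raster(matrix(0, nr, nc), spec$cell_size_km),
      rainfall = grid_raster(rainfall, spec$cell_size_km),
      temperature = grid_raster(temperature, spec$cell_size_km),
      dist_road = d_road,
      dist_river = d_river,
      dist_settlement = d_setl,
      pop_density = grid_raster(pop, spec$cell_size_km)
    ))
  })
}

# internal: standardize driver layers over unmasked cells; returns a matrix
# (cells x drivers, masked rows NA) plus centers and scales
standardize_drivers <- function(drivers, center = NULL, scale = NULL) {
  nm <- names(drivers$layers)
  X <- vapply(drivers$layers, function(l) as.vector(l$values), numeric(length(drivers$mask)))
  colnames(X) <- nm
  keep <- !as.vector(drivers$mask)
  if (is.null(center)) center <- colMeans(X[keep, , drop = FALSE])
  if (is.null(scale)) {
    scale <- apply(X[keep, , drop = FALSE], 2, stats::sd)
    scale[scale == 0] <- 1
  }
  X <- sweep(sweep(X, 2, center[nm]), 2, scale[nm], `/`)
  list(X = X, center = center, scale = scale)
}

#' Sample a synthetic land-use map from known coefficients
#'
#' Each unmasked cell draws one of the six classes from a multinomial logit:
#' the per-class utility is the scene's "true" coefficient vector applied to
#' the standardized drivers, and class probabilities are the softmax of the
#' utilities. A multinomial (rather than six independent binaries) guarantees
#' a valid categorical map. Deterministic given the scene seed.
#'
#' @param drivers A [driver_stack].
#' @param spec The [scene_spec] carrying `logistic_coefficients`.
#' @return A [land_use_map].
#' @export
generate_landuse <- function(drivers, spec) {
  stopifnot(inherits(drivers, "driver_stack"), inherits(spec, "scene_spec"))
  std <- standardize_drivers(drivers)
  n <- nrow(std$X)
  U <- matrix(0, n, 6L)
  for (k in seq_len(6L)) {
    beta <- spec$logistic_coefficients[[landuse_labels[k]]]
    if (is.null(beta)) stop("missing coefficients for class ", landuse_labels[k],
                            call. = FALSE)
    bad <- setdiff(names(beta)[names(beta) != "(Intercept)"], colnames(std$X))
    if (length(bad))
      stop("coefficient names not in driver stack: ", paste(bad, collapse = ", "),
           call. = FALSE)
    u <- rep(unname(beta["(Intercept)"] %|NA|% 0), n)
    for (d in setdiff(names(beta), "(Intercept)"))
      u <- u + beta[[d]] * std$X[, d]
    U[, k] <- u
  }
  U <- U - apply(U, 1, max)
  P <- exp(U); P <- P / rowSums(P)
  withr::with_seed(spec$seed + 3L, {
    draws <- runif(n)
    cum <- t(apply(P, 1, cumsum))
    codes <- 1L + rowSums(cum < draws)
  })
  codes <- matrix(pmin(codes, 6L), spec$n_rows, spec$n_cols)
  codes[drivers$mask] <- NA_integer_
  land_use_map(codes, spec$cell_size_km, drivers$mask)
}

# internal: NA-coalescing scalar helper
`%|NA|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Generate a synthetic monthly climate stack
#'
#' Sinusoidal seasonal cycles (peak temperature and precipitation in July, as
#' in a temperate continental monsoon climate) with spatial noise; relative
#' humidity is clipped to `[0, 1]`. Deterministic given the scene seed.
#'
#' @param spec The [scene_spec].
#' @param temp_mean,temp_amplitude Annual mean and seasonal half-range (deg C).
#' @param precip_annual Annual precipitation total (mm) around which the
#'   monthly cycle is built.
#' @param wind_mean Mean wind speed (m/s) at 10 m.
#' @param noise_scale Multiplier on all spatial noise amplitudes (0 gives
#'   perfectly cyclical, spatially uniform months).
#' @return A [climate_stack] with wind referenced at 10 m.
#' @export
generate_climate <- function(spec, temp_mean = 8, temp_amplitude = 14,
                             precip_annual = 420, wind_mean = 3.5,
                             noise_scale = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  withr::with_seed(spec$seed + 4L, {
    months <- seq_len(12)
    seas <- cos(2 * pi * (months - 7) / 12)
    Tm <- lapply(months, function(m)
      grid_raster(matrix(temp_mean + temp_amplitude * seas[m], nr, nc) +
                    noise_scale * 0.5 * smooth_field(nr, nc, spec$spatial_smoothness),
                  spec$cell_size_km))
    pw <- pmax(0.02, 1 + 1.6 * seas); pw <- pw / sum(pw)
    P <- lapply(months, function(m)
      grid_raster(pmax(matrix(precip_annual * pw[m], nr, nc) +
                         noise_scale * 3 * smooth_field(nr, nc, spec$spatial_smoothness), 0),
                  spec$cell_size_km))
    r <- lapply(months, function(m)
      grid_raster(pmin(pmax(matrix(0.45 + 0.2 * seas[m], nr, nc) +
                              noise_scale * 0.03 * smooth_field(nr, nc, spec$spatial_smoothness),
                            0), 1), spec$cell_size_km))
    u <- lapply(months, function(m)
      grid_raster(pmax(matrix(wind_mean - 1.2 * seas[m], nr, nc) +
                         noise_scale * 0.2 * smooth_field(nr, nc, spec$spatial_smoothness),
                       0.1), spec$cell_size_km))
    climate_stack(P, Tm, r, u, cell_size_km = spec$cell_size_km,
                  dim = c(nr, nc), wind_height_m = 10)
  })
}

#' Generate a synthetic net-primary-productivity raster
#'
#' NPP (gC/m^2/yr) increases with rainfall and temperature; a convenience
#' generator for the sand-fixation service inputs. Deterministic given seed.
#'
#' @param drivers A [driver_stack] containing `rainfall` and `temperature`.
#' @param spec The [scene_spec].
#' @return A [grid_raster].
#' @export
generate_npp <- function(drivers, spec) {
  stopifnot(inherits(drivers, "driver_stack"))
  withr::with_seed(spec$seed + 5L, {
    npp <- 200 + 0.6 * (drivers$layers$rainfall$values - 300) +
      10 * drivers$layers$temperature$values +
      20 * smooth_field(spec$n_rows, spec$n_cols, spec$spatial_smoothness)
    grid_raster(pmax(npp, 0), spec$cell_size_km, drivers$mask)
  })
}

#' Generate a synthetic soil-factor raster
#'
#' A smooth positive field scaled to a requested mean — used for both the USLE
#' erodibility factor and the wind-erosion soil factor. Deterministic given
#' seed (offset by `which` so the two factors differ).
#'
#' @param spec The [scene_spec].
#' @param mean_value Target mean of the factor.
#' @param which Integer sub-seed offset (1 = erodibility, 2 = wind-erosion).
#' @return A [grid_raster] of non-negative values.
#' @export
generate_soil_factor <- function(spec, mean_value = 0.3, which = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed + 10L + as.integer(which), {
    f <- smooth_field(spec$n_rows, spec$n_cols, spec$spatial_smoothness)
    grid_raster(pmax(mean_value * (1 + 0.4 * f), 0), spec$cell_size_km)
  })
}

#' Sample species occurrence points from a suitability surface
#'
#' Occurrences are drawn (with replacement) from unmasked cells with
#' probability proportional to suitability; every species receives at least
#' one point. Deterministic given the scene seed.
#'
#' @param suitability A [grid_raster] with values in `[0, 1]`.
#' @param n_species Number of species.
#' @param spec The [scene_spec].
#' @param n_occurrences Points per species.
#' @param protection_weight Optional named positive weights per species id
#'   (default all 1).
#' @return A `species_occurrences` object: a tibble with columns `row`, `col`,
#'   `species_id`, carrying a `protection_weight` attribute.
#' @export
generate_species <- function(suitability, n_species, spec, n_occurrences = 30L,
                             protection_weight = NULL) {
  stopifnot(inherits(suitability, "grid_raster"))
  v <- suitability$values
  v[suitability$mask] <- 0
  if (any(v[!suitability$mask] < 0 | v[!suitability$mask] > 1))
    stop("suitability must lie in [0, 1]", call. = FALSE)
  if (all(v == 0)) stop("suitability is zero everywhere", call. = FALSE)
  idx <- which(!suitability$mask)
  p <- v[idx] / sum(v[idx])
  withr::with_seed(spec$seed + 6L, {
    occ <- purrr::map_dfr(seq_len(n_species), function(s) {
      cells <- idx[sample.int(length(idx), n_occurrences, replace = TRUE, prob = p)]
      tibble::tibble(
        row = ((cells - 1L) %% nrow(v)) + 1L,
        col = ((cells - 1L) %/% nrow(v)) + 1L,
        species_id = s
      )
    })
  })
  species_occurrences(occ, protection_weight %||%
                        setNames(rep(1, n_species), seq_len(n_species)))
}

#' Construct a species-occurrences object
#'
#' @param occ Tibble/data frame with columns `row`, `col`, `species_id`.
#' @param protection_weight Named positive weights, one per species id.
#' @return A `species_occurrences` tibble.
#' @export
species_occurrences <- function(occ, protection_weight = NULL) {
  occ <- tibble::as_tibble(occ)
  stopifnot(all(c("row", "col", "species_id") %in% names(occ)))
  if (!nrow(occ)) stop("at least one occurrence is required", call. = FALSE)
  ids <- sort(unique(occ$species_id))
  if (is.null(protection_weight))
    protection_weight <- setNames(rep(1, length(ids)), ids)
  if (any(protection_weight <= 0))
    stop("protection weights must be positive", call. = FALSE)
  structure(occ, protection_weight = protection_weight,
            class = c("species_occurrences", class(occ)))
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper chaining the individual generators: DEM, drivers,
#' land-use map, monthly climate, NPP, soil factors and species occurrences.
#'
#' @param spec A [scene_spec].
#' @param n_species Species count for the occurrence sample.
#' @return A named list with elements `spec`, `dem`, `drivers`, `landuse`,
#'   `climate`, `npp`, `soil_k_usle`, `soil_k_wind`, `species`.
#' @export
generate_scene <- function(spec, n_species = 5L) {
  dem <- generate_dem(spec)
  drivers <- generate_drivers(dem, spec)
  landuse <- generate_landuse(drivers, spec)
  rain <- drivers$layers$rainfall$values
  suit <- (rain - min(rain)) / max(1e-9, diff(range(rain)))
  list(
    spec = spec,
    dem = dem,
    drivers = drivers,
    landuse = landuse,
    climate = generate_climate(spec),
    npp = generate_npp(drivers, spec),
    soil_k_usle = generate_soil_factor(spec, 0.3, 1L),
    soil_k_wind = generate_soil_factor(spec, 1.5, 2L),
    species = generate_species(grid_raster(suit, spec$cell_size_km),
                               n_species, spec)
  )
}
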