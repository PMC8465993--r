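#' Land-use class codes and labels
#'
#' The six ecosystem classes used throughout the package, in fixed order:
#' 1 forest, 2 grassland, 3 wetland, 4 cultivated, 5 artificial, 6 other.
#'
#' @format Named integer vector of length 6.
#' @export
landuse_classes <- c(
  forest = 1L, grassland = 2L, wetland = 3L,
  cultivated = 4L, artificial = 5L, other = 6L
)

#' @rdname landuse_classes
#' @export
landuse_labels <- names(landuse_classes)

#' Construct a gridded raster
#'
#' The universal raster carrier: a rectangular grid of real values with a
#' square cell size (km) and a nodata mask. Row-major with the origin at the
#' top-left corner. Masked cells are excluded from every statistic computed
#' downstream.
#'
#' @param values Numeric matrix of cell values.
#' @param cell_size_km Positive cell edge length in kilometres (default 1).
#' @param mask Logical matrix, same shape as `values`; `TRUE` marks nodata.
#'   Defaults to `is.na(values)`.
#' @return A `grid_raster` object.
#' @export
grid_raster <- function(values, cell_size_km = 1, mask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 || cell_size_km <= 0)
    stop("`cell_size_km` must be a single positive number", call. = FALSE)
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!is.logical(mask)) stop("`mask` must be logical", call. = FALSE)
  if (!identical(dim(mask), dim(values)))
    stop("`mask` and `values` must have identical dimensions", call. = FALSE)
  mask <- mask | is.na(values)
  structure(
    list(values = values, cell_size_km = as.numeric(cell_size_km), mask = mask),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[!x$mask]
  cat(sprintf(
    "<grid_raster> %d x %d cells (%.3g km), %d nodata; range [%.4g, %.4g]\n",
    nrow(x$values), ncol(x$values), x$cell_size_km, sum(x$mask),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA
  ))
  invisible(x)
}

#' Construct a categorical land-use map
#'
#' A land-use map carries one of the six ecosystem class codes
#' (see [landuse_classes]) per unmasked cell.
#'
#' @param codes Integer matrix of class codes in 1..6.
#' @inheritParams grid_raster
#' @return A `land_use_map` object.
#' @export
land_use_map <- function(codes, cell_size_km = 1, mask = NULL) {
  codes <- as.matrix(codes)
  if (is.null(mask)) mask <- is.na(codes)
  mask <- as.matrix(mask) | is.na(codes)
  ok <- codes[!mask]
  bad <- setdiff(unique(ok), landuse_classes)
  if (length(bad))
    stop("invalid land-use class code(s): ", paste(bad, collapse = ", "),
         " (expected 1..6)", call. = FALSE)
  storage.mode(codes) <- "integer"
  r <- grid_raster(ifelse(mask, NA_real_, as.numeric(codes)), cell_size_km, mask)
  structure(
    list(codes = codes, cell_size_km = r$cell_size_km, mask = r$mask),
    class = "land_use_map"
  )
}

#' @export
print.land_use_map <- function(x, ...) {
  cat(sprintf("<land_use_map> %d x %d cells (%.3g km), %d nodata\n",
              nrow(x$codes), ncol(x$codes), x$cell_size_km, sum(x$mask)))
  tab <- table(factor(x$codes[!x$mask], levels = landuse_classes,
                      labels = landuse_labels))
  print(tab)
  invisible(x)
}

#' Bundle driver rasters into a stack
#'
#' A driver stack is a named collection of [grid_raster]s sharing shape, cell
#' size and mask — the explanatory surfaces for the suitability models (DEM,
#' slope, climate normals, distances, population density). Nodata propagates:
#' a cell masked in any member is masked in all.
#'
#' @param layers Named list of `grid_raster` objects.
#' @return A `driver_stack` object.
#' @export
driver_stack <- function(layers) {
  if (!length(layers) || is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("`layers` must be a non-empty named list", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "grid_raster")))
    stop("all layers must be grid_raster objects", call. = FALSE)
  dims <- lapply(layers, function(l) dim(l$values))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all layers must share the same dimensions", call. = FALSE)
  sizes <- vapply(layers, `[[`, numeric(1), "cell_size_km")
  if (max(sizes) - min(sizes) > 1e-12)
    stop("all layers must share the same cell size", call. = FALSE)
  mask <- Reduce(`|`, lapply(layers, `[[`, "mask"))
  layers <- lapply(layers, function(l) grid_raster(l$values, l$cell_size_km, mask))
  structure(
    list(layers = layers, cell_size_km = sizes[[1]], mask = mask),
    class = "driver_stack"
  )
}

#' @export
print.driver_stack <- function(x, ...) {
  cat(sprintf("<driver_stack> %d layers, %d x %d cells (%.3g km): %s\n",
              length(x$layers), nrow(x$mask), ncol(x$mask), x$cell_size_km,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Monthly climate stack
#'
#' Twelve monthly layers of precipitation (mm), mean temperature (degrees C),
#' relative humidity (fraction 0-1) and wind speed (m/s at a stated reference
#' height), plus days in each month. Each variable may be supplied as a list of
#' 12 matrices/rasters or a numeric vector of 12 spatially constant values.
#'
#' @param precip,temp,rh,wind Monthly layers (list of 12 matrices /
#'   `grid_raster`s, or numeric vector of length 12).
#' @param days Integer vector of 12 days-in-month, each in 28..31. Defaults to
#'   the non-leap calendar.
#' @param cell_size_km Cell size used when expanding scalar months.
#' @param dim Grid dimensions `c(nrow, ncol)` used when expanding scalar months.
#' @param wind_height_m Height (m) at which `wind` was measured.
#' @return A `climate_stack` object.
#' @export
climate_stack <- function(precip, temp, rh, wind,
                          days = c(31L, 28L, 31L, 30L, 31L, 30L,
                                   31L, 31L, 30L, 31L, 30L, 31L),
                          cell_size_km = 1, dim = c(1L, 1L),
                          wind_height_m = 2) {
  expand <- function(x, what) {
    if (is.numeric(x) && is.null(dim(x))) {
      if (length(x) != 12) stop(what, " must have 12 monthly values", call. = FALSE)
      lapply(x, function(v) grid_raster(matrix(v, dim[1], dim[2]), cell_size_km))
    } else if (is.list(x)) {
      if (length(x) != 12) stop(what, " must have 12 monthly layers", call. = FALSE)
      lapply(x, function(m) if (inherits(m, "grid_raster")) m
             else grid_raster(as.matrix(m), cell_size_km))
    } else stop(what, " must be a 12-vector or list of 12 layers", call. = FALSE)
  }
  P <- expand(precip, "precip"); Tm <- expand(temp, "temp")
  r <- expand(rh, "rh"); u <- expand(wind, "wind")
  days <- as.integer(days)
  if (length(days) != 12 || any(days < 28L | days > 31L))
    stop("`days` must be 12 values in 28..31", call. = FALSE)
  for (m in seq_len(12)) {
    rv <- r[[m]]$values[!r[[m]]$mask]
    if (any(rv < 0 | rv > 1))
      stop("relative humidity must lie in [0, 1] (month ", m, ")", call. = FALSE)
  }
  structure(
    list(precip = P, temp = Tm, rh = r, wind = u, days = days,
         wind_height_m = wind_height_m),
    class = "climate_stack"
  )
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> 12 months, %d x %d cells, wind at %g m\n",
              nrow(x$precip[[1]]$values), ncol(x$precip[[1]]$values),
              x$wind_height_m))
  invisible(x)
}

#' Slope from a digital elevation model
#'
#' Computes per-cell slope (radians) from a DEM using Horn's 3x3
#' finite-difference operator; border cells use replicated edges. The DEM is in
#' metres and the cell size in kilometres, so gradients are rise over run in
#' consistent units. Adding a constant to the DEM leaves the slope unchanged.
#'
#' @param dem A [grid_raster] of elevations in metres.
#' @return A `grid_raster` of slope angles in radians, in `[0, pi/2)`.
#' @export
slope_from_dem <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  z <- dem$values
  if (nrow(z) < 3 || ncol(z) < 3)
    stop("DEM must be at least 3 x 3", call. = FALSE)
  z[dem$mask] <- NA_real_
  # replicate borders so the 3x3 stencil is defined everywhere
  zp <- rbind(z[1, , drop = FALSE], z, z[nrow(z), , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, ncol(zp), drop = FALSE])
  nr <- nrow(z); nc <- ncol(z)
  sh <- function(dr, dc) zp[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)
  d <- sh(1, 0);                e <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); i <- sh(2, 2)
  cell_m <- dem$cell_size_km * 1000
  dzdx <- ((cc + 2 * e + i) - (a + 2 * d + g)) / (8 * cell_m)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cell_m)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  slope[dem$mask] <- NA_real_
  grid_raster(slope, dem$cell_size_km, dem$mask)
}

#' Per-class area statistics
#'
#' Tabulates the area (km^2) of each of the six ecosystem classes on a map.
#' Areas always sum to the total unmasked area (conservation).
#'
#' @param map A [land_use_map].
#' @return A tibble with columns `class_code`, `class_name`, `area_km2`.
#' @export
area_stats <- function(map) {
  stopifnot(inherits(map, "land_use_map"))
  counts <- tabulate(map$codes[!map$mask], nbins = 6L)
  tibble::tibble(
    class_code = unname(landuse_classes),
    class_name = landuse_labels,
    area_km2 = counts * map$cell_size_km^2
  )
}

# internal: unmasked cell values as a vector
raster_values <- function(r) r$values[!r$mask]

# internal: elementwise combination of rasters with nodata propagation
combine_rasters <- function(f, ..., cell_size_km = NULL) {
  rs <- list(...)
  mask <- Reduce(`|`, lapply(rs, `[[`, "mask"))
  vals <- do.call(f, lapply(rs, `[[`, "values"))
  vals[mask] <- NA_real_
  grid_raster(vals, cell_size_km %||% rs[[1]]$cell_size_km, mask)
}

# internal: stop unless two rasters/maps share geometry
check_aligned <- function(a, b, what = "rasters") {
  da <- if (!is.null(a$values)) dim(a$values) else dim(a$codes)
  db <- if (!is.null(b$values)) dim(b$values) else dim(b$codes)
  if (!identical(da, db) || abs(a$cell_size_km - b$cell_size_km) > 1e-12 ||
      !identical(a$mask, b$mask))
    stop(what, " must share shape, cell size and mask", call. = FALSE)
  invisible(TRUE)
}
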