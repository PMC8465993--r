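# small in-code fixtures shared across test files

# a tiny land-use map from a vector of codes (filled column-major)
tiny_map <- function(codes, nrow = 1, cell = 1) {
  land_use_map(matrix(codes, nrow = nrow), cell_size_km = cell)
}

# constant raster helper
const_raster <- function(value, nr = 1, nc = 1, cell = 1) {
  grid_raster(matrix(value, nr, nc), cell_size_km = cell)
}

# a driver stack of named constant/matrix layers
stack_of <- function(..., cell = 1) {
  layers <- list(...)
  driver_stack(lapply(layers, function(m) grid_raster(as.matrix(m), cell)))
}

# a minimal logistic_model object for closed-form probability checks
manual_model <- function(intercept, coefficients,
                         center = NULL, scale = NULL) {
  nm <- names(coefficients)
  structure(
    list(class_code = 1L, class_name = "forest",
         intercept = intercept, coefficients = coefficients,
         selected_drivers = nm,
         center = center %||% setNames(rep(0, length(nm)), nm),
         scale = scale %||% setNames(rep(1, length(nm)), nm),
         p_values = setNames(rep(NA_real_, length(nm)), nm),
         ridge = FALSE, n = 0L, share = NA_real_, roc = NA_real_),
    class = "logistic_model")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a spatially uniform climate stack with one configurable month
one_month_climate <- function(precip, temp, rh, wind, month = 5,
                              fill = list(precip = 1000, temp = 0, rh = 0.99,
                                          wind = 0),
                              days = NULL, wind_height_m = 2) {
  P <- rep(fill$precip, 12); Tm <- rep(fill$temp, 12)
  r <- rep(fill$rh, 12); u <- rep(fill$wind, 12)
  P[month] <- precip; Tm[month] <- temp; r[month] <- rh; u[month] <- wind
  args <- list(precip = P, temp = Tm, rh = r, wind = u,
               wind_height_m = wind_height_m)
  if (!is.null(days)) args$days <- days
  do.call(climate_stack, args)
}
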