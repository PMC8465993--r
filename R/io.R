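#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text ESRI ASCII grid (`.asc`) I/O for [grid_raster] and
#' [land_use_map] objects. The header's `cellsize` is interpreted in
#' kilometres and `NODATA_value` cells become the nodata mask. Values and mask
#' round-trip exactly at the written precision. Land-use rasters are validated
#' against the class codes 1..6; an unknown code is a validation error naming
#' the offending values.
#'
#' @param path File path.
#' @param kind `"grid"` for a continuous raster, `"landuse"` for a
#'   categorical map.
#' @return `read_raster`: a `grid_raster` or `land_use_map`.
#' @export
read_raster <- function(path, kind = c("grid", "landuse")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[2]))))
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path, call. = FALSE)
  nodata <- hdr[["nodata_value"]] %||% -9999
  n_hdr <- length(hdr) + if (is.null(hdr[["nodata_value"]])) 0L else 0L
  # header lines are those at the top matching "key value"
  all_lines <- readLines(path)
  is_hdr <- grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", all_lines)
  body_start <- which(!is_hdr)[1]
  vals <- scan(text = paste(all_lines[body_start:length(all_lines)],
                            collapse = "\n"), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("grid body has ", length(vals), " values; expected ", nr * nc,
         call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == nodata
  m[mask] <- NA_real_
  if (kind == "grid") return(grid_raster(m, hdr$cellsize, mask))
  codes <- m[!mask]
  bad <- setdiff(unique(codes), landuse_classes)
  if (length(bad))
    stop("land-use raster contains invalid class code(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  land_use_map(m, hdr$cellsize, mask)
}

#' @rdname read_raster
#' @param x A [grid_raster] or [land_use_map] to write.
#' @param digits Significant digits written for continuous rasters.
#' @export
write_raster <- function(x, path, digits = 10) {
  if (inherits(x, "land_use_map")) {
    m <- matrix(as.numeric(x$codes), nrow(x$codes), ncol(x$codes))
    mask <- x$mask
    cell <- x$cell_size_km
  } else if (inherits(x, "grid_raster")) {
    m <- x$values; mask <- x$mask; cell <- x$cell_size_km
  } else stop("`x` must be a grid_raster or land_use_map", call. = FALSE)
  m[mask] <- -9999
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cell),
    "NODATA_value -9999"
  )
  body <- apply(m, 1, function(row)
    paste(formatC(row, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and validate a run configuration
#'
#' A run configuration is a single YAML file holding the scene specification,
#' allocation parameters, demand scenario modifiers, grading thresholds and
#' runoff coefficients, all with documented defaults. The schema is validated
#' before any computation: unknown keys are rejected and required keys must be
#' present.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_config
#' @param config A raw configuration list (e.g. from [yaml::read_yaml()]).
#' @export
validate_config <- function(config) {
  known <- c("scene", "seed", "allocation", "scenario", "grading_thresholds",
             "runoff_coefficients", "start_year", "horizon_year", "step_years",
             "historical_artificial_growth", "n_species", "output_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  required <- c("scene", "seed")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("missing required configuration key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sc <- config$scene
  sc_req <- c("n_rows", "n_cols")
  miss <- setdiff(sc_req, names(sc))
  if (length(miss))
    stop("missing required scene key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  coef <- sc$logistic_coefficients
  if (!is.null(coef)) coef <- lapply(coef, unlist)
  spec <- scene_spec(
    n_rows = sc$n_rows, n_cols = sc$n_cols, seed = config$seed,
    logistic_coefficients = coef %||% default_true_coefficients(),
    spatial_smoothness = sc$spatial_smoothness %||% 4,
    runoff_coefficients = unlist(config$runoff_coefficients) %||%
      c(forest = 0.15, grassland = 0.25, wetland = 0.05, cultivated = 0.35,
        artificial = 0.6, other = 0.45),
    cell_size_km = sc$cell_size_km %||% 1
  )
  thr <- unlist(config$grading_thresholds) %||% c(0.35, 0.65, 0.85)
  alloc <- config$allocation %||% list()
  params <- allocation_params(
    elasticity = unlist(alloc$elasticity) %||%
      c(forest = 0.6, grassland = 0.6, wetland = 1.0, cultivated = 0.4,
        artificial = 0.9, other = 0.3),
    tolerance_frac = alloc$tolerance_frac %||% 0.001,
    max_iterations = alloc$max_iterations %||% 1000L,
    step_size = alloc$step_size %||% 0.05
  )
  structure(
    list(spec = spec, params = params,
         scenario = list(
           outflow = unlist(config$scenario$outflow) %||% c(wetland = 0),
           inflow = unlist(config$scenario$inflow)),
         grading_thresholds = thr,
         start_year = config$start_year %||% 2015L,
         horizon_year = config$horizon_year %||% 2025L,
         step_years = config$step_years %||% 5L,
         historical_artificial_growth =
           config$historical_artificial_growth %||% 0.15,
         n_species = config$n_species %||% 5L,
         output_dir = config$output_dir),
    class = "run_config")
}
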