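#' Suitability surfaces for all six classes
#'
#' Computes per-class probability surfaces from fitted models. A class with no
#' fitted model (degenerate share) falls back to a flat surface at its
#' observed share, with a warning, so the allocator always has six surfaces.
#'
#' @param models Named list of `logistic_model`s (a subset of the six classes).
#' @param drivers A [driver_stack].
#' @param map The [land_use_map] supplying observed shares for fallbacks.
#' @return Named list of six probability [grid_raster]s.
#' @export
probability_surfaces <- function(models, drivers, map) {
  shares <- area_stats(map)
  shares <- setNames(shares$area_km2 / sum(shares$area_km2), shares$class_name)
  out <- list()
  for (k in landuse_labels) {
    if (!is.null(models[[k]])) {
      out[[k]] <- probability_surface(models[[k]], drivers)
    } else {
      warning("no fitted model for class ", k,
              "; using a flat surface at its observed share", call. = FALSE)
      out[[k]] <- grid_raster(
        matrix(shares[[k]], nrow(drivers$mask), ncol(drivers$mask)),
        drivers$cell_size_km, drivers$mask)
    }
  }
  out
}

# internal: per-class vegetation cover factor raster
cover_factor_raster <- function(map,
                                cover = c(forest = 0.01, grassland = 0.08,
                                          wetland = 0.0, cultivated = 0.25,
                                          artificial = 1.0, other = 0.7)) {
  v <- cover[landuse_labels][map$codes]
  v <- matrix(unname(v), nrow(map$codes), ncol(map$codes))
  v[map$mask] <- NA_real_
  grid_raster(v, map$cell_size_km, map$mask)
}

#' Run the full synthetic-scene analysis pipeline
#'
#' Chains every stage on one synthetic scene: generate the landscape; fit the
#' six suitability models (with ROC); build an observed "historical" change by
#' reallocating a configured artificial-surface expansion out of cultivated
#' land; derive the transfer matrix, Markov transition probabilities and
#' scenario-adjusted yearly demand; simulate maps to the horizon year; compute
#' the four ecosystem services; grade them and their maximum-value overlay;
#' and account for urban encroachment on the graded services. Optionally
#' writes the tabular outputs as CSV (plus models as YAML and maps as ASCII
#' grids) to `output_dir`.
#'
#' @param config A `run_config` from [read_config()]/[validate_config()], or a
#'   plain list in that schema.
#' @param output_dir Optional output directory (overrides the config's).
#' @return A list with elements `scene`, `models`, `model_summary` (tibble),
#'   `map_t0`, `map_t1`, `transfer`, `transition_probs`, `demand`, `kappa_fit`,
#'   `simulated` (yearly maps), `services` (per-service results),
#'   `importance` (per-service + `combined` importance maps),
#'   `grade_stats` (tibble over services), `new_artificial`, `encroachment`,
#'   `encroachment_totals`.
#' @export
run_scene_report <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  spec <- config$spec
  message(sprintf("run: seed=%d config_hash=%s ecoclues=%s R=%s",
                  spec$seed, rlang::hash(config),
                  as.character(utils::packageVersion("ecoclues")),
                  as.character(getRversion())))
  scene <- generate_scene(spec, n_species = config$n_species)
  map_t0 <- scene$landuse
  drivers <- scene$drivers

  models <- fit_all_classes(map_t0, drivers)
  model_summary <- purrr::map_dfr(models, glance)
  probs <- probability_surfaces(models, drivers, map_t0)

  # historical change: grow artificial out of cultivated by the configured
  # fraction, allocated competitively over the fitted surfaces
  areas0 <- setNames(area_stats(map_t0)$area_km2, landuse_labels)
  g <- config$historical_artificial_growth
  shift <- min(g * areas0[["artificial"]], 0.5 * areas0[["cultivated"]])
  demand_t1 <- areas0
  demand_t1[["artificial"]] <- demand_t1[["artificial"]] + shift
  demand_t1[["cultivated"]] <- demand_t1[["cultivated"]] - shift
  hist_params <- config$params
  hist_params$restricted_mask <- NULL
  map_t1 <- allocate_year(map_t0, probs, demand_t1, hist_params)

  tm <- transfer_matrix(map_t0, map_t1)
  kappa_fit <- kappa_agreement(map_t0, map_t1)
  tp <- estimate_transition_probs(tm)
  areas1 <- setNames(area_stats(map_t1)$area_km2, landuse_labels)
  demand <- project_demand(tp, areas1, config$start_year, config$horizon_year,
                           config$step_years,
                           outflow = config$scenario$outflow,
                           inflow = config$scenario$inflow)
  simulated <- simulate_landuse(map_t1, probs, demand, config$params)
  map_h <- simulated[[as.character(config$horizon_year)]]

  # services on the start-of-simulation landscape
  P <- drivers$layers$rainfall
  R <- estimate_runoff(P, map_t1, spec$runoff_coefficients)
  ET <- annual_evapotranspiration(scene$climate)
  water <- water_conservation(P, R, ET, map_t1)
  slope <- drivers$layers$slope
  soil <- soil_conservation(
    r_f = grid_raster(0.18 * P$values, P$cell_size_km, P$mask),
    k_f = scene$soil_k_usle, l_f = 1,
    s_f = slope_s_factor(slope),
    c_f = cover_factor_raster(map_t1))
  fq <- climate_erosivity(scene$climate)
  sand <- sand_fixation(scene$npp, scene$soil_k_wind, fq,
                        surface_roughness(slope))
  bio <- biodiversity_suitability(scene$species, drivers)

  thr <- config$grading_thresholds
  imp <- list(
    WaterConservation = grade(water$per_cell, thr),
    SoilConservation = grade(soil$a_c, thr),
    SandFixation = grade(sand, thr),
    Biodiversity = grade(bio, thr)
  )
  imp$combined <- combined_importance(imp)
  gstats <- purrr::map_dfr(imp, grade_stats, .id = "service")

  na <- new_artificial(map_t1, map_h)
  enc <- encroachment_table(na, imp[c("WaterConservation", "SoilConservation",
                                      "SandFixation", "Biodiversity")])
  enc_tot <- encroachment_totals(enc)

  out <- list(
    scene = scene, models = models, model_summary = model_summary,
    map_t0 = map_t0, map_t1 = map_t1, transfer = tm,
    transition_probs = tp, demand = demand, kappa_fit = kappa_fit,
    simulated = simulated,
    services = list(water = water, soil = soil, sand = sand,
                    biodiversity = bio),
    importance = imp, grade_stats = gstats,
    new_artificial = na, encroachment = enc, encroachment_totals = enc_tot
  )
  output_dir <- output_dir %||% config$output_dir
  if (!is.null(output_dir)) write_report(out, output_dir)
  out
}

#' Write the tabular outputs of a pipeline run
#'
#' Emits the transfer matrix (with marginal totals), yearly demand, per-service
#' grade statistics (Function Level / Acreage / Area ratio layout, two-decimal
#' fixed point), the encroachment combination rows and severity totals, the
#' per-class model summary, the fitted models (YAML) and the start/horizon
#' land-use maps (ASCII grid).
#'
#' @param result The list returned by [run_scene_report()].
#' @param output_dir Directory to create/write into.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  write_transfer_csv(result$transfer, p("transfer_matrix.csv"))
  write_demand_csv(result$demand, p("demand.csv"))
  gs <- result$grade_stats %>%
    dplyr::transmute(
      service = .data$service,
      `Function Level` = .data$level,
      `Acreage (km2)` = sprintf("%.2f", .data$acreage_km2),
      `Area ratio (%)` = sprintf("%.2f", .data$area_ratio_pct))
  readr::write_csv(gs, p("grade_stats.csv"))
  enc <- result$encroachment %>%
    dplyr::transmute(
      `Invaded Eco-service function` = .data$severity,
      Type = .data$combination,
      `Acreage/km2` = sprintf("%.2f", .data$acreage_km2))
  readr::write_csv(enc, p("encroachment.csv"))
  readr::write_csv(
    dplyr::mutate(result$encroachment_totals,
                  total_acreage_km2 = sprintf("%.2f", .data$total_acreage_km2)),
    p("encroachment_totals.csv"))
  readr::write_csv(result$model_summary, p("model_summary.csv"))
  write_models_yaml(result$models, p("models.yaml"))
  write_raster(result$map_t1, p("landuse_start.asc"))
  last <- result$simulated[[length(result$simulated)]]
  write_raster(last, p("landuse_horizon.asc"))
  invisible(output_dir)
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `ecoclues` script (see
#' `system.file("cli", "ecoclues.R", package = "ecoclues")`). Subcommands:
#' `synth` (write a synthetic scene's rasters and occurrences), `transfer`
#' (transfer matrix CSV from two land-use rasters), `demand` (Markov demand
#' CSV from a transfer CSV), `fit` (suitability models YAML), `simulate`,
#' `services`, `grade`, `overlay` and `report` (chain
#' services -> grade -> overlay and emit the classification and encroachment
#' CSVs). Exit status 0 on success, 2 on a validation/usage error.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(argv = character()) {
  usage <- paste(
    "usage: ecoclues <subcommand> [--key value ...]",
    "subcommands:",
    "  synth    --config run.yaml --out dir           write synthetic scene",
    "  transfer --t0 a.asc --t1 b.asc --out t.csv     transfer matrix",
    "  demand   --transfer t.csv --out d.csv",
    "           [--start-year Y --horizon-year Y --step-years N]",
    "  fit      --config run.yaml --out models.yaml   suitability models",
    "  simulate --config run.yaml --out dir           yearly maps",
    "  services --config run.yaml --out dir           service rasters",
    "  grade    --service s.asc --out stats.csv       grade one service",
    "  overlay  --config run.yaml --out dir           encroachment tables",
    "  report   --config run.yaml --out dir           full pipeline",
    "common:   --seed N overrides the config seed",
    sep = "\n")
  fail <- function(...) {
    message(...)
    message(usage)
    invisible(2L)
  }
  if (!length(argv)) return(fail("no subcommand given"))
  sub <- argv[1]
  args <- argv[-1]
  if (length(args) %% 2 != 0 || any(!grepl("^--", args[c(TRUE, FALSE)])))
    return(fail("flags must come in --key value pairs"))
  opts <- setNames(as.list(args[c(FALSE, TRUE)]),
                   sub("^--", "", args[c(TRUE, FALSE)]))
  need <- function(keys) {
    miss <- setdiff(keys, names(opts))
    if (length(miss))
      stop("missing required flag(s): ",
           paste0("--", miss, collapse = ", "), call. = FALSE)
  }
  load_cfg <- function() {
    need(c("config"))
    cfg <- read_config(opts$config)
    if (!is.null(opts$seed)) {
      cfg$spec$seed <- as.integer(opts$seed)
    }
    cfg
  }
  res <- tryCatch({
    switch(sub,
      synth = {
        cfg <- load_cfg(); need("out")
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        scene <- generate_scene(cfg$spec, n_species = cfg$n_species)
        write_raster(scene$dem, file.path(opts$out, "dem.asc"))
        for (nm in names(scene$drivers$layers))
          write_raster(scene$drivers$layers[[nm]],
                       file.path(opts$out, paste0("driver_", nm, ".asc")))
        write_raster(scene$landuse, file.path(opts$out, "landuse.asc"))
        write_raster(scene$npp, file.path(opts$out, "npp.asc"))
        readr::write_csv(tibble::as_tibble(scene$species),
                         file.path(opts$out, "occurrences.csv"))
        0L
      },
      transfer = {
        need(c("t0", "t1", "out"))
        tm <- transfer_matrix(read_raster(opts$t0, "landuse"),
                              read_raster(opts$t1, "landuse"))
        write_transfer_csv(tm, opts$out)
        0L
      },
      demand = {
        need(c("transfer", "out"))
        tt <- readr::read_csv(opts$transfer, show_col_types = FALSE)
        m <- as.matrix(tt[tt$use_type != "total",
                          landuse_labels])
        rownames(m) <- colnames(m) <- landuse_labels
        tp <- estimate_transition_probs(m)
        initial <- colSums(m)
        d <- project_demand(
          tp, initial,
          as.integer(opts[["start-year"]] %||% 2015),
          as.integer(opts[["horizon-year"]] %||% 2025),
          as.integer(opts[["step-years"]] %||% 5))
        write_demand_csv(d, opts$out)
        0L
      },
      fit = {
        cfg <- load_cfg(); need("out")
        scene <- generate_scene(cfg$spec, n_species = cfg$n_species)
        write_models_yaml(fit_all_classes(scene$landuse, scene$drivers),
                          opts$out)
        0L
      },
      grade = {
        need(c("service", "out"))
        st <- grade_stats(grade(read_raster(opts$service, "grid")))
        readr::write_csv(
          dplyr::transmute(st, `Function Level` = .data$level,
                           `Acreage (km2)` = sprintf("%.2f", .data$acreage_km2),
                           `Area ratio (%)` = sprintf("%.2f", .data$area_ratio_pct)),
          opts$out)
        0L
      },
      simulate = ,
      services = ,
      overlay = ,
      report = {
        cfg <- load_cfg(); need("out")
        run_scene_report(cfg, output_dir = opts$out)
        0L
      },
      return(fail("unknown subcommand: ", sub))
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(as.integer(res))
}
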