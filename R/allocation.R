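#' Allocation parameters
#'
#' Controls for the iterative competitive allocator. `elasticity` is the
#' per-class conversion resistance in `[0, 1]`: 1 means cells of the class are
#' never converted away; 0 means freely convertible; intermediate values add
#' incumbency weight. `conversion_allowed` is a 6 x 6 logical matrix (rows =
#' current class, columns = target class; diagonal must be `TRUE`).
#' `restricted_mask` freezes individual cells regardless of class.
#'
#' The defaults reflect strict protection of water bodies (wetland 1.0), high
#' persistence of built land (artificial 0.9), moderate persistence of forest
#' and grassland (0.6), and more mobile cultivated (0.4) and other (0.3) land;
#' they are configuration, not claimed empirical values.
#'
#' @param elasticity Named per-class numeric in `[0, 1]`.
#' @param conversion_allowed 6 x 6 logical matrix; default all allowed.
#' @param restricted_mask Optional logical matrix; `TRUE` cells never change.
#' @param tolerance_frac Convergence tolerance as a fraction of total area.
#' @param max_iterations Iteration cap for the balancing loop.
#' @param step_size Additive ITER update gain (eta).
#' @return An `allocation_params` object.
#' @export
allocation_params <- function(elasticity = c(forest = 0.6, grassland = 0.6,
                                             wetland = 1.0, cultivated = 0.4,
                                             artificial = 0.9, other = 0.3),
                              conversion_allowed = matrix(TRUE, 6, 6),
                              restricted_mask = NULL,
                              tolerance_frac = 0.001,
                              max_iterations = 1000L,
                              step_size = 0.05) {
  el <- setNames(rep(0.5, 6), landuse_labels)
  el[names(elasticity)] <- elasticity
  if (any(el < 0 | el > 1)) stop("elasticity must lie in [0, 1]", call. = FALSE)
  conversion_allowed <- as.matrix(conversion_allowed)
  if (!identical(dim(conversion_allowed), c(6L, 6L)) ||
      !is.logical(conversion_allowed))
    stop("`conversion_allowed` must be a 6 x 6 logical matrix", call. = FALSE)
  if (!all(diag(conversion_allowed)))
    stop("the diagonal of `conversion_allowed` must be TRUE", call. = FALSE)
  structure(
    list(elasticity = el, conversion_allowed = conversion_allowed,
         restricted_mask = restricted_mask,
         tolerance_frac = tolerance_frac,
         max_iterations = as.integer(max_iterations),
         step_size = step_size),
    class = "allocation_params")
}

#' Allocate one year of demand over suitability surfaces
#'
#' The spatial core of the model: each unmasked, unrestricted cell is assigned
#' the admissible class maximizing its total probability
#' `TPROP_u = P_u + ELAS_u * [u is the current class] + ITER_u`, where `P_u`
#' is the suitability surface, the elasticity term rewards incumbency, and
#' `ITER_u` is a per-class balancing variable. After each assignment pass the
#' allocated areas are compared with the demanded areas and
#' `ITER_u <- ITER_u + eta * (demand_u - allocated_u) / total_area`; the loop
#' repeats until every class is within `tolerance_frac * total_area` of its
#' demand, or errors after `max_iterations` with the last residuals attached.
#'
#' Admissibility: the target class must be reachable under
#' `conversion_allowed[current, target]`, and a cell whose current class has
#' elasticity 1 never converts away. Ties are broken towards the lowest class
#' code. Restricted cells keep their class.
#'
#' @param current A [land_use_map].
#' @param probs Named list of per-class suitability [grid_raster]s (names =
#'   class names, all six present).
#' @param demand Named per-class demanded areas (km^2) summing to the total
#'   unmasked area within tolerance.
#' @param params An [allocation_params()].
#' @return A converged [land_use_map] with attributes `iterations` and
#'   `residuals` (km^2, demand minus allocated) and a `convergence_log`
#'   tibble (`iteration`, `class_name`, `residual_km2`).
#' @export
allocate_year <- function(current, probs, demand, params = allocation_params()) {
  stopifnot(inherits(current, "land_use_map"))
  miss <- setdiff(landuse_labels, names(probs))
  if (length(miss))
    stop("suitability surface(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cell_area <- current$cell_size_km^2
  keep <- !current$mask
  n <- sum(keep)
  total_area <- n * cell_area
  demand <- demand[landuse_labels]
  if (anyNA(demand))
    stop("demand must name all six classes", call. = FALSE)
  if (abs(sum(demand) - total_area) > max(1e-6, params$tolerance_frac) * total_area)
    stop("demand must sum to the total unmasked area", call. = FALSE)

  P <- vapply(landuse_labels, function(k) probs[[k]]$values[keep], numeric(n))
  cur <- current$codes[keep]
  frozen <- if (!is.null(params$restricted_mask))
    params$restricted_mask[keep] else rep(FALSE, n)
  frozen <- frozen | params$elasticity[cur] >= 1
  adm <- params$conversion_allowed[cur, , drop = FALSE]

  base <- P
  base[!adm] <- -Inf
  base[cbind(seq_len(n), cur)] <- P[cbind(seq_len(n), cur)] +
    params$elasticity[cur]

  iter <- rep(0, 6)
  # residuals are normalized by each class's own demand (not the total area)
  # so minority classes receive usable update steps; a per-class gain shrinks
  # on sign flips and grows under persistent one-sided residuals
  gain <- rep(1, 6)
  prev_resid <- rep(NA_real_, 6)
  denom <- pmax(demand, cell_area)
  log_rows <- vector("list", params$max_iterations)
  for (it in seq_len(params$max_iterations)) {
    tprop <- sweep(base, 2, iter, `+`)
    assigned <- max.col(tprop, ties.method = "first")
    assigned[frozen] <- cur[frozen]
    allocated <- tabulate(assigned, nbins = 6L) * cell_area
    resid <- demand - allocated
    log_rows[[it]] <- tibble::tibble(
      iteration = it, class_name = landuse_labels,
      residual_km2 = unname(resid))
    if (all(abs(resid) <= params$tolerance_frac * total_area)) {
      codes <- current$codes
      codes[keep] <- assigned
      out <- land_use_map(codes, current$cell_size_km, current$mask)
      attr(out, "iterations") <- it
      attr(out, "residuals") <- resid
      attr(out, "convergence_log") <- dplyr::bind_rows(log_rows[seq_len(it)])
      return(out)
    }
    flipped <- !is.na(prev_resid) & sign(resid) != sign(prev_resid) & resid != 0
    gain <- ifelse(flipped, pmax(gain * 0.5, 0.01), pmin(gain * 1.1, 20))
    prev_resid <- resid
    iter <- iter + params$step_size * gain * resid / denom
  }
  stop(sprintf(
    "allocation did not converge in %d iterations; worst residual %.3f km^2 (%s)",
    params$max_iterations, max(abs(resid)),
    landuse_labels[which.max(abs(resid))]), call. = FALSE)
}

#' Simulate land-use maps through a demand horizon
#'
#' Chains [allocate_year()] from a start map through every year of the demand
#' series, each year seeded with the previous year's map. Suitability surfaces
#' are treated as static (drivers are not year-varying here).
#'
#' @param start A [land_use_map] for the first year of `demand_series`.
#' @param probs Named list of per-class suitability [grid_raster]s.
#' @param demand_series A `demand_series` tibble (see [project_demand()]).
#' @param params An [allocation_params()].
#' @return Named list (`"<year>"`) of yearly [land_use_map]s, the first entry
#'   being `start` itself.
#' @export
simulate_landuse <- function(start, probs, demand_series,
                             params = allocation_params()) {
  years <- sort(unique(demand_series$year))
  maps <- setNames(vector("list", length(years)), as.character(years))
  maps[[1]] <- start
  for (i in seq_along(years)[-1]) {
    maps[[i]] <- allocate_year(maps[[i - 1]], probs,
                               demand_at(demand_series, years[i]), params)
  }
  maps
}
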