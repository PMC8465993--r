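#' Transition probabilities from a transfer matrix
#'
#' Row-normalizes a class-to-class area transfer matrix into a stochastic
#' matrix of transition probabilities over one observation interval. A class
#' absent at t0 (zero row) is given an identity row (it stays itself), with a
#' warning.
#'
#' @param tm A [transfer_matrix()] or plain non-negative K x K matrix.
#' @return A `transition_probabilities` matrix: rows sum to 1.
#' @export
estimate_transition_probs <- function(tm) {
  m <- unclass(tm)[, , drop = FALSE]
  if (any(m < 0)) stop("transfer matrix entries must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  p <- m
  zero <- rs == 0
  if (any(zero)) {
    warning("class(es) absent at t0 given identity transition row: ",
            paste(rownames(m)[zero] %||% which(zero), collapse = ", "),
            call. = FALSE)
    p[zero, ] <- 0
    p[cbind(which(zero), which(zero))] <- 1
    rs[zero] <- 1
  }
  p <- p / rs
  structure(p, class = c("transition_probabilities", "matrix"))
}

#' @export
print.transition_probabilities <- function(x, ...) {
  cat("<transition_probabilities> rows sum to 1\n")
  print(round(unclass(x)[, ], 4))
  invisible(x)
}

#' Apply scenario modifiers to a transition matrix
#'
#' Scenario adjustments are per-class multiplicative factors on the
#' off-diagonal transition probabilities: `outflow` scales every off-diagonal
#' entry of a class's row (0 = strict protection, the class never leaves;
#' 1 = neutral; >1 = accelerated loss) and `inflow` scales every off-diagonal
#' entry of a class's column (growth slow-down or acceleration). Rows are
#' re-normalized through the diagonal; a modifier that would drive a diagonal
#' negative is a validation error.
#'
#' @param probs A [estimate_transition_probs()] matrix.
#' @param outflow,inflow Named per-class multipliers (defaults all 1).
#' @return A modified `transition_probabilities` matrix.
#' @export
apply_scenario <- function(probs, outflow = NULL, inflow = NULL) {
  p <- unclass(probs)[, , drop = FALSE]
  K <- nrow(p)
  labs <- rownames(p) %||% as.character(seq_len(K))
  o <- setNames(rep(1, K), labs); i <- setNames(rep(1, K), labs)
  if (!is.null(outflow)) o[names(outflow)] <- outflow
  if (!is.null(inflow)) i[names(inflow)] <- inflow
  if (any(o < 0) || any(i < 0))
    stop("scenario modifiers must be non-negative", call. = FALSE)
  off <- matrix(TRUE, K, K); diag(off) <- FALSE
  p[off] <- (p * outer(o, rep(1, K)) * outer(rep(1, K), i))[off]
  diag(p) <- 1 - (rowSums(p) - diag(p))
  if (any(diag(p) < -1e-12))
    stop("scenario modifiers produce a negative staying probability for: ",
         paste(labs[diag(p) < 0], collapse = ", "), call. = FALSE)
  diag(p) <- pmax(diag(p), 0)
  structure(p / rowSums(p), class = c("transition_probabilities", "matrix"))
}

#' Project per-class land-use demand by a Markov chain
#'
#' Propagates the per-class area vector through the step-transition matrix
#' (left multiplication, one application per observation step) and linearly
#' interpolates to yearly demand for the spatial allocator. Total area is
#' conserved at every year. Scenario modifiers (see [apply_scenario()]) are
#' applied to the transition matrix before projection.
#'
#' @param probs A `transition_probabilities` matrix for one step interval.
#' @param initial_areas Named per-class areas (km^2) at `start_year`.
#' @param start_year,horizon_year Projection window; `step_years` must divide
#'   `horizon_year - start_year`.
#' @param step_years Observation-interval length in years (default 5).
#' @param outflow,inflow Optional scenario modifiers.
#' @return A `demand_series` tibble: columns `year`, `class_code`,
#'   `class_name`, `area_km2`.
#' @export
project_demand <- function(probs, initial_areas, start_year, horizon_year,
                           step_years = 5L, outflow = NULL, inflow = NULL) {
  K <- nrow(unclass(probs))
  span <- horizon_year - start_year
  if (span < 0 || span %% step_years != 0)
    stop("`step_years` must divide the projection span", call. = FALSE)
  if (any(initial_areas < 0)) stop("areas must be non-negative", call. = FALSE)
  labs <- rownames(unclass(probs)) %||% names(initial_areas) %||%
    as.character(seq_len(K))
  a <- as.numeric(initial_areas)[match(labs, names(initial_areas) %||% labs)]
  p <- apply_scenario(probs, outflow, inflow)
  n_steps <- span %/% step_years
  steps <- matrix(NA_real_, n_steps + 1L, K)
  steps[1, ] <- a
  for (s in seq_len(n_steps))
    steps[s + 1L, ] <- as.numeric(steps[s, ] %*% unclass(p))
  years <- start_year:horizon_year
  per_year <- vapply(seq_len(K), function(k)
    stats::approx(start_year + step_years * (0:n_steps), steps[, k],
                  xout = years)$y, numeric(length(years)))
  code <- match(labs, landuse_labels)
  code[is.na(code)] <- which(is.na(code))
  out <- tibble::tibble(
    year = rep(years, times = K),
    class_code = rep(code, each = length(years)),
    class_name = rep(labs, each = length(years)),
    area_km2 = as.vector(per_year)
  )
  out <- dplyr::arrange(out, .data$year, .data$class_code)
  structure(out, class = c("demand_series", class(out)))
}

#' Demand at one year as a named vector
#'
#' @param demand A `demand_series` tibble.
#' @param year Year to extract.
#' @return Named per-class areas (km^2).
#' @export
demand_at <- function(demand, year) {
  d <- dplyr::filter(demand, .data$year == !!year)
  if (!nrow(d)) stop("year ", year, " not present in the demand series", call. = FALSE)
  setNames(d$area_km2, d$class_name)
}

#' Read or write a demand series as CSV
#'
#' @param demand A `demand_series` tibble.
#' @param path CSV path (`year, class, area_km2`).
#' @return `write_demand_csv` the path invisibly; `read_demand_csv` a
#'   `demand_series` tibble.
#' @export
write_demand_csv <- function(demand, path) {
  readr::write_csv(
    dplyr::select(tibble::as_tibble(demand), "year",
                  class = "class_name", "area_km2"),
    path)
  invisible(path)
}

#' @rdname write_demand_csv
#' @export
read_demand_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("year", "class", "area_km2") %in% names(d)))
  out <- tibble::tibble(
    year = as.integer(d$year),
    class_code = match(d$class, landuse_labels),
    class_name = d$class,
    area_km2 = as.numeric(d$area_km2)
  )
  structure(dplyr::arrange(out, .data$year, .data$class_code),
            class = c("demand_series", class(out)))
}
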