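#' Importance level labels
#'
#' The four ordinal importance levels, from highest to lowest:
#' Very Important, Important, Moderate, Common. Stored internally as integers
#' 4 (Very Important) down to 1 (Common).
#'
#' @export
importance_levels <- c("Very Important", "Important", "Moderate", "Common")

# internal: level integer (4..1) -> label
level_label <- function(lv) importance_levels[5L - lv]

#' Grade a service raster into four importance levels
#'
#' Each cell is ranked by its contribution to the service total: cells are
#' sorted descending (ties broken by row-major index) and the minimal prefix
#' whose cumulative share of the total reaches `thresholds[1]` is graded
#' Very Important; continuing down the ranking, cells up to cumulative share
#' `thresholds[2]` are Important and up to `thresholds[3]` Moderate; the
#' remainder is Common. Negative service values are floored at zero before
#' grading. An all-zero raster grades every cell Common, with a warning.
#'
#' @param service A [grid_raster] of service quantities.
#' @param thresholds Increasing cumulative-share cut points in (0, 1).
#' @return An `importance_map`: integer levels 4 (Very Important) .. 1
#'   (Common) with the raster's cell size and mask.
#' @export
grade <- function(service, thresholds = c(0.35, 0.65, 0.85)) {
  stopifnot(inherits(service, "grid_raster"))
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0) ||
      any(thresholds <= 0 | thresholds >= 1))
    stop("`thresholds` must be three increasing values in (0, 1)", call. = FALSE)
  v <- pmax(service$values, 0)
  v[service$mask] <- NA_real_
  idx <- which(!service$mask)
  total <- sum(v[idx])
  lv <- matrix(NA_integer_, nrow(v), ncol(v))
  if (total <= 0) {
    warning("service raster is zero everywhere; all cells graded Common",
            call. = FALSE)
    lv[idx] <- 1L
  } else {
    ord <- idx[order(-v[idx], idx)]
    cum_before <- c(0, cumsum(v[ord]))[seq_along(ord)] / total
    band <- ifelse(cum_before < thresholds[1], 4L,
            ifelse(cum_before < thresholds[2], 3L,
            ifelse(cum_before < thresholds[3], 2L, 1L)))
    lv[ord] <- band
  }
  structure(
    list(levels = lv, cell_size_km = service$cell_size_km,
         mask = service$mask),
    class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %d x %d cells (%.3g km)\n",
              nrow(x$levels), ncol(x$levels), x$cell_size_km))
  print(table(factor(level_label(x$levels[!x$mask]),
                     levels = importance_levels)))
  invisible(x)
}

#' Per-level acreage and area-ratio statistics
#'
#' For an importance map, per-level acreage is the cell count times the cell
#' area; area ratios are percentages of the summed level acreages, reported to
#' two decimals. A numeric method accepts already-tabulated acreages (named or
#' ordered Very Important, Important, Moderate, Common) so that published
#' classification tables can be re-derived directly.
#'
#' @param x An `importance_map`, or a numeric vector of four acreages (km^2).
#' @param ... Unused.
#' @return A `grade_stats` tibble: `level`, `acreage_km2`, `area_ratio_pct`
#'   (two decimals).
#' @export
grade_stats <- function(x, ...) UseMethod("grade_stats")

#' @rdname grade_stats
#' @export
grade_stats.importance_map <- function(x, ...) {
  counts <- vapply(4:1, function(l) sum(x$levels[!x$mask] == l), numeric(1))
  grade_stats(setNames(counts * x$cell_size_km^2, importance_levels))
}

#' @rdname grade_stats
#' @export
grade_stats.numeric <- function(x, ...) {
  if (length(x) != 4) stop("expected four per-level acreages", call. = FALSE)
  if (!is.null(names(x))) x <- x[importance_levels]
  if (anyNA(x) || any(x < 0)) stop("acreages must be non-negative", call. = FALSE)
  out <- tibble::tibble(
    level = importance_levels,
    acreage_km2 = unname(x),
    area_ratio_pct = round(100 * unname(x) / sum(x), 2)
  )
  structure(out, class = c("grade_stats", class(out)))
}

#' Combine service importance maps by maximum level
#'
#' The combined importance of a cell is the highest level it attains across
#' the input services (Very Important > Important > Moderate > Common).
#' Idempotent and order-invariant.
#'
#' @param maps List of aligned `importance_map`s.
#' @return A single `importance_map`.
#' @export
combined_importance <- function(maps) {
  if (!length(maps)) stop("at least one importance map required", call. = FALSE)
  ref <- maps[[1]]
  for (m in maps[-1]) check_aligned_imp(ref, m)
  lv <- Reduce(pmax, lapply(maps, `[[`, "levels"))
  structure(list(levels = lv, cell_size_km = ref$cell_size_km, mask = ref$mask),
            class = "importance_map")
}

check_aligned_imp <- function(a, b) {
  if (!identical(dim(a$levels), dim(b$levels)) ||
      abs(a$cell_size_km - b$cell_size_km) > 1e-12 ||
      !identical(a$mask, b$mask))
    stop("importance maps must share shape, cell size and mask", call. = FALSE)
  invisible(TRUE)
}

#' Cells newly converted to artificial surface
#'
#' @param map_t0,map_t1 Aligned [land_use_map]s.
#' @return A binary [grid_raster]: 1 where the cell was not artificial at t0
#'   and is artificial at t1, 0 elsewhere.
#' @export
new_artificial <- function(map_t0, map_t1) {
  check_aligned(map_t0, map_t1, "land-use maps")
  art <- landuse_classes[["artificial"]]
  v <- (map_t0$codes != art & map_t1$codes == art) * 1
  v[map_t0$mask] <- NA_real_
  grid_raster(matrix(v, nrow(map_t0$codes), ncol(map_t0$codes)),
              map_t0$cell_size_km, map_t0$mask)
}

#' Urban-encroachment accounting over graded services
#'
#' For every newly artificial cell, the invaded set is the services whose
#' importance there is Moderate or higher. Severity is the overlap
#' cardinality: one invaded service is a Moderate encroachment (keyed by that
#' service), two an Important one (keyed by the pair), three or more a
#' Very Important one (keyed by the combination). Acreages accumulate per
#' combination; per-severity totals are exact sums of their combination rows.
#'
#' @param new_art Binary [grid_raster] from [new_artificial()].
#' @param service_maps Named list of exactly four aligned `importance_map`s
#'   (e.g. Water Conservation, Soil Conservation, Sand Fixation, Biodiversity).
#' @return An `encroachment_table` tibble: `severity`, `combination`,
#'   `acreage_km2`, ordered by severity then combination.
#' @export
encroachment_table <- function(new_art, service_maps) {
  stopifnot(inherits(new_art, "grid_raster"))
  if (length(service_maps) != 4 || is.null(names(service_maps)))
    stop("`service_maps` must be a named list of exactly four importance maps",
         call. = FALSE)
  for (m in service_maps) {
    if (!inherits(m, "importance_map"))
      stop("all service maps must be importance maps", call. = FALSE)
    if (!identical(dim(m$levels), dim(new_art$values)) ||
        !identical(m$mask, new_art$mask))
      stop("service maps must align with the new-artificial raster",
           call. = FALSE)
  }
  cells <- which(!new_art$mask & new_art$values > 0)
  cell_area <- new_art$cell_size_km^2
  empty <- tibble::tibble(severity = character(0), combination = character(0),
                          acreage_km2 = numeric(0))
  if (!length(cells))
    return(structure(empty, class = c("encroachment_table", class(empty))))
  snames <- names(service_maps)
  invaded <- vapply(service_maps, function(m) m$levels[cells] >= 2L,
                    logical(length(cells)))
  invaded <- matrix(invaded, nrow = length(cells))
  card <- rowSums(invaded)
  combo <- apply(invaded, 1, function(z) paste(snames[z], collapse = "+"))
  sev <- dplyr::case_when(
    card >= 3 ~ "Very Important",
    card == 2 ~ "Important",
    card == 1 ~ "Moderate",
    TRUE ~ NA_character_
  )
  out <- tibble::tibble(severity = sev, combination = combo) %>%
    dplyr::filter(!is.na(.data$severity)) %>%
    dplyr::count(.data$severity, .data$combination) %>%
    dplyr::mutate(acreage_km2 = .data$n * cell_area, n = NULL) %>%
    dplyr::mutate(severity = factor(.data$severity,
                                    levels = c("Moderate", "Important",
                                               "Very Important"))) %>%
    dplyr::arrange(.data$severity, .data$combination) %>%
    dplyr::mutate(severity = as.character(.data$severity))
  structure(out, class = c("encroachment_table", class(out)))
}

#' Per-severity encroachment totals
#'
#' Sums the combination rows of an encroachment table (or any tibble with
#' `severity` and `acreage_km2` columns) into one total per severity level.
#'
#' @param x An `encroachment_table` or compatible tibble.
#' @return A tibble: `severity`, `total_acreage_km2`.
#' @export
encroachment_totals <- function(x) {
  stopifnot(all(c("severity", "acreage_km2") %in% names(x)))
  tibble::as_tibble(x) %>%
    dplyr::mutate(severity = factor(.data$severity,
                                    levels = c("Moderate", "Important",
                                               "Very Important"))) %>%
    dplyr::group_by(.data$severity) %>%
    dplyr::summarise(total_acreage_km2 = sum(.data$acreage_km2),
                     .groups = "drop") %>%
    dplyr::mutate(severity = as.character(.data$severity))
}
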