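## autoplot() methods: quick-look ggplot2 figures for each result type

# internal: raster matrix -> long tibble for geom_raster
raster_tbl <- function(values, mask) {
  tibble::tibble(
    row = rep(seq_len(nrow(values)), times = ncol(values)),
    col = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(ifelse(mask, NA, values))
  )
}

#' Plot a continuous raster
#'
#' @param object A [grid_raster].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grid_raster <- function(object, ...) {
  ggplot(raster_tbl(object$values, object$mask),
         aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_viridis_c(na.value = "grey90") +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "value") +
    theme_minimal()
}

#' Plot a land-use map
#'
#' @param object A [land_use_map].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.land_use_map <- function(object, ...) {
  d <- raster_tbl(object$codes, object$mask)
  d$class <- factor(landuse_labels[d$value], levels = landuse_labels)
  pal <- c(forest = "#1b7837", grassland = "#a6dba0", wetland = "#2166ac",
           cultivated = "#fdb863", artificial = "#b2182b", other = "#bababa")
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$class)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_manual(values = pal, na.value = "grey95", drop = FALSE) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "class") +
    theme_minimal()
}

#' Plot an importance map
#'
#' @param object An `importance_map` from [grade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.importance_map <- function(object, ...) {
  d <- raster_tbl(object$levels, object$mask)
  d$level <- factor(level_label(d$value), levels = importance_levels)
  pal <- setNames(c("#b2182b", "#ef8a62", "#fddbc7", "#f7f7f7"),
                  importance_levels)
  ggplot(d, aes(x = .data$col, y = .data$row, fill = .data$level)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_manual(values = pal, na.value = "grey95", drop = FALSE) +
    coord_equal() +
    labs(x = NULL, y = NULL, fill = "importance") +
    theme_minimal()
}

#' Plot a projected demand series
#'
#' @param object A `demand_series` tibble from [project_demand()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.demand_series <- function(object, ...) {
  ggplot(tibble::as_tibble(object),
         aes(x = .data$year, y = .data$area_km2, colour = .data$class_name)) +
    geom_line() +
    labs(x = "year", y = expression(area ~ (km^2)), colour = "class") +
    theme_minimal()
}

#' Plot per-level grade statistics
#'
#' @param object A `grade_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.grade_stats <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$level <- factor(d$level, levels = importance_levels)
  ggplot(d, aes(x = .data$level, y = .data$area_ratio_pct)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "area ratio (%)") +
    theme_minimal()
}
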