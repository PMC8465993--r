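#' Class-to-class area transfer matrix between two dates
#'
#' Cross-tabulates two aligned land-use maps into a 6 x 6 matrix of areas
#' (km^2): rows are the class at the first date, columns the class at the
#' second. Row sums equal per-class areas at t0, column sums per-class areas
#' at t1, and the grand total equals the total unmasked area — exactly, since
#' entries are integer cell counts times the cell area.
#'
#' @param map_t0,map_t1 Aligned [land_use_map]s.
#' @return A `transfer_matrix`: a 6 x 6 numeric matrix with class-name
#'   dimnames and attributes `cell_size_km` and `total_area_km2`.
#' @export
transfer_matrix <- function(map_t0, map_t1) {
  stopifnot(inherits(map_t0, "land_use_map"), inherits(map_t1, "land_use_map"))
  check_aligned(map_t0, map_t1, "land-use maps")
  keep <- !map_t0$mask
  counts <- table(
    factor(map_t0$codes[keep], levels = landuse_classes),
    factor(map_t1$codes[keep], levels = landuse_classes)
  )
  m <- matrix(as.numeric(counts), 6, 6) * map_t0$cell_size_km^2
  dimnames(m) <- list(t0 = landuse_labels, t1 = landuse_labels)
  structure(m, class = c("transfer_matrix", "matrix"),
            cell_size_km = map_t0$cell_size_km,
            total_area_km2 = sum(m))
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("<transfer_matrix> areas in km^2 (rows = t0, cols = t1)\n")
  print(unclass(x)[, ], ...)
  invisible(x)
}

#' Tidy a transfer matrix into long form
#'
#' @param x A [transfer_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `area_km2`.
#' @exportS3Method generics::tidy
tidy.transfer_matrix <- function(x, ...) {
  tibble::tibble(
    from = rep(landuse_labels, times = 6),
    to = rep(landuse_labels, each = 6),
    area_km2 = as.vector(unclass(x))
  )
}

#' Cohen's kappa agreement between two categorical maps
#'
#' Chance-corrected cell-wise agreement over unmasked cells, computed jointly
#' over all six classes: `(p_o - p_e) / (1 - p_e)` with the expected agreement
#' `p_e` taken from the marginal class frequencies of the two maps. If both
#' maps are single-class and identical (`p_e = 1`), returns 1 by convention
#' with a message.
#'
#' @param map_a,map_b Aligned [land_use_map]s.
#' @return A single value in `[-1, 1]`.
#' @export
kappa_agreement <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "land_use_map"), inherits(map_b, "land_use_map"))
  check_aligned(map_a, map_b, "land-use maps")
  keep <- !map_a$mask
  a <- factor(map_a$codes[keep], levels = landuse_classes)
  b <- factor(map_b$codes[keep], levels = landuse_classes)
  n <- length(a)
  conf <- table(a, b) / n
  p_o <- sum(diag(conf))
  p_e <- sum(rowSums(conf) * colSums(conf))
  if (1 - p_e < .Machine$double.eps) {
    message("both maps are single-class and identical; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Write a transfer matrix as a CSV table with marginal totals
#'
#' Mirrors the classic transfer-table layout: one row per class at t0, one
#' column per class at t1, plus a `total` row and column.
#'
#' @param x A [transfer_matrix()].
#' @param path Output CSV path.
#' @return The written tibble, invisibly.
#' @export
write_transfer_csv <- function(x, path) {
  m <- unclass(x)[, ]
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::mutate(out, total = rowSums(m), .before = 1)
  out <- dplyr::mutate(out, use_type = landuse_labels, .before = 1)
  out <- dplyr::relocate(out, "total", .after = dplyr::last_col())
  totals <- c(use_type = "total",
              as.list(c(colSums(m), total = sum(m))))
  out <- dplyr::bind_rows(out, tibble::as_tibble(totals))
  readr::write_csv(out, path)
  invisible(out)
}
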