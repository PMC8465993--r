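test_that("the cumulative-share prefix rule grades ranked cells", {
  # [10, 5, 3, 2]: prefix shares 0.5 / 0.75 / 0.9 / 1.0
  g <- grade(grid_raster(matrix(c(10, 5, 3, 2), 1, 4)))
  expect_equal(as.vector(g$levels), c(4L, 3L, 2L, 1L))

  # uniform raster over 100 cells: 35 / 30 / 20 / 15 by the prefix rule
  u <- grade(const_raster(7, 10, 10))
  counts <- table(factor(u$levels, levels = 4:1))
  expect_equal(unname(as.vector(counts)), c(35, 30, 20, 15))

  # negatives are floored before grading (they never outrank zero)
  gn <- grade(grid_raster(matrix(c(10, -5, 3, 2), 1, 4)))
  expect_equal(as.vector(gn$levels)[1], 4L)

  # monotonicity: raising one cell's value never lowers its level
  set.seed(14)
  v <- matrix(runif(64), 8, 8)
  before <- grade(grid_raster(v))
  for (idx in c(1, 17, 40, 64)) {
    v2 <- v; v2[idx] <- v2[idx] * 3
    after <- grade(grid_raster(v2))
    expect_gte(after$levels[idx], before$levels[idx])
  }

  # an all-zero raster grades everything Common with a warning
  expect_warning(z <- grade(const_raster(0, 3, 3)), "zero")
  expect_true(all(z$levels == 1L))
  expect_error(grade(const_raster(1, 2, 2), thresholds = c(0.9, 0.5, 0.2)),
               "increasing")
})

test_that("grade statistics reproduce published classification ratios", {
  # water-conservation column of the 2010 classification table
  water <- grade_stats(c(661.96, 763.35, 3479.34, 31851.08))
  expect_equal(water$area_ratio_pct, c(1.80, 2.08, 9.47, 86.66))
  # sand-fixation column
  sand <- grade_stats(c(1992.50, 3753.95, 18804.50, 12205.75))
  expect_equal(sand$area_ratio_pct, c(5.42, 10.21, 51.16, 33.21))
  # soil-conservation column
  soil <- grade_stats(c(1828.07, 4921.71, 8749.80, 21259.12))
  expect_equal(soil$area_ratio_pct, c(4.97, 13.39, 23.80, 57.83))

  # a single-level map concentrates 100% in that level
  one <- grade_stats(c(`Very Important` = 0, Important = 0, Moderate = 0,
                       Common = 12))
  expect_equal(one$area_ratio_pct, c(0, 0, 0, 100))

  # ratios always sum to 100 within rounding, and acreages to the total
  set.seed(15)
  g <- grade(grid_raster(matrix(runif(400), 20, 20)))
  st <- grade_stats(g)
  expect_equal(sum(st$acreage_km2), 400)
  expect_lt(abs(sum(st$area_ratio_pct) - 100), 0.02)
})

test_that("combined importance is the per-cell maximum level", {
  mk <- function(levels) structure(
    list(levels = matrix(levels, 1), cell_size_km = 1,
         mask = matrix(FALSE, 1, length(levels))),
    class = "importance_map")
  a <- mk(c(1L, 2L, 4L)); b <- mk(c(1L, 3L, 1L)); cc <- mk(c(1L, 1L, 1L))
  comb <- combined_importance(list(a, b, cc))
  expect_equal(as.vector(comb$levels), c(1L, 3L, 4L))
  # idempotent and order-invariant
  expect_equal(combined_importance(list(comb))$levels, comb$levels)
  expect_equal(combined_importance(list(cc, b, a))$levels, comb$levels)
  expect_error(combined_importance(list(a, mk(c(1L, 1L)))), "share")
})

test_that("new-artificial detection matches the transfer matrix identity", {
  t0 <- tiny_map(c(4, 4, 5, 1), nrow = 2)
  expect_equal(sum(new_artificial(t0, t0)$values), 0)
  t1 <- tiny_map(c(4, 5, 5, 1), nrow = 2)
  na <- new_artificial(t0, t1)
  expect_equal(as.vector(na$values), c(0, 1, 0, 0))

  # cross-module identity: new-artificial area equals the off-diagonal sum of
  # the transfer matrix's artificial column
  set.seed(16)
  a <- tiny_map(sample(1:6, 400, replace = TRUE), nrow = 20)
  b <- tiny_map(sample(1:6, 400, replace = TRUE), nrow = 20)
  tm <- unclass(transfer_matrix(a, b))[, ]
  off5 <- sum(tm[, "artificial"]) - tm["artificial", "artificial"]
  expect_equal(sum(new_artificial(a, b)$values), off5)
})

test_that("encroachment accounting keys combinations by overlap cardinality", {
  mk_imp <- function(levels) structure(
    list(levels = matrix(levels, 1), cell_size_km = 1,
         mask = matrix(FALSE, 1, length(levels))),
    class = "importance_map")
  # three new-artificial cells invading 1, 2 and 3 services respectively,
  # plus one untouched cell
  na <- grid_raster(matrix(c(1, 1, 1, 0), 1, 4))
  svc <- list(
    WaterConservation = mk_imp(c(1L, 1L, 3L, 4L)),
    SoilConservation = mk_imp(c(1L, 1L, 2L, 4L)),
    SandFixation = mk_imp(c(1L, 2L, 1L, 4L)),
    Biodiversity = mk_imp(c(2L, 3L, 4L, 4L)))
  tab <- encroachment_table(na, svc)
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$severity, c("Moderate", "Important", "Very Important"))
  expect_equal(tab$acreage_km2[tab$severity == "Moderate"], 1)
  expect_equal(tab$combination[tab$severity == "Moderate"], "Biodiversity")
  expect_equal(tab$combination[tab$severity == "Important"],
               "SandFixation+Biodiversity")
  expect_equal(tab$combination[tab$severity == "Very Important"],
               "WaterConservation+SoilConservation+Biodiversity")

  # severity totals are exact sums of their combination rows
  tot <- encroachment_totals(tab)
  expect_equal(tot$total_acreage_km2, c(1, 1, 1))

  # no new cells -> empty table
  none <- encroachment_table(grid_raster(matrix(0, 1, 4)), svc)
  expect_equal(nrow(none), 0)
  expect_error(encroachment_table(na, svc[1:3]), "four")
})

test_that("published encroachment severity totals are the sums of their rows", {
  published <- tibble::tibble(
    severity = c(rep("Moderate", 4), rep("Important", 5),
                 rep("Very Important", 2)),
    combination = c("WaterConservation", "SoilConservation", "SandFixation",
                    "Biodiversity",
                    "Biodiversity+SandFixation", "Biodiversity+SoilConservation",
                    "Biodiversity+WaterConservation",
                    "SandFixation+WaterConservation",
                    "SoilConservation+WaterConservation",
                    "Biodiversity+SandFixation+WaterConservation",
                    "Biodiversity+SoilConservation+WaterConservation"),
    acreage_km2 = c(6.52, 4.57, 4.08, 5.41,
                    1.11, 1.34, 1.27, 1.41, 1.24,
                    3.12, 2.23))
  tot <- encroachment_totals(published)
  expect_equal(tot$total_acreage_km2[tot$severity == "Moderate"], 20.58)
  expect_equal(tot$total_acreage_km2[tot$severity == "Important"], 6.37)
})
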