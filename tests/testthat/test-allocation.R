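# shared helpers: a randomized allocation instance with smooth suitability
random_instance <- function(n, seed) {
  set.seed(seed)
  map <- land_use_map(matrix(sample(1:6, n * n, replace = TRUE,
                                    prob = c(2, 2, 1, 3, 1, 1)), n, n))
  probs <- setNames(lapply(1:6, function(k)
    grid_raster(matrix(runif(n * n), n, n))), landuse_labels)
  list(map = map, probs = probs)
}

test_that("a frozen system returns the input in one iteration", {
  inst <- random_instance(20, 71)
  demand <- setNames(area_stats(inst$map)$area_km2, landuse_labels)
  params <- allocation_params(elasticity = setNames(rep(1, 6), landuse_labels))
  out <- allocate_year(inst$map, inst$probs, demand, params)
  expect_identical(out$codes, inst$map$codes)
  expect_equal(attr(out, "iterations"), 1L)
})

test_that("the hand-enumerated two-cell instance allocates by total probability", {
  # cells [cultivated, cultivated]; class-5 suitability 0.9 / 0.2; demand one
  # cell each of classes 4 and 5; zero elasticity -> the left cell converts
  map <- tiny_map(c(4, 4))
  flat <- function(v) grid_raster(matrix(v, 1, 2))
  probs <- list(
    forest = flat(0), grassland = flat(0), wetland = flat(0),
    cultivated = grid_raster(matrix(c(0.5, 0.5), 1, 2)),
    artificial = grid_raster(matrix(c(0.9, 0.2), 1, 2)),
    other = flat(0))
  demand <- setNames(c(0, 0, 0, 1, 1, 0), landuse_labels)
  params <- allocation_params(elasticity = setNames(rep(0, 6), landuse_labels),
                              tolerance_frac = 1e-9)
  out <- allocate_year(map, probs, demand, params)
  expect_equal(as.vector(out$codes), c(5L, 4L))
})

test_that("converged allocations meet demand, conserve area and honour locks", {
  for (seed in c(81, 82, 83)) {
    inst <- random_instance(50, seed)
    areas <- setNames(area_stats(inst$map)$area_km2, landuse_labels)
    # shift 5% of cultivated into artificial
    demand <- areas
    shift <- 0.05 * areas[["cultivated"]]
    demand[["cultivated"]] <- demand[["cultivated"]] - shift
    demand[["artificial"]] <- demand[["artificial"]] + shift
    restricted <- matrix(FALSE, 50, 50); restricted[1:5, 1:5] <- TRUE
    params <- allocation_params(restricted_mask = restricted)
    out <- allocate_year(inst$map, inst$probs, demand, params)
    total <- sum(area_stats(out)$area_km2)
    expect_equal(total, 2500)
    resid <- attr(out, "residuals")
    expect_true(all(abs(resid) <= params$tolerance_frac * 2500))
    # restricted cells never change
    expect_identical(out$codes[1:5, 1:5], inst$map$codes[1:5, 1:5])
    # elasticity-1 wetland cells are never converted away
    was_wet <- inst$map$codes == 3L
    expect_true(all(out$codes[was_wet] == 3L))
  }
})

test_that("raising a class's demand never lowers its allocated area", {
  inst <- random_instance(30, 91)
  areas <- setNames(area_stats(inst$map)$area_km2, landuse_labels)
  params <- allocation_params(
    elasticity = c(forest = 0.6, grassland = 0.6, wetland = 0.5,
                   cultivated = 0.4, artificial = 0.9, other = 0.3))
  alloc_art <- function(extra) {
    demand <- areas
    demand[["artificial"]] <- demand[["artificial"]] + extra
    demand[["cultivated"]] <- demand[["cultivated"]] - extra
    out <- allocate_year(inst$map, inst$probs, demand, params)
    area_stats(out)$area_km2[5]
  }
  grads <- vapply(c(0, 10, 20, 40), alloc_art, numeric(1))
  expect_true(all(diff(grads) >= 0))
})

test_that("infeasible or inconsistent demand is rejected", {
  inst <- random_instance(10, 95)
  areas <- setNames(area_stats(inst$map)$area_km2, landuse_labels)
  expect_error(allocate_year(inst$map, inst$probs, areas * 2),
               "sum to the total")
  expect_error(allocate_year(inst$map, inst$probs, areas[1:5]), "six classes")
})

test_that("multi-year simulation chains yearly allocations", {
  inst <- random_instance(30, 97)
  areas <- setNames(area_stats(inst$map)$area_km2, landuse_labels)
  years <- 2015:2019
  # static demand with elasticity 1 everywhere: all maps identical
  static <- tibble::tibble(
    year = rep(years, times = 6),
    class_code = rep(1:6, each = length(years)),
    class_name = rep(landuse_labels, each = length(years)),
    area_km2 = rep(unname(areas), each = length(years)))
  frozen <- allocation_params(elasticity = setNames(rep(1, 6), landuse_labels))
  maps <- simulate_landuse(inst$map, inst$probs, static, frozen)
  expect_length(maps, 5)
  for (m in maps[-1]) expect_identical(m$codes, inst$map$codes)

  # growing artificial demand: conversions happen on high-suitability cells
  grow <- static
  for (i in seq_along(years)) {
    g <- 8 * (i - 1)
    grow$area_km2[grow$class_code == 5 & grow$year == years[i]] <-
      areas[["artificial"]] + g
    grow$area_km2[grow$class_code == 4 & grow$year == years[i]] <-
      areas[["cultivated"]] - g
  }
  params <- allocation_params(
    elasticity = c(forest = 0.6, grassland = 0.6, wetland = 1.0,
                   cultivated = 0.4, artificial = 0.9, other = 0.3))
  maps2 <- simulate_landuse(inst$map, inst$probs, grow, params)
  last <- maps2[[length(maps2)]]
  converted <- last$codes == 5L & inst$map$codes != 5L
  expect_gt(sum(converted), 0)
  # converted cells sit high in the artificial-suitability ranking
  p5 <- inst$probs$artificial$values
  ranks <- rank(p5) / length(p5)
  expect_gt(mean(ranks[converted]), 0.8)
})
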