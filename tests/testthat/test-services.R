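test_that("water balance reproduces the unit-conversion oracle", {
  # a single 1 km^2 cell with P=600, R=200, ET=300: 100 mm -> 1e5 m^3
  one <- water_conservation(const_raster(600), const_raster(200),
                            const_raster(300), tiny_map(1))
  expect_equal(one$TQ, 1e5)
  expect_equal(one$per_cell$values[1, 1], 1e5)

  # P = R + ET everywhere: TQ = 0
  P <- const_raster(500, 4, 4); R <- const_raster(200, 4, 4)
  ET <- const_raster(300, 4, 4)
  m <- tiny_map(sample(1:6, 16, replace = TRUE), nrow = 4)
  expect_equal(water_conservation(P, R, ET, m)$TQ, 0)

  # TQ is additive over classes: relabelling cells leaves it unchanged
  set.seed(12)
  Pv <- grid_raster(matrix(runif(16, 300, 800), 4, 4))
  Rv <- grid_raster(matrix(runif(16, 0, 100), 4, 4))
  Ev <- grid_raster(matrix(runif(16, 100, 400), 4, 4))
  m1 <- tiny_map(rep(1, 16), nrow = 4)
  m2 <- tiny_map(rep(c(1, 2), 8), nrow = 4)
  w1 <- water_conservation(Pv, Rv, Ev, m1)
  w2 <- water_conservation(Pv, Rv, Ev, m2)
  expect_equal(w1$TQ, w2$TQ)
  expect_equal(sum(w2$by_class$volume_m3), w2$TQ)

  expect_error(water_conservation(P, R, const_raster(1, 2, 2), m), "share")
})

test_that("runoff coefficients scale rainfall per class", {
  P <- const_raster(800, 2, 2)
  m <- tiny_map(c(1, 1, 2, 2), nrow = 2)
  co <- c(forest = 0, grassland = 1)
  r <- estimate_runoff(P, m, co)
  expect_equal(as.vector(r$values), c(0, 0, 800, 800))
  r2 <- estimate_runoff(P, m, c(forest = 0.35, grassland = 0.35))
  expect_equal(as.vector(r2$values), rep(280, 4))
  expect_error(estimate_runoff(P, m, c(forest = 0.2)), "grassland")
  expect_error(estimate_runoff(P, m, c(forest = 2, grassland = 0)), "\\[0, 1\\]")
})

test_that("the soil-loss calculus matches hand oracles and its identity", {
  # R=100, K=0.3, L=1, S=2, C=0.2 -> A_c = 48
  out <- soil_conservation(const_raster(100), const_raster(0.3), 1,
                           const_raster(2), const_raster(0.2))
  expect_equal(out$a_c$values[1, 1], 48)
  expect_equal(out$a_p$values[1, 1], 60)
  expect_equal(out$a_r$values[1, 1], 12)

  # full cover: zero conservation... and C > 1 rejected
  full <- soil_conservation(const_raster(100, 3, 3), const_raster(0.3, 3, 3),
                            1, const_raster(2, 3, 3), const_raster(1, 3, 3))
  expect_equal(raster_values(full$a_c), rep(0, 9))
  expect_error(
    soil_conservation(const_raster(1), const_raster(1), 1, const_raster(1),
                      const_raster(1.2)), "\\[0, 1\\]")

  # A_c = A_p - A_r exactly, cell by cell, and A_c decreases in C
  set.seed(13)
  rf <- grid_raster(matrix(runif(25, 50, 200), 5, 5))
  kf <- grid_raster(matrix(runif(25, 0.1, 0.5), 5, 5))
  sf <- grid_raster(matrix(runif(25, 0.5, 3), 5, 5))
  cf1 <- grid_raster(matrix(runif(25, 0, 0.5), 5, 5))
  cf2 <- grid_raster(cf1$values + 0.3)
  o1 <- soil_conservation(rf, kf, 1, sf, cf1)
  o2 <- soil_conservation(rf, kf, 1, sf, cf2)
  expect_equal(o1$a_c$values, o1$a_p$values - o1$a_r$values)
  expect_true(all(o2$a_c$values < o1$a_c$values))
})

test_that("potential evapotranspiration follows the quadratic closed form", {
  expect_equal(potential_evapotranspiration(10, 1), 0)
  expect_equal(potential_evapotranspiration(-20, 0.3), 0)
  expect_equal(potential_evapotranspiration(-35, 0.3), 0)  # clamped
  expect_equal(potential_evapotranspiration(10, 0.5), 85.5)
  expect_error(potential_evapotranspiration(10, 1.2), "\\[0, 1\\]")
})

test_that("the wind profile and roughness factors evaluate correctly", {
  expect_equal(wind_at_height(7, 10, 10), 7)
  expect_equal(wind_at_height(4, 10, 2), 4 * 0.2^(1 / 7))
  expect_equal(wind_at_height(4, 10, 2), 3.178, tolerance = 1e-3)
  heights <- seq(1, 30, by = 1)
  expect_true(all(diff(wind_at_height(5, 10, heights)) > 0))
  expect_error(wind_at_height(5, 0, 2), "positive")

  expect_equal(surface_roughness(const_raster(0))$values[1, 1], 1)
  expect_equal(surface_roughness(const_raster(pi / 3))$values[1, 1], 2)
  th <- seq(0, 1.5, by = 0.1)
  d <- vapply(th, function(x) surface_roughness(const_raster(x))$values[1, 1],
              numeric(1))
  expect_true(all(diff(d) > 0))
  expect_error(surface_roughness(const_raster(pi / 2)), "pi/2")
})

test_that("climate erosivity aggregates dry months only", {
  # humid everywhere: every month has P >= ETP, so F_q = 0
  humid <- climate_stack(precip = rep(500, 12), temp = rep(10, 12),
                         rh = rep(0.5, 12), wind = rep(5, 12))
  expect_equal(climate_erosivity(humid)$values[1, 1], 0)

  # one active month: u=5, ETP=100, P=50, d=30 -> 125 * 0.5 * 30 / 100 = 18.75
  # (T and r chosen so 0.19*(20+T)^2*(1-r) = 100)
  Tm <- sqrt(100 / (0.19 * 0.5)) - 20
  cl <- one_month_climate(precip = 50, temp = Tm, rh = 0.5, wind = 5,
                          month = 4,
                          days = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31,
                                   30, 31))
  expect_equal(potential_evapotranspiration(Tm, 0.5), 100)
  expect_equal(climate_erosivity(cl)$values[1, 1], 18.75)

  # additivity over months: two active months sum their contributions
  cl2 <- one_month_climate(precip = 50, temp = Tm, rh = 0.5, wind = 5,
                           month = 9,
                           days = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31,
                                    30, 31))
  both <- climate_stack(
    precip = {p <- rep(1000, 12); p[c(4, 9)] <- 50; p},
    temp = {t <- rep(0, 12); t[c(4, 9)] <- Tm; t},
    rh = {r <- rep(0.99, 12); r[c(4, 9)] <- 0.5; r},
    wind = {u <- rep(0, 12); u[c(4, 9)] <- 5; u})
  expect_equal(climate_erosivity(both)$values[1, 1],
               climate_erosivity(cl)$values[1, 1] +
                 climate_erosivity(cl2)$values[1, 1])
})

test_that("sand fixation is the product of its four factors", {
  s <- sand_fixation(const_raster(500), const_raster(0.4),
                     const_raster(10), const_raster(1.25))
  expect_equal(s$values[1, 1], 2500)
  z <- sand_fixation(const_raster(0, 2, 2), const_raster(0.4, 2, 2),
                     const_raster(10, 2, 2), const_raster(1.25, 2, 2))
  expect_equal(raster_values(z), rep(0, 4))
  # flat terrain: D = 1 leaves NPP * K * F_q
  flat <- sand_fixation(const_raster(500), const_raster(0.4),
                        const_raster(10), const_raster(1))
  expect_equal(flat$values[1, 1], 500 * 0.4 * 10)
})

test_that("envelope suitability scores the in-envelope driver fraction", {
  # two drivers on a 1x10 strip; species occupies cells 3..8 repeatedly
  x <- matrix(1:10, 1, 10)
  dr <- stack_of(a = x, b = x[, 10:1, drop = FALSE])
  occ <- species_occurrences(tibble::tibble(
    row = 1, col = rep(3:8, length.out = 12), species_id = 1))
  s <- biodiversity_suitability(occ, dr, envelope_probs = c(0, 1))
  # envelopes are [3, 8] on both drivers; cell 5 is inside both, cell 1
  # inside neither, cell 10 inside neither, cell 3 inside both
  expect_equal(s$values[1, 5], 1)
  expect_equal(s$values[1, 1], 0)
  expect_equal(s$values[1, 10], 0)
  expect_equal(s$values[1, 9], 0)
  # one driver inside of two -> score one half
  dr_half <- stack_of(a = x, c = matrix(5, 1, 10))
  occ_half <- species_occurrences(tibble::tibble(
    row = 1, col = rep(1:4, length.out = 8), species_id = 1))
  s_half <- biodiversity_suitability(occ_half, dr_half,
                                     envelope_probs = c(0, 1))
  expect_equal(s_half$values[1, 8], 0.5)  # a = 8 outside [1,4]; c = 5 inside
  expect_equal(s_half$values[1, 2], 1)
  occ2 <- species_occurrences(tibble::tibble(
    row = 1, col = rep(1:6, length.out = 12), species_id = 1))
  s2 <- biodiversity_suitability(occ2, dr, envelope_probs = c(0, 1))
  # envelopes: a in [1,6], b in [5,10]; cell 2 has a=2 (in), b=9 (in)  -> 1
  # cell 8 has a=8 (out), b=3 (out) -> 0; cell 6 a=6 in, b=5 in -> 1
  expect_equal(s2$values[1, 2], 1)
  expect_equal(s2$values[1, 8], 0)
  # a species with too few points is skipped; all-skipped is an error
  few <- species_occurrences(tibble::tibble(row = 1, col = c(1, 2),
                                            species_id = 1))
  expect_error(suppressWarnings(biodiversity_suitability(few, dr)), "enough")
  mixed <- species_occurrences(tibble::tibble(
    row = 1, col = c(rep(3:8, 2), 1, 2), species_id = c(rep(1, 12), 2, 2)))
  expect_warning(sm <- biodiversity_suitability(mixed, dr,
                                                envelope_probs = c(0, 1)),
                 "skipped")
  expect_equal(sm$values, s$values)
  # protection weights average the per-species scores
  two <- species_occurrences(
    tibble::tibble(row = 1, col = c(rep(3:8, 2), rep(c(1, 1, 1, 2, 2, 2), 2)),
                   species_id = rep(1:2, each = 12)),
    protection_weight = c(`1` = 3, `2` = 1))
  st <- biodiversity_suitability(two, dr, envelope_probs = c(0, 1))
  expect_true(all(st$values >= 0 & st$values <= 1))
})

test_that("annual climate aggregates bound evapotranspiration by supply", {
  cl <- generate_climate(scene_spec(8, 8, seed = 4))
  aet <- annual_evapotranspiration(cl)
  ap <- annual_precipitation(cl)
  expect_true(all(raster_values(aet) <= raster_values(ap) + 1e-9))
  expect_true(all(raster_values(aet) >= 0))
})
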