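test_that("AUC follows the Mann-Whitney definition and its invariances", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  # invariant under strictly monotone transforms
  set.seed(61)
  s <- runif(200); y <- rbinom(200, 1, plogis(3 * s - 1.5))
  expect_equal(roc_auc(qlogis(pmin(pmax(s, 1e-6), 1 - 1e-6)), y),
               roc_auc(s, y))
  # cross-check against an independent implementation
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
  expect_error(roc_auc(s, rep(1, 200)), "both label values")
})

test_that("probability surfaces evaluate the inverse-logit closed form", {
  dr <- stack_of(x = matrix(c(-1, 0, 1, 2), 2, 2))
  # zero model: constant one half
  m0 <- manual_model(0, c(x = 0))
  expect_equal(raster_values(probability_surface(m0, dr)), rep(0.5, 4))
  # saturating intercept
  m_inf <- manual_model(-50, c(x = 0))
  expect_true(all(raster_values(probability_surface(m_inf, dr)) < 1e-20))
  # hand case: intercept 0, slope 1, standardized value 1 -> 1/(1+e^-1)
  m1 <- manual_model(0, c(x = 1))
  expect_equal(probability_surface(m1, dr)$values[1, 2], plogis(1))
  expect_equal(probability_surface(m1, dr)$values[1, 2], 0.7310586,
               tolerance = 1e-7)
  # a missing driver is an error
  expect_error(probability_surface(manual_model(0, c(z = 1)), dr), "missing")
})

test_that("perfect separation triggers the ridge fallback with AUC 1", {
  set.seed(62)
  codes <- matrix(sample(c(1L, 2L), 400, replace = TRUE), 20, 20)
  map <- land_use_map(codes)
  ind <- stack_of(indicator = (codes == 1) * 1,
                  noise = matrix(rnorm(400), 20, 20))
  expect_warning(m <- fit_logistic(map, ind, 1), "separation")
  expect_true(m$ridge)
  expect_equal(m$roc, 1.0)
  expect_true("indicator" %in% m$selected_drivers)
})

test_that("stepwise selection rejects an uninformative driver at the null rate", {
  # oracle: a single null candidate enters with probability ~ p_enter = 0.05,
  # so across 100 seeded runs at least 90 should select nothing
  rejected <- 0L
  intercepts <- numeric(100)
  for (s in 1:100) {
    set.seed(1000 + s)
    codes <- matrix(sample(c(3L, 4L), 400, replace = TRUE), 20, 20)
    map <- land_use_map(codes)
    dr <- stack_of(noise = matrix(rnorm(400), 20, 20))
    m <- fit_logistic(map, dr, 3)
    if (!length(m$selected_drivers)) rejected <- rejected + 1L
    intercepts[s] <- m$intercept
  }
  expect_gte(rejected, 90)
  # with class share one half the null intercept is log(n1/n0) ~ 0
  expect_lt(abs(mean(intercepts)), 0.05)
})

test_that("models recover the generating coefficients on synthetic scenes", {
  # one-vs-rest logistic fits of a multinomial-logit truth are approximately
  # unbiased under the sparse default design; a small misspecification tail
  # occasionally pushes a single coefficient just past the 0.5 band, so the
  # per-scene check allows at most one of the twelve strong coefficients out
  truth <- default_true_coefficients()
  for (seed in c(101, 202)) {
    spec <- scene_spec(100, 100, seed = seed)
    dem <- generate_dem(spec)
    dr <- generate_drivers(dem, spec)
    lu <- generate_landuse(dr, spec)
    models <- fit_all_classes(lu, dr)
    errs <- c()
    for (k in landuse_labels) {
      tr <- truth[[k]]
      strong <- tr[abs(tr) >= 1]
      est <- models[[k]]$coefficients[names(strong)]
      expect_false(anyNA(est),
                   label = paste(k, "strong drivers all selected"))
      expect_true(all(sign(est) == sign(strong)),
                  label = paste(k, "coefficient signs"))
      errs <- c(errs, abs(est - strong))
      expect_gt(models[[k]]$roc, 0.7)
    }
    expect_lte(sum(errs > 0.5), 1)
    expect_lt(mean(errs), 0.4)
  }
})

test_that("fitted models serialize to YAML and reproduce their surfaces", {
  spec <- scene_spec(40, 40, seed = 77)
  dem <- generate_dem(spec)
  dr <- generate_drivers(dem, spec)
  lu <- generate_landuse(dr, spec)
  m <- fit_logistic(lu, dr, "forest")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_models_yaml(list(forest = m), path)
  back <- read_models_yaml(path)$forest
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-6)
  expect_equal(probability_surface(back, dr)$values,
               probability_surface(m, dr)$values, tolerance = 1e-4)
  # tidy/glance expose the broom-style views
  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(glance(m)), 1)
  expect_equal(glance(m)$roc, m$roc)
  # a degenerate class share is refused
  all1 <- land_use_map(matrix(1L, 40, 40))
  expect_error(fit_logistic(all1, dr, 1), "bounds")
})
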