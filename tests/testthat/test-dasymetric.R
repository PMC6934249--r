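# Zone-level model table, random-forest density model, weight surface,
# dasymetric redistribution and re-aggregation validation.

make_small_scene <- function(seed = 1, ...) {
  generate_landscape(scene_spec(n_rows = 40, n_cols = 40, n_districts = 12,
                                n_settlements = 5, seed = seed, ...))
}

test_that("feature table computes log density with the zero-count pseudo-count", {
  sc <- make_small_scene(2)
  counts <- sc$counts
  ft <- build_feature_table(sc$zones, counts, 2011, sc$stack)
  expect_equal(ft$log_density[3],
               log(counts$count[3] / sc$zones$area_ha[3]))

  # a 100 ha zone with 1000 persons has log density ln(10)
  z <- zone_set("Z", list(list(list(rect_ring(0, 0, 1000, 1000)))))
  st <- grid_stack(c1 = mg_grid(matrix(1, 10, 10)))
  cc <- tibble::tibble(zone_id = "Z", year = 2011L, count = 1000)
  expect_equal(
    build_feature_table(z, cc, 2011, st)$log_density, log(10))

  # zero count falls back to eps = 0.5 persons
  cc0 <- tibble::tibble(zone_id = "Z", year = 2011L, count = 0)
  expect_equal(build_feature_table(z, cc0, 2011, st)$log_density,
               log(0.005))
})

test_that("feature table covariate columns equal zonal means of the stack", {
  sc <- make_small_scene(3)
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  for (nm in names(sc$stack)) {
    expect_equal(ft[[nm]], zonal_mean(sc$stack[[nm]], sc$zones)$value)
  }
})

test_that("the forest recovers a noiseless covariate-density relationship", {
  sc <- generate_landscape(scene_spec(n_rows = 100, n_cols = 100,
                                      n_districts = 120, n_settlements = 12,
                                      seed = 31))
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  model <- fit_density_model(ft, seed = 31)
  expect_gt(model$oob_pseudo_r2, 0.9)
  expect_lte(model$oob_pseudo_r2, 1)
})

test_that("a pure-noise response yields no out-of-bag skill", {
  set.seed(77)
  n <- 200
  ft <- tibble::tibble(zone_id = sprintf("z%03d", 1:n), area_ha = 100,
                       count = 1000, log_density = rnorm(n),
                       c1 = rnorm(n), c2 = rnorm(n), c3 = rnorm(n))
  attr(ft, "covariates") <- c("c1", "c2", "c3")
  model <- fit_density_model(ft, seed = 77)
  expect_lte(model$oob_pseudo_r2, 0.1)
})

test_that("a constant response warns and predicts the constant", {
  n <- 20
  ft <- tibble::tibble(zone_id = sprintf("z%02d", 1:n), area_ha = 100,
                       count = 500, log_density = rep(1.7, n),
                       c1 = rnorm(n))
  attr(ft, "covariates") <- "c1"
  expect_warning(model <- fit_density_model(ft, seed = 1), "constant")
  expect_equal(predict(model, tibble::tibble(c1 = c(-5, 0, 5))),
               rep(1.7, 3))
})

test_that("predictions stay within the range of trained log densities", {
  sc <- make_small_scene(8)
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  model <- fit_density_model(ft, seed = 8)
  ws <- predict_weight_surface(model, sc$stack, mask = sc$mask)
  w <- ws$weights$values[ws$habitable]
  expect_true(all(log(w) >= model$response_range[1] - 1e-9))
  expect_true(all(log(w) <= model$response_range[2] + 1e-9))
})

test_that("weight surface is zero exactly on masked cells, positive elsewhere", {
  sc <- make_small_scene(4)
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  model <- fit_density_model(ft, seed = 4)
  ws <- predict_weight_surface(model, sc$stack, mask = sc$mask)
  masked <- sc$mask$values == 0
  expect_true(all(ws$weights$values[masked] == 0))
  expect_true(all(ws$weights$values[!masked] > 0))
  expect_true(all(is.finite(ws$weights$values)))

  # a model that always predicts c gives weight exp(c) on habitable cells
  n <- 20
  ftc <- tibble::tibble(zone_id = as.character(1:n), area_ha = 1, count = 1,
                        log_density = rep(2, n),
                        settlement_index = rnorm(n))
  attr(ftc, "covariates") <- "settlement_index"
  suppressWarnings(mc <- fit_density_model(ftc, seed = 1))
  wsc <- predict_weight_surface(mc, sc$stack, mask = sc$mask)
  expect_equal(unique(wsc$weights$values[!masked]), exp(2))

  expect_error(
    predict_weight_surface(model, grid_stack(foo = sc$stack[[1]])),
    "missing covariate layer: settlement_index")
})

test_that("redistribution follows weights and conserves zone counts exactly", {
  g <- mg_grid(matrix(0, 2, 2), cell_size_m = 100)
  z <- zone_set("A", list(list(list(rect_ring(0, 0, 200, 200)))))
  cc <- tibble::tibble(zone_id = "A", year = 2011L, count = 100)

  uni <- grid_like(g, matrix(1, 2, 2))
  expect_equal(redistribute(uni, z, cc, 2011)$values, matrix(25, 2, 2))

  two <- zone_set("A", list(list(list(rect_ring(0, 0, 200, 100)))))
  w <- grid_like(mg_grid(matrix(0, 1, 2)), matrix(c(1, 3), 1, 2))
  expect_equal(redistribute(w, two, cc, 2011)$values,
               matrix(c(25, 75), 1, 2))

  # zone with no cells errors by id
  tiny <- zone_set(c("A", "far"),
                   list(list(list(rect_ring(0, 0, 200, 200))),
                        list(list(rect_ring(900, 900, 950, 950)))))
  cc2 <- dplyr::bind_rows(cc, tibble::tibble(zone_id = "far", year = 2011L,
                                             count = 5))
  expect_error(redistribute(uni, tiny, cc2, 2011), "far")
})

test_that("conservation holds for random weights including all-zero zones", {
  set.seed(99)
  for (rep in 1:3) {
    sc <- make_small_scene(rep + 50)
    w <- grid_like(sc$population, matrix(runif(1600), 40, 40))
    # zero out every weight in two districts
    for (zi in sample(nrow(sc$zones), 2)) {
      w$values[sc$district_labels == zi] <- 0
    }
    pop <- redistribute(w, sc$zones, sc$counts, 2011)
    got <- reaggregate_check(pop, sc$zones, sc$counts, 2011)
    expect_equal(got$by_zone$estimated, got$by_zone$count,
                 tolerance = 1e-6)
    expect_equal(sum(pop$values), sum(sc$counts$count), tolerance = 1e-9)
    expect_equal(got$pearson_r, 1, tolerance = 1e-9)
  }
})

test_that("disaggregation is deterministic for a fixed seed", {
  sc <- make_small_scene(12)
  d1 <- disaggregate_population(sc$zones, sc$counts, 2011, sc$stack,
                                mask = sc$mask, n_trees = 100, seed = 42)
  d2 <- disaggregate_population(sc$zones, sc$counts, 2011, sc$stack,
                                mask = sc$mask, n_trees = 100, seed = 42)
  expect_identical(d1$weights$weights$values, d2$weights$weights$values)
  expect_identical(d1$population$values, d2$population$values)
})

test_that("per-cell predicted density tracks the true density on a noiseless scene", {
  # the density surface is an exact monotone function of the
  # settlement_index covariate; fit on that noiseless relationship
  sc <- generate_landscape(scene_spec(n_rows = 100, n_cols = 100,
                                      n_districts = 200, n_settlements = 12,
                                      seed = 21))
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  model <- fit_density_model(ft, seed = 21, covariates = "settlement_index")
  ws <- predict_weight_surface(model, sc$stack, mask = sc$mask)
  hab <- sc$mask$values == 1
  expect_gt(cor(ws$weights$values[hab], sc$density$values[hab]), 0.9)
})

test_that("re-aggregation to independent finer zones correlates with truth", {
  sc <- make_small_scene(61)
  dis <- disaggregate_population(sc$zones, sc$counts, 2011, sc$stack,
                                 mask = sc$mask, seed = 61)
  # independent finer check zones with true reference counts
  set.seed(61)
  fine <- metrogrid:::district_zone_set(24, sc$population)
  fine$zone_id <- sub("^D", "V", fine$zone_id)
  ref <- tibble::tibble(zone_id = fine$zone_id, year = 2011L,
                        count = zonal_sum(sc$population, fine)$value)
  chk <- reaggregate_check(dis$population, fine, ref, 2011)
  expect_gte(chk$pearson_r, 0.8)

  # shuffled reference counts destroy the correlation
  set.seed(9)
  shuf <- ref
  shuf$count <- sample(shuf$count)
  chk2 <- reaggregate_check(dis$population, fine, shuf, 2011)
  expect_lt(abs(chk2$pearson_r), 0.5)

  expect_error(reaggregate_check(dis$population, fine[1:2, ], ref, 2011),
               "at least 3")
})

test_that("tidy and glance expose importances and fit diagnostics", {
  sc <- make_small_scene(5)
  ft <- build_feature_table(sc$zones, sc$counts, 2011, sc$stack)
  model <- fit_density_model(ft, n_trees = 100, seed = 5)
  td <- tidy(model)
  expect_setequal(td$term, names(sc$stack))
  gl <- glance(model)
  expect_equal(gl$n_zones, 12)
  expect_equal(gl$oob_pseudo_r2, model$oob_pseudo_r2)
})
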