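test_that("fertility classes reclassify to 100/65/40/20 kg/ha/yr", {
  expect_equal(reclassify_fertility(1), 100)
  expect_equal(reclassify_fertility(4), 20)
  expect_equal(reclassify_fertility(c(2, 3)), c(65, 40))
  expect_error(reclassify_fertility(5), "1..4")
  expect_error(reclassify_fertility(0), "1..4")
})

test_that("the nitrogen pool integrates content x density over the top 30 cm", {
  one <- data.frame(n_content = 2, bulk_density = 1000, top = 0, bottom = 0.30)
  expect_equal(nitrogen_pool(one), 6000)  # 0.6 kg/m2
  expect_equal(nitrogen_pool(one[0, ]), 0)
  # truncation oracle: a 0-0.50 m layer equals the explicit 0-0.30 m layer
  deep <- data.frame(n_content = 2, bulk_density = 1000, top = 0,
                     bottom = 0.50)
  expect_equal(nitrogen_pool(deep), nitrogen_pool(one))
  # two layers add up
  two <- data.frame(n_content = c(3, 1), bulk_density = c(1200, 1400),
                    top = c(0, 0.15), bottom = c(0.15, 0.30))
  expect_equal(nitrogen_pool(two),
               (3 / 1000 * 1200 * 0.15 + 1 / 1000 * 1400 * 0.15) * 1e4)
  expect_error(nitrogen_pool(data.frame(n_content = -1, bulk_density = 1000,
                                        top = 0, bottom = 0.3)), "negative")
})

test_that("pseudo-rate is the algebraic ratio of flux and pool", {
  expect_equal(pseudo_rate(60, 6000), 0.01)
  expect_equal(pseudo_rate(100, 100), 1)
  expect_error(pseudo_rate(60, 0), "positive")
  set.seed(5)
  fert <- runif(50, 20, 100); pool <- runif(50, 2000, 9000)
  expect_equal(pseudo_rate(fert, pool) * pool, fert, tolerance = 1e-12)
})

test_that("the rate GLM recovers known coefficients", {
  # noiseless: exact recovery and a perfect deviance-explained
  g0 <- gen_soil_grids(seed = 2, noise_sdlog = 0)
  rates <- pseudo_rate(g0$cells$fertility_flux, g0$cells$pool)
  fit0 <- suppressWarnings(fit_rate_glm(
    data.frame(rate = rates, mat = g0$cells$mat, anp = g0$cells$anp,
               seas = g0$cells$seas, ph = g0$cells$ph)))
  expect_equal(unname(fit0$coefficients), unname(default_glm_truth()),
               tolerance = 1e-6)
  expect_equal(fit0$d2, 1, tolerance = 1e-9)

  # with noise: coefficients within 3 SE of truth
  g <- gen_soil_grids(grid_spec = list(lat_min = 42, lat_max = 54,
                                       lon_min = 2, lon_max = 16,
                                       resolution = 0.25),
                      seed = 8, noise_sdlog = 0.05)
  rates <- pseudo_rate(g$cells$fertility_flux, g$cells$pool)
  fit <- fit_rate_glm(data.frame(rate = rates, mat = g$cells$mat,
                                 anp = g$cells$anp, seas = g$cells$seas,
                                 ph = g$cells$ph))
  se <- sqrt(diag(vcov(fit$fit)))
  expect_true(all(abs(fit$coefficients - default_glm_truth()) < 3 * se))

  expect_error(fit_rate_glm(data.frame(rate = 1:10 / 100, mat = 1:10,
                                       anp = 1:10, seas = 1:10, ph = 1:10)),
               "at least 50")
})

test_that("available nitrogen prediction inverts the pool division", {
  g <- fixture_grids()
  rates <- pseudo_rate(g$cells$fertility_flux, g$cells$pool)
  fit <- fit_rate_glm(data.frame(rate = rates, mat = g$cells$mat,
                                 anp = g$cells$anp, seas = g$cells$seas,
                                 ph = g$cells$ph))
  expect_equal(predict_available_n(0, g$cells[1, ], fit), 0)
  # pool x predicted rate, checked against a hand-multiplied response
  r1 <- predict(fit$fit, newdata = g$cells[1, ], type = "response")
  expect_equal(predict_available_n(6000, g$cells[1, ], fit),
               unname(6000 * r1))
  # end-to-end recovery: median relative error below 5% at default noise
  pred <- predict_available_n(g$cells$pool, g$cells, fit)
  rel <- abs(pred - g$truth$available_n_true) / g$truth$available_n_true
  expect_lt(median(rel), 0.05)
})

test_that("soil vectors are completed from metadata, ratings and grids", {
  g <- fixture_grids()
  rates <- pseudo_rate(g$cells$fertility_flux, g$cells$pool)
  fit <- fit_rate_glm(data.frame(rate = rates, mat = g$cells$mat,
                                 anp = g$cells$anp, seas = g$cells$seas,
                                 ph = g$cells$ph))
  full <- list(latitude = 48, longitude = 9, whc = 120, sand = 40, silt = 40,
               clay = 20, depth = 800, available_n = 70)
  sv <- complete_soil_vector(full, g, fit)
  expect_equal(sv[c("whc", "sand", "silt", "clay", "depth", "available_n")],
               full[c("whc", "sand", "silt", "clay", "depth", "available_n")],
               ignore_attr = TRUE)
  # idempotence: completing a completed vector changes nothing
  sv2 <- complete_soil_vector(c(list(latitude = 48, longitude = 9),
                                unclass(sv)), g, fit)
  expect_equal(unclass(sv2), unclass(sv))

  # ratings only: all fields filled, texture sums to 100
  rated <- list(latitude = 48, longitude = 9, water_rating = "dry",
                fertility_rating = "rich")
  sv <- complete_soil_vector(rated, g, fit)
  expect_true(all(!vapply(sv, is.na, TRUE)))
  expect_equal(sv$whc, default_rating_lookup()$water[["dry"]])
  expect_equal(sv$available_n, default_rating_lookup()$fertility[["rich"]])
  expect_equal(sv$sand + sv$silt + sv$clay, 100, tolerance = 1)

  # nothing given: everything from the grids and the GLM
  bare <- list(latitude = 48, longitude = 9)
  sv <- complete_soil_vector(bare, g, fit)
  expect_true(all(!vapply(sv, is.na, TRUE)))
  expect_gt(sv$available_n, 0)

  # outside the grids with missing fields: error naming a field
  far <- list(latitude = 10, longitude = 100, whc = 100)
  expect_error(complete_soil_vector(far, g, fit), "sand")
})
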