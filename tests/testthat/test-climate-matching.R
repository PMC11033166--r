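test_that("trend slopes equal closed-form least squares", {
  t_series <- 10 + 0.1 * (0:19)
  p_series <- rep(800, 20)
  sl <- trend_slopes(t_series, p_series)
  expect_equal(sl$t_slope, 0.1, tolerance = 1e-12)
  expect_equal(sl$p_slope, 0, tolerance = 1e-12)

  # oracle: normal-equation OLS on arbitrary series
  set.seed(12)
  at <- rnorm(30, 8, 1); ap <- runif(30, 500, 900); yrs <- 2001:2030
  sl <- trend_slopes(at, ap, yrs)
  X <- cbind(1, yrs)
  beta_t <- solve(t(X) %*% X, t(X) %*% at)
  beta_p <- solve(t(X) %*% X, t(X) %*% ap)
  expect_equal(sl$t_slope, beta_t[2], tolerance = 1e-10)
  expect_equal(sl$p_slope, beta_p[2] / mean(ap), tolerance = 1e-10)

  expect_error(trend_slopes(c(1, 2, 3), c(1, 2, 3), years = c(5, 5, 5)),
               "constant")
  expect_error(trend_slopes(1:2, 1:2), "at least 3")
})

test_that("the trend index weighs 10% precipitation per century like 1 degree C", {
  s0 <- list(t_slope = 0.02, p_slope = 0.001)
  expect_equal(trajectory_distance(s0, s0), 0)
  # 1 degC per century temperature difference
  s1 <- list(t_slope = 0.03, p_slope = 0.001)
  expect_equal(trajectory_distance(s0, s1), 1.0)
  # 10% per century precipitation difference
  s2 <- list(t_slope = 0.02, p_slope = 0.002)
  expect_equal(trajectory_distance(s0, s2), 1.0)
  # pseudometric: symmetric and non-negative
  expect_equal(trajectory_distance(s1, s2), trajectory_distance(s2, s1))
  expect_gte(trajectory_distance(s1, s2), 0)
})

test_that("trajectory selection recovers the source scenario and honours hints", {
  catal <- fixture_catalogue()
  sims <- fixture_simset()
  truth <- sims$truth$simulations
  picked <- vapply(seq_len(nrow(truth)), function(i) {
    m <- sims$metadata[sims$metadata$simulation_id ==
                         truth$simulation_id[i], ][1, ]
    select_trajectory(m, catal)$scenario_id
  }, "")
  expect_gte(mean(picked == truth$scenario_id), 0.99)

  # an RCP hint restricts scoring to that family's three members
  m <- sims$metadata[sims$metadata$trajectory_family == "RCP", ][1, ]
  m$rcp_hint <- "rcp26"
  sel <- select_trajectory(m, catal)
  expect_identical(nrow(sel$candidates), 3L)
  expect_true(all(startsWith(sel$candidates$scenario_id, "rcp26_")))
  # baseline simulations only see historical trajectories
  mb <- sims$metadata[sims$metadata$trajectory_family == "baseline", ][1, ]
  selb <- select_trajectory(mb, catal)
  expect_true(all(startsWith(selb$candidates$scenario_id, "historical_")))
  # impossible hint combination errors out
  m$rcp_hint <- "rcp99"
  expect_error(select_trajectory(m, catal), "no candidate")
})

test_that("level adjustment reproduces the simulation means exactly", {
  catal <- fixture_catalogue()
  traj <- catal$trajectories[[1]]
  adj <- adjust_trajectory(traj, sim_mat = 10, sim_anp = 600)
  expect_equal(mean(adj$trajectory$annual$mat), 10, tolerance = 1e-9)
  expect_equal(mean(adj$trajectory$annual$anp), 600, tolerance = 1e-9)
  expect_equal(adj$delta, 10 - mean(traj$annual$mat))
  expect_equal(adj$factor, 600 / mean(traj$annual$anp))
  # daily arrays shifted/scaled consistently
  expect_equal(adj$trajectory$tas, traj$tas + adj$delta)
  expect_equal(adj$trajectory$prec, traj$prec * adj$factor)
  expect_identical(adj$trajectory$rad, traj$rad)
  expect_identical(adj$trajectory$vpd, traj$vpd)

  # identity adjustment is bitwise identical
  adj0 <- adjust_trajectory(traj, mean(traj$annual$mat),
                            mean(traj$annual$anp))
  expect_equal(adj0$delta, 0, tolerance = 1e-12)
  expect_equal(adj0$factor, 1, tolerance = 1e-12)
  expect_equal(adj0$trajectory$tas, traj$tas)
})

test_that("the year index combines additive T and multiplicative P differences", {
  expect_equal(year_distance(10, 700, 10, 700), 0)
  expect_equal(year_distance(11, 700, 10, 700), 1.0)
  expect_equal(year_distance(10, 770, 10, 700), 1.0)
  expect_error(year_distance(10, 0, 10, 700), "positive")
})

test_that("year matching samples uniformly among the three best years", {
  catal <- fixture_catalogue()
  traj <- catal$trajectories[[1]]
  adj <- adjust_trajectory(traj, 9, 700)$trajectory

  # a scenario year identical to the simulation year is always a candidate
  y <- 30
  sim <- data.frame(year = 1, t = adj$annual$mat[y], p = adj$annual$anp[y])
  hits <- replicate(30, {
    set.seed(sample.int(1e6, 1))
    match_years(sim, adj)$scen_year
  })
  d <- year_distance(sim$t, sim$p, adj$annual$mat, adj$annual$anp)
  top3 <- adj$annual$year[order(d, adj$annual$year)[1:3]]
  expect_true(all(hits %in% top3))
  expect_true(adj$annual$year[y] %in% top3)

  # fixed seed gives an identical mapping
  sim10 <- data.frame(year = 1:10, t = adj$annual$mat[11:20],
                      p = adj$annual$anp[11:20])
  set.seed(123); m1 <- match_years(sim10, adj)
  set.seed(123); m2 <- match_years(sim10, adj)
  expect_identical(m1, m2)

  # chi-square uniformity over 10,000 draws
  set.seed(7)
  draws <- replicate(10000, match_years(sim, adj)$scen_year)
  tab <- table(factor(draws, levels = top3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("daily assembly copies the mapped scenario year", {
  catal <- fixture_catalogue()
  traj <- catal$trajectories[[3]]
  mapping <- data.frame(sim_year = 2020, scen_year = traj$years[5],
                        distance = 0)
  day <- assemble_daily(traj, mapping, 2020)
  expect_length(day$tas, 365)
  expect_equal(day$tas, traj$tas[5, ])
  expect_true(all(day$prec >= 0))
  expect_true(all(day$vpd >= 0))
  # summation oracle: daily precipitation sums to the mapped year's ANP
  expect_equal(sum(day$prec), traj$annual$anp[5], tolerance = 1e-9)
  expect_error(assemble_daily(traj, mapping, 1999), "no year mapping")
})
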