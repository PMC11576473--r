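test_that("conditional R-squared follows the latent-logit formula", {
  expect_identical(conditional_r_squared(0), 0)
  expect_equal(conditional_r_squared(0, c(1.529, 0.123)),
               1.652 / (1.652 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(conditional_r_squared(0, c(1.529, 0.123)), 0.334,
               tolerance = 1e-3)
  # monotone increasing in each variance, bounded in [0, 1)
  vals <- vapply(c(0.1, 1, 10, 1000), conditional_r_squared,
                 numeric(1), random_effect_variances = 0.5)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
  expect_gt(conditional_r_squared(0, 1e6), 0.999)
  expect_error(conditional_r_squared(-1), "non-negative")
  expect_error(conditional_r_squared(0, -0.5), "non-negative")
})

test_that("coefficients of variation match hand-computed values", {
  obs <- tube_observations(day_id = c(1, 1, 2, 2), tube_id = letters[1:4],
                           arm = NA, n_exposed = 10, n_dead = c(3, 5, 5, 7))
  cv <- coefficient_of_variation(obs)
  # daily means 0.4 and 0.6: overall CoV = sd / mean = 0.1414 / 0.5
  expect_equal(cv$overall, sd(c(0.4, 0.6)) / 0.5, tolerance = 1e-12)
  expect_equal(cv$overall, 0.283, tolerance = 1e-3)
  expect_equal(cv$per_day$cov[1], sd(c(0.3, 0.5)) / 0.4, tolerance = 1e-12)

  same <- tube_observations(day_id = c(1, 1, 2, 2), tube_id = letters[1:4],
                            arm = NA, n_exposed = 10, n_dead = c(4, 4, 6, 6))
  expect_equal(coefficient_of_variation(same)$per_day$cov, c(0, 0))

  pooled <- coefficient_of_variation(obs, overall = "pooled")
  expect_equal(pooled$overall, sd(c(0.3, 0.5, 0.5, 0.7)) / 0.5,
               tolerance = 1e-12)

  dead0 <- tube_observations(day_id = c(1, 1, 2, 2), tube_id = letters[1:4],
                             arm = NA, n_exposed = 10, n_dead = 0)
  expect_error(coefficient_of_variation(dead0), "undefined")
  expect_error(coefficient_of_variation(obs[obs$day_id == 1, ]),
               "at least 2 testing days")
})

test_that("variance components need at least two days", {
  one_day <- tube_observations(day_id = 1, tube_id = c("a", "b"), arm = NA,
                               n_exposed = 25, n_dead = c(10, 12))
  expect_error(estimate_variance_components(one_day), "single testing day")
})

test_that("data with no excess variation give near-zero variance components", {
  obs <- tube_observations(
    day_id = rep(1:10, each = 4), tube_id = paste0("t", 1:40), arm = NA,
    n_exposed = 1000, n_dead = 500
  )
  comp <- estimate_variance_components(obs)
  expect_lte(comp$within_day_sd, 0.05)
  expect_lte(comp$between_day_sd, 0.05)
  expect_equal(comp$within_day_variance, comp$within_day_sd^2)
  expect_identical(comp$n_days, 10L)
})

test_that("variance components recover the simulator's SDs", {
  # single large study at high between-day variability
  set.seed(31)
  obs <- simulate_variability_data(200, 10, 25, 0.5,
                                   variance_assumptions(0.35, 1.24))
  comp <- estimate_variance_components(obs)
  expect_lt(abs(comp$within_day_sd - 0.35) / 0.35, 0.15)
  expect_lt(abs(comp$between_day_sd - 1.24) / 1.24, 0.15)

  # repeated moderate-size studies: mean estimate within 10% of truth,
  # individual estimates within 30%
  set.seed(32)
  ests <- t(replicate(20, {
    d <- simulate_variability_data(50, 8, 25, 0.5,
                                   variance_assumptions(0.25, 0.60))
    cc <- estimate_variance_components(d)
    c(cc$within_day_sd, cc$between_day_sd)
  }))
  expect_lt(abs(mean(ests[, 1]) - 0.25) / 0.25, 0.10)
  expect_lt(abs(mean(ests[, 2]) - 0.60) / 0.60, 0.10)
  # individual estimates are mostly close; the within-day SD of a 25-mosquito
  # tube carries limited information, so single-study estimates scatter
  expect_gte(mean(abs(ests[, 1] - 0.25) / 0.25 < 0.30), 0.9)
  expect_gte(mean(abs(ests[, 2] - 0.60) / 0.60 < 0.30), 0.9)
})

test_that("a zero between-day SD is estimated at the boundary, not negative", {
  set.seed(33)
  hits <- replicate(10, {
    d <- simulate_variability_data(30, 6, 25, 0.5,
                                   variance_assumptions(0.25, 0))
    estimate_variance_components(d)$between_day_sd
  })
  expect_true(all(hits >= 0))
  # the ML estimate piles on the zero boundary (~half of all fits) and its
  # nonzero tail with 25-mosquito tubes stays well below the truth-adjacent
  # scale (90th percentile ~0.09, essentially never above 0.15)
  expect_true(any(hits == 0))
  expect_gte(mean(hits <= 0.15), 0.9)
})

test_that("variance reports bundle components, R-squared and CoV", {
  set.seed(34)
  obs <- simulate_variability_data(20, 5, 25, 0.5,
                                   variance_assumptions(0.25, 0.6))
  path <- tempfile(fileext = ".json")
  rep1 <- variance_report(obs, path = path)
  expect_true(file.exists(path))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$within_day_sd, rep1$within_day_sd, tolerance = 1e-9)
  expect_equal(back$conditional_r_squared,
               conditional_r_squared(0, c(rep1$within_day_variance,
                                          rep1$between_day_variance)),
               tolerance = 1e-9)
  expect_identical(nrow(back$per_day_cov), 20L)
})
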