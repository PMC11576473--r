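test_that("power estimates are proportions with the right Monte-Carlo SE", {
  pe <- estimate_power(assay_design(4), effect_spec(0.5, 0.2),
                       variance_assumptions(0.25, 0),
                       replicates = 1000, seed = 1)
  expect_true(pe$power >= 0 && pe$power <= 1)
  expect_equal(pe$mc_standard_error,
               sqrt(pe$power * (1 - pe$power) / 1000))
})

test_that("type-I error with no random effects matches the exact enumeration", {
  reps <- 4000
  pe <- estimate_power(assay_design(4), effect_spec(0.5, 0),
                       variance_assumptions(0, 0),
                       replicates = reps, seed = 202)
  truth <- exact_type1(100, 0.5, alpha = 0.05)
  expect_lt(abs(truth - 0.05), 0.01)  # test is near exact scale
  se <- sqrt(truth * (1 - truth) / reps)
  expect_lt(abs(pe$power - truth), 3 * se)
})

test_that("overdispersion keeps the null rejection rate at or above alpha", {
  reps <- 4000
  pe <- estimate_power(assay_design(4), effect_spec(0.5, 0),
                       variance_assumptions(0.35, 0),
                       replicates = reps, seed = 203)
  expect_gte(pe$power, 0.05 - 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("power is monotone in effect size and in tubes per arm", {
  reps <- 3000
  p_diff <- vapply(c(0.10, 0.20, 0.30), function(d)
    estimate_power(assay_design(4), effect_spec(0.5, d),
                   variance_assumptions(0.25, 0),
                   replicates = reps, seed = 301)$power, numeric(1))
  se <- sqrt(0.25 / reps)
  expect_true(all(diff(p_diff) > -3 * sqrt(2) * se))

  p_tubes <- vapply(c(4, 7, 10), function(tt)
    estimate_power(assay_design(tt), effect_spec(0.5, 0.2),
                   variance_assumptions(0.25, 0),
                   replicates = reps, seed = 302)$power, numeric(1))
  expect_true(all(diff(p_tubes) > -3 * sqrt(2) * se))
})

test_that("splitting tubes over days never beats running them on one day", {
  reps <- 4000
  single <- estimate_power(assay_design(4, 1), effect_spec(0.5, 0.25),
                           variance_assumptions(0.25, 0.6),
                           replicates = reps, seed = 401)$power
  for (dd in c(2L, 4L)) {
    multi <- estimate_power(assay_design(4, dd), effect_spec(0.5, 0.25),
                            variance_assumptions(0.25, 0.6),
                            replicates = reps, seed = 400 + dd)$power
    expect_lte(multi, single + 3 * sqrt(2 * 0.25 / reps))
  }
})

test_that("an arm at 100% mortality is easier to detect than mid-range mortality", {
  reps <- 3000
  edge <- estimate_power(assay_design(4), effect_spec(0.90, 0.10),
                         variance_assumptions(0.25, 0),
                         replicates = reps, seed = 501)$power
  mid <- estimate_power(assay_design(4), effect_spec(0.50, 0.10),
                        variance_assumptions(0.25, 0),
                        replicates = reps, seed = 502)$power
  expect_gt(edge, mid)
})

test_that("power estimates are reproducible under a fixed seed", {
  a <- estimate_power(assay_design(5, 2), effect_spec(0.5, 0.2),
                      variance_assumptions(0.25, 0.6),
                      replicates = 500, seed = 77)
  b <- estimate_power(assay_design(5, 2), effect_spec(0.5, 0.2),
                      variance_assumptions(0.25, 0.6),
                      replicates = 500, seed = 77)
  expect_identical(a$power, b$power)
})

test_that("grids enumerate the full Cartesian product with per-cell seeds", {
  full <- grid_combinations(simulation_grid())
  expect_identical(nrow(full), 21L * 7L * 5L * 5L * 5L)
  expect_false(anyDuplicated(full[, 1:5]) > 0)

  small <- simulation_grid(differences = c(0.2, 0.5), tubes_per_arm = c(4, 10),
                           days = 1, within_day_sds = 0.25,
                           between_day_sds = 0.6, replicates = 100,
                           base_seed = 5)
  tab <- power_grid(small)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$power >= 0 & tab$power <= 1))
  expect_equal(tab$mc_standard_error,
               sqrt(tab$power * (1 - tab$power) / tab$replicates))
  # bit-reproducibility of the whole grid
  expect_identical(tab, power_grid(small))
  # chunked evaluation returns the matching subset
  expect_identical(power_grid(small, cells = c(2, 3)),
                   `rownames<-`(tab[2:3, ], NULL))
})

test_that("extreme effects reach near-certain detection", {
  tab <- power_grid(simulation_grid(differences = 0.5, tubes_per_arm = 10,
                                    days = 1, within_day_sds = 0.25,
                                    between_day_sds = 0.6,
                                    replicates = 800, base_seed = 2))
  expect_true(all(tab$power >= 0.99))
})

test_that("grid caches round-trip losslessly and reject malformed input", {
  small <- simulation_grid(differences = c(0.1, 0.3), tubes_per_arm = 4,
                           days = 1, within_day_sds = 0.25,
                           between_day_sds = 0.6, replicates = 50,
                           base_seed = 9)
  tab <- power_grid(small)
  path <- tempfile(fileext = ".csv")
  save_grid(tab, path)
  back <- load_grid(path)
  expect_equal(back, tab[, names(back)], tolerance = 1e-12)
  expect_true(file.exists(sub("\\.csv$", ".json", path)))

  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(load_grid(empty), "malformed|no lines")

  mangled <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), mangled)
  expect_error(load_grid(mangled), "missing column")

  hit <- grid_lookup(back, 0.1, 4, 1, 0.25, 0.6)
  expect_identical(nrow(hit), 1L)
  expect_error(grid_lookup(back, 0.2, 4, 1, 0.25, 0.6),
               class = "tubepower_not_precomputed")
})

test_that("the MDD search follows the first-crossing rule on the 2.5% grid", {
  res <- min_detectable_difference(assay_design(4),
                                   variance_assumptions(0.25, 0),
                                   replicates = 1500, seed = 10)
  expect_true(res$achievable)
  expect_true(any(abs(res$mdd - seq(0, 0.5, by = 0.025)) < 1e-9))
  # the reported value is the first evaluated difference reaching the target
  below <- res$curve$power[res$curve$difference < res$mdd]
  expect_true(all(below < 0.80))
  expect_gte(res$curve$power[nrow(res$curve)], 0.80)
})

test_that("degenerate and truncated MDD scans behave as documented", {
  res0 <- min_detectable_difference(assay_design(4),
                                    variance_assumptions(0.25, 0),
                                    power_target = 0, replicates = 50,
                                    seed = 1)
  expect_identical(res0$mdd, 0)

  expect_warning(
    min_detectable_difference(assay_design(4), variance_assumptions(0.25, 0),
                              reference_mortality = 0.9, replicates = 200,
                              seed = 1),
    "truncated"
  )
})

test_that("the minimum-tubes search returns the smallest adequate design", {
  res <- min_tubes_for_difference(0.5, variance_assumptions(0.25, 0),
                                  replicates = 500, seed = 3)
  expect_identical(res$min_tubes, 4L)

  expect_warning(
    res2 <- min_tubes_for_difference(0.5, variance_assumptions(0.25, 0.6),
                                     days = 5, tubes_range = 4:6,
                                     replicates = 300, seed = 3),
    "fewer tubes than testing days"
  )
  expect_false(4L %in% res2$curve$tubes_per_arm)
})
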