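test_that("generated datasets honour the configured structure", {
  params <- generator_params(seed = 3)
  ds <- generate_field_dataset(params)

  expect_s3_class(ds, "field_dataset")
  expect_equal(length(unique(ds$segments$transect_id)), 135)
  expect_true(all(ds$segments$length_m <= 30))
  expect_true(all(ds$segments$length_m >= 1))
  expect_equal(nrow(ds$leaf_counts), 241)
  expect_true(all(ds$leaf_counts$n_leaves >= 1))
  expect_equal(nrow(ds$leaf_areas), 349)
  expect_true(all(ds$leaf_areas$area_mm2 > 0))
  expect_equal(nrow(ds$consumption), 10)
  expect_equal(sum(ds$consumption$sex == "female"), 5)

  # deterministic given the seed
  expect_identical(generate_field_dataset(params), ds)

  # all structural zeros
  all_zero <- generate_field_dataset(generator_params(
    density_zero_weight = 1, density_rate = 1, seed = 4))
  expect_true(all(all_zero$segments$violet_count == 0))
})

test_that("written datasets round-trip through the CSV readers", {
  dir <- withr::local_tempdir()
  ds <- generate_field_dataset(generator_params(seed = 8))
  write_field_dataset(ds, dir)
  back <- read_field_dataset(dir)
  expect_equal(back$segments, ds$segments)
  expect_equal(back$leaf_counts, ds$leaf_counts)
  expect_equal(back$leaf_areas, ds$leaf_areas)
  expect_equal(back$consumption, ds$consumption)
  expect_equal(back$params$seed, 8L)
})

test_that("zero-count fraction exceeds the structural zero weight", {
  # Poisson sampling adds zeros on top of the structural ones
  for (seed in c(1, 2)) {
    ds <- generate_field_dataset(generator_params(n_transects = 600,
                                                  seed = seed))
    expect_gte(nrow(ds$segments), 1000)
    frac_zero <- mean(ds$segments$violet_count == 0)
    expect_gt(frac_zero, 0.55)
  }
})

test_that("zero fraction and mean density track the generator's parameters", {
  # large run pinning the zero fraction against its analytic expectation:
  # P(count = 0) = w + (1 - w) E[exp(-rate_exp_draw * area)]
  params <- generator_params(n_transects = 2500, seed = 10)
  ds <- generate_field_dataset(params)
  area <- ds$segments$area_m2
  # for an exponential(r) latent density, E[e^-dA] = r / (r + A)
  r <- params$density_rate
  expected_zero <- params$density_zero_weight +
    (1 - params$density_zero_weight) * mean(r / (r + area))
  expect_equal(mean(ds$segments$violet_count == 0), expected_zero,
               tolerance = 0.03)
  # law of large numbers: pooled density approaches the mixture mean
  expect_equal(pooled_density(ds$segments), 0.037, tolerance = 0.05)
})

test_that("doubling the belt width doubles expected counts", {
  base <- generator_params(n_transects = 2000, seed = 5)
  wide <- generator_params(n_transects = 2000, belt_width_m = 4, seed = 5)
  c1 <- sum(generate_field_dataset(base)$segments$violet_count)
  c2 <- sum(generate_field_dataset(wide)$segments$violet_count)
  # Poisson totals: 3 SE band around the 2x ratio
  se_ratio <- 2 * sqrt(1 / c1 + 1 / c2)
  expect_lt(abs(c2 / c1 - 2), 3 * se_ratio)
})

test_that("end-to-end recovery selects the right families and matches the oracle", {
  report <- end_to_end_recovery_check(
    generator_params(n_transects = 1000, n_leafcount_plants = 2000,
                     n_leafarea_leaves = 2000, n_larvae = 50, seed = 6),
    n_iterations = 2000, n_density_draws = 500)
  expect_equal(unname(report$selected_families[["leaves"]]), "lognormal")
  expect_equal(unname(report$selected_families[["leafarea"]]), "gamma")
  # lognormal parameters recovered within 3 SE (discretisation absorbed)
  n <- 2000
  expect_lt(abs(report$leaves_fit$params[["meanlog"]] - 2.05),
            3 * 0.792 / sqrt(n) + 0.06) # + ceil() discretisation bias bound
  # simulated mean within 15% of the semi-analytic expectation
  expect_lt(abs(report$mean_ratio - 1), 0.15)
  expect_gte(report$density_lrt$statistic, 0)
})

test_that("near-degenerate generator parameters give a near-deterministic simulation", {
  report <- end_to_end_recovery_check(
    generator_params(n_transects = 300,
                     density_zero_weight = 0.05,
                     leaves_meanlog = 3, leaves_sdlog = 0.02,
                     leafarea_shape = 2500, leafarea_rate = 12.5,
                     consumption_weibull_shape = 80,
                     consumption_scale_female_m2 = 0.025,
                     consumption_scale_male_m2 = 0.025,
                     n_leafcount_plants = 500, n_leafarea_leaves = 500,
                     n_larvae = 40, seed = 9),
    n_iterations = 500, n_density_draws = 2000)
  s <- report$sim_summary
  # spread collapses when every input is a near point mass
  expect_lt((s[["q75"]] - s[["q25"]]) / s[["median"]], 0.1)
})
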