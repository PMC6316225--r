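# Fitted-parameter objects for the headline study regime: leaves per plant
# lognormal(2.05, 0.792), leaf area gamma(3.00, 0.0151) mm2, consumption
# Weibull(6.53, 0.027) m2, density mixture with mean 0.037 per m2, study
# area 243,206.5 m2.
study_fits <- function() {
  list(density = ziexp_spec(zero_weight = 0.5, mean = 0.037),
       leaves = dist_spec("lognormal", meanlog = 2.05, sdlog = 0.792),
       leafarea = dist_spec("gamma", shape = 3.00, rate = 0.0151),
       consumption = dist_spec("weibull", shape = 6.53, scale = 0.027))
}

STUDY_AREA_M2 <- 243206.5

study_sim_config <- function(n_iterations = 10000, n_density_draws = 1000,
                             seed = 42) {
  sim_config(n_iterations = n_iterations, n_density_draws = n_density_draws,
             reference_area_m2 = STUDY_AREA_M2, seed = seed,
             leaf_area_unit_in = "mm2", consumption_unit_in = "m2")
}

run_study_simulation <- function(n_iterations = 10000, seed = 42) {
  fits <- study_fits()
  run_simulation(study_sim_config(n_iterations = n_iterations, seed = seed),
                 density_fit = fits$density, leaves_fit = fits$leaves,
                 leafarea_fit = fits$leafarea,
                 consumption_fit = fits$consumption)
}

# small segments table with known arithmetic
toy_segments <- function() {
  as_segments(data.frame(
    transect_id = c("T1", "T1", "T2", "T2"),
    segment_id = c("S1", "S2", "S1", "S2"),
    length_m = c(30, 20, 30, 30),
    belt_width_m = 2,
    violet_count = c(12L, 0L, 6L, 0L)))
}

# mean and mean reciprocal of a fitted family by quadrature on the
# probability scale; independent of the sampling path under test
quad_mean <- function(fit) {
  integrate(function(p) quantile_from_fit(fit, p), 0, 1, rel.tol = 1e-9)$value
}

quad_reciprocal_mean <- function(fit) {
  integrate(function(p) 1 / quantile_from_fit(fit, p), 0, 1,
            rel.tol = 1e-9)$value
}
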