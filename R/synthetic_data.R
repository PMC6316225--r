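## Synthetic field-data generator. The raw 2013 survey tables are not
## public, so the generator emulates their statistical structure: belt
## transects partitioned into <=30 m segments with zero-inflated
## exponential latent densities and Poisson counts, log-normal leaves per
## plant, gamma leaf areas, and Weibull larval consumption with a sex
## effect. Every downstream stage of the package can then be exercised
## end to end against known truth.

#' Parameters of the synthetic field-data generator
#'
#' Defaults mirror the study conditions the analysis was designed for: 135
#' belt transects averaging 92.16 m split into 30 m segments; per-segment
#' latent density from a zero-inflated exponential with mixture mean 0.037
#' plants per square metre (structural zero weight 0.55, a calibration
#' choice recorded in the manifest); leaves per plant log-normal(2.05,
#' 0.792) rounded up to integers; leaf areas gamma(shape 3.00, rate 0.0151)
#' in mm2; consumption Weibull with shared shape 6.53 and sex-specific
#' scales giving mean totals of about 290.6 (female) and 196.7 (male) cm2;
#' 241 plants, 349 leaves, and 10 larvae sexed 1:1.
#'
#' @param n_transects Number of belt transects.
#' @param mean_transect_length_m Average transect length in metres.
#' @param max_segment_length_m Full segment length in metres.
#' @param belt_width_m Belt width in metres.
#' @param density_zero_weight Structural zero weight of the latent density
#'   mixture.
#' @param density_rate Exponential rate of the positive density component;
#'   default derived so the mixture mean is `density_mean`.
#' @param density_mean Target mixture mean, plants per square metre.
#' @param leaves_meanlog,leaves_sdlog Log-normal parameters of leaves per
#'   plant.
#' @param leafarea_shape,leafarea_rate Gamma parameters of leaf area (mm2).
#' @param consumption_weibull_shape Shared Weibull shape of consumption.
#' @param consumption_scale_female_m2,consumption_scale_male_m2 Sex-specific
#'   Weibull scales, in m2.
#' @param n_leafcount_plants,n_leafarea_leaves,n_larvae Sample sizes of the
#'   three measurement tables.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A named list of class `generator_params`.
#' @export
generator_params <- function(n_transects = 135,
                             mean_transect_length_m = 92.16,
                             max_segment_length_m = MAX_SEGMENT_LENGTH_M,
                             belt_width_m = DEFAULT_BELT_WIDTH_M,
                             density_zero_weight = 0.55,
                             density_rate = NULL,
                             density_mean = 0.037,
                             leaves_meanlog = 2.05,
                             leaves_sdlog = 0.792,
                             leafarea_shape = 3.00,
                             leafarea_rate = 0.0151,
                             consumption_weibull_shape = 6.53,
                             consumption_scale_female_m2 = 0.02906 /
                               gamma(1 + 1 / 6.53),
                             consumption_scale_male_m2 = 0.01967 /
                               gamma(1 + 1 / 6.53),
                             n_leafcount_plants = 241,
                             n_leafarea_leaves = 349,
                             n_larvae = 10,
                             seed = 1L) {
  if (is.null(density_rate)) {
    density_rate <- (1 - density_zero_weight) / density_mean
  }
  p <- list(n_transects = as.integer(n_transects),
            mean_transect_length_m = mean_transect_length_m,
            max_segment_length_m = max_segment_length_m,
            belt_width_m = belt_width_m,
            density_zero_weight = density_zero_weight,
            density_rate = density_rate,
            leaves_meanlog = leaves_meanlog,
            leaves_sdlog = leaves_sdlog,
            leafarea_shape = leafarea_shape,
            leafarea_rate = leafarea_rate,
            consumption_weibull_shape = consumption_weibull_shape,
            consumption_scale_female_m2 = consumption_scale_female_m2,
            consumption_scale_male_m2 = consumption_scale_male_m2,
            n_leafcount_plants = as.integer(n_leafcount_plants),
            n_leafarea_leaves = as.integer(n_leafarea_leaves),
            n_larvae = as.integer(n_larvae),
            seed = as.integer(seed))
  stopifnot(p$n_transects >= 1, p$mean_transect_length_m > 0,
            p$max_segment_length_m > 0, p$belt_width_m > 0,
            p$density_zero_weight >= 0, p$density_zero_weight <= 1,
            p$density_rate > 0, p$leaves_sdlog > 0, p$leafarea_shape > 0,
            p$leafarea_rate > 0, p$consumption_weibull_shape > 0,
            p$consumption_scale_female_m2 > 0,
            p$consumption_scale_male_m2 > 0,
            p$n_leafcount_plants >= 1, p$n_leafarea_leaves >= 1,
            p$n_larvae >= 1)
  structure(p, class = "generator_params")
}

split_transect <- function(length_m, max_len) {
  n_full <- floor(length_m / max_len)
  rem <- length_m - n_full * max_len
  lens <- rep(max_len, n_full)
  if (rem >= 1) lens <- c(lens, rem) # sub-metre stubs are not surveyed
  lens
}

#' Generate a synthetic field dataset
#'
#' Transect lengths are drawn from a gamma distribution (shape 2) with the
#' configured mean, rounded to 0.1 m, and partitioned into full segments
#' plus a remainder of at least 1 m. Each segment receives a latent density
#' from the zero-inflated exponential and a violet count drawn
#' Poisson(density x area), so counts are integers and zero inflation
#' carries both structural zeros (empty latent density) and sampling zeros
#' (Poisson misses at low density). Leaf counts are log-normal draws rounded
#' up to integers; leaf areas gamma; consumption sex-specific Weibull with
#' sexes assigned alternately female/male.
#'
#' @param params A [generator_params()].
#' @return A list of class `field_dataset` with elements `segments`,
#'   `leaf_counts`, `leaf_areas`, `consumption` (data frames in the reader
#'   schemas), and `params`.
#' @export
generate_field_dataset <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  p <- params

  tr_len <- round(stats::rgamma(p$n_transects, shape = 2,
                                rate = 2 / p$mean_transect_length_m), 1)
  tr_len <- pmax(tr_len, 1)
  seg_lens <- lapply(tr_len, split_transect, max_len = p$max_segment_length_m)
  n_seg <- lengths(seg_lens)
  segments <- data.frame(
    transect_id = rep(sprintf("T%03d", seq_len(p$n_transects)), n_seg),
    segment_id = unlist(lapply(n_seg, function(k) sprintf("S%02d", seq_len(k)))),
    length_m = unlist(seg_lens),
    belt_width_m = p$belt_width_m,
    stringsAsFactors = FALSE)
  area <- segments$length_m * segments$belt_width_m

  dens_model <- ziexp_spec(p$density_zero_weight, rate = p$density_rate)
  latent <- sample_ziexp(dens_model, nrow(segments))
  segments$violet_count <- stats::rpois(nrow(segments), latent * area)
  segments <- as_segments(segments, max_length_m = p$max_segment_length_m)

  leaf_counts <- data.frame(
    plant_id = sprintf("P%04d", seq_len(p$n_leafcount_plants)),
    n_leaves = as.integer(ceiling(stats::rlnorm(p$n_leafcount_plants,
                                                p$leaves_meanlog,
                                                p$leaves_sdlog))),
    stringsAsFactors = FALSE)

  leaf_areas <- data.frame(
    leaf_id = sprintf("L%04d", seq_len(p$n_leafarea_leaves)),
    area_mm2 = stats::rgamma(p$n_leafarea_leaves, shape = p$leafarea_shape,
                             rate = p$leafarea_rate),
    stringsAsFactors = FALSE)

  sex <- rep(c("female", "male"), length.out = p$n_larvae)
  scale_m2 <- ifelse(sex == "female", p$consumption_scale_female_m2,
                     p$consumption_scale_male_m2)
  consumption <- data.frame(
    larva_id = sprintf("C%02d", seq_len(p$n_larvae)),
    sex = sex,
    total_area_cm2 = stats::rweibull(p$n_larvae,
                                     shape = p$consumption_weibull_shape,
                                     scale = scale_m2) * 1e4,
    stringsAsFactors = FALSE)

  structure(list(segments = segments, leaf_counts = leaf_counts,
                 leaf_areas = leaf_areas, consumption = consumption,
                 params = params),
            class = "field_dataset")
}

#' Write a synthetic dataset to a directory of CSV tables
#'
#' Writes `segments.csv`, `leaf_counts.csv`, `leaf_areas.csv`,
#' `consumption.csv` in the dialects the readers accept, plus
#' `manifest.json` recording the true generator parameters and seed.
#'
#' @param dataset A `field_dataset` from [generate_field_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "field_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(dataset$segments, file.path(dir, "segments.csv"))
  write_leaf_counts(dataset$leaf_counts, file.path(dir, "leaf_counts.csv"))
  write_leaf_areas(dataset$leaf_areas, file.path(dir, "leaf_areas.csv"))
  write_consumption(dataset$consumption, file.path(dir, "consumption.csv"))
  jsonlite::write_json(unclass(dataset$params),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_field_dataset()]
#'
#' @param dir Directory containing the four CSV tables.
#' @return A `field_dataset` (with `params = NULL` if no manifest present).
#' @export
read_field_dataset <- function(dir) {
  structure(list(
    segments = read_segments(file.path(dir, "segments.csv")),
    leaf_counts = read_leaf_counts(file.path(dir, "leaf_counts.csv")),
    leaf_areas = read_leaf_areas(file.path(dir, "leaf_areas.csv")),
    consumption = read_consumption(file.path(dir, "consumption.csv")),
    params = if (file.exists(file.path(dir, "manifest.json"))) {
      do.call(generator_params,
              jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE))
    }),
    class = "field_dataset")
}

#' End-to-end recovery check on synthetic data
#'
#' Generates a dataset, runs the full pipeline — mixture and family fits
#' with AIC selection, the capacity simulation, and the semi-analytic
#' expectation of the pupae count — and reports fitted-versus-true
#' parameters. The mixture refit sees Poisson-sampled counts rather than
#' the latent densities, so its recovered parameters are expected to drift
#' from the generator's (sampling zeros inflate the zero weight); the
#' mixture mean and the simulation are the quantities that should agree.
#'
#' @param params A [generator_params()].
#' @param n_iterations,n_density_draws Simulation size of the check.
#' @param reference_area_m2 Reference area of the check simulation.
#' @return A list with the fits, the selected family labels, the simulated
#'   pupae summary, the semi-analytic expected mean, and their ratio.
#' @export
end_to_end_recovery_check <- function(params = generator_params(),
                                      n_iterations = 2000,
                                      n_density_draws = 1000,
                                      reference_area_m2 = 243206.5) {
  dataset <- generate_field_dataset(params)

  dens <- segment_densities(dataset$segments)
  zi <- fit_ziexp(dens)
  lrt <- likelihood_ratio_test(zi, fit_exponential(dens))

  leaves_fit <- select_best_model(dataset$leaf_counts$n_leaves)
  leafarea_fit <- select_best_model(dataset$leaf_areas$area_mm2)
  consumption_fit <- select_best_model(dataset$consumption$total_area_cm2)

  cfg <- sim_config(n_iterations = n_iterations,
                    n_density_draws = n_density_draws,
                    reference_area_m2 = reference_area_m2,
                    seed = params$seed,
                    leaf_area_unit_in = "mm2",
                    consumption_unit_in = "cm2")
  sim <- run_simulation(cfg, density_fit = zi, leaves_fit = leaves_fit,
                        leafarea_fit = leafarea_fit,
                        consumption_fit = consumption_fit)

  expected <- reference_area_m2 * zi$mean * fit_mean(leaves_fit) *
    fit_mean(leafarea_fit) * 1e-6 *
    fit_reciprocal_mean(consumption_fit) * 1e4

  list(true_params = params,
       density_fit = zi,
       density_lrt = lrt,
       leaves_fit = leaves_fit,
       leafarea_fit = leafarea_fit,
       consumption_fit = consumption_fit,
       selected_families = c(leaves = leaves_fit$family,
                             leafarea = leafarea_fit$family,
                             consumption = consumption_fit$family),
       sim_summary = sim$summary,
       expected_mean = expected,
       mean_ratio = sim$summary[["mean"]] / expected)
}

## E[X] and E[1/X] of a fitted family by adaptive quadrature on the
## quantile scale (integrating q(p) dp avoids infinite-domain issues)
fit_mean <- function(fit) {
  stats::integrate(function(p) quantile_from_fit(fit, p), 0, 1,
                   rel.tol = 1e-9)$value
}

fit_reciprocal_mean <- function(fit) {
  stats::integrate(function(p) 1 / quantile_from_fit(fit, p), 0, 1,
                   rel.tol = 1e-9)$value
}
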