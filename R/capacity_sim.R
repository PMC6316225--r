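## Monte Carlo simulation of the number of pupae a site's host biomass can
## support:
##   leaf area present [m2] = area sampled [m2] x plant density [1/m2]
##                            x leaves per plant x leaf area per leaf [m2]
##   pupae supported        = leaf area present / leaf area consumed per
##                            larva [m2]
## Each iteration draws leaves per plant, leaf area and consumption once
## from their fitted distributions; plant density enters as the mean of a
## block of draws from the zero-inflated mixture, which keeps single
## iterations away from all-zero densities while preserving between-
## iteration variation in the mean.

unit_to_m2 <- function(unit) {
  switch(unit,
    m2 = 1,
    cm2 = 1e-4,
    mm2 = 1e-6,
    stop("unknown area unit '", unit, "' (use m2, cm2 or mm2)", call. = FALSE))
}

#' Simulation configuration
#'
#' @param n_iterations Number of Monte Carlo iterations (default 10,000).
#' @param n_density_draws Mixture draws averaged to form each iteration's
#'   plant density (default 1,000).
#' @param reference_area_m2 The "area sampled" of the leaf-area identity; the
#'   total study-site area for a site-level capacity run.
#' @param seed Optional integer seed; when non-`NULL`, [run_simulation()]
#'   seeds the R generator so runs are exactly reproducible.
#' @param leaf_area_unit_in Unit the leaf-area distribution is expressed in
#'   (`"mm2"` by default; converted to m2 internally).
#' @param consumption_unit_in Unit the consumption distribution is expressed
#'   in (`"cm2"` by default at I/O; a fit stated directly in m2 uses
#'   `"m2"`).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(n_iterations = 10000, n_density_draws = 1000,
                       reference_area_m2, seed = NULL,
                       leaf_area_unit_in = "mm2",
                       consumption_unit_in = "cm2") {
  stopifnot(n_iterations >= 1, n_density_draws >= 1, reference_area_m2 > 0)
  unit_to_m2(leaf_area_unit_in)
  unit_to_m2(consumption_unit_in)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_density_draws = as.integer(n_density_draws),
                 reference_area_m2 = reference_area_m2,
                 seed = seed,
                 leaf_area_unit_in = leaf_area_unit_in,
                 consumption_unit_in = consumption_unit_in),
            class = "sim_config")
}

#' Leaf area present at a site
#'
#' `area_m2 * density * leaves * leaf_area`, with the per-leaf area
#' converted to square metres.
#'
#' @param area_m2 Reference ground area in square metres, positive.
#' @param density Plant density per square metre.
#' @param leaves Leaves per plant.
#' @param leaf_area Area of one leaf, in `unit`.
#' @param unit Unit of `leaf_area`: `"mm2"` (default), `"cm2"` or `"m2"`.
#' @return Total leaf area in square metres.
#' @export
leaf_area_present <- function(area_m2, density, leaves, leaf_area,
                              unit = "mm2") {
  if (area_m2 <= 0) stop("area must be positive", call. = FALSE)
  if (any(density < 0) || any(leaves < 0) || any(leaf_area < 0)) {
    stop("density, leaves and leaf area must be non-negative", call. = FALSE)
  }
  area_m2 * density * leaves * leaf_area * unit_to_m2(unit)
}

#' Pupae supported by a given leaf area
#'
#' Leaf area present divided by the leaf area one larva consumes to reach
#' pupation; the continuous quotient is returned, not rounded.
#'
#' @param leaf_area_present_m2 Leaf area present, square metres, non-negative.
#' @param consumption_m2 Leaf area consumed per larva, square metres, positive.
#' @return Number of pupae supported (continuous).
#' @export
pupae_supported <- function(leaf_area_present_m2, consumption_m2) {
  if (any(leaf_area_present_m2 < 0)) {
    stop("leaf area present must be non-negative", call. = FALSE)
  }
  if (any(consumption_m2 <= 0)) {
    stop("consumption must be positive", call. = FALSE)
  }
  leaf_area_present_m2 / consumption_m2
}

draw_density_means <- function(density_fit, n_iterations, n_density_draws) {
  ## one block of mixture draws per iteration, reduced to its mean; blocked
  ## to bound memory when iterations x draws is large
  out <- numeric(n_iterations)
  block <- max(1L, min(n_iterations, as.integer(2e6 / n_density_draws)))
  i <- 1L
  while (i <= n_iterations) {
    j <- min(n_iterations, i + block - 1L)
    m <- matrix(sample_ziexp(density_fit, (j - i + 1L) * n_density_draws),
                nrow = j - i + 1L)
    out[i:j] <- rowMeans(m)
    i <- j + 1L
  }
  out
}

#' Run the capacity Monte Carlo simulation
#'
#' Per iteration: the plant density is the mean of `n_density_draws` draws
#' from the zero-inflated exponential `density_fit` (or the fixed value
#' `fixed_density` when supplied, bypassing the density stage); one draw
#' each is taken from the leaves-per-plant, leaf-area and consumption fits;
#' and the pupae count follows from [leaf_area_present()] and
#' [pupae_supported()]. All draws use inversion, so a run is fully
#' deterministic given `config$seed`.
#'
#' A consumption draw of exactly 0 (possible only for families whose support
#' touches 0) is rejected and redrawn; the number of redraws is recorded in
#' the result as `n_consumption_redraws`.
#'
#' @param config A [sim_config()].
#' @param density_fit A `ziexp_fit` for plant density per square metre;
#'   ignored when `fixed_density` is given.
#' @param leaves_fit,leafarea_fit,consumption_fit `dist_fit` objects for
#'   leaves per plant, leaf area per leaf (in `config$leaf_area_unit_in`),
#'   and leaf area consumed per larva (in `config$consumption_unit_in`).
#' @param fixed_density Optional fixed plant density per square metre.
#' @return An object of class `pupae_sample`: a list with `values` (the
#'   `n_iterations` pupae counts), `iterations` (a data frame of the drawn
#'   terms), `summary` (from [summarize_pupae()]), the `config`, and
#'   `n_consumption_redraws`.
#' @export
run_simulation <- function(config, density_fit = NULL, leaves_fit,
                           leafarea_fit, consumption_fit,
                           fixed_density = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(fixed_density) && !inherits(density_fit, "ziexp_fit")) {
    stop("supply a ziexp_fit density model or a fixed density", call. = FALSE)
  }
  if (!is.null(fixed_density) && fixed_density < 0) {
    stop("fixed density must be non-negative", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_iterations

  mean_density <- if (is.null(fixed_density)) {
    draw_density_means(density_fit, n, config$n_density_draws)
  } else {
    rep(fixed_density, n)
  }
  leaves <- sample_from_fit(leaves_fit, n)
  la_draw <- sample_from_fit(leafarea_fit, n)
  cons_draw <- sample_from_fit(consumption_fit, n)

  n_redraw <- 0L
  repeat {
    zero <- which(cons_draw <= 0)
    if (length(zero) == 0) break
    n_redraw <- n_redraw + length(zero)
    cons_draw[zero] <- sample_from_fit(consumption_fit, length(zero))
  }

  la_present <- config$reference_area_m2 * mean_density * leaves *
    la_draw * unit_to_m2(config$leaf_area_unit_in)
  cons_m2 <- cons_draw * unit_to_m2(config$consumption_unit_in)
  pupae <- la_present / cons_m2

  structure(list(values = pupae,
                 iterations = data.frame(mean_density = mean_density,
                                         leaves_per_plant = leaves,
                                         leaf_area_per_leaf = la_draw,
                                         consumption = cons_m2,
                                         leaf_area_present = la_present,
                                         pupae = pupae),
                 summary = summarize_values(pupae),
                 config = config,
                 n_consumption_redraws = n_redraw),
            class = "pupae_sample")
}

summarize_values <- function(values,
                             probs = c(0.025, 0.25, 0.5, 0.75, 0.95, 0.975)) {
  q <- stats::quantile(values, probs, type = 7, names = FALSE)
  names(q) <- sprintf("q%g", 100 * probs)
  c(mean = mean(values), median = stats::median(values), q)
}

#' Summary statistics of a simulated pupae distribution
#'
#' Mean, median, and quantiles (type-7 interpolation).
#'
#' @param sample A `pupae_sample` from [run_simulation()], or a numeric
#'   vector of simulated values.
#' @param probs Quantile probabilities.
#' @return Named numeric vector.
#' @export
summarize_pupae <- function(sample,
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.95, 0.975)) {
  values <- if (inherits(sample, "pupae_sample")) sample$values else sample
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  summarize_values(values, probs)
}

#' Percentile rank of a value within the simulated distribution
#'
#' `100 x` the fraction of simulated values strictly below `value`; used to
#' place an independent adult population estimate within the simulated pupae
#' distribution.
#'
#' @inheritParams summarize_pupae
#' @param value The reference value (e.g. a mark-release-recapture adult
#'   estimate).
#' @return Percentage in `[0, 100]`.
#' @export
percentile_rank <- function(sample, value) {
  values <- if (inherits(sample, "pupae_sample")) sample$values else sample
  if (length(values) == 0) stop("empty sample", call. = FALSE)
  100 * mean(values < value)
}

#' @export
print.pupae_sample <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Simulated pupae supported (%d iterations, area %.1f m2)\n",
              x$config$n_iterations, x$config$reference_area_m2))
  cat(sprintf("  mean = %.1f, median = %.1f\n", s[["mean"]], s[["median"]]))
  cat(sprintf("  quartiles [%.1f, %.1f], 95th percentile = %.1f\n",
              s[["q25"]], s[["q75"]], s[["q95"]]))
  if (x$n_consumption_redraws > 0) {
    cat(sprintf("  (%d zero consumption draws rejected and redrawn)\n",
                x$n_consumption_redraws))
  }
  invisible(x)
}
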