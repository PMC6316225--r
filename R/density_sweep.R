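## Re-run the capacity simulation over a grid of fixed plant densities and
## regress the per-density median pupae count on density. Because every
## other term of the leaf-area identity is independent of density, the
## medians are proportional to density up to Monte Carlo noise, and the
## spread of the simulated distribution widens with density.

#' Default density grid: 0.010 to 0.100 plants per square metre, step 0.001
#' @export
DEFAULT_DENSITY_GRID <- seq(0.010, 0.100, by = 0.001)

#' Simulate pupae supported across a grid of plant densities
#'
#' At each grid density, [run_simulation()] is run with the density fixed
#' (the mixture-draw stage bypassed) and the same leaves, leaf-area and
#' consumption fits; the 25th, 50th and 75th percentiles of the pupae
#' distribution are recorded. The per-density medians are then regressed on
#' density by [fit_density_regression()] (skipped, with a message recorded,
#' when the grid has fewer than 2 points).
#'
#' @param config A [sim_config()]; `config$seed` (when set) seeds the whole
#'   sweep, and each density re-uses `config$n_iterations` iterations.
#' @param leaves_fit,leafarea_fit,consumption_fit As in [run_simulation()].
#' @param grid Strictly increasing vector of positive densities per square
#'   metre.
#' @return An object of class `sweep_result`: a data frame `table` with
#'   columns `density`, `q25`, `median`, `q75`, plus the `regression`
#'   (slope, intercept, r_squared) when the grid allows one.
#' @export
run_sweep <- function(config, leaves_fit, leafarea_fit, consumption_fit,
                      grid = DEFAULT_DENSITY_GRID) {
  stopifnot(inherits(config, "sim_config"))
  if (length(grid) < 1 || any(grid <= 0)) {
    stop("density grid must be positive", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("density grid must be strictly increasing", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL # one seeding for the whole sweep, set above

  rows <- lapply(grid, function(d) {
    sim <- run_simulation(inner, leaves_fit = leaves_fit,
                          leafarea_fit = leafarea_fit,
                          consumption_fit = consumption_fit,
                          fixed_density = d)
    q <- stats::quantile(sim$values, c(0.25, 0.5, 0.75), type = 7,
                         names = FALSE)
    data.frame(density = d, q25 = q[1], median = q[2], q75 = q[3])
  })
  tab <- do.call(rbind, rows)
  out <- structure(list(table = tab, regression = NULL), class = "sweep_result")
  if (length(grid) >= 2) out$regression <- fit_density_regression(out)
  out
}

#' Regress median pupae on plant density
#'
#' Ordinary least squares of the per-density median pupae count on density.
#' The slope is in pupae per unit density (plants per square metre); at a
#' fixed reference area it summarises how many additional pupae each unit of
#' plant density supports.
#'
#' @param sweep A `sweep_result` from [run_sweep()], or a data frame with
#'   columns `density` and `median`.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value`, and the
#'   underlying `lm` fit as `model`.
#' @export
fit_density_regression <- function(sweep) {
  tab <- if (inherits(sweep, "sweep_result")) sweep$table else sweep
  if (NROW(tab) < 2) {
    stop("need at least 2 grid points for a regression", call. = FALSE)
  }
  fit <- stats::lm(median ~ density, data = tab)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]),
       model = fit)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Density sweep over %d densities [%.3f, %.3f] per m2\n",
              nrow(x$table), min(x$table$density), max(x$table$density)))
  if (!is.null(x$regression)) {
    cat(sprintf("  median pupae ~ density: slope = %.1f, intercept = %.3f, r2 = %.4f\n",
                x$regression$slope, x$regression$intercept,
                x$regression$r_squared))
  }
  invisible(x)
}
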