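## Field tables: belt-transect segments, leaves per plant, leaf areas,
## larval consumption, and the site configuration constants.

#' Default belt width of a transect segment, in metres
#'
#' Plants are counted within one metre of each side of the transect line,
#' giving a 2 m belt.
#' @export
DEFAULT_BELT_WIDTH_M <- 2

#' Maximum segment length, in metres
#'
#' Transects are broken into segments of at most 30 m.
#' @export
MAX_SEGMENT_LENGTH_M <- 30

resolve_input <- function(path) {
  if (inherits(path, "connection")) return(path)
  if (identical(path, "-")) return(file("stdin"))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  path
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

row_check <- function(ok, what, msg) {
  bad <- which(!ok)
  if (length(bad) > 0) {
    stop(sprintf("%s: %s at row(s) %s", what, msg,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
}

#' Read belt-transect segment records
#'
#' Reads a CSV of belt-transect segments with columns `transect_id`,
#' `segment_id`, `length_m`, `violet_count`, and optionally `belt_width_m`
#' (default `r DEFAULT_BELT_WIDTH_M` m). Each row is one segment of at most
#' `max_length_m` metres with its violet count; the sampled area of a segment
#' is `length_m * belt_width_m`.
#'
#' @param path Path to a CSV file, `"-"` for standard input, or a connection.
#' @param max_length_m Maximum admissible segment length in metres.
#' @return A data frame with columns `transect_id`, `segment_id`, `length_m`,
#'   `belt_width_m`, `violet_count`, `area_m2`, and `density_per_m2`
#'   (= `violet_count / area_m2`), one row per segment in file order.
#' @seealso [segment_densities()], [pooled_density()], [write_segments()]
#' @export
read_segments <- function(path, max_length_m = MAX_SEGMENT_LENGTH_M) {
  df <- utils::read.csv(resolve_input(path), stringsAsFactors = FALSE)
  require_columns(df, c("transect_id", "segment_id", "length_m", "violet_count"),
                  "segments table")
  if (is.null(df$belt_width_m)) df$belt_width_m <- DEFAULT_BELT_WIDTH_M
  as_segments(df[, c("transect_id", "segment_id", "length_m", "belt_width_m",
                     "violet_count")], max_length_m = max_length_m)
}

#' Validate a data frame of segment records
#'
#' @param df Data frame with columns `transect_id`, `segment_id`, `length_m`,
#'   `belt_width_m`, `violet_count`.
#' @inheritParams read_segments
#' @return The validated data frame with derived `area_m2` and
#'   `density_per_m2` columns.
#' @export
as_segments <- function(df, max_length_m = MAX_SEGMENT_LENGTH_M) {
  what <- "segments table"
  require_columns(df, c("transect_id", "segment_id", "length_m", "belt_width_m",
                        "violet_count"), what)
  row_check(is.finite(df$length_m) & df$length_m > 0, what,
            "segment length must be positive")
  row_check(df$length_m <= max_length_m, what,
            sprintf("segment length exceeds %g m", max_length_m))
  row_check(is.finite(df$belt_width_m) & df$belt_width_m > 0, what,
            "belt width must be positive")
  row_check(is.finite(df$violet_count) & df$violet_count >= 0 &
              df$violet_count == round(df$violet_count), what,
            "violet count must be a non-negative integer")
  df$violet_count <- as.integer(df$violet_count)
  df$area_m2 <- df$length_m * df$belt_width_m
  df$density_per_m2 <- df$violet_count / df$area_m2
  rownames(df) <- NULL
  df
}

#' Read leaves-per-plant records
#'
#' CSV columns: `plant_id`, `n_leaves` (positive integer).
#'
#' @inheritParams read_segments
#' @return A data frame with columns `plant_id` and `n_leaves`.
#' @export
read_leaf_counts <- function(path) {
  df <- utils::read.csv(resolve_input(path), stringsAsFactors = FALSE)
  require_columns(df, c("plant_id", "n_leaves"), "leaf-count table")
  row_check(is.finite(df$n_leaves) & df$n_leaves >= 1 &
              df$n_leaves == round(df$n_leaves),
            "leaf-count table", "n_leaves must be a positive integer")
  df$n_leaves <- as.integer(df$n_leaves)
  df[, c("plant_id", "n_leaves")]
}

#' Read leaf-area records
#'
#' CSV columns: `leaf_id`, `area_mm2` (positive, in square millimetres).
#'
#' @inheritParams read_segments
#' @return A data frame with columns `leaf_id` and `area_mm2`.
#' @export
read_leaf_areas <- function(path) {
  df <- utils::read.csv(resolve_input(path), stringsAsFactors = FALSE)
  require_columns(df, c("leaf_id", "area_mm2"), "leaf-area table")
  row_check(is.finite(df$area_mm2) & df$area_mm2 > 0,
            "leaf-area table", "area_mm2 must be positive")
  df[, c("leaf_id", "area_mm2")]
}

#' Read larval consumption records
#'
#' CSV columns: `larva_id`, `sex` (one of `female`, `male`, `unknown`), and
#' `total_area_cm2`, the total leaf area one larva consumed from first instar
#' to pupation, in square centimetres.
#'
#' @inheritParams read_segments
#' @return A data frame with columns `larva_id`, `sex`, `total_area_cm2`.
#' @export
read_consumption <- function(path) {
  df <- utils::read.csv(resolve_input(path), stringsAsFactors = FALSE)
  require_columns(df, c("larva_id", "sex", "total_area_cm2"),
                  "consumption table")
  row_check(df$sex %in% c("female", "male", "unknown"),
            "consumption table", "sex must be female, male or unknown")
  row_check(is.finite(df$total_area_cm2) & df$total_area_cm2 > 0,
            "consumption table", "total_area_cm2 must be positive")
  df[, c("larva_id", "sex", "total_area_cm2")]
}

#' Read the site configuration
#'
#' YAML or JSON file with fields `total_area_m2`, `adult_estimate`,
#' `adult_ci_low`, `adult_ci_high`: the study-site area and the adult
#' mark-release-recapture population estimate with its 95% confidence
#' interval (an input constant, not a quantity this package estimates).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated named list.
#' @export
read_site_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  site_config(cfg$total_area_m2, cfg$adult_estimate, cfg$adult_ci_low,
              cfg$adult_ci_high)
}

#' Construct a site configuration
#'
#' @param total_area_m2 Total study-site area in square metres.
#' @param adult_estimate Adult population point estimate (mark-release-recapture).
#' @param adult_ci_low,adult_ci_high 95% confidence bounds on the estimate.
#' @return A named list of class `site_config`.
#' @export
site_config <- function(total_area_m2, adult_estimate = NA_real_,
                        adult_ci_low = NA_real_, adult_ci_high = NA_real_) {
  stopifnot(is.numeric(total_area_m2), total_area_m2 > 0)
  if (!is.na(adult_estimate)) {
    stopifnot(adult_estimate > 0)
    if (!is.na(adult_ci_low) && !is.na(adult_ci_high) &&
        !(adult_ci_low <= adult_estimate && adult_estimate <= adult_ci_high)) {
      stop("adult estimate must lie within its confidence interval",
           call. = FALSE)
    }
  }
  structure(list(total_area_m2 = total_area_m2,
                 adult_estimate = adult_estimate,
                 adult_ci_low = adult_ci_low,
                 adult_ci_high = adult_ci_high),
            class = "site_config")
}

#' Pooled violet density across all segments
#'
#' Total violets counted divided by total belt area sampled, in plants per
#' square metre. This pools all segments regardless of transect, so long
#' transects carry proportionally more weight.
#'
#' @param segments A segments data frame, as from [read_segments()].
#' @return Density in plants per square metre.
#' @seealso [mean_transect_density()] for the per-transect average.
#' @export
pooled_density <- function(segments) {
  if (NROW(segments) == 0) stop("no segments supplied", call. = FALSE)
  sum(segments$violet_count) / sum(segments$area_m2)
}

#' Mean of per-transect violet densities
#'
#' Computes the density of each transect (its total count over its total belt
#' area) and returns the unweighted mean across transects, in plants per
#' square metre. Unlike [pooled_density()] this gives every transect equal
#' weight, which down-weights a few long, dense transects.
#'
#' @inheritParams pooled_density
#' @return Density in plants per square metre.
#' @export
mean_transect_density <- function(segments) {
  if (NROW(segments) == 0) stop("no segments supplied", call. = FALSE)
  counts <- tapply(segments$violet_count, segments$transect_id, sum)
  areas <- tapply(segments$area_m2, segments$transect_id, sum)
  mean(counts / areas)
}

#' Per-segment violet densities
#'
#' Violet count over belt area for every segment, in input order. This vector
#' (with its many exact zeros from empty segments) is the data the
#' zero-inflated exponential mixture [fit_ziexp()] is fitted to.
#'
#' @inheritParams pooled_density
#' @return Numeric vector of densities in plants per square metre.
#' @export
segment_densities <- function(segments) {
  segments$violet_count / segments$area_m2
}

#' Write field tables to CSV
#'
#' Inverse of the corresponding readers; round-trips records exactly.
#'
#' @param segments,leaf_counts,leaf_areas,consumption Data frames as returned
#'   by the readers.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments[, c("transect_id", "segment_id", "length_m",
                                "belt_width_m", "violet_count")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
write_leaf_counts <- function(leaf_counts, path) {
  utils::write.csv(leaf_counts[, c("plant_id", "n_leaves")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
write_leaf_areas <- function(leaf_areas, path) {
  utils::write.csv(leaf_areas[, c("leaf_id", "area_mm2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_segments
#' @export
write_consumption <- function(consumption, path) {
  utils::write.csv(consumption[, c("larva_id", "sex", "total_area_cm2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
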