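## Distribution-aware capacity: rather than assuming larvae reach every
## plant at the site, count the transect segments that individually hold
## enough plants to feed one larva to pupation at average leaf metrics, and
## extrapolate that count from the sampled belt area to the whole site.

#' Plants needed to support one pupa
#'
#' Ceiling of the leaf area one larva consumes over the average leaf area a
#' plant offers (`mean_leaves x mean_leaf_area_cm2`).
#'
#' @param consumption_cm2 Leaf area consumed per larva, square centimetres.
#' @param mean_leaves Average leaves per plant.
#' @param mean_leaf_area_cm2 Average area of one leaf, square centimetres.
#' @return Integer threshold number of plants.
#' @export
plants_per_pupa_threshold <- function(consumption_cm2, mean_leaves,
                                      mean_leaf_area_cm2) {
  if (consumption_cm2 <= 0 || mean_leaves <= 0 || mean_leaf_area_cm2 <= 0) {
    stop("all inputs must be positive", call. = FALSE)
  }
  as.integer(ceiling(consumption_cm2 / (mean_leaves * mean_leaf_area_cm2)))
}

#' Count segments with enough plants to support a pupa
#'
#' @param segments A segments data frame, as from [read_segments()].
#' @param threshold Minimum violet count for a segment to qualify.
#' @param full_length_only When `TRUE` (default) only full-length segments
#'   (`length_m == max_length_m`) are considered, so the sampled area is a
#'   whole number of full belts.
#' @param max_length_m Full segment length in metres.
#' @return A list with `n_supporting_segments`, `sampled_area_m2` (total belt
#'   area of the considered segments), and `supporting` (the qualifying
#'   rows).
#' @export
count_supporting_segments <- function(segments, threshold,
                                      full_length_only = TRUE,
                                      max_length_m = MAX_SEGMENT_LENGTH_M) {
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  considered <- if (full_length_only) {
    segments[segments$length_m == max_length_m, , drop = FALSE]
  } else {
    segments
  }
  supporting <- considered[considered$violet_count >= threshold, ,
                           drop = FALSE]
  list(n_supporting_segments = nrow(supporting),
       sampled_area_m2 = sum(considered$area_m2),
       supporting = supporting)
}

#' Extrapolate supporting segments to the whole site
#'
#' Scales the number of supporting segments by the ratio of total site area
#' to sampled belt area, truncating to a whole number of pupae.
#'
#' @param n_segments Number of supporting segments, non-negative.
#' @param sampled_area_m2 Belt area actually surveyed, square metres.
#' @param total_area_m2 Total site area, square metres (at least
#'   `sampled_area_m2`).
#' @return Integer number of pupae.
#' @export
extrapolate_pupae <- function(n_segments, sampled_area_m2, total_area_m2) {
  if (n_segments < 0) stop("segment count must be non-negative", call. = FALSE)
  if (sampled_area_m2 <= 0) stop("sampled area must be positive", call. = FALSE)
  if (total_area_m2 < sampled_area_m2) {
    stop("total area must be at least the sampled area", call. = FALSE)
  }
  as.integer(floor(n_segments * total_area_m2 / sampled_area_m2))
}

#' Food density: leaf area offered per square metre of ground
#'
#' `mean_density x mean_leaves x mean_leaf_area_cm2`, in square centimetres
#' of leaf per square metre of ground, assuming spatially uniform density.
#'
#' @param mean_density Plants per square metre.
#' @param mean_leaves Average leaves per plant.
#' @param mean_leaf_area_cm2 Average leaf area, square centimetres.
#' @return Food density in cm2 leaf per m2 ground.
#' @export
food_per_area <- function(mean_density, mean_leaves, mean_leaf_area_cm2) {
  if (mean_density < 0 || mean_leaves < 0 || mean_leaf_area_cm2 < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  mean_density * mean_leaves * mean_leaf_area_cm2
}

#' Ground area one larva must graze to reach pupation
#'
#' Consumption divided by food density: the area over which a larva at a
#' uniformly spread food density would have to find and eat every leaf.
#'
#' @param consumption_cm2 Leaf area consumed per larva, square centimetres.
#' @param food_per_m2 Food density from [food_per_area()], cm2 per m2,
#'   positive.
#' @return Area in square metres (unrounded).
#' @export
area_required_per_larva <- function(consumption_cm2, food_per_m2) {
  if (consumption_cm2 <= 0) stop("consumption must be positive", call. = FALSE)
  if (food_per_m2 <= 0) stop("food density must be positive", call. = FALSE)
  consumption_cm2 / food_per_m2
}
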