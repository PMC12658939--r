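# Range-change codes: every pixel falls in exactly one class per species.
RC_ABSENT <- 0L
RC_LOST <- 1L
RC_RETAINED <- 2L
RC_GAINED <- 3L

#' Range-change category codes
#'
#' Integer codes used in range-change maps: `ABSENT = 0`, `LOST = 1`,
#' `RETAINED = 2`, `GAINED = 3`.
#' @return Named integer vector of codes.
#' @export
range_change_codes <- function() {
  c(ABSENT = RC_ABSENT, LOST = RC_LOST, RETAINED = RC_RETAINED,
    GAINED = RC_GAINED)
}

#' Classify per-pixel range change for one species
#'
#' Overlays a species' past and recent presence masks: pixels present in the
#' past but not recently are LOST, present in both RETAINED, newly present
#' GAINED, and never present ABSENT.
#'
#' @param past,recent `bool_raster` presence layers on one grid.
#' @return A `range_change` map: integer matrix of category codes (see
#'   [range_change_codes()]) with the grid attached.
#' @export
classify_range_change <- function(past, recent) {
  assert_same_grid(past, recent)
  g <- raster_grid(past)
  m <- matrix(RC_ABSENT, g$n_rows, g$n_cols)
  m[past & !recent] <- RC_LOST
  m[past & recent] <- RC_RETAINED
  m[!past & recent] <- RC_GAINED
  structure(m, grid = g, class = c("range_change", "matrix", "array"))
}

change_mask <- function(change, code) {
  bool_raster(unclass(change) == code, raster_grid(change))
}

#' Species richness map
#'
#' Per-pixel count of species whose presence mask is TRUE.
#'
#' @param presences Non-empty list of `bool_raster` layers on one grid.
#' @return Integer matrix (class `grid_layer`) of co-occurring species counts.
#' @export
richness_map <- function(presences) {
  if (!length(presences)) stop("empty species collection", call. = FALSE)
  do.call(assert_same_grid, presences)
  g <- raster_grid(presences[[1]])
  acc <- matrix(0L, g$n_rows, g$n_cols)
  for (p in presences) acc <- acc + unclass(p)
  grid_layer(acc, g)
}

#' Local extinction (extirpation) rate map
#'
#' The per-pixel ratio of species lost from the pixel to species present in
#' the past, conditional on past presence: pixels with no past species carry
#' `NA` (the rate is undefined there, not zero). Range gains never offset
#' losses in this statistic.
#'
#' @param past_rich Richness of past presence masks.
#' @param lost_rich Richness of the per-species LOST masks.
#' @return A `grid_layer` of rates in `[0, 1]`, `NA` where past richness is 0.
#' @export
extinction_rate_map <- function(past_rich, lost_rich) {
  assert_same_grid(past_rich, lost_rich)
  if (any(lost_rich > past_rich))
    stop("lost richness exceeds past richness; inputs are inconsistent",
         call. = FALSE)
  g <- raster_grid(past_rich)
  rate <- ifelse(unclass(past_rich) >= 1L,
                 unclass(lost_rich) / unclass(past_rich), NA_real_)
  grid_layer(rate, g)
}

#' Sample representation ratio map
#'
#' Ratio of sampled species co-occurring recently in each pixel to the total
#' number of extant species known from the pixel; a coverage diagnostic for
#' a species sample.
#'
#' @param sampled_rich,total_rich Recent richness of the sample and of the
#'   full species pool, on one grid.
#' @return A `grid_layer` of ratios in `[0, 1]`, `NA` where the total is 0.
#' @export
representation_ratio_map <- function(sampled_rich, total_rich) {
  assert_same_grid(sampled_rich, total_rich)
  if (any(sampled_rich > total_rich))
    stop("sampled richness exceeds total richness", call. = FALSE)
  g <- raster_grid(sampled_rich)
  grid_layer(ifelse(unclass(total_rich) >= 1L,
                    unclass(sampled_rich) / unclass(total_rich), NA_real_), g)
}

#' Per-species range-change summary
#'
#' Areas of past range, loss and gain, percentage lost/gained relative to the
#' past range, and a net classification: `contraction` when loss exceeds gain,
#' `expansion` when gain exceeds loss, and `no_change` when the two areas
#' balance exactly (including the strict case of identical masks).
#'
#' @param change A `range_change` map from [classify_range_change()].
#' @param species_id Optional identifier carried into the output.
#' @return One-row data.frame with columns `species_id`, `area_past_km2`,
#'   `area_lost_km2`, `area_gained_km2`, `pct_lost`, `pct_gained`, `net_class`.
#' @export
species_change_summary <- function(change, species_id = NA_character_) {
  g <- raster_grid(change)
  pa <- pixel_area_km2(g)
  m <- unclass(change)
  n_lost <- sum(m == RC_LOST)
  n_ret <- sum(m == RC_RETAINED)
  n_gain <- sum(m == RC_GAINED)
  n_past <- n_lost + n_ret
  if (n_past == 0L)
    stop("species has no past range on this grid", call. = FALSE)
  net <- n_gain - n_lost
  net_class <- if (net < 0L) "contraction" else if (net > 0L) "expansion" else
    "no_change"
  data.frame(
    species_id = species_id,
    area_past_km2 = n_past * pa,
    area_lost_km2 = n_lost * pa,
    area_gained_km2 = n_gain * pa,
    pct_lost = 100 * n_lost / n_past,
    pct_gained = 100 * n_gain / n_past,
    net_class = net_class,
    stringsAsFactors = FALSE)
}
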