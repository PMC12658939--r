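# Protection time-frame codes (stored in protection maps).
PROT_NEVER <- 0L
PROT_BUFFER <- 1L
PROT_P15 <- 2L
PROT_P70 <- 3L

#' Protection time-frame codes
#'
#' Integer codes for the four mutually exclusive protection categories:
#' `NEVER = 0` (never protected), `BUFFER = 1` (within one pixel of any PA),
#' `P15 = 2` (first protected after the past reference year, by the recent
#' one), `P70 = 3` (protected continuously since the past reference year).
#' @return Named integer vector.
#' @export
protection_codes <- function() {
  c(NEVER = PROT_NEVER, BUFFER = PROT_BUFFER, P15 = PROT_P15, P70 = PROT_P70)
}

#' Construct a protected-area record
#'
#' A PA is described by a polygon boundary or, when no boundary is available,
#' by its centroid plus a reported extent. Records carry an establishment
#' year, an existence status, and an IUCN management category
#' (Ia/Ib/II/III/IV/V/VI, or `unassigned`).
#'
#' @param pa_id Identifier.
#' @param geometry A `planar_polygon`, or `NULL` for centroid-only records.
#' @param centroid Numeric `(x, y)` in km; required when `geometry` is NULL.
#' @param reported_area_km2 Reported extent; required for centroid-only
#'   records.
#' @param year_established Calendar year of establishment.
#' @param status `"current"` for confirmed existing PAs, anything else
#'   (e.g. `"proposed"`) marks records the filters drop.
#' @param iucn_category One of Ia, Ib, II, III, IV, V, VI, or `"unassigned"`.
#' @return An object of class `pa_record`.
#' @export
pa_record <- function(pa_id, geometry = NULL, centroid = NULL,
                      reported_area_km2 = NA_real_, year_established,
                      status = "current", iucn_category = "II") {
  if (is.null(geometry) && is.null(centroid))
    stop("record needs a polygon or a centroid", call. = FALSE)
  structure(list(pa_id = pa_id, geometry = geometry, centroid = centroid,
                 reported_area_km2 = reported_area_km2,
                 year_established = as.integer(year_established),
                 status = status, iucn_category = iucn_category),
            class = "pa_record")
}

#' Filter protected-area records for analysis
#'
#' Keeps only records that are confirmed as currently existing, carry an
#' assigned IUCN category, and are spatially explicit: either a polygon
#' boundary or a centroid with a positive reported extent. Every dropped
#' record is logged with its reason.
#'
#' @param records List of `pa_record`s.
#' @return A list with `kept` (records) and `dropped` (data.frame of
#'   `pa_id`, `reason`).
#' @export
filter_pa <- function(records) {
  kept <- list(); drop_id <- character(); drop_why <- character()
  for (r in records) {
    reason <- NULL
    if (!identical(r$status, "current")) {
      reason <- "status not current"
    } else if (identical(r$iucn_category, "unassigned")) {
      reason <- "no assigned IUCN category"
    } else if (is.null(r$geometry) &&
               (is.null(r$centroid) || !isTRUE(r$reported_area_km2 > 0))) {
      reason <- "no spatially explicit information"
    }
    if (is.null(reason)) kept[[length(kept) + 1L]] <- r
    else { drop_id <- c(drop_id, as.character(r$pa_id)); drop_why <- c(drop_why, reason) }
  }
  list(kept = kept,
       dropped = data.frame(pa_id = drop_id, reason = drop_why,
                            stringsAsFactors = FALSE))
}

#' Realize a centroid-only PA as a circular polygon
#'
#' A PA known only by centroid and reported extent A is demarcated as a
#' circle of radius `r = sqrt(A / pi)` km around the centroid, approximated
#' by a regular 64-gon (whose area is within 0.2 percent of the true circle).
#'
#' @param centroid Numeric `(x, y)` in km.
#' @param reported_area_km2 Reported extent in km2; must be positive.
#' @param n_vertices Number of polygon vertices (default 64).
#' @return A `planar_polygon`.
#' @export
centroid_to_circle <- function(centroid, reported_area_km2, n_vertices = 64L) {
  if (!isTRUE(reported_area_km2 > 0))
    stop("reported area must be positive", call. = FALSE)
  r <- sqrt(reported_area_km2 / pi)
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  planar_polygon(cbind(centroid[1] + r * cos(th), centroid[2] + r * sin(th)))
}

pa_polygon <- function(record) {
  if (!is.null(record$geometry)) record$geometry
  else centroid_to_circle(record$centroid, record$reported_area_km2)
}

#' Classify every pixel into a protection time frame
#'
#' Pixels covered by a PA established in or before `year_past` are `P70`;
#' remaining pixels covered by a PA established by `year_recent` are `P15`;
#' remaining pixels within one pixel (Moore neighbourhood) of the union of
#' all PAs are `BUFFER`; everything else is `NEVER`. Earliest protection wins
#' where PAs overlap, and the buffer is taken around all PAs regardless of
#' their vintage but never overrides a protected pixel.
#'
#' @param records Pre-filtered list of `pa_record`s (see [filter_pa()]).
#' @param grid A `grid_spec`.
#' @param year_past,year_recent Reference years bounding the two protection
#'   epochs (defaults 1970 and 2015).
#' @return A `protection_map`: integer matrix of codes (see
#'   [protection_codes()]) with the grid attached.
#' @export
classify_protection <- function(records, grid, year_past = 1970,
                                year_recent = 2015) {
  p70 <- matrix(FALSE, grid$n_rows, grid$n_cols)
  p15 <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (r in records) {
    if (r$year_established > year_recent) next
    mask <- unclass(rasterize_polygon(pa_polygon(r), grid))
    if (r$year_established <= year_past) p70 <- p70 | mask
    else p15 <- p15 | mask
  }
  p15 <- p15 & !p70
  protected <- p70 | p15
  buf <- unclass(dilate_one_pixel(bool_raster(protected, grid))) & !protected
  m <- matrix(PROT_NEVER, grid$n_rows, grid$n_cols)
  m[buf] <- PROT_BUFFER
  m[p15] <- PROT_P15
  m[p70] <- PROT_P70
  structure(m, grid = grid, class = c("protection_map", "matrix", "array"))
}

#' @export
print.protection_map <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = protection_codes(),
                      labels = names(protection_codes())))
  cat("<protection_map>", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

protection_mask <- function(pmap, codes) {
  bool_raster(matrix(unclass(pmap) %in% codes,
                     nrow(pmap), ncol(pmap)), raster_grid(pmap))
}

#' Protected extent and proportion of one species' range
#'
#' Proportion of the past range protected in the past epoch (pixels in P70)
#' and of the recent range protected in the recent epoch (pixels in P70 or
#' P15), with the corresponding extents in km2 and the change in proportion.
#'
#' @param past,recent `bool_raster` presence layers.
#' @param pmap A `protection_map` on the same grid.
#' @param species_id Optional identifier.
#' @return One-row data.frame: `species_id`, `extent_P70_km2` (past range
#'   inside continuously protected pixels), `extent_P15only_km2` (recent
#'   range inside later-protected pixels), `prop_protected_past`,
#'   `prop_protected_recent`, `delta_prop`. Proportions are `NA` when the
#'   respective range is empty.
#' @export
species_protection_summary <- function(past, recent, pmap,
                                       species_id = NA_character_) {
  assert_same_grid(past, recent, pmap)
  pa <- pixel_area_km2(raster_grid(pmap))
  m <- unclass(pmap)
  n_past <- sum(past); n_recent <- sum(recent)
  n_p70_past <- sum(past & m == PROT_P70)
  n_prot_recent <- sum(recent & (m == PROT_P70 | m == PROT_P15))
  n_p15_recent <- sum(recent & m == PROT_P15)
  prop_past <- if (n_past > 0) n_p70_past / n_past else NA_real_
  prop_recent <- if (n_recent > 0) n_prot_recent / n_recent else NA_real_
  data.frame(
    species_id = species_id,
    extent_P70_km2 = n_p70_past * pa,
    extent_P15only_km2 = n_p15_recent * pa,
    prop_protected_past = prop_past,
    prop_protected_recent = prop_recent,
    delta_prop = prop_recent - prop_past,
    stringsAsFactors = FALSE)
}

#' Decompose a species' range loss by protection time frame
#'
#' Splits the LOST pixels of a range-change map across the three-way
#' protection strata: continuously protected (P70), protected later (P15),
#' and never protected. Buffer pixels are counted in the never-protected
#' stratum, so the three shares always sum to one when any loss occurred.
#'
#' @param change A `range_change` map.
#' @param pmap A `protection_map` on the same grid.
#' @return One-row data.frame with areas (`lost_P70_km2`, `lost_P15_km2`,
#'   `lost_never_km2`) and shares (`share_P70`, `share_P15`, `share_never`);
#'   shares are `NA` when the species lost nothing.
#' @export
loss_by_protection <- function(change, pmap) {
  assert_same_grid(change, pmap)
  pa <- pixel_area_km2(raster_grid(pmap))
  lost <- unclass(change) == RC_LOST
  m <- unclass(pmap)
  n70 <- sum(lost & m == PROT_P70)
  n15 <- sum(lost & m == PROT_P15)
  nnv <- sum(lost & (m == PROT_NEVER | m == PROT_BUFFER))
  tot <- n70 + n15 + nnv
  share <- function(n) if (tot > 0) n / tot else NA_real_
  data.frame(lost_P70_km2 = n70 * pa, lost_P15_km2 = n15 * pa,
             lost_never_km2 = nnv * pa,
             share_P70 = share(n70), share_P15 = share(n15),
             share_never = share(nnv))
}

# ---- GeoJSON interchange for PA records ------------------------------------

#' Write PA records as a GeoJSON FeatureCollection
#'
#' Polygon records are written as Polygon features; centroid-only records as
#' Point features. Attributes (`pa_id`, `year_established`, `status`,
#' `iucn_category`, `reported_area_km2`) travel in the feature properties.
#'
#' @param records List of `pa_record`s.
#' @param path Output path.
#' @export
write_pa_geojson <- function(records, path) {
  feat <- lapply(records, function(r) {
    props <- list(pa_id = r$pa_id, year_established = r$year_established,
                  status = r$status, iucn_category = r$iucn_category,
                  reported_area_km2 = r$reported_area_km2)
    geom <- if (!is.null(r$geometry)) {
      ring <- rbind(r$geometry$exterior, r$geometry$exterior[1, ])
      rings <- c(list(unname(ring)),
                 lapply(r$geometry$holes, function(h) unname(rbind(h, h[1, ]))))
      list(type = "Polygon", coordinates = rings)
    } else {
      list(type = "Point", coordinates = as.numeric(r$centroid))
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = NA, pretty = FALSE,
                       na = "null")
  invisible(path)
}

#' Read PA records from a GeoJSON FeatureCollection
#'
#' @param path File written by [write_pa_geojson()] or any conforming
#'   FeatureCollection of Polygon/Point features with the same properties.
#' @return List of `pa_record`s.
#' @export
read_pa_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  lapply(fc$features, function(f) {
    p <- f$properties
    g <- f$geometry
    area <- if (is.null(p$reported_area_km2)) NA_real_ else
      as.numeric(p$reported_area_km2)
    if (identical(g$type, "Polygon")) {
      rings <- lapply(g$coordinates, function(rg)
        do.call(rbind, lapply(rg, function(xy) as.numeric(unlist(xy)))))
      geom <- planar_polygon(rings[[1]], holes = rings[-1])
      pa_record(p$pa_id, geometry = geom, reported_area_km2 = area,
                year_established = p$year_established, status = p$status,
                iucn_category = p$iucn_category)
    } else {
      pa_record(p$pa_id, centroid = as.numeric(unlist(g$coordinates)),
                reported_area_km2 = area,
                year_established = p$year_established, status = p$status,
                iucn_category = p$iucn_category)
    }
  })
}
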