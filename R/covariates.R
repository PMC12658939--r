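#' Intersect biome and anthrome classes into bioanthromes
#'
#' A bioanthrome is the unique combination of a biome (natural ecoregion
#' aggregate) and an anthrome (anthropogenic land-use class). Each observed
#' pair receives its own id; the label table records the constituent classes.
#' Pixels missing either input are missing in the output.
#'
#' @param biomes,anthromes Integer class-id matrices (`grid_layer`s) on one
#'   grid; `NA` marks missing.
#' @return A list of class `bioanthrome_raster`: `values` (`grid_layer` of
#'   bioanthrome ids) and `labels` (data.frame `id`, `biome`, `anthrome`).
#' @export
build_bioanthromes <- function(biomes, anthromes) {
  assert_same_grid(biomes, anthromes)
  g <- raster_grid(biomes)
  b <- as.integer(unclass(biomes)); a <- as.integer(unclass(anthromes))
  ok <- !is.na(b) & !is.na(a)
  key <- ifelse(ok, paste(b, a, sep = ":"), NA_character_)
  seen <- sort(unique(key[ok]))
  id <- match(key, seen)
  parts <- do.call(rbind, strsplit(seen, ":", fixed = TRUE))
  labels <- data.frame(id = seq_along(seen),
                       biome = as.integer(parts[, 1]),
                       anthrome = as.integer(parts[, 2]))
  structure(list(values = grid_layer(matrix(id, g$n_rows, g$n_cols), g),
                 labels = labels),
            class = "bioanthrome_raster")
}

#' Bin a continuous layer at its quartile cut points
#'
#' Cut points are the 25th/50th/75th percentiles of the non-missing values;
#' intervals are closed on the right (a value equal to a cut point falls in
#' the lower bin). Coarsening continuous covariates this way reduces their
#' variability before matching. A constant layer yields bin 1 everywhere,
#' with a warning.
#'
#' @param values Numeric vector or matrix; `NA`s propagate.
#' @return Integer bins in `{1, 2, 3, 4}`, same shape as the input.
#' @export
quartile_bin <- function(values) {
  v <- as.numeric(values)
  ok <- !is.na(v)
  if (sum(ok) < 4L) stop("need at least 4 non-missing values", call. = FALSE)
  q <- stats::quantile(v[ok], c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(q)) == 1L && q[1] == min(v[ok]) && q[1] == max(v[ok])) {
    warning("constant layer: all values assigned bin 1")
    bins <- ifelse(ok, 1L, NA_integer_)
  } else {
    bins <- rep(NA_integer_, length(v))
    bins[ok] <- 1L + (v[ok] > q[1]) + (v[ok] > q[2]) + (v[ok] > q[3])
  }
  if (is.matrix(values)) {
    out <- matrix(bins, nrow(values), ncol(values))
    if (!is.null(raster_grid(values))) out <- grid_layer(out, raster_grid(values))
    out
  } else bins
}

#' Assemble the pixel-level matching table
#'
#' One row per eligible pixel — those with a defined local extinction rate
#' (at least one species present in the past) and complete covariates. The
#' outcome is the percentage of past species lost from the pixel; covariates
#' carry both continuous values and their pooled quartile bins. Rows dropped
#' for missing covariates are counted in the attached log.
#'
#' @param extinction An extinction-rate `grid_layer` (see
#'   [extinction_rate_map()]).
#' @param pmap A `protection_map`.
#' @param covariates Named list of continuous `grid_layer`s; expected names
#'   `elevation`, `slope`, `pop_density`, `travel_time` (any set accepted).
#' @param bioanthromes A `bioanthrome_raster` from [build_bioanthromes()].
#' @return A data.frame (`pixel_table`) with columns `pixel_id`, `row`,
#'   `col`, `outcome_pct_lost`, `protection` (factor NEVER/BUFFER/P15/P70),
#'   each covariate and its `<name>_bin`, and `bioanthrome_id`. Attribute
#'   `drop_log` records how many eligible pixels were lost to missing
#'   covariates.
#' @export
assemble_pixel_table <- function(extinction, pmap, covariates, bioanthromes) {
  layers <- c(list(extinction, pmap), unname(covariates),
              list(bioanthromes$values))
  do.call(assert_same_grid, layers)
  g <- raster_grid(pmap)

  rate <- as.numeric(unclass(extinction))
  eligible <- !is.na(rate)
  n_eligible <- sum(eligible)
  if (n_eligible == 0L) stop("no pixel has a defined extinction rate",
                             call. = FALSE)

  df <- data.frame(
    pixel_id = seq_len(g$n_rows * g$n_cols),
    row = rep(seq_len(g$n_rows), times = g$n_cols),
    col = rep(seq_len(g$n_cols), each = g$n_rows),
    outcome_pct_lost = 100 * rate,
    protection = factor(names(protection_codes())[match(
      as.integer(unclass(pmap)), protection_codes())],
      levels = c("NEVER", "BUFFER", "P15", "P70")),
    bioanthrome_id = as.integer(unclass(bioanthromes$values)))

  for (nm in names(covariates))
    df[[nm]] <- as.numeric(unclass(covariates[[nm]]))

  df <- df[eligible, , drop = FALSE]

  complete <- stats::complete.cases(df)
  dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  if (nrow(df) == 0L) stop("all eligible pixels have missing covariates",
                           call. = FALSE)

  # pooled quartile bins across all retained pixels (one binning shared by
  # treatment and control groups)
  for (nm in names(covariates))
    df[[paste0(nm, "_bin")]] <- quartile_bin(df[[nm]])

  rownames(df) <- NULL
  attr(df, "drop_log") <- data.frame(n_eligible = n_eligible,
                                     n_dropped_missing = dropped,
                                     n_rows = nrow(df))
  class(df) <- c("pixel_table", "data.frame")
  df
}

covariate_names <- function(table) {
  bins <- grep("_bin$", names(table), value = TRUE)
  sub("_bin$", "", bins)
}

#' Summarize extirpation and protection change by bioanthrome
#'
#' Landscape-level units for regressions of local extinction on protection
#' change: per bioanthrome, the percentage of species locally extinct
#' (pooled lost richness over pooled past richness across its pixels), the
#' proportional change in PA coverage between the two epochs, and the unit
#' area.
#'
#' @param past_rich,lost_rich Richness `grid_layer`s of past presence and of
#'   per-species lost masks.
#' @param pmap A `protection_map`.
#' @param bioanthromes A `bioanthrome_raster`.
#' @return Data.frame: `bioanthrome_id`, `pct_species_locally_extinct`,
#'   `delta_pa_coverage`, `area_km2`. Units with no past species carry `NA`
#'   extinction and are retained for inspection but unusable in regressions.
#' @export
bioanthrome_summary <- function(past_rich, lost_rich, pmap, bioanthromes) {
  assert_same_grid(past_rich, lost_rich, pmap, bioanthromes$values)
  pa <- pixel_area_km2(raster_grid(pmap))
  id <- as.integer(unclass(bioanthromes$values))
  ok <- !is.na(id)
  m <- as.integer(unclass(pmap))[ok]
  pastv <- as.numeric(unclass(past_rich))[ok]
  lostv <- as.numeric(unclass(lost_rich))[ok]
  idv <- id[ok]
  agg <- function(v) tapply(v, idv, sum)
  past_s <- agg(pastv); lost_s <- agg(lostv)
  n_pix <- tapply(idv, idv, length)
  prot70 <- tapply(m == PROT_P70, idv, sum)
  prot15 <- tapply(m == PROT_P70 | m == PROT_P15, idv, sum)
  data.frame(
    bioanthrome_id = as.integer(names(n_pix)),
    pct_species_locally_extinct =
      ifelse(past_s > 0, 100 * lost_s / past_s, NA_real_),
    delta_pa_coverage = prot15 / n_pix - prot70 / n_pix,
    area_km2 = as.numeric(n_pix) * pa,
    row.names = NULL)
}
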