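# Species- and landscape-level linear models of range loss on protection.
#
# All outcomes are percentages on the 0-100 scale. Log transforms use the
# fixed small constants 0.01 (proportional coverage change, i.e. a 1%
# increase) and 1 (extents, i.e. a 1-km2 increase) so that species with no
# change or no protected extent stay in the model.

ols_fit <- function(formula, data, label) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(label = label,
                 coefficients = data.frame(
                   term = rownames(co), estimate = co[, 1],
                   std_error = co[, 2], t_value = co[, 3],
                   p_value = co[, 4], row.names = NULL,
                   stringsAsFactors = FALSE),
                 r_squared = sm$r.squared, n = stats::nobs(fit),
                 lm = fit),
            class = "pa_regression")
}

#' @export
print.pa_regression <- function(x, ...) {
  cat(sprintf("<pa_regression> %s (n = %d, R2 = %.4f)\n", x$label, x$n,
              x$r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Species-level regression of range loss on protection-coverage change
#'
#' OLS of the percentage of range lost on the natural log of the
#' proportional change in protected range coverage plus the constant 0.01
#' (a 1% increase), so species whose protected proportion did not change
#' enter with predictor `log(0.01)`. Species with coverage change at or
#' below -0.01, for which the log is undefined, are excluded with a
#' warning.
#'
#' @param species A data.frame with columns `pct_range_lost` and
#'   `delta_prop` (see [species_protection_summary()]).
#' @return A `pa_regression` (coefficients, R2, n).
#' @export
fit_loss_vs_coverage_change <- function(species) {
  if (nrow(species) < 3L) stop("need at least 3 species", call. = FALSE)
  x <- species$delta_prop + 0.01
  bad <- !(x > 0) | is.na(x)
  if (any(bad)) {
    warning(sprintf(
      "%d species excluded: coverage change <= -0.01 or missing", sum(bad)))
    species <- species[!bad, , drop = FALSE]
    x <- x[!bad]
  }
  dat <- data.frame(y = species$pct_range_lost, lx = log(x))
  if (stats::var(dat$lx) == 0)
    stop("predictor has no variation across species", call. = FALSE)
  ols_fit(y ~ lx, dat, "pct range lost ~ log(coverage change + 0.01)")
}

#' Species-level regressions of range loss on protected extent
#'
#' Two OLS fits of the percentage of range lost on the natural log of a
#' protected extent plus 1 km2: either the extent of range protected
#' continuously since the past reference year (`which = "since_past"`,
#' column `extent_P70_km2`) or the extent protected only in the recent
#' epoch (`which = "recent_only"`, column `extent_P15only_km2`). Species
#' with no protected extent enter with predictor `log(1) = 0`.
#'
#' @param species Data.frame with `pct_range_lost` and the extent columns.
#' @param which Which extent enters the model.
#' @return A `pa_regression`.
#' @export
fit_loss_vs_protected_extent <- function(species,
                                         which = c("since_past",
                                                   "recent_only")) {
  which <- match.arg(which)
  if (nrow(species) < 3L) stop("need at least 3 species", call. = FALSE)
  col <- if (which == "since_past") "extent_P70_km2" else "extent_P15only_km2"
  dat <- data.frame(y = species$pct_range_lost,
                    lx = log(species[[col]] + 1))
  if (stats::var(dat$lx) == 0)
    stop("predictor has no variation across species", call. = FALSE)
  ols_fit(y ~ lx, dat,
          sprintf("pct range lost ~ log(extent %s + 1)", which))
}

#' Landscape-level regression of local extinction on protection change
#'
#' OLS of the percentage of species locally extinct per bioanthrome on the
#' proportional change in PA coverage and the bioanthrome area, the latter
#' either in km2 or its natural log.
#'
#' @param bioanthromes Data.frame from [bioanthrome_summary()] (columns
#'   `pct_species_locally_extinct`, `delta_pa_coverage`, `area_km2`); rows
#'   with missing extinction are dropped.
#' @param area_transform `"identity"` or `"log"`.
#' @return A `pa_regression` with two predictors.
#' @export
fit_extirpation_vs_coverage <- function(bioanthromes,
                                        area_transform = c("identity",
                                                           "log")) {
  area_transform <- match.arg(area_transform)
  b <- bioanthromes[!is.na(bioanthromes$pct_species_locally_extinct), ,
                    drop = FALSE]
  if (nrow(b) < 4L) stop("need at least 4 bioanthromes", call. = FALSE)
  area <- if (area_transform == "log") log(b$area_km2) else b$area_km2
  dat <- data.frame(y = b$pct_species_locally_extinct,
                    coverage = b$delta_pa_coverage, area = area)
  if (abs(stats::cor(dat$coverage, dat$area)) >= 1 - 1e-12)
    stop("predictors are perfectly collinear", call. = FALSE)
  ols_fit(y ~ coverage + area, dat,
          sprintf("pct locally extinct ~ coverage change + area (%s)",
                  area_transform))
}
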