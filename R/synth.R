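# Seeded synthetic worlds with the statistical structure the analysis
# assumes: spatially autocorrelated covariates, contiguous biome/anthrome
# patches, protected areas placed preferentially in remote high terrain
# (confounded placement), blob-shaped species ranges, and a per-pixel
# extirpation process whose probability depends on covariates and
# protection history through known coefficients. Because the generative
# coefficients are known, every treatment effect has a computable truth.

#' Configuration of a synthetic world
#'
#' Defaults describe the standard study world: a 200 x 200 grid of 10-km
#' pixels, 50 species, 60 PAs, strong confounded placement (`gamma = 1.5`),
#' and extirpation offsets calibrated so that category mean extirpation
#' targets roughly 10% in long-protected pixels against roughly 21% in
#' never-protected ones, echoing the magnitude of protection effects
#' reported for terrestrial mammals.
#'
#' @param n_rows,n_cols,pixel_size_km Grid dimensions (see [grid_spec()]).
#' @param n_species Number of species ranges to simulate.
#' @param n_pas Number of protected areas.
#' @param seed Integer seed fixing all randomness.
#' @param smooth_sigma Gaussian-blur radius (pixels) of the covariate and
#'   suitability noise fields; larger = smoother landscapes.
#' @param n_biomes,n_anthromes Number of biome / anthrome classes.
#' @param gamma Confounding strength: PA seed points are drawn with
#'   probability proportional to `exp(gamma * (z_elevation + z_travel))`,
#'   so `gamma = 0` places PAs at random and larger values bias placement
#'   toward remote high terrain.
#' @param beta0 Baseline extirpation log-odds of a never-protected pixel at
#'   average covariates.
#' @param beta_cov Named covariate effects (per SD) on the extirpation
#'   log-odds: `elevation`, `slope`, `pop_density`, `travel_time`.
#' @param delta Named protection offsets (`P70`, `P15`, `BUFFER`) on the
#'   log-odds; negative values are protective.
#' @param frac_pre_past Fraction of PAs established at or before
#'   `year_past`.
#' @param centroid_frac Fraction of PA records emitted centroid-only (with
#'   reported area) to exercise the circle realization rule.
#' @param gain_rate Per-pixel probability that a pixel adjacent to the past
#'   range is gained by the recent epoch (protection-independent).
#' @param pa_radius_km Range of PA blob base radii (km).
#' @param pa_min_sep_km Minimum separation between PA centers (km); spreads
#'   the network across the landscape while keeping the placement bias.
#' @param range_steps Range of region-growing steps for species ranges.
#' @param year_past,year_recent Epoch reference years.
#' @return A `world_config` list.
#' @export
world_config <- function(n_rows = 200, n_cols = 200, pixel_size_km = 10,
                         n_species = 50, n_pas = 60, seed = 1L,
                         smooth_sigma = 6, n_biomes = 3, n_anthromes = 3,
                         gamma = 1.5,
                         beta0 = NULL,
                         beta_cov = c(elevation = -0.30, slope = -0.10,
                                      pop_density = 0.35,
                                      travel_time = -0.30),
                         delta = NULL,
                         frac_pre_past = 0.5, centroid_frac = 0.2,
                         gain_rate = 0.01,
                         pa_radius_km = c(25, 70), pa_min_sep_km = 200,
                         range_steps = c(8, 30),
                         year_past = 1970, year_recent = 2015) {
  if (is.null(beta0)) beta0 <- stats::qlogis(0.21)
  if (is.null(delta))
    delta <- c(P70 = stats::qlogis(0.103) - stats::qlogis(0.21),
               P15 = stats::qlogis(0.158) - stats::qlogis(0.21),
               BUFFER = stats::qlogis(0.168) - stats::qlogis(0.21))
  stopifnot(n_species >= 1, n_pas >= 1,
            smooth_sigma < min(n_rows, n_cols),
            all(c("elevation", "slope", "pop_density", "travel_time") %in%
                  names(beta_cov)),
            all(c("P70", "P15", "BUFFER") %in% names(delta)))
  structure(list(
    n_rows = n_rows, n_cols = n_cols, pixel_size_km = pixel_size_km,
    n_species = n_species, n_pas = n_pas, seed = as.integer(seed),
    smooth_sigma = smooth_sigma, n_biomes = n_biomes,
    n_anthromes = n_anthromes, gamma = gamma, beta0 = beta0,
    beta_cov = beta_cov, delta = delta, frac_pre_past = frac_pre_past,
    centroid_frac = centroid_frac, gain_rate = gain_rate,
    pa_radius_km = pa_radius_km, pa_min_sep_km = pa_min_sep_km,
    range_steps = range_steps,
    year_past = year_past, year_recent = year_recent),
    class = "world_config")
}

# ---- smoothed random fields ------------------------------------------------

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# separable Gaussian blur with renormalized (zero-padded) edges
smooth_matrix <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  blur1 <- function(mat) {
    n <- nrow(mat)
    pad <- matrix(0, r, ncol(mat))
    num <- stats::filter(rbind(pad, mat, pad), k, sides = 2)
    one <- stats::filter(c(rep(0, r), rep(1, n), rep(0, r)), k, sides = 2)
    num <- num[(r + 1):(r + n), , drop = FALSE]
    one <- one[(r + 1):(r + n)]
    num / one
  }
  t(blur1(t(blur1(m))))
}

random_field <- function(n_rows, n_cols, sigma) {
  z <- smooth_matrix(matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols),
                     sigma)
  (z - mean(z)) / stats::sd(z)
}

zscore <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate spatially autocorrelated covariate and class rasters
#'
#' Continuous layers are smoothed seeded Gaussian noise mapped onto
#' realistic scales: elevation (m), slope as the gradient magnitude of
#' elevation (degree-like), log-normal population density (persons/km2) and
#' travel time to the nearest city (minutes). Biomes and anthromes are
#' level sets of independent smoothed fields, giving contiguous patches.
#'
#' @param config A [world_config()].
#' @return List with `grid`, continuous `grid_layer`s (`elevation`,
#'   `slope`, `pop_density`, `travel_time`), categorical layers (`biomes`,
#'   `anthromes`), and z-scored fields `z` used by the generative model.
#' @export
gen_covariates <- function(config) {
  if (config$smooth_sigma >= min(config$n_rows, config$n_cols))
    stop("blur radius exceeds grid size", call. = FALSE)
  set.seed(config$seed + 1L)
  g <- grid_spec(config$n_rows, config$n_cols, config$pixel_size_km)
  nr <- g$n_rows; nc <- g$n_cols; s <- config$smooth_sigma

  z_elev <- random_field(nr, nc, s)
  elevation <- 800 + 600 * z_elev

  # slope from central differences of elevation
  dx <- cbind(elevation[, 2] - elevation[, 1],
              (elevation[, -(1:2), drop = FALSE] -
                 elevation[, 1:(nc - 2), drop = FALSE]) / 2,
              elevation[, nc] - elevation[, nc - 1])
  dy <- rbind(elevation[2, ] - elevation[1, ],
              (elevation[-(1:2), , drop = FALSE] -
                 elevation[1:(nr - 2), , drop = FALSE]) / 2,
              elevation[nr, ] - elevation[nr - 1, ])
  slope <- atan(sqrt(dx^2 + dy^2) / (1000 * g$pixel_size_km)) * 180 / pi

  z_pop <- random_field(nr, nc, s)
  pop_density <- exp(2.5 + 0.8 * z_pop)
  z_tt <- random_field(nr, nc, s)
  travel_time <- exp(4.5 + 0.5 * z_tt)

  cut_classes <- function(field, n) {
    if (n == 1L) return(matrix(1L, nr, nc))
    q <- stats::quantile(field, probs = seq_len(n - 1) / n, names = FALSE)
    matrix(1L + findInterval(field, q), nr, nc)
  }
  biomes <- cut_classes(random_field(nr, nc, 2 * s), config$n_biomes)
  anthromes <- cut_classes(random_field(nr, nc, 1.5 * s), config$n_anthromes)

  list(grid = g,
       elevation = grid_layer(elevation, g),
       slope = grid_layer(slope, g),
       pop_density = grid_layer(pop_density, g),
       travel_time = grid_layer(travel_time, g),
       biomes = grid_layer(biomes, g),
       anthromes = grid_layer(anthromes, g),
       z = list(elevation = zscore(elevation), slope = zscore(slope),
                pop_density = zscore(pop_density),
                travel_time = zscore(travel_time)))
}

# star-shaped blob polygon around a center: a circle with low-order radial
# harmonics, always simple
blob_polygon <- function(center, base_radius, n_vertices = 48L,
                         roughness = 0.25) {
  th <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  rad <- rep(1, n_vertices)
  for (h in 1:3) {
    a <- stats::rnorm(1, 0, roughness / h)
    b <- stats::rnorm(1, 0, roughness / h)
    rad <- rad + a * cos(h * th) + b * sin(h * th)
  }
  rad <- pmax(rad, 0.25) * base_radius
  planar_polygon(cbind(center[1] + rad * cos(th), center[2] + rad * sin(th)))
}

#' Generate protected-area records with confounded placement
#'
#' PA seed pixels are drawn with probability proportional to
#' `exp(gamma * (z_elevation + z_travel_time))`, biasing protection toward
#' remote, high terrain as documented for real PA networks. Each seed grows
#' into a blob polygon; establishment years split before/after the past
#' reference year by `frac_pre_past`; a `centroid_frac` fraction of records
#' is emitted centroid-only with the polygon's area as reported extent.
#'
#' @param config A [world_config()].
#' @param covariates Output of [gen_covariates()].
#' @return List of `pa_record`s.
#' @export
gen_pas <- function(config, covariates) {
  g <- covariates$grid
  n_pix <- g$n_rows * g$n_cols
  if (config$n_pas > n_pix) stop("more PAs than pixels", call. = FALSE)
  set.seed(config$seed + 2L)
  w <- as.numeric(exp(config$gamma *
                        (covariates$z$elevation + covariates$z$travel_time)))
  ctr <- pixel_centers(g)
  # sequential weighted draws with a minimum center separation so the
  # network spreads across the landscape instead of nesting in one hotspot;
  # the marginal placement bias toward high exp(gamma * z) pixels remains
  xs <- rep(ctr$x, each = g$n_rows)
  ys <- rep(ctr$y, times = g$n_cols)
  idx <- integer(config$n_pas)
  blocked <- rep(FALSE, n_pix)
  for (i in seq_len(config$n_pas)) {
    if (sum(w) <= 0) {
      if (all(blocked)) stop("grid cannot hold this many separated PAs",
                             call. = FALSE)
      w[!blocked] <- 1
    }
    cand <- sample.int(n_pix, 1L, prob = w)
    idx[i] <- cand
    near <- (xs - xs[cand])^2 + (ys - ys[cand])^2 < config$pa_min_sep_km^2
    blocked <- blocked | near
    w[near] <- 0
  }
  rows <- (idx - 1L) %% g$n_rows + 1L
  cols <- (idx - 1L) %/% g$n_rows + 1L

  n_pre <- round(config$frac_pre_past * config$n_pas)
  # epoch assigned independently of placement order so both protection
  # vintages share one placement distribution
  pre <- seq_len(config$n_pas) %in% sample.int(config$n_pas, n_pre)
  n_centroid <- round(config$centroid_frac * config$n_pas)
  pick <- unique(round(seq(1, config$n_pas, length.out = max(n_centroid, 0L))))
  if (length(pick) < n_centroid)
    pick <- c(pick, setdiff(seq_len(config$n_pas), pick)[
      seq_len(n_centroid - length(pick))])
  centroid_only <- seq_len(config$n_pas) %in% pick

  cats <- c("Ia", "Ib", "II", "III", "IV", "V", "VI")
  records <- vector("list", config$n_pas)
  for (i in seq_len(config$n_pas)) {
    center <- c(ctr$x[cols[i]], ctr$y[rows[i]])
    radius <- stats::runif(1, config$pa_radius_km[1], config$pa_radius_km[2])
    poly <- blob_polygon(center, radius)
    year <- if (pre[i]) sample(1920:config$year_past, 1) else
      sample((config$year_past + 1L):config$year_recent, 1)
    cat_i <- sample(cats, 1)
    if (centroid_only[i]) {
      records[[i]] <- pa_record(sprintf("PA%03d", i), centroid = center,
                                reported_area_km2 = polygon_area_km2(poly),
                                year_established = year,
                                iucn_category = cat_i)
    } else {
      records[[i]] <- pa_record(sprintf("PA%03d", i), geometry = poly,
                                reported_area_km2 = polygon_area_km2(poly),
                                year_established = year,
                                iucn_category = cat_i)
    }
  }
  records
}

# contiguous range mask: seeded region growing on a smoothed suitability
# field (dilate from the seed, keep pixels above the suitability threshold)
grow_range <- function(grid, suitability, threshold_q, steps) {
  ok <- suitability > stats::quantile(suitability, threshold_q)
  idx_ok <- which(ok)
  if (!length(idx_ok)) return(NULL)
  seed_idx <- idx_ok[sample.int(length(idx_ok), 1)]
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[seed_idx] <- TRUE
  mask <- bool_raster(m, grid)
  for (i in seq_len(steps))
    mask <- bool_raster(unclass(dilate_one_pixel(mask)) & ok, grid)
  mask
}

#' Generate species ranges and the extirpation process
#'
#' Past ranges are contiguous blobs grown on per-species suitability
#' fields. Each past-occupied pixel is extirpated independently with
#' probability `plogis(beta0 + beta_cov . z + delta[category])`, where the
#' category comes from the supplied protection map; recent presence is past
#' minus extirpations plus protection-independent small gains on the range
#' margin. The generative probabilities are returned along with the truth:
#' realized per-category mean extirpation probability and the true ATT of
#' each of the four protection comparisons, computed from the model on the
#' realized landscape.
#'
#' @param config A [world_config()].
#' @param covariates Output of [gen_covariates()].
#' @param pmap A `protection_map` for the same grid.
#' @return List with `past` and `recent` (lists of `bool_raster`, one per
#'   species), `p` (`grid_layer` of per-pixel extirpation probability),
#'   `truth` (see Details).
#' @export
gen_species_and_extirpation <- function(config, covariates, pmap) {
  g <- covariates$grid
  assert_same_grid(covariates$elevation, pmap)
  set.seed(config$seed + 3L)

  bc <- config$beta_cov
  lin_cov <- config$beta0 +
    bc[["elevation"]] * covariates$z$elevation +
    bc[["slope"]] * covariates$z$slope +
    bc[["pop_density"]] * covariates$z$pop_density +
    bc[["travel_time"]] * covariates$z$travel_time
  dvec <- c(NEVER = 0, BUFFER = config$delta[["BUFFER"]],
            P15 = config$delta[["P15"]], P70 = config$delta[["P70"]])
  cat_name <- names(protection_codes())[match(as.integer(unclass(pmap)),
                                              protection_codes())]
  lin <- lin_cov + matrix(dvec[cat_name], g$n_rows, g$n_cols)
  p <- stats::plogis(lin)
  if (any(p <= 0 | p >= 1)) {
    warning("extirpation probabilities clamped away from 0/1")
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  }

  past <- vector("list", config$n_species)
  recent <- vector("list", config$n_species)
  for (s in seq_len(config$n_species)) {
    suit <- random_field(g$n_rows, g$n_cols, config$smooth_sigma)
    steps <- sample(config$range_steps[1]:config$range_steps[2], 1)
    mask <- grow_range(g, suit, threshold_q = 0.4, steps = steps)
    past[[s]] <- mask
    ext <- unclass(mask) & matrix(stats::runif(length(p)) < p,
                                  g$n_rows, g$n_cols)
    surv <- unclass(mask) & !ext
    margin <- unclass(dilate_one_pixel(mask)) & !unclass(mask)
    gains <- margin & matrix(stats::runif(length(p)) < config$gain_rate,
                             g$n_rows, g$n_cols)
    recent[[s]] <- bool_raster(surv | gains, g)
  }

  # truth: eligible pixels are those with at least one past species
  past_rich <- richness_map(past)
  eligible <- unclass(past_rich) >= 1L
  catv <- matrix(cat_name, g$n_rows, g$n_cols)

  realized_means <- vapply(names(dvec), function(cn) {
    sel <- eligible & catv == cn
    if (!any(sel)) return(NA_real_)
    # weight pixels by past richness: each species-pixel is one trial
    sum(p[sel] * unclass(past_rich)[sel]) / sum(unclass(past_rich)[sel])
  }, numeric(1))

  counterfactual_att <- function(treated_cats, control_cat) {
    sel <- eligible & catv %in% treated_cats
    if (!any(sel)) return(NA_real_)
    p_cf <- stats::plogis(lin[sel] - dvec[catv[sel]] + dvec[[control_cat]])
    mean(100 * (p[sel] - p_cf))
  }
  truth <- list(
    realized_category_means = realized_means,
    att = c(a = counterfactual_att(c("P70", "P15"), "NEVER"),
            b = counterfactual_att("P70", "P15"),
            c = counterfactual_att(c("P70", "P15"), "BUFFER"),
            d = counterfactual_att("BUFFER", "NEVER")))

  list(past = past, recent = recent, p = grid_layer(p, g), truth = truth)
}

#' Generate a complete synthetic world
#'
#' Runs covariate generation, PA placement, protection classification, and
#' the species/extirpation process for one seed, returning every layer the
#' analysis pipeline consumes together with the generative truth.
#'
#' @param config A [world_config()].
#' @return List with `config`, `grid`, `covariates`, `pa_records`
#'   (filtered), `pa_dropped`, `pmap`, `species` (the
#'   [gen_species_and_extirpation()] output), and `truth`.
#' @export
gen_world <- function(config = world_config()) {
  covs <- gen_covariates(config)
  pas <- gen_pas(config, covs)
  flt <- filter_pa(pas)
  pmap <- classify_protection(flt$kept, covs$grid,
                              year_past = config$year_past,
                              year_recent = config$year_recent)
  sp <- gen_species_and_extirpation(config, covs, pmap)
  list(config = config, grid = covs$grid, covariates = covs,
       pa_records = flt$kept, pa_dropped = flt$dropped, pmap = pmap,
       species = sp, truth = sp$truth)
}

#' Build the pixel matching table of a synthetic world
#'
#' Convenience wrapper: richness and extinction-rate maps from the world's
#' species layers, bioanthromes from its class rasters, then
#' [assemble_pixel_table()].
#'
#' @param world Output of [gen_world()].
#' @return A `pixel_table` (with attribute `drop_log`), plus attributes
#'   `past_rich` and `lost_rich` for reuse.
#' @export
world_pixel_table <- function(world) {
  past_rich <- richness_map(world$species$past)
  lost <- mapply(function(p, r) change_mask(classify_range_change(p, r),
                                            RC_LOST),
                 world$species$past, world$species$recent,
                 SIMPLIFY = FALSE)
  lost_rich <- richness_map(lost)
  ext <- extinction_rate_map(past_rich, lost_rich)
  ba <- build_bioanthromes(world$covariates$biomes,
                           world$covariates$anthromes)
  tab <- assemble_pixel_table(
    ext, world$pmap,
    covariates = list(elevation = world$covariates$elevation,
                      slope = world$covariates$slope,
                      pop_density = world$covariates$pop_density,
                      travel_time = world$covariates$travel_time),
    bioanthromes = ba)
  attr(tab, "past_rich") <- past_rich
  attr(tab, "lost_rich") <- lost_rich
  attr(tab, "bioanthromes") <- ba
  tab
}
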