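# Shared fixtures, built in code.

# A hand-checkable 3x3 world with 3 species and 2 PAs.
#
# Layout (rows north to south). Species masks:
#   A: past everywhere, recent loses the top row (3 pixels LOST).
#   B: past = left column, recent identical (all RETAINED).
#   C: past = center pixel only, recent = center + east pixel (1 GAINED).
# PA "old" (est. 1960) covers the north-west pixel; PA "new" (est. 1990)
# covers the south-east pixel.
tiny_world <- function() {
  g <- grid_spec(3, 3, pixel_size_km = 10)
  msk <- function(cells) {
    m <- matrix(FALSE, 3, 3)
    for (rc in cells) m[rc[1], rc[2]] <- TRUE
    bool_raster(m, g)
  }
  all9 <- bool_raster(TRUE, g)
  a_recent <- msk(list(c(2, 1), c(2, 2), c(2, 3), c(3, 1), c(3, 2), c(3, 3)))
  b_past <- msk(list(c(1, 1), c(2, 1), c(3, 1)))
  c_past <- msk(list(c(2, 2)))
  c_recent <- msk(list(c(2, 2), c(2, 3)))

  square <- function(r, c) {
    ps <- 10
    planar_polygon(rbind(c((c - 1) * ps, -(r - 1) * ps),
                         c(c * ps, -(r - 1) * ps),
                         c(c * ps, -r * ps),
                         c((c - 1) * ps, -r * ps)))
  }
  pas <- list(
    pa_record("old", geometry = square(1, 1), year_established = 1960,
              iucn_category = "II"),
    pa_record("new", geometry = square(3, 3), year_established = 1990,
              iucn_category = "IV"))

  list(grid = g,
       past = list(A = all9, B = b_past, C = c_past),
       recent = list(A = a_recent, B = b_past, C = c_recent),
       pas = pas,
       pmap = classify_protection(pas, g))
}

# A random polygon-free pixel table for matching/boosting unit tests.
make_table <- function(n, seed = 1, n_bioanthromes = 3,
                       outcome = NULL, protection = NULL) {
  set.seed(seed)
  elev <- rnorm(n); slp <- rnorm(n); pop <- rnorm(n); tt <- rnorm(n)
  tab <- data.frame(
    pixel_id = seq_len(n),
    outcome_pct_lost = if (is.null(outcome)) runif(n, 0, 100) else outcome,
    protection = if (is.null(protection))
      factor(sample(c("NEVER", "BUFFER", "P15", "P70"), n, replace = TRUE),
             levels = c("NEVER", "BUFFER", "P15", "P70"))
    else factor(protection, levels = c("NEVER", "BUFFER", "P15", "P70")),
    bioanthrome_id = sample.int(n_bioanthromes, n, replace = TRUE),
    elevation = elev, slope = slp, pop_density = pop, travel_time = tt,
    elevation_bin = quartile_bin(elev), slope_bin = quartile_bin(slp),
    pop_density_bin = quartile_bin(pop), travel_time_bin = quartile_bin(tt))
  class(tab) <- c("pixel_table", "data.frame")
  tab
}

# Independent oracle for greedy 1:1 nearest-neighbour matching: a literal
# double-loop simulation of the stated procedure.
greedy_match_oracle <- function(scores, treated_ids, control_ids) {
  ord <- treated_ids[order(-scores[treated_ids], treated_ids)]
  avail <- control_ids
  pairs <- NULL
  for (tid in ord) {
    if (!length(avail)) break
    d <- abs(scores[avail] - scores[tid])
    best <- avail[d == min(d)]
    ctrl <- min(best)
    pairs <- rbind(pairs, c(tid, ctrl))
    avail <- setdiff(avail, ctrl)
  }
  data.frame(treated_id = pairs[, 1], control_id = pairs[, 2])
}

# Small synthetic world shared by several suites (cached per session).
.world_cache <- new.env(parent = emptyenv())
small_world <- function() {
  if (is.null(.world_cache$w)) {
    .world_cache$w <- gen_world(world_config(
      seed = 7, n_rows = 70, n_cols = 70, n_species = 15, n_pas = 10,
      pa_min_sep_km = 120, pa_radius_km = c(20, 45)))
  }
  .world_cache$w
}
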