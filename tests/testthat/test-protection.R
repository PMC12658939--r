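test_that("PA filtering keeps only current, categorized, spatially explicit records", {
  poly <- planar_polygon(rbind(c(0, 0), c(10, 0), c(10, -10), c(0, -10)))
  recs <- list(
    pa_record("ok", geometry = poly, year_established = 1960),
    pa_record("uncat", geometry = poly, year_established = 1960,
              iucn_category = "unassigned"),
    pa_record("proposed", geometry = poly, year_established = 1980,
              status = "proposed"),
    pa_record("pt_ok", centroid = c(5, -5), reported_area_km2 = 30,
              year_established = 1990),
    pa_record("pt_noarea", centroid = c(5, -5), year_established = 1990))
  f <- filter_pa(recs)
  expect_equal(vapply(f$kept, function(r) r$pa_id, ""), c("ok", "pt_ok"))
  expect_setequal(f$dropped$pa_id, c("uncat", "proposed", "pt_noarea"))
  expect_true(any(grepl("IUCN", f$dropped$reason)))
  expect_true(any(grepl("spatially explicit", f$dropped$reason)))
})

test_that("centroid records become circles with radius sqrt(A/pi)", {
  c1 <- centroid_to_circle(c(0, 0), pi)
  d1 <- sqrt(rowSums(c1$exterior^2))
  expect_equal(max(abs(d1 - 1)), 0, tolerance = 1e-12)
  c2 <- centroid_to_circle(c(3, -4), 100 * pi)
  d2 <- sqrt((c2$exterior[, 1] - 3)^2 + (c2$exterior[, 2] + 4)^2)
  expect_equal(max(abs(d2 - 10)), 0, tolerance = 1e-10)
  expect_equal(nrow(c2$exterior), 64L)

  # the 64-gon area stays within 0.5% of the reported extent
  for (A in c(pi, 17, 100 * pi, 4000))
    expect_lt(abs(polygon_area_km2(centroid_to_circle(c(0, 0), A)) - A) / A,
              0.005)

  expect_error(centroid_to_circle(c(0, 0), 0), "positive")
  expect_error(centroid_to_circle(c(0, 0), -3), "positive")
})

test_that("protection time frames partition the grid with earliest protection winning", {
  g <- grid_spec(9, 9, 10)
  sq <- function(r1, r2, c1, c2)
    planar_polygon(rbind(c((c1 - 1) * 10, -(r1 - 1) * 10),
                         c(c2 * 10, -(r1 - 1) * 10),
                         c(c2 * 10, -r2 * 10),
                         c((c1 - 1) * 10, -r2 * 10)))
  old <- pa_record("old", geometry = sq(4, 6, 4, 6), year_established = 1960)
  pm <- classify_protection(list(old), g)
  codes <- protection_codes()
  expect_true(all(pm[4:6, 4:6] == codes["P70"]))
  expect_true(all(pm[3, 3:7] == codes["BUFFER"]))
  expect_true(all(pm[c(1, 9), ] == codes["NEVER"]))
  expect_equal(sum(pm == codes["P70"]), 9L)
  expect_equal(sum(pm == codes["BUFFER"]), 16L)

  # overlapping newer PA: overlap stays P70, its own extension becomes P15
  new <- pa_record("new", geometry = sq(5, 8, 5, 8), year_established = 1990)
  pm2 <- classify_protection(list(old, new), g)
  expect_true(all(pm2[5:6, 5:6] == codes["P70"]))
  expect_true(all(pm2[7:8, 7:8] == codes["P15"]))
  # partition: every pixel exactly one category
  expect_true(all(unclass(pm2) %in% codes))
})

test_that("protection classification equals brute-force per-pixel rule evaluation", {
  g <- grid_spec(20, 20, 10)
  set.seed(12)
  recs <- lapply(1:6, function(i) {
    ctr <- c(runif(1, 20, 180), -runif(1, 20, 180))
    pa_record(paste0("p", i),
              geometry = centroid_to_circle(ctr, runif(1, 300, 2500)),
              year_established = sample(c(1950, 1960, 1980, 2000), 1))
  })
  pm <- classify_protection(recs, g)

  masks <- lapply(recs, function(r) unclass(rasterize_polygon(r$geometry, g)))
  yrs <- vapply(recs, function(r) r$year_established, 0)
  p70 <- Reduce(`|`, masks[yrs <= 1970], matrix(FALSE, 20, 20))
  p15 <- Reduce(`|`, masks[yrs > 1970 & yrs <= 2015],
                matrix(FALSE, 20, 20)) & !p70
  prot <- p70 | p15
  buf <- unclass(dilate_one_pixel(bool_raster(prot, g))) & !prot
  expected <- matrix(protection_codes()["NEVER"], 20, 20)
  expected[buf] <- protection_codes()["BUFFER"]
  expected[p15] <- protection_codes()["P15"]
  expected[p70] <- protection_codes()["P70"]
  expect_equal(unclass(pm)[, ], expected, ignore_attr = TRUE)
})

test_that("species protection summary measures range-protection overlap", {
  g <- grid_spec(9, 9, 10)
  w <- tiny_world()  # not used here; build a dedicated case
  sq <- planar_polygon(rbind(c(0, 0), c(90, 0), c(90, -90), c(0, -90)))
  pm_all <- classify_protection(list(
    pa_record("all", geometry = sq, year_established = 1950)), g)
  rng <- bool_raster(matrix(c(rep(TRUE, 20), rep(FALSE, 61)), 9, 9), g)
  s <- species_protection_summary(rng, rng, pm_all, "sp")
  expect_equal(s$prop_protected_past, 1)
  expect_equal(s$prop_protected_recent, 1)
  expect_equal(s$delta_prop, 0)

  pm_none <- classify_protection(list(
    pa_record("far", geometry = planar_polygon(
      rbind(c(500, 0), c(600, 0), c(600, -100), c(500, -100))),
      year_established = 1950)), g)
  s2 <- species_protection_summary(rng, rng, pm_none, "sp")
  expect_equal(s2$prop_protected_past, 0)
  expect_equal(s2$prop_protected_recent, 0)

  empty <- bool_raster(FALSE, g)
  s3 <- species_protection_summary(empty, rng, pm_all, "sp")
  expect_true(is.na(s3$prop_protected_past))
})

test_that("species protection proportions match brute-force pixel intersections", {
  w <- small_world()
  codes <- protection_codes()
  m <- unclass(w$pmap)
  for (s in c(1, 5, 9)) {
    past <- unclass(w$species$past[[s]]); recent <- unclass(w$species$recent[[s]])
    out <- species_protection_summary(w$species$past[[s]],
                                      w$species$recent[[s]], w$pmap)
    expect_equal(out$prop_protected_past,
                 sum(past & m == codes["P70"]) / sum(past))
    expect_equal(out$prop_protected_recent,
                 sum(recent & (m == codes["P70"] | m == codes["P15"])) /
                   sum(recent))
    expect_equal(out$extent_P70_km2,
                 sum(past & m == codes["P70"]) * 100)
    expect_equal(out$extent_P15only_km2,
                 sum(recent & m == codes["P15"]) * 100)
  }
})

test_that("loss decomposes across the three protection strata", {
  w <- small_world()
  codes <- protection_codes()
  m <- unclass(w$pmap)
  any_loss <- FALSE
  for (s in seq_along(w$species$past)) {
    ch <- classify_range_change(w$species$past[[s]], w$species$recent[[s]])
    d <- loss_by_protection(ch, w$pmap)
    lost <- unclass(ch) == range_change_codes()["LOST"]
    if (sum(lost) == 0) {
      expect_true(is.na(d$share_never))
      next
    }
    any_loss <- TRUE
    expect_equal(d$share_P70 + d$share_P15 + d$share_never, 1)
    expect_equal(d$lost_P70_km2 / 100, sum(lost & m == codes["P70"]))
    expect_equal(d$lost_never_km2 / 100,
                 sum(lost & (m == codes["NEVER"] | m == codes["BUFFER"])))
  }
  expect_true(any_loss)

  # loss entirely outside protection
  g <- grid_spec(5, 5, 10)
  pm <- classify_protection(list(pa_record(
    "far", geometry = planar_polygon(
      rbind(c(400, 0), c(500, 0), c(500, -100), c(400, -100))),
    year_established = 1950)), g)
  ch <- classify_range_change(bool_raster(TRUE, g), bool_raster(FALSE, g))
  expect_equal(loss_by_protection(ch, pm)$share_never, 1)
})

test_that("PA records round-trip through GeoJSON", {
  poly <- planar_polygon(rbind(c(0, 0), c(30, 5), c(25, -28), c(-2, -20)),
                         holes = list(rbind(c(5, -5), c(10, -5), c(8, -12))))
  recs <- list(
    pa_record("poly1", geometry = poly, reported_area_km2 = 700,
              year_established = 1955, iucn_category = "Ib"),
    pa_record("pt1", centroid = c(120, -80), reported_area_km2 = 314,
              year_established = 1999, iucn_category = "V"))
  p <- tempfile(fileext = ".geojson")
  on.exit(unlink(p))
  write_pa_geojson(recs, p)
  back <- read_pa_geojson(p)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$geometry$exterior, poly$exterior, ignore_attr = TRUE)
  expect_equal(back[[1]]$geometry$holes[[1]], poly$holes[[1]],
               ignore_attr = TRUE)
  expect_equal(back[[1]]$year_established, 1955L)
  expect_equal(back[[2]]$centroid, c(120, -80))
  expect_equal(back[[2]]$reported_area_km2, 314)
  expect_equal(back[[2]]$iucn_category, "V")
})
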