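test_that("range-change overlay classifies lost, retained, gained and absent", {
  g <- grid_spec(5, 5, 10)
  set.seed(3)
  m <- matrix(runif(25) < 0.5, 5, 5)
  same <- classify_range_change(bool_raster(m, g), bool_raster(m, g))
  codes <- range_change_codes()
  expect_equal(sum(same == codes["RETAINED"]), sum(m))
  expect_equal(sum(same == codes["LOST"]), 0L)
  expect_equal(sum(same == codes["GAINED"]), 0L)

  gone <- classify_range_change(bool_raster(TRUE, g), bool_raster(FALSE, g))
  expect_true(all(gone == codes["LOST"]))

  # exhaustive truth-table oracle on random pairs
  for (i in 1:5) {
    p <- matrix(runif(25) < 0.5, 5, 5); r <- matrix(runif(25) < 0.5, 5, 5)
    ch <- classify_range_change(bool_raster(p, g), bool_raster(r, g))
    expected <- ifelse(p & !r, codes["LOST"],
                ifelse(p & r, codes["RETAINED"],
                ifelse(!p & r, codes["GAINED"], codes["ABSENT"])))
    expect_equal(unclass(ch)[, ], expected, ignore_attr = TRUE)
  }

  g2 <- grid_spec(4, 4, 10)
  expect_error(classify_range_change(bool_raster(TRUE, g),
                                     bool_raster(TRUE, g2)), "grid")
})

test_that("richness counts co-occurring species per pixel", {
  g <- grid_spec(6, 6, 10)
  set.seed(4)
  one <- bool_raster(matrix(runif(36) < 0.5, 6, 6), g)
  expect_equal(unclass(richness_map(list(one)))[, ],
               unclass(one) + 0L, ignore_attr = TRUE)

  k <- replicate(4, bool_raster(TRUE, g), simplify = FALSE)
  expect_true(all(richness_map(k) == 4L))

  masks <- replicate(10, bool_raster(matrix(runif(36) < 0.4, 6, 6), g),
                     simplify = FALSE)
  brute <- Reduce(`+`, lapply(masks, function(m) unclass(m) + 0L))
  expect_equal(unclass(richness_map(masks))[, ], brute, ignore_attr = TRUE)

  expect_error(richness_map(list()), "empty")
})

test_that("extinction rate is lost over past, undefined without past presence", {
  g <- grid_spec(2, 2, 10)
  past <- grid_layer(matrix(c(10, 0, 4, 1), 2, 2), g)
  lost <- grid_layer(matrix(c(3, 0, 4, 0), 2, 2), g)
  rate <- extinction_rate_map(past, lost)
  expect_equal(rate[1, 1], 0.30)
  expect_true(is.na(rate[2, 1]))    # no past species
  expect_equal(rate[1, 2], 1)       # complete loss
  expect_equal(rate[2, 2], 0)

  bad <- grid_layer(matrix(c(11, 0, 0, 0), 2, 2), g)
  expect_error(extinction_rate_map(past, bad), "exceeds")
})

test_that("gains do not offset losses in the extinction rate", {
  # species A loses the pixel, B retains it, C gains it: rate 1/2
  g <- grid_spec(1, 1, 10)
  past <- list(A = bool_raster(TRUE, g), B = bool_raster(TRUE, g),
               C = bool_raster(FALSE, g))
  recent <- list(A = bool_raster(FALSE, g), B = bool_raster(TRUE, g),
                 C = bool_raster(TRUE, g))
  lost <- mapply(function(p, r) {
    ch <- classify_range_change(p, r)
    bool_raster(unclass(ch) == range_change_codes()["LOST"], g)
  }, past, recent, SIMPLIFY = FALSE)
  rate <- extinction_rate_map(richness_map(past), richness_map(lost))
  expect_equal(rate[1, 1], 0.5)
})

test_that("representation ratio divides sampled by total richness", {
  g <- grid_spec(3, 3, 10)
  tot <- grid_layer(matrix(8L, 3, 3), g)
  expect_true(all(representation_ratio_map(tot, tot) == 1))
  samp <- grid_layer(matrix(2L, 3, 3), g)
  expect_true(all(representation_ratio_map(samp, tot) == 0.25))

  set.seed(5)
  t2 <- grid_layer(matrix(rpois(9, 3), 3, 3), g)
  s2 <- grid_layer(matrix(pmin(unclass(t2), rpois(9, 2)), 3, 3), g)
  rr <- representation_ratio_map(s2, t2)
  expected <- ifelse(unclass(t2) >= 1, unclass(s2) / unclass(t2), NA)
  expect_equal(unclass(rr)[, ], expected, ignore_attr = TRUE)
  expect_error(representation_ratio_map(t2, s2), "exceeds")
})

test_that("species change summary reports areas, percentages and net class", {
  g <- grid_spec(10, 10, 10)
  past <- matrix(TRUE, 10, 10)
  recent <- past; recent[1:4, 1:8] <- FALSE  # 32 pixels lost
  ch <- classify_range_change(bool_raster(past, g), bool_raster(recent, g))
  s <- species_change_summary(ch, "sp1")
  expect_equal(s$pct_lost, 32.0)
  expect_equal(s$area_past_km2, 100 * 100)
  expect_equal(s$net_class, "contraction")

  # equal loss and gain balances to no_change despite nonzero loss
  p2 <- matrix(FALSE, 10, 10); p2[1:2, 1] <- TRUE
  r2 <- matrix(FALSE, 10, 10); r2[2, 1] <- TRUE; r2[3, 1] <- TRUE
  s2 <- species_change_summary(
    classify_range_change(bool_raster(p2, g), bool_raster(r2, g)))
  expect_equal(s2$net_class, "no_change")
  expect_gt(s2$pct_lost, 0)

  expect_error(species_change_summary(
    classify_range_change(bool_raster(FALSE, g), bool_raster(FALSE, g))),
    "no past range")
})

test_that("per-species areas are conserved across the overlay", {
  g <- grid_spec(12, 12, 10)
  set.seed(6)
  codes <- range_change_codes()
  for (i in 1:5) {
    p <- bool_raster(matrix(runif(144) < 0.5, 12, 12), g)
    r <- bool_raster(matrix(runif(144) < 0.5, 12, 12), g)
    ch <- classify_range_change(p, r)
    n_lost <- sum(ch == codes["LOST"]); n_ret <- sum(ch == codes["RETAINED"])
    n_gain <- sum(ch == codes["GAINED"])
    expect_equal(n_lost + n_ret, sum(p))
    expect_equal(n_ret + n_gain, sum(r))
  }
})

test_that("richness of past minus lost equals richness of retained", {
  g <- grid_spec(8, 8, 10)
  set.seed(7)
  codes <- range_change_codes()
  past <- replicate(6, bool_raster(matrix(runif(64) < 0.5, 8, 8), g),
                    simplify = FALSE)
  recent <- replicate(6, bool_raster(matrix(runif(64) < 0.5, 8, 8), g),
                      simplify = FALSE)
  chg <- mapply(classify_range_change, past, recent, SIMPLIFY = FALSE)
  lost <- lapply(chg, function(ch) bool_raster(unclass(ch) == codes["LOST"],
                                               g))
  ret <- lapply(chg, function(ch)
    bool_raster(unclass(ch) == codes["RETAINED"], g))
  expect_equal(unclass(richness_map(past)) - unclass(richness_map(lost)),
               unclass(richness_map(ret)), ignore_attr = TRUE)
})
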