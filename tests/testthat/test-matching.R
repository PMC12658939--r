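test_that("propensity scores reduce to the treated fraction without confounding", {
  tab <- make_table(2000, seed = 31)
  treated <- rep(c(TRUE, FALSE), each = 1000)  # independent of covariates
  fit <- fit_propensity(tab, treated)
  expect_true(all(abs(fit$scores - 0.5) < 0.15))
  expect_equal(mean(fit$scores), 0.5, tolerance = 1e-6)
  expect_false(fit$ridged)

  expect_error(fit_propensity(tab, rep(TRUE, 2000)), "non-empty")
})

test_that("a saturated single-covariate fit returns the closed-form cell probabilities", {
  # one binary covariate: level 1 holds 30 treated / 10 control,
  # level 0 holds 10 treated / 30 control -> P(T | level 1) = 0.75
  n <- 80
  lev <- rep(c(1L, 2L), each = 40)
  treated <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 10))
  tab <- make_table(n, seed = 32)
  tab$elevation_bin <- lev
  tab$slope_bin <- 1L; tab$pop_density_bin <- 1L; tab$travel_time_bin <- 1L
  tab$bioanthrome_id <- 1L
  fit <- fit_propensity(tab, treated)
  expect_equal(unname(fit$scores[lev == 2L]), rep(0.75, 40),
               tolerance = 1e-6)
  expect_equal(unname(fit$scores[lev == 1L]), rep(0.25, 40),
               tolerance = 1e-6)
})

test_that("propensity scores track the confounder that drives PA placement", {
  w <- small_world()
  tab <- world_pixel_table(w)
  grp <- tab$protection %in% c("P70", "P15")
  sub <- grp | tab$protection == "NEVER"
  fit <- fit_propensity(tab[sub, ], grp[sub])
  expect_gt(cor(fit$scores, tab$elevation[sub]), 0.2)
  expect_lt(cor(fit$scores, -tab$travel_time[sub]), 0)
})

test_that("greedy nearest-neighbour matching follows the stated procedure", {
  s <- c(0.9, 0.8, 0.85, 0.1)
  m <- nn_match(s, treated_ids = c(1L, 2L), control_ids = c(3L, 4L))
  expect_equal(m$treated_id, c(1L, 2L))
  expect_equal(m$control_id, c(3L, 4L))  # greedy order matters: 0.8 gets 0.1

  m1 <- nn_match(c(0.4, 0.6), 1L, 2L)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$control_id, 2L)

  expect_error(nn_match(c(0.5, 0.6), 1L, integer(0)), "control")
})

test_that("matching equals the exhaustive greedy oracle on small instances", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(2:10, 1)
    nt <- sample(seq_len(n - 1), 1)
    scores <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    ids <- sample.int(n)
    treated <- ids[seq_len(nt)]; control <- ids[(nt + 1):n]
    got <- suppressWarnings(nn_match(scores, treated, control))
    want <- greedy_match_oracle(scores, treated, control)
    expect_identical(got$treated_id, want$treated_id)
    expect_identical(got$control_id, want$control_id)
    # without replacement
    expect_false(any(duplicated(got$control_id)))
    expect_false(any(duplicated(got$treated_id)))
  }
})

test_that("standardized mean differences are scaled mean gaps", {
  v <- c(1, 1, 1, 0, 0, 0)
  expect_equal(smd(v, 1:3, 4:6, denominator_sd = 2), 0.5)
  expect_equal(smd(v, 1:3, 1:3, denominator_sd = 2), 0)
  expect_equal(smd(c(5, 5, 5, 5), 1:2, 3:4, denominator_sd = 0), 0)
  expect_error(smd(c(1, 1, 0, 0), 1:2, 3:4, denominator_sd = 0),
               "zero-variance")

  set.seed(34)
  x <- rnorm(100); t_id <- 1:40; c_id <- 41:100
  sd0 <- sqrt((var(x[t_id]) + var(x[c_id])) / 2)
  expect_equal(smd(x, t_id, c_id, sd0),
               abs(mean(x[t_id]) - mean(x[c_id])) / sd0)
})

test_that("matched-pair effect estimates carry paired-normal confidence intervals", {
  tab <- make_table(40, seed = 35)
  tab$outcome_pct_lost <- rep(50, 40)
  m <- structure(data.frame(treated_id = 1:10, control_id = 11:20),
                 class = c("matched_set", "data.frame"))
  e <- att(tab, m)
  expect_equal(e$estimate, 0)
  expect_equal(e$ci_lower, 0)

  tab$outcome_pct_lost[1:10] <- 30; tab$outcome_pct_lost[11:20] <- 40
  e2 <- att(tab, m)
  expect_equal(e2$estimate, -10)
  expect_equal(e2$ci_lower, -10)  # zero variance of differences
  expect_equal(e2$ci_upper, -10)
  expect_equal(e2$n_pairs, 10L)

  m1 <- structure(data.frame(treated_id = 1L, control_id = 11L),
                  class = c("matched_set", "data.frame"))
  expect_error(att(tab, m1), "at least 2")
})

test_that("balance reports cover the Table-style rows and improve under matching", {
  w <- small_world()
  tab <- world_pixel_table(w)
  res <- suppressWarnings(run_comparison(tab, "a"))
  b <- res$balance
  expect_equal(b$covariate,
               c("distance", "elevation", "slope", "pop_density",
                 "travel_time", "bioanthromes (average)"))
  expect_true(all(b$smd_before >= 0 & b$smd_after >= 0))
  # the confounders that drive placement must improve
  conf <- b$covariate %in% c("distance", "elevation", "travel_time")
  expect_true(all(b$smd_after[conf] < b$smd_before[conf]))
})

test_that("randomized treatment yields balance and ATT near the naive difference", {
  set.seed(36)
  n <- 8000
  tab <- make_table(n, seed = 36)
  tab$protection <- factor(sample(c("NEVER", "P70"), n, TRUE,
                                  prob = c(0.7, 0.3)),
                           levels = c("NEVER", "BUFFER", "P15", "P70"))
  tab$outcome_pct_lost <- runif(n, 0, 100)
  res <- run_comparison(tab, "a")
  expect_true(all(res$balance$smd_before < 0.1))
  expect_lt(abs(res$effect$estimate - res$naive_diff), 2.5)
})

test_that("the four pairwise comparisons run with the stated orientations", {
  set.seed(37)
  n <- 1200
  tab <- make_table(n, seed = 37)
  # make buffer clearly better than never so orientation is visible
  tab$outcome_pct_lost <- ifelse(tab$protection == "BUFFER", 10,
                          ifelse(tab$protection == "NEVER", 30, 20)) +
    rnorm(n)
  res <- suppressWarnings(run_comparisons(tab))
  expect_setequal(names(res), c("a", "b", "c", "d"))
  expect_equal(nrow(attr(res, "skipped")), 0L)
  # (d): buffer is the treatment -> negative estimate vs never
  expect_lt(res$d$effect$estimate, 0)
  expect_lt(res$d$effect$mean_treated, res$d$effect$mean_control)

  # drop buffers: (c) and (d) skipped
  tab2 <- tab[tab$protection != "BUFFER", ]
  class(tab2) <- c("pixel_table", "data.frame")
  res2 <- suppressWarnings(run_comparisons(tab2))
  expect_setequal(names(res2), c("a", "b"))
  expect_setequal(attr(res2, "skipped")$comparison, c("c", "d"))
})

test_that("matching reduces confounding bias on the synthetic world", {
  w <- small_world()
  tab <- world_pixel_table(w)
  res <- suppressWarnings(run_comparison(tab, "a"))
  truth <- w$truth$att[["a"]]
  expect_lt(abs(res$effect$estimate - truth), abs(res$naive_diff - truth))
})
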