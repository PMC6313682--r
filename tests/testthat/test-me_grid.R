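test_that("gravimetric correction multiplies by the run factor", {
  rec <- data.frame(date = "d1", minute_of_day = c(0L, 100L, 200L),
                    pm25 = c(20, 10, 5),
                    microenv = c("other", "residential_indoor",
                                 "transportation"),
                    run_id = c("r1", "r1", "r2"), stringsAsFactors = FALSE)
  # identity
  expect_identical(apply_correction(rec, c(r1 = 1, r2 = 1)), rec)
  # per-run multiplication, count and order unchanged
  out <- apply_correction(rec, c(r1 = 1.1, r2 = 2))
  expect_equal(out$pm25, c(22, 11, 10))
  expect_equal(nrow(out), 3L)
  # single unnamed global factor
  expect_equal(apply_correction(rec, 1.1)$pm25, c(22, 11, 5.5))
  # missing run -> configuration error naming the run
  expect_error(apply_correction(rec, c(r1 = 1.1)), "r2")
  expect_error(apply_correction(rec, c(r1 = -1, r2 = 1)), "positive")
})

test_that("grid always has 432 cells and slot assignment is floor(min/10)+1", {
  rec <- data.frame(date = "d1", minute_of_day = c(0L, 5L, 9L),
                    pm25 = c(10, 20, 30), microenv = "other",
                    run_id = "r1", stringsAsFactors = FALSE)
  g <- build_grid(rec, min_obs_per_cell = 3)
  expect_equal(nrow(g$cells), 432L)
  # all three land in slot 1 of "other"
  c1 <- g$cells[g$cells$slot == 1 & g$cells$microenv == "other", ]
  expect_equal(c1$n_obs, 3L)
  expect_equal(c1$mean, 20)
  expect_true(c1$available)
  expect_equal(sum(g$cells$n_obs), 3L)
  # a cell below min_obs is flagged unavailable, not dropped
  g2 <- build_grid(rec, min_obs_per_cell = 4)
  expect_equal(nrow(g2$cells), 432L)
  expect_false(any(g2$cells$available))
  expect_error(build_grid(rec[0, ], 5), "non-empty")
})

test_that("cell means match a brute-force recomputation on random records", {
  set.seed(42)
  n <- 2000
  rec <- data.frame(date = "d1",
                    minute_of_day = sample(0:1439, n, TRUE),
                    pm25 = rlnorm(n, 3, 0.6),
                    microenv = sample(ME_LEVELS, n, TRUE),
                    run_id = "r1", stringsAsFactors = FALSE)
  g <- build_grid(rec, min_obs_per_cell = 1)
  for (i in sample(nrow(g$cells), 50)) {
    row <- g$cells[i, ]
    member <- rec$pm25[rec$minute_of_day %/% 10 + 1 == row$slot &
                         rec$microenv == row$microenv]
    if (length(member)) {
      expect_equal(row$mean, mean(member))
      expect_equal(row$n_obs, length(member))
    } else {
      expect_false(row$available)
    }
  }
})

test_that("full coverage yields 432 available cells; 23 blanks yield 409", {
  g <- constant_grid(20)
  expect_equal(sum(g$cells$available), 432L)
  g2 <- build_grid(generate_campaign(campaign_spec(seed = 11)), 5)
  expect_equal(sum(g2$cells$available), 409L)
})

test_that("lognormal cell fits recover generating parameters", {
  set.seed(7)
  x <- rlnorm(500, meanlog = 3, sdlog = 0.5)
  fit <- fit_cell_distribution(x)
  expect_equal(fit$family, "lognormal")
  expect_lt(abs(fit$params[["meanlog"]] - 3) / 3, 0.1)
  expect_lt(abs(fit$params[["sdlog"]] - 0.5) / 0.5, 0.1)
  expect_true(is.finite(fit$fit_score))
  # KS criterion is selectable and also picks the generating family here
  fit_ks <- fit_cell_distribution(x, criterion = "KS")
  expect_equal(fit_ks$family, "lognormal")
  expect_equal(fit_ks$fit_score, fit_ks$ks_stat)
})

test_that("degenerate cells fall back to a point mass with a warning", {
  expect_warning(fit <- fit_cell_distribution(rep(10, 20)), "point mass")
  expect_equal(fit$family, "point")
  expect_equal(sample_fitted(fit, 5), rep(10, 5))
  expect_equal(mean(fit), 10)
})

test_that("misspecified (mixture) cells still return a finite fit", {
  set.seed(8)
  x <- c(rlnorm(200, 2, 0.3), rlnorm(200, 4, 0.3))
  fit <- fit_cell_distribution(x)
  expect_true(fit$family %in% c("lognormal", "gamma", "weibull", "tnorm"))
  expect_true(is.finite(fit$fit_score))
})

test_that("draws from any fitted family are non-negative", {
  set.seed(9)
  fits <- list(
    fit_cell_distribution(rlnorm(300, 3, 0.5), families = "lognormal"),
    fit_cell_distribution(rgamma(300, 2, 0.1), families = "gamma"),
    fit_cell_distribution(rweibull(300, 1.5, 30), families = "weibull"),
    fit_cell_distribution(pmax(0.1, rnorm(300, 25, 10)), families = "tnorm"))
  for (f in fits) {
    d <- sample_fitted(f, 1e4)
    expect_true(all(is.finite(d)))
    expect_true(all(d >= 0))
    # analytic mean agrees with the empirical mean of a large sample
    expect_lt(abs(mean(d) - mean(f)) / mean(f), 0.1)
  }
})

test_that("tnorm numerics survive the exponential-like left-tail regime", {
  f <- pmexposure:::new_fitted_dist("tnorm", c(mean = -1800, sd = 225))
  set.seed(10)
  d <- sample_fitted(f, 1e4)
  expect_true(all(is.finite(d)))
  expect_true(all(d >= 0))
  expect_lt(abs(mean(d) - mean(f)) / mean(f), 0.1)
})

test_that("grid summary files round-trip means, availability and fits", {
  set.seed(12)
  spec <- campaign_spec(seed = 12,
                        minutes_per_cell = c(30, 8, 20))
  g <- fit_grid_distributions(build_grid(generate_campaign(spec), 5),
                              families = c("lognormal", "gamma"))
  path <- tempfile(fileext = ".csv")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_equal(g2$cells$mean, g$cells$mean)
  expect_equal(g2$cells$available, g$cells$available)
  k <- which(g$cells$available)[1]
  expect_equal(g2$fits[[k]]$family, g$fits[[k]]$family)
  expect_equal(g2$fits[[k]]$params, g$fits[[k]]$params, tolerance = 1e-12)
})
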