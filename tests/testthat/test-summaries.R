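test_that("aggregate_index sums draws over member colonies", {
  cols <- tiny_colonies(2)
  years <- 2009:2011
  # hand-written N draws: 3 draws x (2 colonies * 3 years), site-major
  N <- rbind(c(10, 20, 30, 1, 2, 3),
             c(40, 50, 60, 4, 5, 6),
             c(7, 8, 9, 0, 1, 2))
  fit <- fake_fit(N, cols, years)
  # single-colony group is the colony's own draws
  one <- aggregate_index(fit, list(just1 = "C01"))$just1
  expect_equal(unname(one$draws), N[, 1:3])
  # hand-summed union
  glob <- aggregate_index(fit, "global")
  expect_equal(unname(glob$draws), N[, 1:3] + N[, 4:6])
  # two disjoint groups add to their union, draw-wise
  gr <- aggregate_index(fit, list(a = "C01", b = "C02"))
  expect_equal(gr$a$draws + gr$b$draws, glob$draws,
               ignore_attr = TRUE)
  expect_error(aggregate_index(fit, list(x = "C99")), "unknown colony")
})

test_that("partition additivity holds for both region schemes", {
  sim <- simulate_dataset(design = design_config(n_colonies = 10,
                                                 n_years = 4), seed = 8)
  fit <- fit_colony_model(sim$data, mcmc = small_mcmc(seed = 8))
  glob <- aggregate_index(fit, "global")$draws
  for (g in c("fast_ice", "pack_ice")) {
    parts <- aggregate_index(fit, g)
    expect_equal(Reduce(`+`, lapply(parts, `[[`, "draws")), glob,
                 ignore_attr = TRUE)
  }
})

test_that("percent_change arithmetic", {
  s <- index_series(rbind(c(252000, 240000, 228000)), 2009:2011)
  expect_equal(percent_change(s), -9.523810, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(percent_change(s, 2009, 2009), 0, ignore_attr = TRUE)
  s2 <- index_series(rbind(c(100, 90), c(100, 110)), 2009:2010)
  expect_equal(as.vector(percent_change(s2)), c(-10, 10))
  # zero base-year draws are excluded with a logged count
  s3 <- index_series(rbind(c(0, 10), c(100, 150)), 2009:2010)
  expect_message(ch <- percent_change(s3), "1 draw")
  expect_equal(as.vector(ch), 50)
  expect_equal(attr(ch, "n_excluded"), 1)
  expect_error(percent_change(s, 2000, 2011), "out of range")
})

test_that("prob_decline thresholds, boundaries, and identities", {
  draws <- c(-10, 5, -20, -30)
  expect_equal(prob_decline(draws, 0), 0.75)
  # boundary: strict excludes the -30 draw; inclusive keeps it
  expect_equal(prob_decline(draws, 30), 0)
  expect_equal(prob_decline(draws, 30, inclusive = TRUE), 0.25)
  expect_equal(prob_decline(c(1, 2, 3), 0), 0)
  # monotone in the threshold
  set.seed(9)
  ch <- rnorm(500, -5, 20)
  p <- vapply(c(0, 10, 20, 30, 50), prob_decline, 0, changes = ch)
  expect_true(all(diff(p) <= 0))
  # P(decline) = 1 - P(change >= 0) exactly
  expect_equal(prob_decline(ch, 0), 1 - mean(ch >= 0))
  expect_error(prob_decline(numeric(0)), "no valid")
})

test_that("annual_trend closed forms", {
  dbl <- index_series(rbind(100 * 2^(0:4)), 2009:2013)
  expect_equal(as.vector(annual_trend(dbl)), 100)
  const <- index_series(rbind(rep(7, 5)), 2009:2013)
  expect_equal(as.vector(annual_trend(const)), 0)
  geom <- index_series(rbind(c(100, 110, 121)), 2009:2011)
  expect_equal(as.vector(annual_trend(geom)), 10)
  expect_equal(as.vector(annual_trend(geom, method = "endpoint")), 10)
  # a draw with a zero index is excluded
  s <- index_series(rbind(c(100, 0, 121), c(100, 110, 121)), 2009:2011)
  expect_message(tr <- annual_trend(s), "1 draw")
  expect_equal(as.vector(tr), 10)
})

test_that("summarize_draws uses equal-tailed percentiles", {
  s <- summarize_draws(1:1000)
  expect_equal(unname(s), quantile(1:1000, c(0.025, 0.5, 0.975),
                                   names = FALSE))
  expect_equal(s[["median"]], 500.5)
  expect_equal(s[["lo"]], 25.975)
  expect_equal(summarize_draws(rep(3, 10)), c(lo = 3, median = 3, hi = 3))
  expect_equal(summarize_draws(c(-1, 0, 1))[["median"]], 0)
})

test_that("change_summary orders its probabilities and CI", {
  set.seed(10)
  cs <- change_summary(rnorm(2000, -20, 25))
  expect_lte(cs$p_decline_50, cs$p_decline_30)
  expect_lte(cs$p_decline_30, cs$p_decline)
  expect_lt(cs$lo, cs$hi)
  expect_equal(cs$mean_change, -20, tolerance = 2)
})

test_that("spearman_cor matches a brute-force rank oracle", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10)), 1)
  expect_equal(spearman_cor(1:5, c(10, 8, 6, 4, 2)), -1)
  set.seed(11)
  x <- sample(1:5, 20, replace = TRUE)  # heavy ties
  y <- x + rnorm(20)
  brute <- function(v) {
    sapply(seq_along(v), function(i) {
      mean(which(sort(v) == v[i]))  # average rank with ties
    })
  }
  rx <- brute(x); ry <- brute(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(x, y), oracle)
  expect_error(spearman_cor(1:4, 1:5), "length mismatch")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("ice_correlation pairs regional scalars with trends", {
  sim <- simulate_dataset(design = design_config(n_colonies = 16,
                                                 n_years = 4), seed = 12)
  fit <- fit_colony_model(sim$data, mcmc = small_mcmc(seed = 12))
  ice <- rbind(
    data.frame(region = pengindex:::FAST_ICE_REGIONS, ice_type = "fast",
               trend_value = seq(-2, 2, length.out = 8)),
    data.frame(region = pengindex:::PACK_ICE_REGIONS, ice_type = "pack",
               trend_value = seq(1, -1, length.out = 5)))
  res <- ice_correlation(fit, ice, "fast")
  expect_equal(nrow(res$regions), 8)
  expect_equal(res$cor$scalar, c("p_decline", "median_change"))
  expect_true(all(abs(res$cor$spearman) <= 1))
  res2 <- ice_correlation(fit, ice, "pack")
  expect_equal(nrow(res2$regions), 5)
})
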