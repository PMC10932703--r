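test_that("process_logdensity matches per-transition lognormal oracles", {
  hp <- tiny_hp()
  # length-1 trajectory: only the initial-prior term
  expect_equal(process_logdensity(750, 0.01, hp),
               dlnorm(750, log(hp$xbar1), hp$sigma_logx1, log = TRUE))
  # 3-year trajectory: brute-force sum of per-transition densities
  x <- c(900, 870, 940); r_j <- -0.02
  oracle <- dlnorm(x[1], log(hp$xbar1), hp$sigma_logx1, log = TRUE) +
    dlnorm(x[2], log(x[1]) + r_j, hp$sigma_process, log = TRUE) +
    dlnorm(x[3], log(x[2]) + r_j, hp$sigma_process, log = TRUE)
  expect_equal(process_logdensity(x, r_j, hp), oracle)
  # r_j = 0, constant X: at matched small sigma the dynamic terms equal
  # the oracle and grow as sigma shrinks (density maximum at the median)
  for (s in c(0.1, 0.01, 0.001)) {
    hps <- tiny_hp(); hps$sigma_process <- s
    const <- rep(1000, 4)
    expect_equal(process_logdensity(const, 0, hps),
                 dlnorm(1000, log(hps$xbar1), hps$sigma_logx1,
                        log = TRUE) +
                   3 * dlnorm(1000, log(1000), s, log = TRUE))
  }
  expect_error(process_logdensity(c(10, -1), 0, hp), "positive")
})

test_that("presence_logpmf handles boundaries", {
  expect_equal(presence_logpmf(1, 1), 0)
  expect_equal(presence_logpmf(0, 0), 0)
  expect_equal(presence_logpmf(1, 0.5), log(0.5))
  expect_equal(presence_logpmf(0, 0.9), log(0.1))
  expect_equal(presence_logpmf(1, 0), -Inf)
})

test_that("direct count model: expectation, density, mode, symmetry", {
  expect_equal(direct_count_expected(1000, 0, 25), 1000)
  expect_equal(direct_count_expected(1000, -0.01, 10),
               1000 * exp(-0.1))
  # density equals an independently coded lognormal oracle
  expect_equal(
    direct_count_logdensity(900, 1000, 0, 0, 0.1),
    dlnorm(900, log(1000) - 0.1^2 / 2, 0.1, log = TRUE))
  # the -sigma^2/2 correction makes the analytic mean X*exp(alpha*doy):
  # Monte-Carlo check
  set.seed(42)
  sa <- 0.3; X <- 1000; a <- -0.005; d <- 12
  draws <- rlnorm(2e5, log(X) + a * d - sa^2 / 2, sa)
  expect_equal(mean(draws), direct_count_expected(X, a, d),
               tolerance = 3 * sd(draws) / sqrt(2e5) /
                 direct_count_expected(X, a, d))
  # mode of the corrected lognormal: X*exp(alpha*doy - 1.5 sigma^2)
  grid <- seq(500, 1500, by = 0.25)
  dens <- direct_count_logdensity(grid, X, a, d, sa)
  expect_equal(grid[which.max(dens)],
               X * exp(a * d - 1.5 * sa^2), tolerance = 1e-3)
  # only the product alpha*doy matters
  expect_equal(direct_count_logdensity(900, 1000, 0.37, 0, 0.1),
               direct_count_logdensity(900, 1000, 0, 123, 0.1))
  expect_error(direct_count_logdensity(0, 1000, 0, 0, 0.1), "positive")
})

test_that("satellite model: expectation, density, proportional error, degenerate branch", {
  expect_equal(satellite_expected(5000, 0, 10, 1), 5000)
  expect_equal(satellite_expected(1000, -0.1, 0, 0.8), 800)
  expect_equal(satellite_expected(0, -0.01, 5, 0.9), 0)
  expect_equal(
    satellite_logdensity(950, 1000, 0, 0, 1, 0.1),
    dnorm(950, 1000, 100, log = TRUE))
  # doubling N doubles the sd: equal proportional error
  set.seed(7)
  for (N in c(1000, 2000)) {
    v <- rnorm(2e5, N, N * 0.2)
    expect_equal(sd(v) / mean(v), 0.2, tolerance = 0.01)
  }
  ld1 <- satellite_logdensity(1000 * 1.1, 1000, 0, 0, 1, 0.1)
  ld2 <- satellite_logdensity(2000 * 1.1, 2000, 0, 0, 1, 0.1)
  # same z-score, sd scales with N => densities differ by log(2)
  expect_equal(ld1 - ld2, log(2))
  # degenerate branch at N = 0
  expect_equal(satellite_logdensity(0, 0, 0, 0, 1, 0.1), 0)
  expect_equal(satellite_logdensity(100, 0, 0, 0, 1, 0.1), -Inf)
  # beta placement switches
  expect_equal(
    satellite_logdensity(900, 1000, 0, 0, 0.9, 0.1,
                         beta_in_variance = TRUE),
    dnorm(900, 900, 0.9 * 100, log = TRUE))
  expect_equal(
    satellite_logdensity(900, 1000, 0, 0, 0.9, 0.1,
                         beta_in_mean = FALSE),
    dnorm(900, 1000, 100, log = TRUE))
})

test_that("joint_log_posterior equals the term-by-term oracle on a 2x3 instance", {
  ds <- tiny_dataset(); hp <- tiny_hp(); lat <- tiny_latent()
  pc <- prior_config()

  oracle <- pengindex:::.hyperprior_logdensity(hp, pc)
  for (j in 1:2) {
    oracle <- oracle + process_logdensity(lat$X[j, ], lat$r[j], hp)
  }
  oracle <- oracle + sum(presence_logpmf(lat$z, hp$p)) +
    sum(dnorm(lat$r, hp$r_bar, hp$sigma_r, log = TRUE))
  # observations, hand-enumerated: direct C01/2009 d289, C01/2010 d300,
  # C02/2011 d280; satellite C01/2011 q3 d289, C02/2009 q1 d295,
  # C02/2010 q2 d310 (value 0, z = 0 -> degenerate 0 contribution)
  oracle <- oracle +
    dlnorm(1000, log(lat$X[1, 1]) + hp$alpha * 0 - hp$sigma_aerial^2 / 2,
           hp$sigma_aerial, log = TRUE) +
    dlnorm(900, log(lat$X[1, 2]) + hp$alpha * 11 - hp$sigma_aerial^2 / 2,
           hp$sigma_aerial, log = TRUE) +
    dlnorm(450, log(lat$X[2, 3]) + hp$alpha * -9 - hp$sigma_aerial^2 / 2,
           hp$sigma_aerial, log = TRUE) +
    dnorm(1050, hp$beta[3] * lat$X[1, 3] * exp(hp$alpha * 0),
          lat$X[1, 3] * exp(hp$alpha * 0) * hp$cv_sat[3], log = TRUE) +
    dnorm(480, hp$beta[1] * lat$X[2, 1] * exp(hp$alpha * 6),
          lat$X[2, 1] * exp(hp$alpha * 6) * hp$cv_sat[1], log = TRUE) +
    0

  lp <- joint_log_posterior(hp, lat, ds, pc)
  expect_equal(lp, oracle, tolerance = 1e-10)

  # additivity: removing all observations leaves prior + process +
  # presence terms only
  ds0 <- survey_dataset(ds$colonies, empty_direct(), empty_satellite(),
                        years = c(2009, 2011))
  obs_terms <- lp - joint_log_posterior(hp, lat, ds0, pc)
  direct_sat <- oracle - pengindex:::.hyperprior_logdensity(hp, pc) -
    sum(vapply(1:2, function(j)
      process_logdensity(lat$X[j, ], lat$r[j], hp), 0)) -
    sum(presence_logpmf(lat$z, hp$p)) -
    sum(dnorm(lat$r, hp$r_bar, hp$sigma_r, log = TRUE))
  expect_equal(obs_terms, direct_sat, tolerance = 1e-10)

  # inconsistent states are impossible, not just unlikely
  lat_bad <- tiny_latent(); lat_bad$z[1, 1] <- 0
  lat_bad <- latent_state(lat_bad$X, lat_bad$z, lat_bad$r)
  expect_identical(joint_log_posterior(hp, lat_bad, ds, pc), -Inf)

  # dimension mismatch is a structural error
  lat3 <- latent_state(matrix(1000, 3, 3), matrix(1, 3, 3), rep(0, 3))
  expect_error(joint_log_posterior(hp, lat3, ds, pc), "grid")
})

test_that("prior_config round-trips through its text format", {
  pc <- prior_config(alpha_sd = 0.2, cv_scale = 0.4,
                     beta_in_variance = TRUE, beta_fixed = c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# comment", "alpha_sd: 0.2", "cv_scale: 0.4",
               "beta_in_variance: true", "beta_fixed: 1, 1, 1"), path)
  expect_equal(read_prior_config(path), pc)
  expect_error(prior_config(nonsense = 1), "unknown")
  writeLines("not a config", path)
  expect_error(read_prior_config(path), "malformed")
})

test_that("observation term shrinks as sigma_aerial grows at well-fitting data", {
  sig <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  at_mode <- vapply(sig, function(s)
    direct_count_logdensity(1000, 1000, 0, 0, s), 0)
  expect_true(all(diff(at_mode) < 0))
})
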