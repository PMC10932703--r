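test_that("rmse formula and invariances", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(12.5))
  set.seed(13)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(rmse(a, b), sqrt(mean((a - b)^2)))
  perm <- sample(40)
  expect_equal(rmse(a[perm], b[perm]), rmse(a, b))
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("bayesian_pvalue counts replicates strictly below", {
  expect_equal(bayesian_pvalue(c(1, 2, 3), 10), 1)
  expect_equal(bayesian_pvalue(c(1, 2, 3), 0), 0)
  expect_equal(bayesian_pvalue(c(1, 2, 3, 4), 2.5), 0.5)
  expect_error(bayesian_pvalue(numeric(0), 1), "no replicate")
})

test_that("replicates preserve the observation design", {
  sim <- simulate_dataset(design = design_config(n_colonies = 5,
                                                 n_years = 4), seed = 14)
  fit <- fit_colony_model(sim$data, mcmc = small_mcmc(seed = 14))
  reps <- replicate_datasets(fit, n_rep = 20, seed = 1)
  expect_equal(dim(reps$direct), c(20, nrow(sim$data$direct)))
  expect_equal(dim(reps$satellite), c(20, nrow(sim$data$satellite)))
  expect_error(replicate_datasets(fit, n_rep = 10^6), "stored draws")
  # determinism
  reps2 <- replicate_datasets(fit, n_rep = 20, seed = 1)
  expect_identical(reps, reps2)
})

test_that("a noiseless doctored posterior replicates its expectations", {
  sim <- simulate_dataset(design = design_config(n_colonies = 3,
                                                 n_years = 3), seed = 15)
  fit <- fit_colony_model(sim$data, mcmc = small_mcmc(seed = 15))
  # doctor every stored draw: exact latent state, vanishing noise
  for (i in seq_along(fit$chains)) {
    ch <- fit$chains[[i]]
    ch$hyper[, "alpha"] <- 0
    ch$hyper[, "sigma_aerial"] <- 1e-9
    ch$hyper[, c("beta1", "beta2", "beta3")] <- 1
    ch$hyper[, c("cv1", "cv2", "cv3")] <- 1e-9
    ch$X[] <- rep(as.vector(t(sim$truth$latent$X)), each = nrow(ch$X))
    ch$z[] <- rep(as.vector(t(sim$truth$latent$z)), each = nrow(ch$z))
    ch$N <- ch$X * ch$z
    fit$chains[[i]] <- ch
  }
  reps <- replicate_datasets(fit, n_rep = 10, seed = 2)
  X <- pengindex:::posterior_draws(fit, "X")
  z <- pengindex:::posterior_draws(fit, "z")
  hy <- pengindex:::posterior_draws(fit, "hyper")
  ex <- pengindex:::.slot_expectations(sim$data, X[1, ], z[1, ], hy[1, ])
  for (r in 1:10) {
    expect_equal(unname(reps$direct[r, ]), ex$direct, tolerance = 1e-6)
    expect_equal(unname(reps$satellite[r, ]), ex$satellite,
                 tolerance = 1e-6)
  }
})

test_that("replicate means match posterior-predictive means (MC oracle)", {
  # constant posterior pinned at known values: replicate means must
  # approach the analytic observation-model means
  sim <- simulate_dataset(design = design_config(n_colonies = 2,
                                                 n_years = 2), seed = 16)
  fit <- fit_colony_model(sim$data, mcmc = mcmc_config(1, 100, 1, 1000,
                                                       seed = 16))
  hpv <- c(r_bar = 0, sigma_r = 0.05, sigma_process = 0.1, p = 1,
           alpha = 0, sigma_aerial = 0.2, beta1 = 0.8, beta2 = 0.9,
           beta3 = 1, cv1 = 0.3, cv2 = 0.2, cv3 = 0.1)
  ch <- fit$chains[[1]]
  ch$hyper[] <- rep(hpv, each = nrow(ch$hyper))
  ch$X[] <- 1000
  ch$z[] <- 1L
  ch$N <- ch$X * ch$z
  fit$chains[[1]] <- ch
  reps <- replicate_datasets(fit, n_rep = 1000, seed = 3)
  ex <- pengindex:::.slot_expectations(sim$data, ch$X[1, ], ch$z[1, ],
                                       ch$hyper[1, ])
  # lognormal mean is exactly X (alpha = 0); satellite mean beta_q * X
  expect_equal(unname(colMeans(reps$direct)), ex$direct,
               tolerance = 0.03)
  expect_equal(unname(colMeans(reps$satellite)), ex$satellite,
               tolerance = 0.04)
})

test_that("posterior_predictive_check is calibrated on model-generated data", {
  sim <- simulate_dataset(design = design_config(n_colonies = 10,
                                                 n_years = 6), seed = 17)
  fit <- fit_colony_model(sim$data,
                          mcmc = mcmc_config(2, 800, 4, 500, seed = 17))
  res <- posterior_predictive_check(fit, n_rep = 500, seed = 4)
  expect_true(all(res$p_value > 0 & res$p_value < 1))
  # loose smoke bound at this small scale; the desk-scale calibration
  # criterion (0.2, 0.8) is asserted in test-acceptance.R
  expect_true(all(res$p_value > 0.05 & res$p_value < 0.95))
  expect_length(res$rep_rmse$direct, 500)
})
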