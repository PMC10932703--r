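# Shared fixture builders. Everything is generated in code; no files on
# disk beyond tempdir scratch.

tiny_colonies <- function(n = 2) {
  data.frame(
    colony_id = sprintf("C%02d", seq_len(n)),
    name = sprintf("colony %d", seq_len(n)),
    fast_ice_region = rep_len(pengindex:::FAST_ICE_REGIONS, n),
    pack_ice_region = rep_len(pengindex:::PACK_ICE_REGIONS, n))
}

empty_direct <- function() {
  data.frame(colony_id = character(), year = integer(), doy = integer(),
             count = numeric(), platform = character())
}

empty_satellite <- function() {
  data.frame(colony_id = character(), year = integer(), doy = integer(),
             value = numeric(), quality = integer(),
             catalog_id = character())
}

# 2 colonies x 3 years with a mix of observation types, used by the
# joint-posterior oracle tests
tiny_dataset <- function() {
  cols <- tiny_colonies(2)
  direct <- data.frame(
    colony_id = c("C01", "C01", "C02"),
    year = c(2009L, 2010L, 2011L),
    doy = c(289L, 300L, 280L),
    count = c(1000L, 900L, 450L),
    platform = c("aerial", "ground", "camera"))
  satellite <- data.frame(
    colony_id = c("C01", "C02", "C02"),
    year = c(2011L, 2009L, 2010L),
    doy = c(289L, 295L, 310L),
    value = c(1050, 480, 0),
    quality = c(3L, 1L, 2L),
    catalog_id = c("A1", "A2", "A3"))
  survey_dataset(cols, direct, satellite, years = c(2009L, 2011L))
}

tiny_latent <- function() {
  X <- rbind(c(1000, 950, 1020), c(470, 500, 520))
  z <- rbind(c(1, 1, 1), c(1, 0, 1))
  latent_state(X, z, r = c(-0.01, 0.02))
}

tiny_hp <- function() {
  hyperparams(r_bar = -0.01, sigma_r = 0.05, sigma_process = 0.12,
              p = 0.9, alpha = -0.004, sigma_aerial = 0.1,
              beta = c(0.85, 0.9, 1.0), cv_sat = c(0.3, 0.2, 0.1),
              xbar1 = 800, sigma_logx1 = 0.8)
}

# a fabricated minimal fit object (one chain, hand-written N draws) for
# summary-arithmetic tests that need no sampler run
fake_fit <- function(N_draws, colonies, years) {
  J <- nrow(colonies); Y <- length(years)
  stopifnot(ncol(N_draws) == J * Y)
  grid <- paste0("[", rep(colonies$colony_id, each = Y), ",",
                 rep(years, J), "]")
  colnames(N_draws) <- paste0("N", grid)
  X <- pmax(N_draws, 1e-9)
  z <- (N_draws > 0) + 0
  chain <- list(hyper = matrix(0, nrow(N_draws), 12,
                               dimnames = list(NULL, pengindex:::.hyper_names)),
                r = matrix(0, nrow(N_draws), J),
                X = X, z = z, N = N_draws)
  structure(list(chains = list(chain),
                 data = list(colonies = colonies),
                 priors = prior_config(),
                 colonies = colonies$colony_id,
                 years = as.integer(years), J = J, Y = Y),
            class = "peng_fit")
}

small_mcmc <- function(seed = 1, chains = 2) {
  mcmc_config(n_chains = chains, burn_in = 300, thin = 2, n_store = 200,
              seed = seed)
}
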