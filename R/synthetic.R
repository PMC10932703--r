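## Truth and observation simulator: the generative side of the model,
## with the survey imbalance the empirical record shows (a few colonies
## with repeated within-season direct counts, most colony-years
## satellite-only or unobserved, occasional colony "blinking").

FAST_ICE_REGIONS <- c("Amundsen Sea", "Australia", "Bellingshausen Sea",
                      "Dronning Maud Land", "East Indian Ocean",
                      "Victoria Oates Land", "Weddell Sea",
                      "West Indian Ocean")
PACK_ICE_REGIONS <- c("Bell-Amundsen", "Indian", "Pacific", "Ross",
                      "Weddell")

#' Survey design for the simulator
#'
#' Defaults emulate the empirical imbalance: 5 of 50 colonies receive
#' 1-5 direct counts per year; every colony-year carries 0-2 satellite
#' observations (probabilities `sat_n_probs` over 0/1/2, mean ~0.9
#' images, echoing ~460 images over 500 colony-years); image quality is
#' drawn from `quality_probs`; survey days are uniform on
#' `doy_window` = 274-319.
#'
#' @param n_colonies,n_years Grid size.
#' @param years First modelled year (grid is contiguous).
#' @param aerial_colonies Indices of colonies with direct-count surveys.
#' @param aerial_surveys_per_year Range (min, max) of direct counts per
#'   surveyed colony-year.
#' @param sat_n_probs Probabilities of 0, 1, 2 satellite observations
#'   per colony-year.
#' @param quality_probs Probabilities of quality classes 1 (poor), 2, 3
#'   (good).
#' @param doy_window Inclusive day-of-year sampling window.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_colonies = 50, n_years = 10, years = 2009,
                          aerial_colonies = seq_len(min(5, n_colonies)),
                          aerial_surveys_per_year = c(1, 5),
                          sat_n_probs = c(0.3, 0.5, 0.2),
                          quality_probs = c(0.25, 0.35, 0.40),
                          doy_window = c(274, 319)) {
  stopifnot(n_colonies >= 1, n_years >= 1,
            all(aerial_colonies %in% seq_len(n_colonies)),
            length(sat_n_probs) == 3, all(sat_n_probs >= 0),
            abs(sum(sat_n_probs) - 1) < 1e-8,
            length(quality_probs) == 3, all(quality_probs >= 0),
            abs(sum(quality_probs) - 1) < 1e-8,
            doy_window[1] <= doy_window[2])
  structure(list(n_colonies = as.integer(n_colonies),
                 n_years = as.integer(n_years),
                 years = seq.int(years, years + n_years - 1),
                 aerial_colonies = as.integer(aerial_colonies),
                 aerial_surveys_per_year = as.integer(aerial_surveys_per_year),
                 sat_n_probs = sat_n_probs,
                 quality_probs = quality_probs,
                 doy_window = as.integer(doy_window)),
            class = "design_config")
}

#' Fixture hyperparameters for simulation
#'
#' Package defaults standing in for the unpublished empirical estimates:
#' a gently declining global population (`r_bar = -0.013`, ~ -1.3% per
#' year), moderate colony heterogeneity and process noise, rare blinking
#' (`p = 0.97`), a small negative day-of-year effect, and satellite bias
#' / CV ordered by image quality (poor images more biased and noisier).
#' The initial-abundance scale puts ~50 colonies in the low hundreds of
#' thousands of adults overall.
#'
#' @return A [hyperparams()].
#' @export
fixture_hyperparams <- function() {
  hyperparams(r_bar = -0.013, sigma_r = 0.05, sigma_process = 0.15,
              p = 0.97, alpha = -0.005, sigma_aerial = 0.1,
              beta = c(0.8, 0.9, 1.0), cv_sat = c(0.30, 0.20, 0.10),
              xbar1 = 5000, sigma_logx1 = 1.0)
}

#' Simulate true colony trajectories
#'
#' Runs the process model generatively: `r_j ~ Normal(r_bar,
#' sigma_r^2)`, `X[,1]` from the initial prior, `X[,y]` forward from the
#' lognormal dynamics, `z` iid `Bernoulli(p)`, `N = z * X`. The true
#' global trend is [annual_trend()] of the realized noiseless global sum
#' and the true change is the percent change of that sum between the
#' first and last year.
#'
#' @param hp A [hyperparams()].
#' @param design A [design_config()].
#' @param seed RNG seed.
#' @return An object of class `truth_set`: the hyperparameters, a
#'   [latent_state()], the colony roster (regions assigned round-robin),
#'   and the derived true trend/change.
#' @export
simulate_truth <- function(hp = fixture_hyperparams(),
                           design = design_config(), seed = 1) {
  stopifnot(inherits(hp, "hyperparams"), inherits(design, "design_config"))
  set.seed(seed)
  J <- design$n_colonies; Yn <- design$n_years
  r <- rnorm(J, hp$r_bar, hp$sigma_r)
  X <- matrix(0, J, Yn)
  X[, 1] <- rlnorm(J, log(hp$xbar1), hp$sigma_logx1)
  if (Yn > 1) {
    for (y in 2:Yn) {
      X[, y] <- rlnorm(J, log(X[, y - 1]) + r, hp$sigma_process)
    }
  }
  z <- matrix(rbinom(J * Yn, 1, hp$p), J, Yn)
  latent <- latent_state(X, z, r)
  global <- colSums(latent$N)
  series <- index_series(matrix(global, 1), design$years, "true global")
  truth <- list(
    hyperparams = hp, latent = latent, design = design,
    colonies = data.frame(
      colony_id = sprintf("C%02d", seq_len(J)),
      name = sprintf("colony %d", seq_len(J)),
      fast_ice_region = rep_len(FAST_ICE_REGIONS, J),
      pack_ice_region = rep_len(PACK_ICE_REGIONS, J)),
    true_trend = if (Yn > 1 && all(global > 0))
      annual_trend(series)[1] else NA_real_,
    true_change = if (Yn > 1 && global[1] > 0)
      100 * (global[Yn] - global[1]) / global[1] else NA_real_)
  structure(truth, class = "truth_set")
}

#' Simulate observations of a truth set
#'
#' For each designed survey slot, draws a direct count from the
#' lognormal count model or a satellite value from the
#' constant-CV normal model with the slot's quality class. Colony-years
#' with `z = 0` yield observations of exactly 0 (the degenerate
#' branch). Counts are rounded to integers (floored at 1 for present
#' colonies so a positive-abundance draw is never coerced to an
#' apparent absence).
#'
#' @param truth A `truth_set` from [simulate_truth()].
#' @param design A [design_config()]; defaults to the truth's design.
#' @param seed RNG seed.
#' @return A validated `survey_dataset`.
#' @export
simulate_observations <- function(truth, design = truth$design, seed = 1) {
  stopifnot(inherits(truth, "truth_set"))
  set.seed(seed)
  hp <- truth$hyperparams
  X <- truth$latent$X; z <- truth$latent$z
  J <- design$n_colonies; Yn <- design$n_years
  rdoy <- function(n) {
    sample(seq.int(design$doy_window[1], design$doy_window[2]), n,
           replace = TRUE)
  }

  drows <- list(); srows <- list(); k <- 0L
  for (j in design$aerial_colonies) {
    for (y in seq_len(Yn)) {
      n_srv <- sample(seq.int(design$aerial_surveys_per_year[1],
                              design$aerial_surveys_per_year[2]), 1)
      if (n_srv == 0) next
      doy <- rdoy(n_srv)
      if (z[j, y] == 1) {
        lam <- rlnorm(n_srv,
                      log(X[j, y]) + hp$alpha * doy_covariate(doy) -
                        hp$sigma_aerial^2 / 2, hp$sigma_aerial)
        cnt <- pmax(round(lam), 1)
      } else {
        cnt <- rep(0, n_srv)
      }
      k <- k + 1L
      drows[[k]] <- data.frame(
        colony_id = truth$colonies$colony_id[j],
        year = design$years[y], doy = doy, count = cnt,
        platform = sample(PLATFORMS, n_srv, replace = TRUE,
                          prob = c(0.6, 0.2, 0.2)))
    }
  }
  k <- 0L
  img <- 0L
  for (j in seq_len(J)) {
    for (y in seq_len(Yn)) {
      n_sat <- sample(0:2, 1, prob = design$sat_n_probs)
      if (n_sat == 0) next
      doy <- rdoy(n_sat)
      q <- sample(1:3, n_sat, replace = TRUE,
                  prob = design$quality_probs)
      if (z[j, y] == 1) {
        mu0 <- X[j, y] * exp(hp$alpha * doy_covariate(doy))
        val <- pmax(rnorm(n_sat, hp$beta[q] * mu0, mu0 * hp$cv_sat[q]),
                    1)
      } else {
        val <- rep(0, n_sat)
      }
      k <- k + 1L
      img <- img + n_sat
      srows[[k]] <- data.frame(
        colony_id = truth$colonies$colony_id[j],
        year = design$years[y], doy = doy, value = val, quality = q,
        catalog_id = sprintf("IMG%06d", seq.int(img - n_sat + 1L, img)))
    }
  }
  empty_direct <- data.frame(colony_id = character(), year = integer(),
                             doy = integer(), count = numeric(),
                             platform = character())
  empty_sat <- data.frame(colony_id = character(), year = integer(),
                          doy = integer(), value = numeric(),
                          quality = integer(), catalog_id = character())
  survey_dataset(
    colonies = truth$colonies,
    direct = if (length(drows)) do.call(rbind, drows) else empty_direct,
    satellite = if (length(srows)) do.call(rbind, srows) else empty_sat,
    years = range(design$years))
}

#' Simulate truth and observations in one call
#'
#' @inheritParams simulate_truth
#' @param obs_seed Seed for the observation layer (default `seed + 1`,
#'   keeping truth and observation randomness separable).
#' @return List with `truth` (a `truth_set`) and `data` (a
#'   `survey_dataset`).
#' @export
simulate_dataset <- function(hp = fixture_hyperparams(),
                             design = design_config(), seed = 1,
                             obs_seed = seed + 1) {
  truth <- simulate_truth(hp, design, seed)
  list(truth = truth,
       data = simulate_observations(truth, design, obs_seed))
}
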