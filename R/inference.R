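## Posterior sampling: initialization, the fit driver around the compiled
## Metropolis-within-Gibbs kernel, and the stored-draw container.

#' MCMC configuration
#'
#' Defaults follow the study protocol: three chains, 50000 burn-in
#' iterations, then every 50th iteration stored until 10000 draws per
#' chain are accumulated. [mcmc_config_test()] is a scaled-down
#' configuration for desk-scale runs (tests, simulation replicates).
#'
#' @param n_chains,burn_in,thin,n_store Positive integers.
#' @param seed Integer RNG seed.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, burn_in = 50000, thin = 50,
                        n_store = 10000, seed = 1) {
  stopifnot(n_chains >= 1, burn_in >= 1, thin >= 1, n_store >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_store = as.integer(n_store), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_test <- function(n_chains = 3, burn_in = 1000, thin = 5,
                             n_store = 1000, seed = 1) {
  mcmc_config(n_chains, burn_in, thin, n_store, seed)
}

## Map observations to the (colony, year) grid; classify the forced
## presence states. Returns the arrays consumed by the compiled kernel.
.prepare_obs <- function(data, priors) {
  J <- nrow(data$colonies); Y <- length(data$years)
  jidx <- match(data$direct$colony_id, data$colonies$colony_id)
  yidx <- match(data$direct$year, data$years)
  sidx <- match(data$satellite$colony_id, data$colonies$colony_id)
  syidx <- match(data$satellite$year, data$years)
  eps <- priors$eps_abs

  a_pos <- if (nrow(data$direct)) data$direct$count > eps else logical(0)
  s_pos <- if (nrow(data$satellite)) data$satellite$value > eps else logical(0)

  site_a <- (jidx - 1L) * Y + (yidx - 1L)
  site_s <- (sidx - 1L) * Y + (syidx - 1L)

  z_forced <- rep(-1L, J * Y)
  pos_sites <- unique(c(site_a[a_pos], site_s[s_pos]))
  zero_sites <- unique(c(site_a[!a_pos], site_s[!s_pos]))
  conflict <- intersect(pos_sites, zero_sites)
  if (length(conflict)) {
    s <- conflict[1]
    stop(sprintf(
      "colony %s year %d has both zero and positive observations; the model cannot assign a presence state",
      data$colonies$colony_id[s %/% Y + 1], data$years[s %% Y + 1]),
      call. = FALSE)
  }
  z_forced[pos_sites + 1L] <- 1L
  z_forced[zero_sites + 1L] <- 0L

  list(
    J = J, Y = Y,
    a_site = site_a[a_pos],
    a_logc = log(data$direct$count[a_pos]),
    a_doy = as.numeric(doy_covariate(data$direct$doy[a_pos])),
    s_site = site_s[s_pos],
    s_val = data$satellite$value[s_pos],
    s_doy = as.numeric(doy_covariate(data$satellite$doy[s_pos])),
    s_qual = as.integer(data$satellite$quality[s_pos]) - 1L,
    z_forced = z_forced,
    n_active = sum(a_pos) + sum(s_pos))
}

#' Initial latent state and hyperparameter values
#'
#' `X` is initialized from per-colony-year means of the positive
#' observations (satellite values divided by an initial bias of 1),
#' carried forward then backward through unobserved years; `z` is 1
#' wherever a positive observation exists, 0 where only zero
#' observations exist, and drawn from `Bernoulli(0.9)` elsewhere;
#' `r_j = 0`. The initial-abundance hyperparameters `xbar1` /
#' `sigma_logx1` are estimated from the first-year initial values
#' (geometric mean; log-sd floored at 0.3).
#'
#' @param data A `survey_dataset`.
#' @param priors A [prior_config()].
#' @param p0 Presence probability used for unobserved colony-years.
#' @return List with a [latent_state()] and a [hyperparams()].
#' @export
initialize_state <- function(data, priors = prior_config(), p0 = 0.9) {
  stopifnot(inherits(data, "survey_dataset"))
  J <- nrow(data$colonies); Y <- length(data$years)
  eps <- priors$eps_abs

  sums <- matrix(0, J, Y); cnts <- matrix(0L, J, Y)
  zeros <- matrix(FALSE, J, Y)
  add_obs <- function(ids, yrs, vals) {
    j <- match(ids, data$colonies$colony_id)
    y <- match(yrs, data$years)
    for (i in seq_along(vals)) {
      if (vals[i] > eps) {
        sums[j[i], y[i]] <<- sums[j[i], y[i]] + vals[i]
        cnts[j[i], y[i]] <<- cnts[j[i], y[i]] + 1L
      } else {
        zeros[j[i], y[i]] <<- TRUE
      }
    }
  }
  add_obs(data$direct$colony_id, data$direct$year, data$direct$count)
  add_obs(data$satellite$colony_id, data$satellite$year,
          data$satellite$value)

  X <- matrix(NA_real_, J, Y)
  X[cnts > 0] <- (sums / pmax(cnts, 1L))[cnts > 0]
  global_fallback <- if (any(cnts > 0)) {
    exp(mean(log(X[cnts > 0])))
  } else 5000
  for (j in seq_len(J)) {
    for (y in seq_len(Y)) {  # carry forward
      if (is.na(X[j, y]) && y > 1) X[j, y] <- X[j, y - 1]
    }
    for (y in rev(seq_len(Y))) {  # then backward
      if (is.na(X[j, y]) && y < Y) X[j, y] <- X[j, y + 1]
    }
    X[j, is.na(X[j, ])] <- global_fallback
  }

  z <- matrix(NA_integer_, J, Y)
  z[cnts > 0] <- 1L
  z[zeros & cnts == 0] <- 0L
  free <- is.na(z)
  z[free] <- rbinom(sum(free), 1L, p0)

  lx1 <- log(X[, 1])
  sigma_logx1 <- if (J > 1) max(sd(lx1), 0.3) else 1
  hp <- hyperparams(
    r_bar = 0, sigma_r = 0.1, sigma_process = 0.2,
    p = if (is.null(priors$p_fixed)) 0.9 else priors$p_fixed,
    alpha = if (is.null(priors$alpha_fixed)) 0 else priors$alpha_fixed,
    sigma_aerial = if (is.null(priors$sigma_aerial_fixed)) 0.2 else
      priors$sigma_aerial_fixed,
    beta = if (is.null(priors$beta_fixed)) c(1, 1, 1) else
      rep(priors$beta_fixed, length.out = 3),
    cv_sat = if (is.null(priors$cv_fixed)) c(0.2, 0.2, 0.2) else
      rep(priors$cv_fixed, length.out = 3),
    xbar1 = exp(mean(lx1)), sigma_logx1 = sigma_logx1)

  list(latent = latent_state(X, z, rep(0, J)), hyperparams = hp)
}

.hyper_names <- c("r_bar", "sigma_r", "sigma_process", "p", "alpha",
                  "sigma_aerial", "beta1", "beta2", "beta3", "cv1",
                  "cv2", "cv3")

.hp_to_vec <- function(hp) {
  c(hp$r_bar, hp$sigma_r, hp$sigma_process, hp$p, hp$alpha,
    hp$sigma_aerial, hp$beta, hp$cv_sat)
}

.fixed_mask <- function(priors) {
  m <- numeric(12)
  if (!is.null(priors$p_fixed)) m[4] <- 1
  if (!is.null(priors$alpha_fixed)) m[5] <- 1
  if (!is.null(priors$sigma_aerial_fixed)) m[6] <- 1
  if (!is.null(priors$beta_fixed)) m[7:9] <- 1
  if (!is.null(priors$cv_fixed)) m[10:12] <- 1
  m
}

#' Fit the state-space abundance model
#'
#' Runs `n_chains` adaptive Metropolis-within-Gibbs chains over the
#' latent states (log-scale random walk), presence indicators (exact
#' full conditional), colony effects and `r_bar` (conjugate normal),
#' `p` (conjugate beta) and the remaining scalars (random-walk
#' Metropolis, log scale for positives). Adaptation runs during burn-in
#' only. Given identical data, priors, configuration and seed the stored
#' draws are bit-reproducible.
#'
#' @param data A `survey_dataset`.
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param prior_only Allow a dataset with zero observations (latent grid
#'   retained); by default such a fit is refused.
#' @return An object of class `peng_fit`: per-chain draw matrices of the
#'   hyperparameters, colony effects `r_j`, latent `X`, presence `z` and
#'   index `N = z * X`.
#' @export
fit_colony_model <- function(data, priors = prior_config(),
                             mcmc = mcmc_config(), prior_only = FALSE) {
  stopifnot(inherits(data, "survey_dataset"),
            inherits(priors, "prior_config"),
            inherits(mcmc, "mcmc_config"))
  obs <- .prepare_obs(data, priors)
  if (obs$n_active == 0 && !prior_only) {
    stop("dataset has no positive observations; use prior_only = TRUE for a prior-only run",
         call. = FALSE)
  }
  set.seed(mcmc$seed)
  init <- initialize_state(data, priors)

  lp0 <- joint_log_posterior(init$hyperparams, init$latent, data, priors)
  if (!is.finite(lp0)) {
    stop(sprintf("non-finite joint log-posterior at initialization (%s); check observation/presence consistency",
                 format(lp0)), call. = FALSE)
  }

  J <- obs$J; Y <- obs$Y
  hp0 <- .hp_to_vec(init$hyperparams)
  fixed <- .fixed_mask(priors)
  prior_list <- priors[c("r_bar_mean", "r_bar_sd", "sigma_r_scale",
                         "sigma_process_scale", "sigma_aerial_scale",
                         "p_a", "p_b", "alpha_mean", "alpha_sd",
                         "log_beta_mean", "log_beta_sd", "cv_scale",
                         "beta_in_mean", "beta_in_variance")]

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    # overdispersed starts: jitter the latent log-abundances and free
    # scalars chain by chain
    lx0 <- as.vector(t(log(init$latent$X))) + rnorm(J * Y, 0, 0.25)
    z0 <- as.vector(t(init$latent$z))
    hpc <- hp0
    jit <- exp(rnorm(12, 0, 0.1))
    hpc[c(2, 3, 6)] <- hpc[c(2, 3, 6)] * jit[c(2, 3, 6)]
    if (!fixed[7]) hpc[7:9] <- hpc[7:9] * jit[7:9]
    if (!fixed[10]) hpc[10:12] <- hpc[10:12] * jit[10:12]
    raw <- .mcmc_chain(J, Y, obs$a_site, obs$a_logc, obs$a_doy,
                       obs$s_site, obs$s_val, obs$s_doy, obs$s_qual,
                       obs$z_forced, lx0, z0, rep(0, J), hpc, fixed,
                       log(init$hyperparams$xbar1),
                       init$hyperparams$sigma_logx1, prior_list,
                       mcmc$burn_in, mcmc$thin, mcmc$n_store)
    colnames(raw$hyper) <- .hyper_names
    colnames(raw$r) <- paste0("r[", data$colonies$colony_id, "]")
    grid <- paste0("[", rep(data$colonies$colony_id, each = Y), ",",
                   rep(data$years, J), "]")
    colnames(raw$X) <- paste0("X", grid)
    colnames(raw$z) <- paste0("z", grid)
    raw$N <- raw$X * raw$z
    colnames(raw$N) <- paste0("N", grid)
    chains[[ch]] <- raw
  }

  structure(
    list(chains = chains, data = data, priors = priors, mcmc = mcmc,
         init = init, colonies = data$colonies$colony_id,
         years = data$years, J = J, Y = Y),
    class = "peng_fit")
}

#' @export
print.peng_fit <- function(x, ...) {
  cat(sprintf(
    "peng_fit: %d colonies x %d years, %d chain(s) x %d stored draws\n  (burn-in %d, thin %d, seed %d)\n",
    x$J, x$Y, length(x$chains), x$mcmc$n_store, x$mcmc$burn_in,
    x$mcmc$thin, x$mcmc$seed))
  invisible(x)
}

## Per-chain matrices of the monitored continuous quantities
## (hyperparameters, colony effects, latent X). Fixed parameters are
## dropped (constant chains have no defined PSRF).
.monitored_matrices <- function(fit, include_latent = TRUE) {
  free <- .fixed_mask(fit$priors) == 0
  lapply(fit$chains, function(ch) {
    m <- cbind(ch$hyper[, free, drop = FALSE], ch$r)
    if (include_latent) m <- cbind(m, ch$X)
    m
  })
}

#' Extract pooled posterior draws
#'
#' Stacks chains into one matrix (draws in rows) of the requested
#' component: `"hyper"`, `"r"`, `"X"`, `"z"` or `"N"`.
#'
#' @param fit A `peng_fit`.
#' @param component Which draw block to extract.
#' @return Numeric matrix, `n_chains * n_store` rows.
#' @export
posterior_draws <- function(fit, component = c("hyper", "r", "X", "z",
                                               "N")) {
  component <- match.arg(component)
  do.call(rbind, lapply(fit$chains, `[[`, component))
}
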