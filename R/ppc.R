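## Posterior predictive checks: RMSE discrepancy and Bayesian p-values.

#' Root mean square error
#'
#' @param observed,expected Equal-length numeric vectors.
#' @return `sqrt(mean((observed - expected)^2))`.
#' @export
rmse <- function(observed, expected) {
  if (length(observed) != length(expected)) {
    stop("length mismatch", call. = FALSE)
  }
  if (!length(observed)) stop("empty vectors", call. = FALSE)
  sqrt(mean((observed - expected)^2))
}

#' Bayesian p-value
#'
#' Fraction of replicate discrepancies strictly lower than the observed
#' one. Values close to 0.5 indicate that the fitted model generates
#' data resembling the observations.
#'
#' @param rep_stats Per-replicate discrepancy statistics.
#' @param obs_stat Observed-data discrepancy (scalar, or per-replicate
#'   vector when the observed discrepancy is conditioned on the paired
#'   posterior draw).
#' @return Probability in `[0, 1]`.
#' @export
bayesian_pvalue <- function(rep_stats, obs_stat) {
  if (!length(rep_stats)) stop("no replicate statistics", call. = FALSE)
  mean(rep_stats < obs_stat)
}

## Model expectations at every observed slot under one posterior draw.
## Returns list(direct =, satellite =) of expectation vectors aligned
## with the dataset rows.
.slot_expectations <- function(data, X, z, hyper) {
  expect_one <- function(obs, satellite) {
    if (!nrow(obs)) return(numeric(0))
    j <- match(obs$colony_id, data$colonies$colony_id)
    y <- match(obs$year, data$years)
    s <- (j - 1) * length(data$years) + y
    dc <- doy_covariate(obs$doy)
    if (satellite) {
      N <- z[s] * X[s]
      hyper[paste0("beta", obs$quality)] * N * exp(hyper[["alpha"]] * dc)
    } else {
      z[s] * X[s] * exp(hyper[["alpha"]] * dc)
    }
  }
  list(direct = unname(expect_one(data$direct, FALSE)),
       satellite = unname(expect_one(data$satellite, TRUE)))
}

## Simulate every observed slot from the observation models under one
## posterior draw.
.simulate_slots <- function(data, X, z, hyper) {
  Yn <- length(data$years)
  out <- list(direct = numeric(0), satellite = numeric(0))
  d <- data$direct
  if (nrow(d)) {
    j <- match(d$colony_id, data$colonies$colony_id)
    y <- match(d$year, data$years)
    s <- (j - 1) * Yn + y
    dc <- doy_covariate(d$doy)
    present <- z[s] == 1
    cnt <- numeric(nrow(d))
    if (any(present)) {
      sa <- hyper[["sigma_aerial"]]
      cnt[present] <- rlnorm(sum(present),
                             log(X[s[present]]) + hyper[["alpha"]] *
                               dc[present] - sa^2 / 2, sa)
    }
    out$direct <- cnt
  }
  st <- data$satellite
  if (nrow(st)) {
    j <- match(st$colony_id, data$colonies$colony_id)
    y <- match(st$year, data$years)
    s <- (j - 1) * Yn + y
    dc <- doy_covariate(st$doy)
    N <- z[s] * X[s]
    mu0 <- N * exp(hyper[["alpha"]] * dc)
    val <- numeric(nrow(st))
    pos <- N > 0
    if (any(pos)) {
      b <- hyper[paste0("beta", st$quality[pos])]
      cv <- hyper[paste0("cv", st$quality[pos])]
      val[pos] <- rnorm(sum(pos), b * mu0[pos], mu0[pos] * cv)
    }
    out$satellite <- val
  }
  out
}

#' Posterior predictive replicate datasets
#'
#' For each replicate, takes the corresponding stored posterior draw
#' (replicate `r` is paired with pooled draw `r`) and simulates every
#' observed (colony, year, day, platform/quality) slot from its
#' observation model, preserving the observation design exactly.
#'
#' @param fit A `peng_fit`.
#' @param n_rep Number of replicates (at most the number of stored
#'   draws).
#' @param seed RNG seed.
#' @return List with `direct` and `satellite` matrices (`n_rep` rows,
#'   one column per observed slot) and the paired draw indices.
#' @export
replicate_datasets <- function(fit, n_rep = 1000, seed = 1) {
  stopifnot(inherits(fit, "peng_fit"), n_rep >= 1)
  X <- posterior_draws(fit, "X"); z <- posterior_draws(fit, "z")
  hy <- posterior_draws(fit, "hyper")
  if (n_rep > nrow(X)) {
    stop("n_rep exceeds the number of stored draws", call. = FALSE)
  }
  set.seed(seed)
  data <- fit$data
  dmat <- matrix(0, n_rep, nrow(data$direct))
  smat <- matrix(0, n_rep, nrow(data$satellite))
  for (r in seq_len(n_rep)) {
    sim <- .simulate_slots(data, X[r, ], z[r, ], hy[r, ])
    if (ncol(dmat)) dmat[r, ] <- sim$direct
    if (ncol(smat)) smat[r, ] <- sim$satellite
  }
  list(direct = dmat, satellite = smat, draw_index = seq_len(n_rep))
}

#' Posterior predictive check with RMSE discrepancy
#'
#' For each replicate `r` (paired with posterior draw `r`), computes the
#' RMSE of the observed values against the draw's model expectations,
#' and the RMSE of the simulated replicate against the same
#' expectations; the Bayesian p-value is the fraction of replicates
#' whose RMSE is strictly lower than the observed one. Direct-count and
#' satellite checks are computed separately.
#'
#' @param fit A `peng_fit`.
#' @param n_rep Number of posterior predictive replicates.
#' @param seed RNG seed for the replicate simulation.
#' @return An object of class `ppc_result` with per-replicate and
#'   observed RMSEs and the two p-values.
#' @export
posterior_predictive_check <- function(fit, n_rep = 1000, seed = 1) {
  reps <- replicate_datasets(fit, n_rep, seed)
  X <- posterior_draws(fit, "X"); z <- posterior_draws(fit, "z")
  hy <- posterior_draws(fit, "hyper")
  data <- fit$data
  obs_rmse <- rep_rmse <- list(direct = rep(NA_real_, n_rep),
                               satellite = rep(NA_real_, n_rep))
  for (r in seq_len(n_rep)) {
    ex <- .slot_expectations(data, X[r, ], z[r, ], hy[r, ])
    if (nrow(data$direct)) {
      obs_rmse$direct[r] <- rmse(data$direct$count, ex$direct)
      rep_rmse$direct[r] <- rmse(reps$direct[r, ], ex$direct)
    }
    if (nrow(data$satellite)) {
      obs_rmse$satellite[r] <- rmse(data$satellite$value, ex$satellite)
      rep_rmse$satellite[r] <- rmse(reps$satellite[r, ], ex$satellite)
    }
  }
  pval <- function(type) {
    if (all(is.na(rep_rmse[[type]]))) return(NA_real_)
    bayesian_pvalue(rep_rmse[[type]], obs_rmse[[type]])
  }
  structure(
    list(rep_rmse = rep_rmse, obs_rmse = obs_rmse,
         p_value = c(direct = pval("direct"),
                     satellite = pval("satellite")),
         n_rep = n_rep),
    class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf(
    "posterior predictive check (%d replicates):\n  direct counts: p = %.3f\n  satellite:     p = %.3f\n",
    x$n_rep, x$p_value[["direct"]], x$p_value[["satellite"]]))
  invisible(x)
}
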