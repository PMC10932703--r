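## Process and observation densities, hyperparameter containers, priors,
## and the joint log-posterior assembled from them.
##
## Model. Latent abundance at colony j in year y is X[j,y] > 0 with
## presence indicator z[j,y] in {0,1}; the abundance index is
## N[j,y] = z[j,y] * X[j,y].
##   X[j,1]  ~ lognormal(log(Xbar1), sigma_logX1^2)
##   X[j,y]  ~ lognormal(log(X[j,y-1]) + r_j, sigma_process^2)
##   z[j,y]  ~ Bernoulli(p)
##   r_j     ~ Normal(r_bar, sigma_r^2)
## Direct counts (aerial/ground/camera pooled), conditional on z = 1:
##   count   ~ lognormal(log(X) + alpha*doy_c - sigma_aerial^2/2, sigma_aerial^2)
## Satellite values of quality q, with mu0 = N * exp(alpha*doy_c):
##   S       ~ Normal(beta_q * mu0, (mu0 * cv_q)^2)
## When a colony is absent (N = 0) both observation laws degenerate to a
## point mass at 0.

#' Global model hyperparameters
#'
#' Container for the parameters shared across colonies: the mean annual
#' log-change `r_bar` and its across-colony sd `sigma_r`; the process sd
#' `sigma_process` (log scale); the colony presence probability `p`; the
#' log-linear day-of-year effect `alpha` (per day); the direct-count
#' lognormal sd `sigma_aerial`; satellite bias constants `beta` and
#' coefficients of variation `cv_sat`, one per image-quality class
#' (1 = poor, 2 = moderate, 3 = good); and the initial-abundance
#' hyperparameters `xbar1`, `sigma_logx1`.
#'
#' @param r_bar,sigma_r,sigma_process,p,alpha,sigma_aerial Scalars.
#' @param beta,cv_sat Numeric length-3 vectors indexed by quality class.
#' @param xbar1,sigma_logx1 Initial-abundance scale and log-sd.
#' @return An object of class `hyperparams`.
#' @export
hyperparams <- function(r_bar = 0, sigma_r = 0.1, sigma_process = 0.15,
                        p = 0.95, alpha = 0, sigma_aerial = 0.1,
                        beta = c(1, 1, 1), cv_sat = c(0.3, 0.2, 0.1),
                        xbar1 = 5000, sigma_logx1 = 1) {
  hp <- list(r_bar = r_bar, sigma_r = sigma_r,
             sigma_process = sigma_process, p = p, alpha = alpha,
             sigma_aerial = sigma_aerial, beta = beta, cv_sat = cv_sat,
             xbar1 = xbar1, sigma_logx1 = sigma_logx1)
  with(hp, {
    stopifnot(sigma_r > 0, sigma_process > 0, sigma_aerial > 0,
              sigma_logx1 > 0, p >= 0, p <= 1, xbar1 > 0,
              length(beta) == 3, all(beta > 0),
              length(cv_sat) == 3, all(cv_sat > 0))
  })
  structure(hp, class = "hyperparams")
}

#' Latent state of the population model
#'
#' @param X Colony-by-year matrix of positive latent abundances.
#' @param z Colony-by-year 0/1 presence matrix.
#' @param r Per-colony growth rates `r_j`.
#' @return An object of class `latent_state` with derived `N = z * X`.
#' @export
latent_state <- function(X, z, r) {
  X <- as.matrix(X); z <- as.matrix(z)
  stopifnot(all(dim(X) == dim(z)), nrow(X) == length(r),
            all(X > 0), all(z %in% c(0, 1)))
  structure(list(X = X, z = z, r = as.numeric(r), N = z * X),
            class = "latent_state")
}

#' Prior configuration and likelihood switches
#'
#' Hyperpriors (the package's defaults; overridable field by field):
#' `r_bar ~ Normal(0, 0.5^2)`, `sigma_r, sigma_process, sigma_aerial ~
#' half-Normal(0, 1)`, `p ~ Beta(1, 1)` (uniform), `alpha ~ Normal(0,
#' 0.1^2)`, `beta_q ~ lognormal(0, 0.5^2)`, `cv_q ~ half-Normal(0, 0.5)`.
#' `Xbar1` and `sigma_logX1` are estimated empirically from first-year
#' observations at initialization and held fixed.
#'
#' `eps_abs` is the absolute tolerance of the degenerate (absent-colony)
#' observation branch: an observation with magnitude at most `eps_abs` is
#' treated as an exact zero. `beta_in_mean` / `beta_in_variance` switch
#' where the satellite bias constant enters (defaults: mean yes,
#' variance no). `alpha_fixed`, `p_fixed`, `sigma_aerial_fixed`,
#' `beta_fixed`, `cv_fixed` pin a parameter at a known value (used e.g.
#' in noiseless validation fits).
#'
#' @param ... Named overrides of the fields listed above plus
#'   `r_bar_mean`, `r_bar_sd`, `sigma_r_scale`, `sigma_process_scale`,
#'   `sigma_aerial_scale`, `p_a`, `p_b`, `alpha_mean`, `alpha_sd`,
#'   `log_beta_mean`, `log_beta_sd`, `cv_scale`.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(...) {
  pc <- list(
    r_bar_mean = 0, r_bar_sd = 0.5,
    sigma_r_scale = 1, sigma_process_scale = 1, sigma_aerial_scale = 1,
    p_a = 1, p_b = 1,
    alpha_mean = 0, alpha_sd = 0.1,
    log_beta_mean = 0, log_beta_sd = 0.5,
    cv_scale = 0.5,
    eps_abs = 1e-6,
    beta_in_mean = TRUE, beta_in_variance = FALSE,
    alpha_fixed = NULL, p_fixed = NULL, sigma_aerial_fixed = NULL,
    beta_fixed = NULL, cv_fixed = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(pc))
  if (length(unknown)) {
    stop("unknown prior_config field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pc[names(dots)] <- dots
  structure(pc, class = "prior_config")
}

#' Read a prior configuration from a plain-text `key: value` file
#'
#' Lines are `key: value`; blank lines and `#` comments ignored. Vector
#' values (e.g. `beta_fixed`) are comma-separated. Logical values are
#' `true`/`false`.
#'
#' @param path File path.
#' @return A `prior_config`.
#' @export
read_prior_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln, call. = FALSE)
    val <- trimws(strsplit(m[3], ",")[[1]])
    parsed <- if (all(tolower(val) %in% c("true", "false"))) {
      tolower(val) == "true"
    } else {
      as.numeric(val)
    }
    kv[[m[2]]] <- parsed
  }
  do.call(prior_config, kv)
}

## ---- component densities ----------------------------------------------

#' Log-density of a latent abundance trajectory
#'
#' Year 1 uses the initial prior `lognormal(log(xbar1), sigma_logx1^2)`;
#' each later year contributes
#' `lognormal(log(X[y-1]) + r_j, sigma_process^2)`.
#'
#' @param x_traj Positive per-year abundances for one colony.
#' @param r_j Colony growth rate.
#' @param hp A [hyperparams()].
#' @return Scalar log-density.
#' @export
process_logdensity <- function(x_traj, r_j, hp) {
  if (any(!is.finite(x_traj)) || any(x_traj <= 0)) {
    stop("latent abundances must be positive", call. = FALSE)
  }
  ll <- dlnorm(x_traj[1], log(hp$xbar1), hp$sigma_logx1, log = TRUE)
  n <- length(x_traj)
  if (n > 1) {
    ll <- ll + sum(dlnorm(x_traj[-1],
                          log(x_traj[-n]) + r_j,
                          hp$sigma_process, log = TRUE))
  }
  ll
}

#' Log-probability of a presence indicator
#'
#' `z * log(p) + (1 - z) * log(1 - p)` with the convention
#' `0 * log(0) = 0` at the boundaries.
#'
#' @param z 0/1 indicator(s).
#' @param p Presence probability.
#' @return Log-probability (vectorised over `z`).
#' @export
presence_logpmf <- function(z, p) {
  stopifnot(all(z %in% c(0, 1)), p >= 0, p <= 1)
  dbinom(z, 1, p, log = TRUE)
}

#' Expected direct count
#'
#' The analytic mean of the direct-count lognormal: the `-sigma^2/2` term
#' in its log-location is exactly the correction that centres the count
#' on `X * exp(alpha * doy_c)` for any `sigma_aerial`.
#'
#' @param X Positive latent abundance.
#' @param alpha Day-of-year log-linear effect.
#' @param doy_c Centred day-of-year (see [doy_covariate()]).
#' @return Expected count.
#' @export
direct_count_expected <- function(X, alpha, doy_c) {
  stopifnot(all(X > 0))
  X * exp(alpha * doy_c)
}

#' Log-density of a direct count given colony presence
#'
#' `lognormal(log(X) + alpha*doy_c - sigma_aerial^2/2, sigma_aerial^2)`.
#' Zero counts are evidence of absence and must be routed through the
#' presence model, not this density.
#'
#' @param count Positive observed count.
#' @inheritParams direct_count_expected
#' @param sigma_aerial Lognormal sd (log scale).
#' @return Log-density (vectorised).
#' @export
direct_count_logdensity <- function(count, X, alpha, doy_c, sigma_aerial) {
  if (any(count <= 0)) {
    stop("count must be positive; route zeros through the presence model",
         call. = FALSE)
  }
  stopifnot(all(X > 0), sigma_aerial > 0)
  dlnorm(count, log(X) + alpha * doy_c - sigma_aerial^2 / 2,
         sigma_aerial, log = TRUE)
}

#' Expected satellite value
#'
#' `beta_q * N * exp(alpha * doy_c)`: the expected number of adults on the
#' survey day scaled by the image-quality bias constant. Zero when the
#' colony is absent (`N = 0`).
#'
#' @param N Non-negative abundance index (`z * X`).
#' @inheritParams direct_count_expected
#' @param beta_q Bias constant of the observation's quality class.
#' @return Expected value.
#' @export
satellite_expected <- function(N, alpha, doy_c, beta_q) {
  stopifnot(all(N >= 0), all(beta_q > 0))
  beta_q * N * exp(alpha * doy_c)
}

#' Log-density of a satellite observation
#'
#' Normal with mean [satellite_expected()] and sd
#' `N * exp(alpha*doy_c) * cv_q` — a constant coefficient of variation,
#' so larger colonies have larger absolute but equal proportional error.
#' When `N = 0` the distribution is a point mass at zero: the log-density
#' is 0 if `|S| <= eps_abs` and `-Inf` otherwise.
#'
#' @param S Observed satellite value (adult-count scale).
#' @inheritParams satellite_expected
#' @param cv_q Coefficient of variation of the quality class.
#' @param eps_abs Absolute tolerance of the degenerate branch.
#' @param beta_in_mean,beta_in_variance Where the bias constant enters.
#' @return Log-density (vectorised over `S`, `N`, `doy_c`).
#' @export
satellite_logdensity <- function(S, N, alpha, doy_c, beta_q, cv_q,
                                 eps_abs = 1e-6, beta_in_mean = TRUE,
                                 beta_in_variance = FALSE) {
  stopifnot(all(N >= 0), all(beta_q > 0), all(cv_q > 0))
  mu0 <- N * exp(alpha * doy_c)
  mean_ <- if (beta_in_mean) beta_q * mu0 else mu0
  sd_ <- if (beta_in_variance) beta_q * mu0 * cv_q else mu0 * cv_q
  out <- ifelse(abs(S) <= eps_abs, 0, -Inf)
  pos <- N > 0
  if (any(pos)) {
    out[pos] <- dnorm(rep(S, length.out = length(out))[pos],
                      rep(mean_, length.out = length(out))[pos],
                      rep(sd_, length.out = length(out))[pos], log = TRUE)
  }
  out
}

## ---- joint posterior --------------------------------------------------

.half_normal_logpdf <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + dnorm(x, 0, scale, log = TRUE)
}

## Hyperprior log-density on the natural scale of each parameter.
.hyperprior_logdensity <- function(hp, pc) {
  lp <- dnorm(hp$r_bar, pc$r_bar_mean, pc$r_bar_sd, log = TRUE) +
    .half_normal_logpdf(hp$sigma_r, pc$sigma_r_scale) +
    .half_normal_logpdf(hp$sigma_process, pc$sigma_process_scale)
  lp <- lp + if (is.null(pc$p_fixed)) {
    stats::dbeta(hp$p, pc$p_a, pc$p_b, log = TRUE)
  } else 0
  lp <- lp + if (is.null(pc$alpha_fixed)) {
    dnorm(hp$alpha, pc$alpha_mean, pc$alpha_sd, log = TRUE)
  } else 0
  lp <- lp + if (is.null(pc$sigma_aerial_fixed)) {
    .half_normal_logpdf(hp$sigma_aerial, pc$sigma_aerial_scale)
  } else 0
  lp <- lp + if (is.null(pc$beta_fixed)) {
    sum(dlnorm(hp$beta, pc$log_beta_mean, pc$log_beta_sd, log = TRUE))
  } else 0
  lp <- lp + if (is.null(pc$cv_fixed)) {
    sum(vapply(hp$cv_sat, .half_normal_logpdf, 0, scale = pc$cv_scale))
  } else 0
  lp
}

#' Joint log-posterior of the state-space model
#'
#' Sum of the process terms, presence terms, colony random-effect terms
#' (`r_j ~ Normal(r_bar, sigma_r^2)`), both observation likelihoods and
#' the hyperprior log-densities. Observations at absent colony-years
#' contribute through the degenerate point-mass branch; a positive
#' observation at an absent colony-year (or a zero count at a present
#' one) yields `-Inf`.
#'
#' @param hp A [hyperparams()].
#' @param latent A [latent_state()] whose dimensions match `data`.
#' @param data A `survey_dataset`.
#' @param priors A [prior_config()].
#' @return Scalar log-posterior (up to an additive constant).
#' @export
joint_log_posterior <- function(hp, latent, data,
                                priors = prior_config()) {
  stopifnot(inherits(hp, "hyperparams"), inherits(latent, "latent_state"),
            inherits(data, "survey_dataset"))
  J <- nrow(data$colonies); Y <- length(data$years)
  if (!all(dim(latent$X) == c(J, Y))) {
    stop(sprintf("latent state is %dx%d but data grid is %dx%d",
                 nrow(latent$X), ncol(latent$X), J, Y), call. = FALSE)
  }
  jidx <- function(id) match(id, data$colonies$colony_id)
  yidx <- function(yr) match(yr, data$years)

  lp <- .hyperprior_logdensity(hp, priors)
  for (j in seq_len(J)) {
    lp <- lp + process_logdensity(latent$X[j, ], latent$r[j], hp)
  }
  lp <- lp + sum(presence_logpmf(latent$z, hp$p))
  lp <- lp + sum(dnorm(latent$r, hp$r_bar, hp$sigma_r, log = TRUE))

  eps <- priors$eps_abs
  d <- data$direct
  for (i in seq_len(nrow(d))) {
    j <- jidx(d$colony_id[i]); y <- yidx(d$year[i])
    dc <- doy_covariate(d$doy[i])
    if (latent$z[j, y] == 1) {
      if (d$count[i] <= eps) return(-Inf)
      lp <- lp + direct_count_logdensity(d$count[i], latent$X[j, y],
                                         hp$alpha, dc, hp$sigma_aerial)
    } else if (abs(d$count[i]) > eps) {
      return(-Inf)
    }
  }
  s <- data$satellite
  for (i in seq_len(nrow(s))) {
    j <- jidx(s$colony_id[i]); y <- yidx(s$year[i])
    dc <- doy_covariate(s$doy[i])
    q <- s$quality[i]
    lp <- lp + satellite_logdensity(
      s$value[i], latent$N[j, y], hp$alpha, dc,
      hp$beta[q], hp$cv_sat[q], eps_abs = eps,
      beta_in_mean = priors$beta_in_mean,
      beta_in_variance = priors$beta_in_variance)
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}
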