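## Convergence diagnostics: potential scale reduction factor and
## autocorrelation-based effective sample size.

.psrf_one <- function(mat) {
  # mat: iterations x chains
  n <- nrow(mat); m <- ncol(mat)
  means <- colMeans(mat)
  vars <- apply(mat, 2, var)
  W <- mean(vars)
  B_over_n <- var(means)  # = B / n
  if (!is.finite(W) || W == 0) {
    return(if (!is.finite(B_over_n) || B_over_n == 0) 1 else Inf)
  }
  var_hat <- (n - 1) / n * W + B_over_n
  sqrt(var_hat / W + B_over_n / (m * W))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) formula: with within-chain variance `W` and
#' between-chain variance `B`, `psrf = sqrt(((n-1)/n W + B/n)/W +
#' B/(m n W))`. Values below 1.1 are conventionally taken as converged.
#' `split = TRUE` halves each chain first, which also flags
#' within-chain trends.
#'
#' @param x A `peng_fit` (diagnosed over hyperparameters, colony effects
#'   and latent abundances), or an iterations-by-chains numeric matrix
#'   for a single scalar parameter.
#' @param split Split each chain in half before computing.
#' @param include_latent For fit objects, include latent `X` draws.
#' @return Named numeric vector of per-parameter statistics (a scalar
#'   for matrix input). Parameters held fixed are excluded.
#' @export
gelman_rubin <- function(x, split = FALSE, include_latent = TRUE) {
  if (inherits(x, "peng_fit")) {
    mats <- .monitored_matrices(x, include_latent)
    if (length(mats) < 2) stop("need at least 2 chains", call. = FALSE)
    params <- colnames(mats[[1]])
    out <- vapply(seq_along(params), function(k) {
      gelman_rubin(vapply(mats, function(m) m[, k],
                          numeric(nrow(mats[[1]]))), split = split)
    }, numeric(1))
    names(out) <- params
    return(out)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 chains", call. = FALSE)
  if (nrow(x) < 10) stop("need at least 10 draws per chain", call. = FALSE)
  if (split) {
    h <- floor(nrow(x) / 2)
    x <- cbind(x[seq_len(h), , drop = FALSE],
               x[(nrow(x) - h + 1):nrow(x), , drop = FALSE])
  }
  .psrf_one(x)
}

## FFT-based autocorrelations rho_0..rho_lag_max (rho_0 = 1)
.autocorr_fft <- function(v, lag_max) {
  n <- length(v)
  x <- c(v - mean(v), numeric(stats::nextn(2 * n) - n))
  ac <- Re(stats::fft(Mod(stats::fft(x))^2, inverse = TRUE))[1:(lag_max + 1)]
  ac / ac[1]
}

.ess_one <- function(v) {
  # Geyer initial monotone positive-sequence estimator for one chain
  n <- length(v)
  if (var(v) == 0) {
    warning("constant chain: effective sample size is degenerate",
            call. = FALSE)
    return(1)
  }
  lag_max <- min(n - 1, 10 * floor(sqrt(n)) + 100)
  rho <- .autocorr_fft(v, lag_max)
  # pair sums Gamma_k = rho_{2k} + rho_{2k+1}; keep while positive and
  # enforce monotone non-increase
  npair <- floor((length(rho)) / 2)
  gam <- numeric(0)
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]  # lags 2(k-1), 2k-1
    if (g <= 0) break
    if (length(gam) && g > gam[length(gam)]) g <- gam[length(gam)]
    gam <- c(gam, g)
  }
  tau <- max(-1 + 2 * sum(gam), 1 / n)
  min(n / tau, n)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS per scalar parameter, using Geyer's initial
#' monotone positive-sequence truncation of the autocorrelation sum;
#' multi-chain ESS is the sum of per-chain estimates.
#'
#' @inheritParams gelman_rubin
#' @return Named numeric vector (scalar for vector/matrix input).
#' @export
effective_sample_size <- function(x, include_latent = TRUE) {
  if (inherits(x, "peng_fit")) {
    mats <- .monitored_matrices(x, include_latent)
    params <- colnames(mats[[1]])
    out <- vapply(seq_along(params), function(k) {
      sum(vapply(mats, function(m) .ess_one(m[, k]), numeric(1)))
    }, numeric(1))
    names(out) <- params
    return(out)
  }
  x <- as.matrix(x)
  sum(apply(x, 2, .ess_one))
}
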