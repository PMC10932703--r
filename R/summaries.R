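## Posterior index aggregation and change/trend/decline summaries.

#' Construct an index series from a draws-by-years matrix
#'
#' @param draws Numeric matrix, one row per posterior draw, one column
#'   per year.
#' @param years Integer years labelling the columns.
#' @param label Grouping label (colony id, region name, or "global").
#' @return An object of class `index_series`.
#' @export
index_series <- function(draws, years, label = "global") {
  draws <- as.matrix(draws)
  stopifnot(ncol(draws) == length(years), all(draws >= 0))
  colnames(draws) <- years
  structure(list(label = label, years = as.integer(years),
                 draws = draws), class = "index_series")
}

#' Aggregate colony indices into regional or global series
#'
#' Sums the abundance-index draws `N[j,y]` over member colonies,
#' draw-wise, preserving posterior dependence between colonies. Under a
#' partition of colonies the global series equals the draw-wise sum of
#' the group series.
#'
#' @param fit A `peng_fit`.
#' @param grouping `"global"`, `"fast_ice"`, `"pack_ice"` (region labels
#'   taken from the colony roster), or a named list mapping group labels
#'   to colony-id vectors.
#' @return A single `index_series` (for `"global"` or a one-group list)
#'   or a named list of them.
#' @export
aggregate_index <- function(fit, grouping = "global") {
  stopifnot(inherits(fit, "peng_fit"))
  N <- posterior_draws(fit, "N")  # columns ordered colony-major by year
  Y <- fit$Y
  sum_group <- function(ids) {
    j <- match(ids, fit$colonies)
    if (anyNA(j)) {
      stop("unknown colony id(s): ",
           paste(ids[is.na(j)], collapse = ", "), call. = FALSE)
    }
    cols <- outer((j - 1) * Y, seq_len(Y), `+`)  # sites of members
    out <- matrix(0, nrow(N), Y)
    for (y in seq_len(Y)) {
      out[, y] <- rowSums(N[, cols[, y], drop = FALSE])
    }
    out
  }
  if (is.character(grouping) && length(grouping) == 1) {
    if (grouping == "global") {
      return(index_series(sum_group(fit$colonies), fit$years, "global"))
    }
    if (grouping %in% c("fast_ice", "pack_ice")) {
      col <- paste0(sub("_ice", "", grouping), "_ice_region")
      groups <- split(fit$data$colonies$colony_id,
                      fit$data$colonies[[col]])
    } else {
      stop("unknown grouping: ", grouping, call. = FALSE)
    }
  } else if (is.list(grouping) && !is.null(names(grouping))) {
    groups <- grouping
  } else {
    stop("grouping must be a keyword or a named list of colony ids",
         call. = FALSE)
  }
  out <- lapply(names(groups), function(g) {
    index_series(sum_group(groups[[g]]), fit$years, g)
  })
  names(out) <- names(groups)
  out
}

#' @export
print.index_series <- function(x, ...) {
  s <- t(apply(x$draws, 2, summarize_draws))
  cat(sprintf("index_series '%s' (%d draws):\n", x$label, nrow(x$draws)))
  print(data.frame(year = x$years, round(s, 1)), row.names = FALSE)
  invisible(x)
}

#' Per-draw percent change between two years
#'
#' `100 * (N[y1] - N[y0]) / N[y0]` for each posterior draw. Draws with a
#' zero index in the base year are undefined and excluded; the number
#' excluded is attached as attribute `n_excluded` and messaged.
#'
#' @param series An `index_series`.
#' @param y0,y1 Calendar years (default: first and last of the series).
#' @return Numeric vector of per-draw changes (percent).
#' @export
percent_change <- function(series, y0 = series$years[1],
                           y1 = series$years[length(series$years)]) {
  stopifnot(inherits(series, "index_series"))
  i0 <- match(y0, series$years); i1 <- match(y1, series$years)
  if (is.na(i0) || is.na(i1)) stop("year out of range", call. = FALSE)
  base <- series$draws[, i0]
  ok <- base > 0
  if (any(!ok)) {
    message(sprintf("percent_change: %d draw(s) with zero base-year index excluded",
                    sum(!ok)))
  }
  out <- unname(100 * (series$draws[ok, i1] - base[ok]) / base[ok])
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Probability of decline beyond a threshold
#'
#' Fraction of change draws strictly below `-threshold_pct`. Strict
#' inequality is the conventional reading of "decline"; for continuous
#' posteriors boundary ties have probability zero. Set
#' `inclusive = TRUE` for the `<=` variant.
#'
#' @param changes Per-draw percent changes (see [percent_change()]).
#' @param threshold_pct Non-negative decline threshold in percent.
#' @param inclusive Count draws exactly at the boundary.
#' @return Probability in `[0, 1]`.
#' @export
prob_decline <- function(changes, threshold_pct = 0, inclusive = FALSE) {
  stopifnot(threshold_pct >= 0)
  changes <- changes[is.finite(changes)]
  if (!length(changes)) stop("no valid change draws", call. = FALSE)
  if (inclusive) mean(changes <= -threshold_pct)
  else mean(changes < -threshold_pct)
}

#' Per-draw log-linear annual trend
#'
#' For each draw, the least-squares slope `b` of `log(index)` on year,
#' reported as `100 * (exp(b) - 1)` percent per year. Draws containing a
#' zero index are excluded (attribute `n_excluded`). The endpoint-ratio
#' alternative `100 * ((N[Y]/N[1])^(1/(Y-1)) - 1)` is available via
#' `method = "endpoint"`.
#'
#' @param series An `index_series` spanning at least two years.
#' @param method `"ols"` (default) or `"endpoint"`.
#' @return Numeric vector of per-draw annual rates (percent per year).
#' @export
annual_trend <- function(series, method = c("ols", "endpoint")) {
  stopifnot(inherits(series, "index_series"))
  method <- match.arg(method)
  Y <- length(series$years)
  if (Y < 2) stop("need at least two years", call. = FALSE)
  ok <- apply(series$draws > 0, 1, all)
  if (any(!ok)) {
    message(sprintf("annual_trend: %d draw(s) with a zero index excluded",
                    sum(!ok)))
  }
  d <- series$draws[ok, , drop = FALSE]
  b <- if (method == "ols") {
    yr <- series$years - mean(series$years)
    (log(d) %*% yr) / sum(yr^2)
  } else {
    (log(d[, Y]) - log(d[, 1])) / (Y - 1)
  }
  out <- 100 * (exp(as.vector(b)) - 1)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Median and 95% equal-tailed credible interval
#'
#' @param draws Numeric draws.
#' @return Named vector `c(lo, median, hi)`: the 2.5th, 50th and 97.5th
#'   percentiles (default quantile rule, type 7).
#' @export
summarize_draws <- function(draws) {
  stopifnot(length(draws) >= 1)
  q <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE)
  c(lo = q[1], median = q[2], hi = q[3])
}

#' Posterior change summary for one group
#'
#' The row format of the regional change table: probabilities of any /
#' 30% / 50% decline, posterior mean and sd ("s.e.") of the percent
#' change, and its median and 95% equal-tailed CI.
#'
#' @param changes Per-draw percent changes.
#' @return One-row data.frame.
#' @export
change_summary <- function(changes) {
  changes <- changes[is.finite(changes)]
  if (!length(changes)) {
    # no draw defines the change (base-year index zero throughout)
    return(data.frame(p_decline = NA_real_, p_decline_30 = NA_real_,
                      p_decline_50 = NA_real_, mean_change = NA_real_,
                      se_change = NA_real_, median_change = NA_real_,
                      lo = NA_real_, hi = NA_real_))
  }
  s <- summarize_draws(changes)
  data.frame(
    p_decline = prob_decline(changes, 0),
    p_decline_30 = prob_decline(changes, 30),
    p_decline_50 = prob_decline(changes, 50),
    mean_change = mean(changes),
    se_change = sd(changes),
    median_change = s[["median"]],
    lo = s[["lo"]], hi = s[["hi"]])
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged).
#'
#' @param x,y Equal-length numeric vectors, length at least 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  cor(rank(x), rank(y))
}

#' Correlate regional population summaries with published ice trends
#'
#' For each region of the chosen ice type, computes the probability of
#' decline and the median percent change of the regional index over the
#' fitted period, then reports the Spearman rank correlation of each
#' scalar with the region's published ice-trend value. Both pairings are
#' reported because "regional population" does not name a single scalar.
#'
#' @param fit A `peng_fit`.
#' @param ice_trends data.frame from [read_ice_trends()].
#' @param ice_type `"fast"` or `"pack"`.
#' @return List with the per-region table (`regions`) and a `cor`
#'   data.frame of the two Spearman correlations.
#' @export
ice_correlation <- function(fit, ice_trends, ice_type = c("fast", "pack")) {
  ice_type <- match.arg(ice_type)
  series <- aggregate_index(fit, paste0(ice_type, "_ice"))
  trends <- ice_trends[ice_trends$ice_type == ice_type, ]
  tab <- do.call(rbind, lapply(names(series), function(g) {
    ch <- percent_change(series[[g]])
    cbind(data.frame(region = g), change_summary(ch))
  }))
  tab$trend_value <- trends$trend_value[match(tab$region, trends$region)]
  if (anyNA(tab$trend_value)) {
    stop("ice_trends is missing region(s): ",
         paste(tab$region[is.na(tab$trend_value)], collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(tab$p_decline)  # regions with a defined change
  list(regions = tab,
       cor = data.frame(
         scalar = c("p_decline", "median_change"),
         spearman = c(spearman_cor(tab$p_decline[ok],
                                   tab$trend_value[ok]),
                      spearman_cor(tab$median_change[ok],
                                   tab$trend_value[ok]))))
}
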