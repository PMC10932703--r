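## Survey data containers, CSV readers/writers, validation.

PLATFORMS <- c("aerial", "ground", "camera")

## Spring survey window (Aug-Nov) used for soft DOY validation.
DOY_WINDOW <- c(213L, 334L)

## Mid-point of the spring survey period; observation-day covariates are
## centred on this day so that alpha measures proportional change in
## expected count per day elapsed.
DOY_MIDPOINT <- 289L

#' Centred day-of-year covariate
#'
#' Survey timing enters both observation models through a log-linear
#' day-of-year effect. The covariate is the survey day-of-year minus 289,
#' the mid-point of the spring survey period, so that a survey at the
#' season mid-point has covariate 0.
#'
#' @param doy Integer day(s) of year, 1-366.
#' @return Integer centred day(s), `doy - 289`.
#' @examples
#' doy_covariate(289) # 0
#' doy_covariate(304) # 15
#' @export
doy_covariate <- function(doy) {
  if (!is.numeric(doy) || any(!is.finite(doy)) ||
      any(doy != as.integer(doy)) || any(doy < 1L) || any(doy > 366L)) {
    stop("`doy` must be integer day(s) of year in 1..366", call. = FALSE)
  }
  as.integer(doy) - DOY_MIDPOINT
}

#' Assemble and validate a survey dataset
#'
#' Bundles the colony roster, direct-count observations (aerial, ground,
#' remote camera — all share one observation model; platform is kept as
#' metadata) and satellite penguin-area observations (pre-converted to the
#' adult-count scale) on a contiguous year grid. Colony-years with no
#' observations are retained as latent.
#'
#' @param colonies data.frame with columns `colony_id`, `name`,
#'   `fast_ice_region`, `pack_ice_region`.
#' @param direct data.frame with columns `colony_id`, `year`, `doy`,
#'   `count`, `platform`.
#' @param satellite data.frame with columns `colony_id`, `year`, `doy`,
#'   `value`, `quality`, `catalog_id`.
#' @param years Optional inclusive integer year range `c(first, last)`;
#'   defaults to the observed range.
#' @return An object of class `survey_dataset`.
#' @export
survey_dataset <- function(colonies, direct, satellite, years = NULL) {
  colonies <- .check_columns(colonies, "regions",
    c("colony_id", "name", "fast_ice_region", "pack_ice_region"))
  direct <- .check_columns(direct, "counts",
    c("colony_id", "year", "doy", "count", "platform"))
  satellite <- .check_columns(satellite, "satellite",
    c("colony_id", "year", "doy", "value", "quality", "catalog_id"))

  colonies$colony_id <- as.character(colonies$colony_id)
  if (anyDuplicated(colonies$colony_id)) {
    stop("duplicated colony_id in colony roster", call. = FALSE)
  }

  for (nm in c("direct", "satellite")) {
    d <- get(nm)
    d$colony_id <- as.character(d$colony_id)
    unknown <- setdiff(d$colony_id, colonies$colony_id)
    if (length(unknown)) {
      stop(sprintf("%s observations reference unknown colony_id: %s",
                   nm, paste(unique(unknown), collapse = ", ")),
           call. = FALSE)
    }
    if (any(!is.finite(d$doy)) || any(d$doy < 1) || any(d$doy > 366)) {
      stop(sprintf("%s: doy must be in 1..366", nm), call. = FALSE)
    }
    out_win <- d$doy < DOY_WINDOW[1] | d$doy > DOY_WINDOW[2]
    if (any(out_win)) {
      warning(sprintf(
        "%s: %d observation(s) outside the spring survey window (doy %d-%d)",
        nm, sum(out_win), DOY_WINDOW[1], DOY_WINDOW[2]), call. = FALSE)
    }
    assign(nm, d)
  }

  if (nrow(direct)) {
    if (any(!is.finite(direct$count)) || any(direct$count < 0)) {
      stop("counts: count must be a non-negative integer", call. = FALSE)
    }
    if (any(direct$count != round(direct$count))) {
      stop("counts: count must be a non-negative integer", call. = FALSE)
    }
    bad <- !direct$platform %in% PLATFORMS
    if (any(bad)) {
      stop(sprintf("counts: platform must be one of {%s}; got: %s",
                   paste(PLATFORMS, collapse = ", "),
                   paste(unique(direct$platform[bad]), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (nrow(satellite)) {
    if (any(!is.finite(satellite$value)) || any(satellite$value < 0)) {
      stop("satellite: value must be non-negative", call. = FALSE)
    }
    if (any(!satellite$quality %in% c(1L, 2L, 3L))) {
      stop("satellite: quality must be 1, 2 or 3", call. = FALSE)
    }
  }

  # canonical column types so that write -> read roundtrips exactly
  direct$year <- as.integer(direct$year)
  direct$doy <- as.integer(direct$doy)
  direct$count <- as.integer(direct$count)
  direct$platform <- as.character(direct$platform)
  satellite$year <- as.integer(satellite$year)
  satellite$doy <- as.integer(satellite$doy)
  satellite$value <- as.numeric(satellite$value)
  satellite$quality <- as.integer(satellite$quality)
  satellite$catalog_id <- as.character(satellite$catalog_id)
  rownames(colonies) <- rownames(direct) <- rownames(satellite) <- NULL

  obs_years <- c(direct$year, satellite$year)
  if (is.null(years)) {
    if (!length(obs_years)) {
      stop("no observations and no explicit `years` range", call. = FALSE)
    }
    years <- range(obs_years)
  }
  years <- as.integer(years)
  if (length(years) != 2L || years[1] > years[2]) {
    stop("`years` must be an inclusive range c(first, last)", call. = FALSE)
  }
  if (length(obs_years) &&
      (min(obs_years) < years[1] || max(obs_years) > years[2])) {
    stop("`years` range does not cover every observation year",
         call. = FALSE)
  }

  structure(
    list(colonies = colonies, direct = direct, satellite = satellite,
         years = seq.int(years[1], years[2])),
    class = "survey_dataset")
}

.check_columns <- function(df, what, cols) {
  if (!is.data.frame(df)) stop(sprintf("%s: not a data.frame", what),
                               call. = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

#' Read a survey dataset from its three CSV files
#'
#' Schemas (comma-separated, UTF-8, header row required):
#' \describe{
#'   \item{counts.csv}{`colony_id,year,doy,count,platform`}
#'   \item{satellite.csv}{`colony_id,year,doy,value,quality,catalog_id`}
#'   \item{regions.csv}{`colony_id,name,fast_ice_region,pack_ice_region`}
#' }
#' Dates are supplied as day-of-year integers. Rows referencing a colony
#' absent from the region map fail validation rather than being dropped.
#'
#' @param counts_path,satellite_path,regions_path Paths to the CSV files.
#' @param years Optional inclusive year range passed to [survey_dataset()].
#' @return A validated `survey_dataset`.
#' @export
read_survey_dataset <- function(counts_path, satellite_path, regions_path,
                                years = NULL) {
  for (p in c(counts_path, satellite_path, regions_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p),
                              call. = FALSE)
  }
  survey_dataset(
    colonies  = read.csv(regions_path, colClasses = "character"),
    direct    = read.csv(counts_path),
    satellite = read.csv(satellite_path,
                         colClasses = c(catalog_id = "character")),
    years = years)
}

#' Write a survey dataset to a directory of CSV files
#'
#' Inverse of [read_survey_dataset()]: emits `counts.csv`, `satellite.csv`
#' and `regions.csv` under `dir`.
#'
#' @param data A `survey_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_survey_dataset <- function(data, dir) {
  stopifnot(inherits(data, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("counts.csv", "satellite.csv", "regions.csv"))
  write.csv(data$direct, paths[1], row.names = FALSE)
  write.csv(data$satellite, paths[2], row.names = FALSE)
  write.csv(data$colonies, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a regional ice-trend table
#'
#' Schema: `region,ice_type,trend_value` with `ice_type` in
#' `{fast, pack}`. Used by [ice_correlation()].
#'
#' @param path Path to `ice_trends.csv`.
#' @return data.frame with the three columns.
#' @export
read_ice_trends <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- .check_columns(read.csv(path), "ice_trends",
                      c("region", "ice_type", "trend_value"))
  if (any(!d$ice_type %in% c("fast", "pack"))) {
    stop("ice_trends: ice_type must be 'fast' or 'pack'", call. = FALSE)
  }
  d
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf(
    "survey_dataset: %d colonies, years %d-%d\n  %d direct count(s) [%s]\n  %d satellite observation(s)\n",
    nrow(x$colonies), x$years[1], x$years[length(x$years)],
    nrow(x$direct),
    paste(sprintf("%s: %d", PLATFORMS,
                  tabulate(factor(x$direct$platform, PLATFORMS),
                           length(PLATFORMS))), collapse = ", "),
    nrow(x$satellite)))
  invisible(x)
}
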