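#' Breeding window
#'
#' Months are coded 1 = January ... 12 = December. A window may wrap the year
#' boundary: `start > end` means the season runs through December into the
#' next calendar months (e.g. `(11, 2)` covers Nov-Feb).
#'
#' @param start,end months in 1..12.
#' @return list of class `breeding_window`.
#' @export
breeding_window <- function(start, end) {
  if (length(start) != 1 || length(end) != 1 ||
      !start %in% 1:12 || !end %in% 1:12)
    stop("window months must be single integers in 1..12")
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "breeding_window")
}

#' Months covered by a breeding window
#'
#' Cyclic inclusive sequence from start to end; length in 1..12.
#'
#' @param w a [breeding_window()] (or anything coercible via
#'   `breeding_window(w[[1]], w[[2]])`).
#' @return integer vector of months.
#' @export
window_months <- function(w) {
  if (!inherits(w, "breeding_window")) w <- breeding_window(w[[1]], w[[2]])
  if (w$start <= w$end) w$start:w$end else c(w$start:12, 1:w$end)
}

#' Resolve a breeding window whose end month is unrecorded
#'
#' Species with a known season start but unknown end are closed at December.
#'
#' @param start start month 1..12.
#' @param end end month, or `NA`/`NULL` when unknown.
#' @return a [breeding_window()].
#' @export
resolve_open_window <- function(start, end = NA) {
  if (is.null(end) || is.na(end)) end <- 12L
  breeding_window(start, end)
}

#' Range-averaged monthly climate series
#'
#' Averages (unweighted) the climate values over a species' range cells,
#' returning a (year x 12) matrix.
#'
#' @param grid a `climate_grid`.
#' @param mask two-column (row, col) matrix of grid cells.
#' @param variable `"temperature"` or `"precipitation"`.
#' @return numeric matrix, years by 12 months, class `monthly_series`.
#' @export
range_series <- function(grid, mask, variable = c("temperature",
                                                  "precipitation")) {
  variable <- match.arg(variable)
  arr <- grid[[variable]]
  mask <- matrix(as.integer(as.matrix(mask)), ncol = 2)
  if (nrow(mask) == 0) stop("empty range mask: range does not meet the grid")
  d <- dim(arr)
  if (any(mask[, 1] < 1) || any(mask[, 1] > d[3]) ||
      any(mask[, 2] < 1) || any(mask[, 2] > d[4]))
    stop("range mask cells fall outside the climate grid")
  ny <- d[1]
  acc <- matrix(0, ny, 12)
  for (i in seq_len(nrow(mask)))
    acc <- acc + arr[, , mask[i, 1], mask[i, 2]]
  out <- acc / nrow(mask)
  structure(out, variable = variable, class = c("monthly_series", "matrix"))
}

.window_pool <- function(series, w) {
  series[, window_months(w), drop = FALSE]
}

#' Median ambient value over the breeding window
#'
#' Median of the pooled set of range-averaged values over all years and all
#' window months.
#'
#' @param series a (year x 12) matrix from [range_series()].
#' @param w a [breeding_window()].
#' @return scalar median.
#' @export
median_ambient <- function(series, w) {
  stats::median(as.numeric(.window_pool(series, w)))
}

#' Within-year seasonality over the breeding window
#'
#' For each year, the sample variance across the window's months within that
#' year; returns the mean over years. One-month windows have no within-year
#' spread and return 0, flagged with attribute `single_month = TRUE`.
#'
#' @inheritParams median_ambient
#' @return scalar (variance units); attribute `single_month` when length 1.
#' @export
seasonality <- function(series, w) {
  months <- window_months(w)
  if (length(months) == 1)
    return(structure(0, single_month = TRUE))
  mean(apply(series[, months, drop = FALSE], 1, stats::var))
}

#' Interannual fluctuation over the breeding window
#'
#' For each month of the window, the sample variance of that month's value
#' across years; returns the mean over the window's months.
#'
#' @inheritParams median_ambient
#' @return scalar (variance units).
#' @export
interannual_fluctuation <- function(series, w) {
  if (nrow(series) < 2)
    stop("interannual fluctuation needs at least 2 years")
  months <- window_months(w)
  mean(apply(series[, months, drop = FALSE], 2, stats::var))
}

#' All breeding-window climate statistics for one species
#'
#' Computes, for temperature and precipitation, the median ambient value,
#' seasonality and interannual fluctuation over the breeding window and over
#' the full year (window 1..12), plus the window length.
#'
#' @param grid a `climate_grid` holding both variables.
#' @param mask species range mask (row, col matrix).
#' @param w a [breeding_window()].
#' @return one-row data.frame.
#' @export
summarize_species <- function(grid, mask, w) {
  annual <- breeding_window(1, 12)
  out <- list(window_length = length(window_months(w)))
  for (v in c("temperature", "precipitation")) {
    s <- range_series(grid, mask, v)
    tag <- if (v == "temperature") "temp" else "precip"
    out[[paste0(tag, "_median_breeding")]] <- median_ambient(s, w)
    out[[paste0(tag, "_median_annual")]] <- median_ambient(s, annual)
    out[[paste0(tag, "_seasonality_breeding")]] <- as.numeric(seasonality(s, w))
    out[[paste0(tag, "_seasonality_annual")]] <- as.numeric(seasonality(s, annual))
    out[[paste0(tag, "_interannual_breeding")]] <- interannual_fluctuation(s, w)
    out[[paste0(tag, "_interannual_annual")]] <- interannual_fluctuation(s, annual)
  }
  as.data.frame(out)
}

#' Consecutive-month randomization null for window placement
#'
#' Compares an observed window's seasonality against windows of the same
#' length placed at other start months. `"enumerate"` uses all 12 cyclic
#' start months (the exact null); `"sample"` draws start months with
#' replacement. The observed quantile counts ties as below-or-equal.
#'
#' @param series a (year x 12) matrix from [range_series()].
#' @param window_length window length in months (1..12).
#' @param observed observed seasonality value; defaults to the seasonality of
#'   a window starting at `observed_start` when that is given.
#' @param observed_start optional start month of the observed window.
#' @param mode `"enumerate"` or `"sample"`.
#' @param n_draws number of draws in sample mode.
#' @param seed optional RNG seed for sample mode.
#' @return list with `null` (numeric vector), `observed`, `quantile`.
#' @export
null_window_test <- function(series, window_length, observed = NULL,
                             observed_start = NULL,
                             mode = c("enumerate", "sample"), n_draws = NULL,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (!window_length %in% 1:12) stop("window_length must be in 1..12")
  win_at <- function(s) breeding_window(s, ((s + window_length - 2) %% 12) + 1)
  if (is.null(observed)) {
    if (is.null(observed_start))
      stop("supply either observed or observed_start")
    observed <- as.numeric(seasonality(series, win_at(observed_start)))
  }
  starts <- if (mode == "enumerate") {
    1:12
  } else {
    if (is.null(n_draws)) stop("n_draws is required in sample mode")
    if (!is.null(seed)) set.seed(seed)
    sample.int(12, n_draws, replace = TRUE)
  }
  null <- vapply(starts, function(s) as.numeric(seasonality(series, win_at(s))),
                 numeric(1))
  list(null = null, observed = as.numeric(observed),
       quantile = mean(null <= observed))
}
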