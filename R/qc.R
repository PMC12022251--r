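# Quality-control screening of yield time-series. Two rules, both operating
# per (unit, product, season, production-system) series and both flagging,
# never altering, values:
#
#   outlier (code 1): a year whose yield Z-score exceeds a threshold above
#   the series mean AND is at least `neighbor_ratio` times an adjacent
#   observed value, applied only when the series ever exceeds a low-yield
#   guard (low-yielding systems have high relative variance and would
#   otherwise generate spurious flags);
#
#   low variance (code 2): runs of second differences of yield that are all
#   below a small fraction of the series median yield, catching repeated
#   values and values lying exactly on a trend line.

#' Quality-control parameters
#'
#' @param z_threshold Z-score threshold in standard-deviation multiples above
#'   the mean (default 3).
#' @param neighbor_ratio Minimum ratio of a candidate outlier to an adjacent
#'   observed yield (default 2.5, i.e. 250%).
#' @param yield_guard The outlier rule is applied only when at least one
#'   yield in the series exceeds this level, in t/ha (default 0.5).
#' @param second_diff_frac Second differences below this fraction of the
#'   median series yield count as "no variance" (default 0.015, i.e. 1.5%).
#' @param run_length Number of consecutive sub-threshold second differences
#'   that triggers the low-variance flag (default 3, spanning 5 years).
#' @param sd_type Standard-deviation convention for the Z-score:
#'   `"population"` (divide by n, the default) or `"sample"` (n - 1).
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(z_threshold = 3, neighbor_ratio = 2.5,
                      yield_guard = 0.5, second_diff_frac = 0.015,
                      run_length = 3L,
                      sd_type = c("population", "sample")) {
  stopifnot(z_threshold > 0, neighbor_ratio > 0, yield_guard > 0,
            second_diff_frac > 0, run_length >= 1)
  structure(
    list(z_threshold = z_threshold, neighbor_ratio = neighbor_ratio,
         yield_guard = yield_guard, second_diff_frac = second_diff_frac,
         run_length = as.integer(run_length),
         sd_type = match.arg(sd_type)),
    class = "qc_params"
  )
}

empty_flag_result <- function(series) {
  tibble::tibble(
    year = series$years, yield = series$yield,
    flag = ifelse(is.na(series$yield), NA_integer_, 0L),
    z_score = NA_real_, ratio_prev = NA_real_, ratio_next = NA_real_,
    second_diff = NA_real_
  )
}

#' Flag high-yield outliers in one series
#'
#' A year is flagged (code 1) iff all three conditions hold: its yield
#' Z-score exceeds `z_threshold` (mean and sd over the observed yields of the
#' series); the yield is at least `neighbor_ratio` times the nearest observed
#' preceding OR following yield (endpoints use their single neighbour); and
#' the series maximum yield exceeds `yield_guard`. A constant series (sd = 0)
#' or a series with fewer than two observed yields produces no flags.
#'
#' @param series A [stat_series].
#' @param params A [qc_params] object.
#' @return A tibble with columns `year`, `yield`, `flag` (0/1, NA where
#'   yield unobserved) and diagnostics `z_score`, `ratio_prev`, `ratio_next`.
#' @export
flag_outliers <- function(series, params = qc_params()) {
  out <- empty_flag_result(series)
  y <- series$yield
  obs <- which(!is.na(y))
  if (length(obs) < 2) return(out)
  yo <- y[obs]
  mu <- mean(yo)
  sdv <- if (params$sd_type == "population") {
    sqrt(mean((yo - mu)^2))
  } else {
    stats::sd(yo)
  }
  if (!is.finite(sdv) || sdv == 0) return(out)
  z <- (y - mu) / sdv
  out$z_score[obs] <- z[obs]
  guard_ok <- max(yo) > params$yield_guard
  for (k in seq_along(obs)) {
    i <- obs[k]
    prev <- if (k > 1) y[obs[k - 1]] else NA_real_
    nxt <- if (k < length(obs)) y[obs[k + 1]] else NA_real_
    out$ratio_prev[i] <- if (!is.na(prev) && prev > 0) y[i] / prev else NA_real_
    out$ratio_next[i] <- if (!is.na(nxt) && nxt > 0) y[i] / nxt else NA_real_
    neighbor_hit <-
      (!is.na(prev) && y[i] >= params$neighbor_ratio * prev) ||
      (!is.na(nxt) && y[i] >= params$neighbor_ratio * nxt)
    if (guard_ok && z[i] > params$z_threshold && neighbor_hit) {
      out$flag[i] <- 1L
    }
  }
  out
}

#' Flag low-variance runs in one series
#'
#' Computes the second difference d(i) = y(i+1) - 2 y(i) + y(i-1) along each
#' maximal run of consecutively observed years. Wherever `run_length`
#' consecutive |d| fall below `second_diff_frac` times the median observed
#' yield of the series, all years spanned by the window (5 years for the
#' default run length of 3) are flagged code 2; overlapping windows merge.
#' Catches repeated values and values lying exactly on a linear trend (whose
#' second difference is zero).
#'
#' @inheritParams flag_outliers
#' @return A tibble like [flag_outliers()] with `flag` 0/2 and the
#'   `second_diff` diagnostic.
#' @export
flag_low_variance <- function(series, params = qc_params()) {
  out <- empty_flag_result(series)
  y <- series$yield
  obs <- !is.na(y)
  if (sum(obs) < params$run_length + 2L) return(out)
  med <- stats::median(y[obs])
  thresh <- params$second_diff_frac * med
  # maximal runs of consecutive calendar years with observed yield
  idx <- which(obs)
  consecutive <- c(TRUE, diff(series$years[idx]) == 1L)
  run_id <- cumsum(!consecutive)
  for (rid in unique(run_id)) {
    ii <- idx[run_id == rid]
    L <- length(ii)
    if (L < params$run_length + 2L) next
    yy <- y[ii]
    d <- yy[3:L] - 2 * yy[2:(L - 1)] + yy[1:(L - 2)]   # d[k] at position k+1
    out$second_diff[ii[2:(L - 1)]] <- d
    small <- abs(d) < thresh
    run <- rle(small)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (k in seq_along(run$values)) {
      if (run$values[k] && run$lengths[k] >= params$run_length) {
        # d[starts[k]..ends[k]] sit at series positions ii[starts[k]+1 .. ends[k]+1];
        # the window spans one year either side of the flagged differences
        span <- ii[starts[k]]:ii[ends[k] + 2L]
        out$flag[span] <- 2L
      }
    }
  }
  out
}

#' Combined per-series QC flags
#'
#' Runs both rules and merges them into a single flag column; where a year
#' satisfies both, the outlier code (1) takes precedence over low variance
#' (2), since the table schema carries a single integer code.
#'
#' @inheritParams flag_outliers
#' @return A tibble with `year`, `yield`, `flag` (0/1/2) and all
#'   diagnostics.
#' @export
qc_flag_series <- function(series, params = qc_params()) {
  o <- flag_outliers(series, params)
  l <- flag_low_variance(series, params)
  o$second_diff <- l$second_diff
  merged <- dplyr::case_when(
    is.na(o$flag) ~ NA_integer_,
    o$flag == 1L ~ 1L,
    l$flag == 2L ~ 2L,
    TRUE ~ 0L
  )
  o$flag <- merged
  o
}

#' Apply quality control to a crop-record table
#'
#' Groups records by (fnid, product, season_name, crop_production_system),
#' builds each yield series along harvest years, runs both screening rules,
#' and rewrites the `qc_flag` column. Statistic values are never modified,
#' and flags are recomputed from scratch (idempotent: pre-existing flags are
#' overwritten, not OR-ed). Records with no observed yield get flag 0.
#'
#' @param records Crop-record tibble.
#' @param params A [qc_params] object.
#' @return The records with `qc_flag` rewritten; per-year diagnostics are
#'   attached as attribute `"qc_diagnostics"`.
#' @export
apply_qc <- function(records, params = qc_params()) {
  keys <- c("fnid", "product", "season_name", "crop_production_system")
  diag_list <- list()
  grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(keys)))
  flag_tbl <- dplyr::bind_rows(dplyr::group_map(grouped, function(g, k) {
    yrs <- sort(unique(g$harvest_year))
    yield <- vapply(yrs, function(yy) {
      v <- g$yield[g$harvest_year == yy]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    s <- stat_series(years = yrs, yield = yield, key = as.list(k))
    res <- qc_flag_series(s, params)
    dplyr::bind_cols(k[rep(1, nrow(res)), , drop = FALSE], res)
  }))
  diag <- flag_tbl
  flag_join <- dplyr::select(flag_tbl, dplyr::all_of(keys),
                             harvest_year = "year", new_flag = "flag")
  out <- dplyr::left_join(records, flag_join,
                          by = c(keys, "harvest_year"))
  out$qc_flag <- ifelse(is.na(out$new_flag), 0L, out$new_flag)
  out$new_flag <- NULL
  attr(out, "qc_diagnostics") <- diag
  out
}
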