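# Standardization: (i) re-aggregate reported sub-crops (e.g. "pearl millet",
# "finger millet") into continuous canonical categories; (ii) aggregate
# fine-level statistics to coarser administrative units, but only in years
# where reporting subunits account for at least half of the expected
# production of the coarse unit, expectation taken from a Gaussian-smoothed
# production climatology. Yield is recomputed after every aggregation.
# Season heterogeneity is always preserved: seasons are never merged here.

#' Sub-crop to canonical product mapping
#'
#' @param reported Character vector of reported product names, or a
#'   two-column data frame (reported, canonical).
#' @param canonical Character vector of canonical names (with `reported`).
#' @return A named character vector: names are reported products, values the
#'   canonical product each maps to.
#' @export
crop_mapping <- function(reported, canonical = NULL) {
  if (is.data.frame(reported)) {
    stopifnot(ncol(reported) >= 2)
    canonical <- as.character(reported[[2]])
    reported <- as.character(reported[[1]])
  }
  stopifnot(length(reported) == length(canonical),
            !anyNA(reported), !anyNA(canonical), all(nzchar(canonical)))
  if (anyDuplicated(reported)) stop("duplicate reported product in mapping")
  stats::setNames(canonical, reported)
}

#' Re-aggregate sub-crops into canonical products
#'
#' Within each (fnid, season, production system, canonical product, harvest
#' year), production and area are summed (missing values contribute nothing;
#' all-missing stays missing) and yield is recomputed as production / area
#' where area > 0. Statistics must share units (ha, mt) across sub-crops.
#'
#' @param records Crop-record tibble.
#' @param mapping A [crop_mapping()]; products absent from the mapping map to
#'   themselves unless `strict`.
#' @param strict Error when a reported product is missing from the mapping.
#' @return Records at canonical product resolution. `qc_flag` is reset to 0:
#'   flags apply to the series that was screened, so QC should be re-run
#'   after aggregation.
#' @export
aggregate_subcrops <- function(records, mapping, strict = FALSE) {
  present <- unique(records$product)
  unmapped <- setdiff(present, names(mapping))
  if (strict && length(unmapped) > 0) {
    stop("products missing from crop mapping: ",
         paste(unmapped, collapse = ", "))
  }
  full_map <- c(mapping, stats::setNames(unmapped, unmapped))
  records$product <- unname(full_map[records$product])
  keys <- c("fnid", "country", "country_code", "admin_1", "admin_2",
            "product", "season_name", "crop_production_system",
            "harvest_year")
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  out <- records %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::summarise(
      planting_year = .data$planting_year[1],
      planting_month = .data$planting_month[1],
      harvest_month = .data$harvest_month[1],
      area = sum_or_na(.data$area),
      production = sum_or_na(.data$production),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      yield = dplyr::if_else(!is.na(.data$area) & .data$area > 0 &
                               !is.na(.data$production),
                             .data$production / .data$area, NA_real_),
      qc_flag = 0L
    )
  dplyr::select(out, dplyr::all_of(crop_table_columns()))
}

#' Gaussian smoothing parameters
#'
#' @param kernel_sd Kernel standard deviation in years (default 3).
#' @param truncation Kernel support half-width in multiples of `kernel_sd`
#'   (default 4).
#' @return A list of class `smoothing_params`.
#' @export
smoothing_params <- function(kernel_sd = 3, truncation = 4) {
  stopifnot(kernel_sd > 0, truncation > 0)
  structure(list(kernel_sd = kernel_sd, truncation = truncation),
            class = "smoothing_params")
}

#' Smoothed production climatology of one series
#'
#' Normalised Gaussian convolution of the observed production values: the
#' estimate at year t is sum(w * prod) / sum(w) over observed years, with
#' Gaussian weights of standard deviation `kernel_sd` truncated at
#' `truncation` standard deviations. Because the weights renormalise over
#' whatever is observed, the estimate is defined at every year of the series
#' span, including unobserved years, and preserves constants exactly.
#'
#' @param series A [stat_series] with at least one observed production value.
#' @param params A [smoothing_params] object.
#' @param years Years at which to evaluate (default: the full series span).
#' @return A tibble with columns `year` and `expected_production`.
#' @export
smoothed_production <- function(series, params = smoothing_params(),
                                years = NULL) {
  obs <- which(!is.na(series$production))
  if (length(obs) == 0) stop("series has no observed production values")
  if (is.null(years)) {
    years <- seq(min(series$years), max(series$years))
  }
  obs_years <- series$years[obs]
  obs_prod <- series$production[obs]
  est <- vapply(years, function(t) {
    d <- abs(t - obs_years)
    w <- stats::dnorm(d / params$kernel_sd)
    w[d > params$truncation * params$kernel_sd] <- 0
    if (sum(w) == 0) {
      # beyond kernel support of every observation: fall back to the
      # nearest observation (weights renormalise in the limit)
      obs_prod[which.min(d)]
    } else {
      sum(w * obs_prod) / sum(w)
    }
  }, numeric(1))
  tibble::tibble(year = as.integer(years), expected_production = est)
}

#' Coverage-gate parameters
#'
#' @param min_coverage Minimum fraction of expected production that reporting
#'   subunits must account for before an aggregate is emitted (default 0.5).
#' @return A list of class `coverage_params`.
#' @export
coverage_params <- function(min_coverage = 0.5) {
  stopifnot(min_coverage > 0, min_coverage <= 1)
  structure(list(min_coverage = min_coverage), class = "coverage_params")
}

#' Aggregate fine-level records to coarser administrative units
#'
#' For each coarse unit, product, season, production system and year, the
#' coverage is the summed smoothed-production climatology of the subunits
#' reporting that year divided by that of all member subunits (unobserved
#' member-years still contribute their climatological expectation to the
#' denominator). When coverage meets `min_coverage`, the aggregate is the
#' plain sum of the reporting members' production and area with yield
#' recomputed; otherwise the observation is marked missing. The aggregate is
#' never inflated by 1/coverage unless `inflate = TRUE` is requested
#' explicitly.
#'
#' @param records Fine-level crop records.
#' @param unit_mapping Named character vector (fine fnid -> coarse fnid) or a
#'   two-column data frame. Every fine fnid present must map to exactly one
#'   coarse fnid.
#' @param coverage A [coverage_params] object.
#' @param smoothing A [smoothing_params] object.
#' @param coarse_meta Optional tibble with columns `fnid`, `country`,
#'   `country_code`, `admin_1`, `admin_2` describing the coarse units;
#'   defaults are inherited from the member records.
#' @param inflate If TRUE, reported aggregates are scaled by 1/coverage to
#'   estimate the full-unit total; default FALSE (minimal adjustment).
#' @return Coarse-level records. A coverage diagnostic table is attached as
#'   attribute `"coverage"`.
#' @export
aggregate_admin <- function(records, unit_mapping,
                            coverage = coverage_params(),
                            smoothing = smoothing_params(),
                            coarse_meta = NULL, inflate = FALSE) {
  if (is.data.frame(unit_mapping)) {
    unit_mapping <- stats::setNames(as.character(unit_mapping[[2]]),
                                    as.character(unit_mapping[[1]]))
  }
  orphan <- setdiff(unique(records$fnid), names(unit_mapping))
  if (length(orphan) > 0) {
    stop("fine unit(s) with no coarse parent in unit_mapping: ",
         paste(orphan, collapse = ", "))
  }
  rec <- dplyr::mutate(records, .coarse = unname(unit_mapping[.data$fnid]))
  keys <- c(".coarse", "product", "season_name", "crop_production_system")
  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  cov_rows <- list()
  out_rows <- rec %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) %>%
    dplyr::group_map(function(g, k) {
      members <- unique(g$fnid)
      yrs <- seq(min(g$harvest_year), max(g$harvest_year))
      # climatology per member over the full group span
      clim <- lapply(members, function(m) {
        gm <- g[g$fnid == m, ]
        if (all(is.na(gm$production))) return(NULL)
        s <- stat_series(sort(unique(gm$harvest_year)),
                         production = vapply(sort(unique(gm$harvest_year)),
                           function(y) {
                             v <- gm$production[gm$harvest_year == y]
                             if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
                           }, numeric(1)))
        stats::setNames(
          smoothed_production(s, smoothing, years = yrs)$expected_production,
          yrs)
      })
      names(clim) <- members
      clim <- clim[!vapply(clim, is.null, logical(1))]
      per_year <- lapply(yrs, function(y) {
        gy <- g[g$harvest_year == y, ]
        reporting <- unique(gy$fnid[!is.na(gy$production)])
        denom <- sum(vapply(names(clim), function(m) clim[[m]][[as.character(y)]],
                            numeric(1)))
        numer <- sum(vapply(intersect(reporting, names(clim)),
                            function(m) clim[[m]][[as.character(y)]],
                            numeric(1)))
        cov_frac <- if (denom > 0) numer / denom else 0
        has_any <- nrow(gy) > 0 && any(!is.na(gy$production) | !is.na(gy$area))
        if (!has_any) return(NULL)
        gated <- cov_frac < coverage$min_coverage
        prod <- if (gated) NA_real_ else sum_or_na(gy$production)
        area <- if (gated) NA_real_ else sum_or_na(gy$area)
        if (!gated && inflate && cov_frac > 0) {
          if (!is.na(prod)) prod <- prod / cov_frac
          if (!is.na(area)) area <- area / cov_frac
        }
        list(year = y, coverage = cov_frac,
             n_reporting = length(reporting), n_members = length(members),
             production = prod, area = area,
         meta = gy[1, , drop = FALSE])
      })
      per_year <- per_year[!vapply(per_year, is.null, logical(1))]
      if (length(per_year) == 0) return(NULL)
      cov_rows[[length(cov_rows) + 1L]] <<- tibble::tibble(
        fnid = k$.coarse, product = k$product, season_name = k$season_name,
        crop_production_system = k$crop_production_system,
        year = vapply(per_year, `[[`, integer(1), "year"),
        coverage = vapply(per_year, `[[`, numeric(1), "coverage"),
        n_reporting = vapply(per_year, `[[`, integer(1), "n_reporting"),
        n_members = vapply(per_year, `[[`, integer(1), "n_members")
      )
      dplyr::bind_rows(lapply(per_year, function(p) {
        m <- p$meta
        tibble::tibble(
          fnid = k$.coarse,
          country = m$country, country_code = m$country_code,
          admin_1 = k$.coarse, admin_2 = NA_character_,
          product = k$product, season_name = k$season_name,
          planting_year = m$planting_year, planting_month = m$planting_month,
          harvest_year = as.integer(p$year), harvest_month = m$harvest_month,
          crop_production_system = k$crop_production_system,
          qc_flag = 0L,
          area = p$area, production = p$production,
          yield = if (!is.na(p$area) && p$area > 0 && !is.na(p$production)) {
            p$production / p$area
          } else NA_real_
        )
      }))
    }) %>%
    dplyr::bind_rows()
  if (!is.null(coarse_meta)) {
    out_rows <- out_rows %>%
      dplyr::select(-dplyr::any_of(c("country", "country_code",
                                     "admin_1", "admin_2"))) %>%
      dplyr::left_join(coarse_meta, by = "fnid") %>%
      dplyr::select(dplyr::all_of(crop_table_columns()))
  }
  out <- dplyr::select(out_rows, dplyr::all_of(crop_table_columns()))
  attr(out, "coverage") <- dplyr::bind_rows(cov_rows)
  out
}
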