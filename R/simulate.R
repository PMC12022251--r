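# Synthetic scenario generator: complete, ground-truthed inputs for every
# pipeline stage - gridded administrative vintages with split/merge/
# reorganization events, crop statistics with injected outliers and
# repeated-value runs, cropland rasters, and a national reference series.
# Geometries live on integer coordinate grids so intersection areas are
# exact; all randomness flows from one seed, so a fixed seed gives
# byte-identical outputs (Mersenne-Twister, inversion normals).
#
# Truth labelling contract: the generator guarantees that its clean
# background contains no year satisfying the screening rules, by rejection
# sampling against an inline re-derivation of the rules (kept separate from
# the qc module so the fixture does not depend on the code it tests), and
# that every injected anomaly does satisfy them. Truth tables can therefore
# be compared to detector output at face value.

#' Scenario configuration
#'
#' Defines the synthetic study conditions. Defaults give the standard
#' recovery scenario: 2 level-1 provinces of 5 level-2 districts each, 5
#' crops over 20 years (50 series), lognormal yield noise at 15% CV, 5
#' injected spike outliers (multiplier 6) and 5 injected constant runs of 5
#' years, full reporting, and no boundary event unless requested.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_admin1 Number of level-1 units.
#' @param n_admin2_per1 Level-2 units per level-1 unit.
#' @param years Calendar years of the record (integer vector).
#' @param crops Tibble with columns `product`, `mean_yield` (t/ha), `trend`
#'   (t/ha per year), `cv` (coefficient of variation of the lognormal yield
#'   noise).
#' @param base_area_range Range (ha) from which each unit-crop's base planted
#'   area is drawn (uniform, fixed over time).
#' @param area_cv CV of the small year-to-year area noise.
#' @param n_outliers Number of spike outliers injected (one per series, in
#'   distinct series).
#' @param outlier_multiplier Factor applied to the spiked year's yield.
#' @param n_runs Number of repeated-value runs injected (distinct series,
#'   disjoint from spiked series).
#' @param run_years Length of each injected constant run (default 5, the
#'   minimal span of three consecutive second differences).
#' @param boundary_event `"none"`, `"split"`, `"merge"` or `"reorganize"`.
#' @param event_year First year reported on the new vintage.
#' @param split_shares Ground-truth production/area shares of the two units
#'   created by a split.
#' @param reporting_prob Probability that a unit-year is observed (1 = full
#'   reporting).
#' @param cropland Constant cropland area per 1x1 cell of the raster (ha), or
#'   `"random"` for a seeded uniform(0.2, 1) surface.
#' @param reference_noise_cv CV of the multiplicative noise between true
#'   national totals and the generated reference series.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_admin1 = 2L,
                            n_admin2_per1 = 5L,
                            years = 2000:2019,
                            crops = default_crops(),
                            base_area_range = c(500, 2000),
                            area_cv = 0.05,
                            n_outliers = 5L,
                            outlier_multiplier = 6,
                            n_runs = 5L,
                            run_years = 5L,
                            boundary_event = c("none", "split", "merge",
                                               "reorganize"),
                            event_year = 2010L,
                            split_shares = c(0.4, 0.6),
                            reporting_prob = 1,
                            cropland = 1,
                            reference_noise_cv = 0.02) {
  boundary_event <- match.arg(boundary_event)
  stopifnot(seed == as.integer(seed), length(years) >= 5,
            reporting_prob > 0, reporting_prob <= 1,
            abs(sum(split_shares) - 1) < 1e-12,
            run_years >= 5, outlier_multiplier > 1)
  structure(
    list(seed = as.integer(seed), n_admin1 = as.integer(n_admin1),
         n_admin2_per1 = as.integer(n_admin2_per1),
         years = as.integer(years), crops = crops,
         base_area_range = base_area_range, area_cv = area_cv,
         n_outliers = as.integer(n_outliers),
         outlier_multiplier = outlier_multiplier,
         n_runs = as.integer(n_runs), run_years = as.integer(run_years),
         boundary_event = boundary_event, event_year = as.integer(event_year),
         split_shares = split_shares, reporting_prob = reporting_prob,
         cropland = cropland, reference_noise_cv = reference_noise_cv),
    class = "scenario_config"
  )
}

#' Default synthetic crop set
#'
#' Five staples with typical Sub-Saharan smallholder yield levels and mild
#' positive trends.
#'
#' @return A tibble usable as the `crops` field of [scenario_config()].
#' @export
default_crops <- function() {
  tibble::tibble(
    product = c("maize", "sorghum", "millet", "rice", "cassava"),
    mean_yield = c(1.8, 1.0, 0.8, 2.2, 6.0),
    trend = c(0.02, 0.01, 0.01, 0.03, 0.05),
    cv = c(0.15, 0.15, 0.15, 0.15, 0.15)
  )
}

scenario_seed <- function(config, offset) {
  (config$seed * 1009L + as.integer(offset)) %% 2147483647L
}

unit_size <- 10  # integer grid edge of one level-2 unit

admin2_layout <- function(config) {
  n1 <- config$n_admin1; n2 <- config$n_admin2_per1
  grid <- expand.grid(col = seq_len(n2), row = seq_len(n1))
  tibble::tibble(
    fnid = sprintf("XX2U%02d", seq_len(n1 * n2)),
    admin1 = sprintf("XX1P%d", grid$row),
    xmin = (grid$col - 1) * unit_size,
    ymin = (grid$row - 1) * unit_size
  )
}

#' Generate two boundary vintages and the true change event
#'
#' Level-2 units are integer-grid squares arranged in rows (one row per
#' level-1 unit). The configured boundary event is realised geometrically on
#' the last unit(s) of the grid: a split replaces the last square by two
#' tiling halves; a merge replaces the last two squares by their union; a
#' reorganization replaces the last three squares of a row by four tiling
#' strips, each interior strip overlapping two old units.
#'
#' @param config A [scenario_config()].
#' @return A list with `old` and `new` ([admin_units] vintages) and `truth`
#'   (a list describing the constructed event: `case`, `old_fnids`,
#'   `new_fnids`; empty for `"none"`).
#' @export
make_admin_vintages <- function(config) {
  lay <- admin2_layout(config)
  geoms <- lapply(seq_len(nrow(lay)), function(i) {
    rect_geometry(lay$xmin[i], lay$ymin[i],
                  lay$xmin[i] + unit_size, lay$ymin[i] + unit_size)
  })
  old <- admin_units(fnid = lay$fnid, geometry = geoms, country_code = "XX",
                     level = 2L, vintage = "old")
  ev <- config$boundary_event
  truth <- list()
  if (ev == "none") {
    new <- admin_units(fnid = lay$fnid, geometry = geoms,
                       country_code = "XX", level = 2L, vintage = "new")
    return(list(old = old, new = new, truth = truth))
  }
  n <- nrow(lay)
  if (ev == "split") {
    i <- n
    keep <- setdiff(seq_len(n), i)
    r <- lay[i, ]
    halves <- list(
      rect_geometry(r$xmin, r$ymin, r$xmin + unit_size / 2,
                    r$ymin + unit_size),
      rect_geometry(r$xmin + unit_size / 2, r$ymin, r$xmin + unit_size,
                    r$ymin + unit_size)
    )
    new_ids <- paste0(r$fnid, c("A", "B"))
    new <- admin_units(
      fnid = c(lay$fnid[keep], new_ids),
      geometry = c(geoms[keep], halves),
      country_code = "XX", level = 2L, vintage = "new")
    truth <- list(case = "A", direction = "split",
                  old_fnids = r$fnid, new_fnids = new_ids)
  } else if (ev == "merge") {
    if (n < 2) stop("merge event needs at least 2 level-2 units")
    ii <- c(n - 1L, n)
    if (lay$ymin[n - 1L] != lay$ymin[n]) {
      stop("merge event needs two adjacent units in the last row")
    }
    keep <- setdiff(seq_len(n), ii)
    merged <- rect_geometry(lay$xmin[n - 1L], lay$ymin[n],
                            lay$xmin[n] + unit_size, lay$ymin[n] + unit_size)
    new_id <- "XX2M01"
    new <- admin_units(
      fnid = c(lay$fnid[keep], new_id),
      geometry = c(geoms[keep], list(merged)),
      country_code = "XX", level = 2L, vintage = "new")
    truth <- list(case = "A", direction = "merge",
                  old_fnids = lay$fnid[ii], new_fnids = new_id)
  } else {  # reorganize
    if (config$n_admin2_per1 < 3) {
      stop("reorganize event needs at least 3 units in one row")
    }
    ii <- (n - 2L):n
    if (length(unique(lay$ymin[ii])) != 1) {
      stop("reorganize event needs three adjacent units in the last row")
    }
    keep <- setdiff(seq_len(n), ii)
    x0 <- lay$xmin[ii[1]]; y0 <- lay$ymin[ii[1]]
    w <- 3 * unit_size / 4
    strips <- lapply(0:3, function(k) {
      rect_geometry(x0 + k * w, y0, x0 + (k + 1) * w, y0 + unit_size)
    })
    new_ids <- sprintf("XX2R%02d", 1:4)
    new <- admin_units(
      fnid = c(lay$fnid[keep], new_ids),
      geometry = c(geoms[keep], strips),
      country_code = "XX", level = 2L, vintage = "new")
    truth <- list(case = "B", direction = "reorganize",
                  old_fnids = lay$fnid[ii], new_fnids = new_ids)
  }
  list(old = old, new = new, truth = truth)
}

#' Generate the cropland raster
#'
#' A 1x1-cell grid covering the administrative extent, with constant
#' cropland area per cell (default 1 ha) or a seeded uniform surface.
#'
#' @param config A [scenario_config()].
#' @return A [cropland_raster].
#' @export
make_cropland_raster <- function(config) {
  nc <- config$n_admin2_per1 * unit_size
  nr <- config$n_admin1 * unit_size
  if (identical(config$cropland, "random")) {
    set.seed(scenario_seed(config, 7L))
    vals <- matrix(stats::runif(nr * nc, 0.2, 1), nr, nc)
  } else {
    stopifnot(is.numeric(config$cropland), config$cropland >= 0)
    vals <- matrix(config$cropland, nr, nc)
  }
  cropland_raster(vals, xmin = 0, ymin = 0, cellsize = 1)
}

# ---- inline anomaly checks (independent of the qc module) ------------------

# Years (indices) satisfying the spike rule on a complete yield vector:
# population z-score > 3, value at least 2.5x the preceding or following
# value, and series max above 0.5 t/ha.
.inline_spike_idx <- function(y) {
  mu <- mean(y)
  sdv <- sqrt(mean((y - mu)^2))
  if (sdv == 0 || max(y) <= 0.5) return(integer(0))
  n <- length(y)
  hits <- integer(0)
  for (i in seq_len(n)) {
    z <- (y[i] - mu) / sdv
    prev_ok <- i > 1 && y[i] >= 2.5 * y[i - 1]
    next_ok <- i < n && y[i] >= 2.5 * y[i + 1]
    if (z > 3 && (prev_ok || next_ok)) hits <- c(hits, i)
  }
  hits
}

# Years (indices) spanned by any window of 3 consecutive second differences
# all below 1.5% of the median yield.
.inline_lowvar_idx <- function(y) {
  n <- length(y)
  if (n < 5) return(integer(0))
  d <- y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]
  small <- abs(d) < 0.015 * stats::median(y)
  hits <- logical(n)
  for (k in seq_len(length(d) - 2)) {
    if (all(small[k:(k + 2)])) hits[k:(k + 4)] <- TRUE
  }
  which(hits)
}

# ---- crop statistics --------------------------------------------------------

simulate_series_yield <- function(config, crop) {
  t_idx <- seq_along(config$years) - 1
  sigma <- sqrt(log(1 + crop$cv^2))
  noise <- exp(stats::rnorm(length(t_idx), -sigma^2 / 2, sigma))
  pmax((crop$mean_yield + crop$trend * t_idx) * noise, 0.01)
}

#' Generate ground-truthed crop statistics
#'
#' One latent series per level-2 unit and crop over the configured years:
#' yield = (mean + trend * t) * lognormal noise, planted area = unit-crop
#' base area * small lognormal noise, production = yield * area exactly.
#' Injected spikes multiply one interior year's yield by the configured
#' multiplier; injected runs overwrite `run_years` consecutive yields with a
#' constant. The background is guaranteed anomaly-free and every injection is
#' guaranteed detectable (rejection sampling on the inline rules), so the
#' attached truth table is exact. When a boundary event is configured, years
#' before `event_year` are reported on the old vintage and later years on the
#' new vintage, with post-change statistics derived from the latent old-unit
#' series (proportional shares for a split, sums for a merge,
#' cropland-overlap combinations for a reorganization).
#'
#' @param config A [scenario_config()].
#' @param vintages Output of [make_admin_vintages()] (generated from `config`
#'   when omitted).
#' @return A list: `records` (all records, both vintages), `records_old` /
#'   `records_new` (the two reporting periods), `truth_flags` (tibble fnid,
#'   product, season_name, crop_production_system, harvest_year, true_flag),
#'   and `truth_shares` (split ground truth, when applicable).
#' @export
make_crop_series <- function(config, vintages = NULL) {
  if (is.null(vintages)) vintages <- make_admin_vintages(config)
  lay <- admin2_layout(config)
  crops <- config$crops
  years <- config$years
  ny <- length(years)
  set.seed(scenario_seed(config, 1L))

  combos <- expand.grid(u = seq_len(nrow(lay)), c = seq_len(nrow(crops)))
  n_series <- nrow(combos)
  if (config$n_outliers + config$n_runs > n_series) {
    stop("more injections than available series")
  }
  pick <- sample.int(n_series, config$n_outliers + config$n_runs)
  spike_series <- pick[seq_len(config$n_outliers)]
  run_series <- setdiff(pick, spike_series)

  base_area <- matrix(
    stats::runif(n_series, config$base_area_range[1],
                 config$base_area_range[2]),
    nrow = n_series)
  sigma_a <- sqrt(log(1 + config$area_cv^2))

  rec_rows <- vector("list", n_series)
  truth_rows <- vector("list", n_series)
  for (s in seq_len(n_series)) {
    u <- combos$u[s]; cidx <- combos$c[s]
    crop <- as.list(crops[cidx, ])
    spike_at <- if (s %in% spike_series) sample(3:(ny - 2), 1) else NA_integer_
    run_at <- if (s %in% run_series) {
      sample(2:(ny - config$run_years), 1)  # interior start
    } else NA_integer_
    area <- base_area[s] *
      exp(stats::rnorm(ny, -sigma_a^2 / 2, sigma_a))
    ok <- FALSE
    for (try in 1:200) {
      y <- simulate_series_yield(config, crop)
      if (!is.na(spike_at)) y[spike_at] <- y[spike_at] * config$outlier_multiplier
      if (!is.na(run_at)) {
        y[run_at:(run_at + config$run_years - 1)] <- y[run_at]
      }
      want_spike <- if (is.na(spike_at)) integer(0) else spike_at
      want_run <- if (is.na(run_at)) integer(0) else
        run_at:(run_at + config$run_years - 1)
      if (identical(.inline_spike_idx(y), want_spike) &&
          identical(.inline_lowvar_idx(y), as.integer(want_run))) {
        ok <- TRUE
        break
      }
      if (crop$cv < 1e-8) {
        # no randomness to redraw: a noiseless series is deterministic and
        # the clean-background guarantee is vacuous (a pure trend is, by
        # definition, low-variance); accept the draw as generated
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not realise a clean background for series ", s,
           " after 200 draws; lower the noise CV or injection density")
    }
    production <- y * area
    flag <- rep(0L, ny)
    if (!is.na(spike_at)) flag[spike_at] <- 1L
    if (!is.na(run_at)) flag[run_at:(run_at + config$run_years - 1)] <- 2L
    rec_rows[[s]] <- tibble::tibble(
      fnid = lay$fnid[u], admin1 = lay$admin1[u],
      product = crop$product, harvest_year = years,
      area = area, production = production, yield = y)
    truth_rows[[s]] <- tibble::tibble(
      fnid = lay$fnid[u], product = crop$product,
      season_name = "Main", crop_production_system = "none",
      harvest_year = years, true_flag = flag)
  }
  latent <- dplyr::bind_rows(rec_rows)
  truth <- dplyr::bind_rows(truth_rows)

  # reporting coverage schedule
  if (config$reporting_prob < 1) {
    keyed <- dplyr::distinct(latent, .data$fnid, .data$harvest_year)
    keyed$observed <- stats::runif(nrow(keyed)) < config$reporting_prob
    latent <- dplyr::inner_join(latent, keyed[keyed$observed, 1:2],
                                by = c("fnid", "harvest_year"))
    truth <- dplyr::semi_join(truth, latent,
                              by = c("fnid", "product", "harvest_year"))
  }

  finalize <- function(df) {
    crop_records(
      fnid = df$fnid, country = "Testland", country_code = "XX",
      admin_1 = df$admin1, admin_2 = df$fnid,
      product = df$product, season_name = "Main",
      planting_year = df$harvest_year, planting_month = 4L,
      harvest_year = df$harvest_year, harvest_month = 10L,
      crop_production_system = "none", qc_flag = 0L,
      area = df$area, production = df$production, yield = df$yield,
      validate = FALSE)
  }

  ev <- config$boundary_event
  truth_shares <- NULL
  if (ev == "none") {
    records <- finalize(latent)
    return(list(records = records, records_old = records,
                records_new = records[0, ], truth_flags = truth,
                truth_shares = NULL))
  }

  tr <- vintages$truth
  pre <- latent[latent$harvest_year < config$event_year, ]
  post <- latent[latent$harvest_year >= config$event_year, ]
  affected <- post$fnid %in% tr$old_fnids
  post_keep <- post[!affected, ]
  post_aff <- post[affected, ]
  if (ev == "split") {
    sh <- config$split_shares
    truth_shares <- tibble::tibble(new_fnid = tr$new_fnids, share = sh)
    parts <- lapply(seq_along(tr$new_fnids), function(k) {
      p <- post_aff
      p$fnid <- tr$new_fnids[k]
      p$admin1 <- post_aff$admin1
      p$area <- p$area * sh[k]
      p$production <- p$production * sh[k]
      p
    })
    post_new <- dplyr::bind_rows(parts)
  } else if (ev == "merge") {
    post_new <- post_aff %>%
      dplyr::group_by(.data$admin1, .data$product, .data$harvest_year) %>%
      dplyr::summarise(area = sum(.data$area),
                       production = sum(.data$production), .groups = "drop") %>%
      dplyr::mutate(fnid = tr$new_fnids[1],
                    yield = .data$production / .data$area) %>%
      dplyr::select("fnid", "admin1", "product", "harvest_year",
                    "area", "production", "yield")
  } else {  # reorganize: combine latent old series by exact overlap weights
    old_g <- vintages$old$geometry[match(tr$old_fnids, vintages$old$fnid)]
    new_g <- vintages$new$geometry[match(tr$new_fnids, vintages$new$fnid)]
    w <- outer(seq_along(tr$new_fnids), seq_along(tr$old_fnids),
               Vectorize(function(i, j) {
                 intersection_area(new_g[[i]], old_g[[j]]) /
                   geom_area(old_g[[j]])
               }))
    post_new <- dplyr::bind_rows(lapply(seq_along(tr$new_fnids), function(i) {
      dplyr::bind_rows(lapply(unique(post_aff$product), function(p) {
        yrs <- sort(unique(post_aff$harvest_year))
        sub <- post_aff[post_aff$product == p, ]
        stat <- function(col) {
          vapply(yrs, function(t) {
            v <- vapply(seq_along(tr$old_fnids), function(j) {
              row <- sub[sub$fnid == tr$old_fnids[j] &
                           sub$harvest_year == t, ]
              if (nrow(row) == 0) return(NA_real_)
              w[i, j] * row[[col]][1]
            }, numeric(1))
            if (anyNA(v)) NA_real_ else sum(v)
          }, numeric(1))
        }
        area <- stat("area"); prod <- stat("production")
        tibble::tibble(fnid = tr$new_fnids[i], admin1 = sub$admin1[1],
                       product = p, harvest_year = yrs, area = area,
                       production = prod, yield = prod / area)
      }))
    }))
    post_new <- post_new[!is.na(post_new$production), ]
  }
  records_old <- finalize(pre)
  records_new <- finalize(dplyr::bind_rows(post_keep, post_new))
  truth <- dplyr::semi_join(
    truth,
    dplyr::bind_rows(pre[c("fnid", "product", "harvest_year")],
                     post_keep[c("fnid", "product", "harvest_year")]),
    by = c("fnid", "product", "harvest_year"))
  list(records = dplyr::bind_rows(records_old, records_new),
       records_old = records_old, records_new = records_new,
       truth_flags = truth, truth_shares = truth_shares)
}

#' Generate a national reference series
#'
#' True national annual totals of the scenario's records, perturbed by
#' multiplicative lognormal noise of CV `reference_noise_cv`, emulating an
#' independently compiled reference (FAOSTAT-style).
#'
#' @param config A [scenario_config()].
#' @param records Record table whose national totals anchor the reference.
#' @return A reference tibble ([national_series()] layout).
#' @export
make_reference_series <- function(config, records) {
  nat <- national_annual_production(records)
  set.seed(scenario_seed(config, 3L))
  sigma <- sqrt(log(1 + config$reference_noise_cv^2))
  noise <- exp(stats::rnorm(nrow(nat), -sigma^2 / 2, sigma))
  national_series(nat$country_code, nat$product, nat$year,
                  nat$production * noise)
}

#' Generate a complete synthetic scenario
#'
#' Bundles [make_admin_vintages()], [make_cropland_raster()],
#' [make_crop_series()] and [make_reference_series()] into the full input
#' set of one study scenario.
#'
#' @param config A [scenario_config()].
#' @return A list with `config`, `vintages`, `raster`, `series` (records and
#'   truth) and `reference`.
#' @export
make_scenario <- function(config = scenario_config()) {
  vintages <- make_admin_vintages(config)
  raster <- make_cropland_raster(config)
  series <- make_crop_series(config, vintages)
  reference <- make_reference_series(config, series$records)
  list(config = config, vintages = vintages, raster = raster,
       series = series, reference = reference)
}

#' Write a scenario to disk in the pipeline's file formats
#'
#' Emits the same formats the real pipeline consumes: crop tables as CSV,
#' boundary vintages as GeoPackage, the cropland raster as an ASCII grid, the
#' reference series as CSV, and the truth tables as sidecar CSVs so tests
#' never re-derive ground truth.
#'
#' @param scenario Output of [make_scenario()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    records = file.path(dir, "crop_statistics.csv"),
    records_old = file.path(dir, "crop_statistics_old_vintage.csv"),
    records_new = file.path(dir, "crop_statistics_new_vintage.csv"),
    boundaries_old = file.path(dir, "boundaries_old.gpkg"),
    boundaries_new = file.path(dir, "boundaries_new.gpkg"),
    cropland = file.path(dir, "cropland.asc"),
    reference = file.path(dir, "reference_national.csv"),
    truth_flags = file.path(dir, "truth_flags.csv")
  )
  write_crop_table(scenario$series$records, paths["records"])
  write_crop_table(scenario$series$records_old, paths["records_old"])
  write_crop_table(scenario$series$records_new, paths["records_new"])
  write_boundaries(scenario$vintages$old, paths["boundaries_old"])
  write_boundaries(scenario$vintages$new, paths["boundaries_new"])
  write_cropland_raster(scenario$raster, paths["cropland"])
  readr::write_csv(scenario$reference, paths["reference"], na = "")
  readr::write_csv(scenario$series$truth_flags, paths["truth_flags"], na = "")
  paths
}
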