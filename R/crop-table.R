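# Tabular crop statistics: the 16-column harmonized schema. One row is one
# statistical observation of a (unit, product, season, production system,
# year): planted/harvested area (ha), quantity produced (mt), yield (mt/ha),
# plus a quality-control flag. Missing means "not collected" and is never
# conflated with zero.

#' Canonical column names of the harmonized crop table
#'
#' @return Character vector of the 16 column names in canonical order.
#' @export
crop_table_columns <- function() {
  c("fnid", "country", "country_code", "admin_1", "admin_2",
    "product", "season_name", "planting_year", "planting_month",
    "harvest_year", "harvest_month", "crop_production_system",
    "qc_flag", "area", "production", "yield")
}

crop_table_coltypes <- function() {
  readr::cols(
    fnid = readr::col_character(),
    country = readr::col_character(),
    country_code = readr::col_character(),
    admin_1 = readr::col_character(),
    admin_2 = readr::col_character(),
    product = readr::col_character(),
    season_name = readr::col_character(),
    planting_year = readr::col_integer(),
    planting_month = readr::col_integer(),
    harvest_year = readr::col_integer(),
    harvest_month = readr::col_integer(),
    crop_production_system = readr::col_character(),
    qc_flag = readr::col_integer(),
    area = readr::col_double(),
    production = readr::col_double(),
    yield = readr::col_double(),
    .default = readr::col_guess()
  )
}

#' Assemble crop records
#'
#' Builds a tibble in the harmonized 16-column schema from whatever fields
#' are supplied, filling the rest with missing values. Intended for tests and
#' programmatic construction; files go through [read_crop_table()].
#'
#' @param ... Name-value pairs for any subset of the canonical columns.
#' @param validate Check record invariants and stop on violation.
#' @return A tibble with the 16 canonical columns.
#' @export
crop_records <- function(..., validate = TRUE) {
  supplied <- tibble::tibble(...)
  unknown <- setdiff(names(supplied), crop_table_columns())
  if (length(unknown) > 0) {
    stop("unknown crop-table columns: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(supplied)
  out <- tibble::as_tibble(c(
    stats::setNames(
      lapply(crop_table_columns(), function(col) {
        if (col %in% names(supplied)) {
          supplied[[col]]
        } else if (col %in% c("planting_year", "planting_month",
                              "harvest_year", "harvest_month", "qc_flag")) {
          rep(NA_integer_, n)
        } else if (col %in% c("area", "production", "yield")) {
          rep(NA_real_, n)
        } else {
          rep(NA_character_, n)
        }
      }),
      crop_table_columns())
  ))
  if (!"qc_flag" %in% names(supplied)) out$qc_flag <- rep(0L, n)
  if (validate && n > 0) {
    viol <- validate_crop_records(out)
    if (nrow(viol) > 0) {
      stop("invalid crop records:\n",
           paste(utils::head(viol$message, 5), collapse = "\n"))
    }
  }
  out
}

#' Validate crop records against the schema invariants
#'
#' Checks each row for: `qc_flag` in {0, 1, 2}; non-negative statistics;
#' months in 1-12 and `harvest_year >= planting_year`; and internal yield
#' consistency, `yield == production / area` to relative tolerance 1e-6
#' wherever all three are present and `area > 0`.
#'
#' @param records A crop-record tibble.
#' @param yield_rtol Relative tolerance of the yield consistency check.
#' @return A tibble of violations with columns `row`, `field`, `message`
#'   (zero rows when clean).
#' @export
validate_crop_records <- function(records, yield_rtol = 1e-6) {
  v <- list()
  bad <- function(rows, field, what) {
    if (length(rows) == 0) return(NULL)
    tibble::tibble(row = rows, field = field,
                   message = paste0("row ", rows, ": ", what))
  }
  flag_bad <- which(!is.na(records$qc_flag) & !records$qc_flag %in% c(0L, 1L, 2L))
  v$flag <- bad(flag_bad, "qc_flag", "qc_flag not in {0,1,2}")
  for (col in c("area", "production", "yield")) {
    neg <- which(!is.na(records[[col]]) & records[[col]] < 0)
    v[[col]] <- bad(neg, col, paste0(col, " < 0"))
  }
  for (col in c("planting_month", "harvest_month")) {
    m <- records[[col]]
    out_of_range <- which(!is.na(m) & (m < 1 | m > 12))
    v[[paste0(col, "_r")]] <- bad(out_of_range, col, paste0(col, " not in 1-12"))
  }
  yr_bad <- which(!is.na(records$harvest_year) & !is.na(records$planting_year) &
                    records$harvest_year < records$planting_year)
  v$years <- bad(yr_bad, "harvest_year", "harvest_year < planting_year")
  with_all <- !is.na(records$area) & records$area > 0 &
    !is.na(records$production) & !is.na(records$yield)
  implied <- records$production / records$area
  inconsistent <- which(with_all &
    abs(records$yield - implied) > yield_rtol * pmax(abs(implied), 1e-12))
  v$yield_c <- bad(inconsistent, "yield",
                   "yield differs from production/area beyond tolerance")
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    tibble::tibble(row = integer(0), field = character(0),
                   message = character(0))
  } else {
    dplyr::arrange(out, .data$row)
  }
}

#' Read a harmonized crop table
#'
#' Reads a CSV in the 16-column schema (UTF-8, comma-separated, header row,
#' empty field = missing). Missing values are preserved as `NA`, never
#' coerced to zero. Extra columns are preserved; missing or renamed canonical
#' columns are a schema error naming the column.
#'
#' @param path CSV path.
#' @param strict If TRUE, any record violating the schema invariants aborts
#'   the read; if FALSE (default) violations are collected into a report
#'   attached as attribute `"violations"`.
#' @return A tibble of crop records (attribute `"violations"` in lenient
#'   mode).
#' @export
read_crop_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(crop_table_columns(), header)
  if (length(missing_cols) > 0) {
    stop("crop table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl <- readr::read_csv(path, col_types = crop_table_coltypes(),
                         na = "", show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop("non-numeric or malformed value(s): ",
         paste0("row ", probs$row, " column '", probs$col, "'",
                collapse = "; "))
  }
  tbl <- dplyr::relocate(tbl, dplyr::all_of(crop_table_columns()))
  viol <- validate_crop_records(tbl)
  if (strict && nrow(viol) > 0) {
    stop("schema invariant violations in strict mode:\n",
         paste(utils::head(viol$message, 10), collapse = "\n"))
  }
  attr(tbl, "violations") <- viol
  tbl
}

#' Write a harmonized crop table
#'
#' Writes records in canonical column order; missing values become empty
#' fields (never the string "NA"). Extra columns are dropped on canonical
#' write. Round-trips exactly through [read_crop_table()].
#'
#' @param records Crop-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_crop_table <- function(records, path) {
  missing_cols <- setdiff(crop_table_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- dplyr::select(records, dplyr::all_of(crop_table_columns()))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Census of a harmonized crop table
#'
#' Counts the dataset-level summary statistics used to describe a release:
#' total records, records carrying each statistic, and the number of distinct
#' countries and crop products.
#'
#' @param records Crop-record tibble.
#' @return A list with `n_records`, `n_production`, `n_area`, `n_yield`,
#'   `n_countries`, `n_products`.
#' @export
dataset_census <- function(records) {
  list(
    n_records = nrow(records),
    n_production = sum(!is.na(records$production)),
    n_area = sum(!is.na(records$area)),
    n_yield = sum(!is.na(records$yield)),
    n_countries = dplyr::n_distinct(records$country_code),
    n_products = dplyr::n_distinct(records$product)
  )
}

# ---- StatSeries ------------------------------------------------------------

#' Year-indexed statistic series
#'
#' The unit of analysis for quality control, smoothing and calibration: the
#' production/area/yield triple of one (fnid, product, season, production
#' system) over an ordered set of calendar years.
#'
#' @param years Strictly increasing integer years.
#' @param production,area,yield Numeric vectors aligned to `years` (NA =
#'   missing).
#' @param key Optional named list identifying the series (fnid, product,
#'   season_name, crop_production_system).
#' @return An object of class `stat_series`.
#' @export
stat_series <- function(years, production = NULL, area = NULL, yield = NULL,
                        key = NULL) {
  years <- as.integer(years)
  n <- length(years)
  if (n > 1 && any(diff(years) <= 0)) {
    stop("years must be strictly increasing")
  }
  fill <- function(x) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (length(x) != n) stop("series vectors must match length(years)")
    as.double(x)
  }
  structure(
    list(key = key, years = years, production = fill(production),
         area = fill(area), yield = fill(yield)),
    class = "stat_series"
  )
}

#' @export
print.stat_series <- function(x, ...) {
  cat("<stat_series> ", length(x$years), " years ",
      if (length(x$years) > 0) paste0("(", min(x$years), "-", max(x$years), ")"),
      if (!is.null(x$key)) paste0(" ", paste(unlist(x$key), collapse = " / ")),
      "\n", sep = "")
  invisible(x)
}

# Extract per-key stat_series from a record table. Duplicate (key, year)
# rows are summed for production and area (sub-observations of one
# series-year); yield is recomputed from the sums where possible.
records_to_series <- function(records) {
  keys <- c("fnid", "product", "season_name", "crop_production_system")
  grouped <- dplyr::group_by(records, dplyr::across(dplyr::all_of(keys)))
  dplyr::group_map(grouped, function(g, k) {
    yrs <- sort(unique(g$harvest_year))
    agg <- function(col) {
      vapply(yrs, function(y) {
        v <- g[[col]][g$harvest_year == y]
        if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
      }, numeric(1))
    }
    prod <- agg("production")
    area <- agg("area")
    yield <- ifelse(!is.na(area) & area > 0 & !is.na(prod),
                    prod / area, agg("yield"))
    stat_series(years = yrs, production = prod, area = area, yield = yield,
                key = as.list(k))
  })
}
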