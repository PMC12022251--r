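# Cross-validation against a national reference: subnational, seasonal
# statistics are aggregated to national annual totals (by harvest year) and
# correlated, per country and product, with an independent national series
# (FAOSTAT-style). Correlations are only reported when at least `min_years`
# overlapping years exist.

#' National annual production totals
#'
#' Sums production over administrative units, seasons and production systems
#' per (country, product, harvest year). Years with no subnational
#' observation are absent from the output, never zero. Annual assignment is
#' by harvest year, the closest analogue of calendar-year reference
#' statistics; switchable via `year_col`.
#'
#' @param records Crop-record tibble.
#' @param year_col Which year column defines the annual bin
#'   (`"harvest_year"`, the default, or `"planting_year"`).
#' @return A tibble with columns `country_code`, `product`, `year`,
#'   `production`.
#' @export
national_annual_production <- function(records,
                                       year_col = c("harvest_year",
                                                    "planting_year")) {
  year_col <- match.arg(year_col)
  records %>%
    dplyr::filter(!is.na(.data$production)) %>%
    dplyr::group_by(.data$country_code, .data$product,
                    year = .data[[year_col]]) %>%
    dplyr::summarise(production = sum(.data$production), .groups = "drop")
}

#' Build a national reference series table
#'
#' Light constructor/validator for reference tables (e.g. FAOSTAT exports
#' reshaped to long form): one production value per (country, product, year).
#'
#' @param country_code,product,year,production Equal-length vectors.
#' @return A validated tibble.
#' @export
national_series <- function(country_code, product, year, production) {
  out <- tibble::tibble(country_code = country_code, product = product,
                        year = as.integer(year),
                        production = as.double(production))
  if (anyDuplicated(out[c("country_code", "product", "year")])) {
    stop("reference series has duplicate (country, product, year) entries")
  }
  if (any(out$production < 0, na.rm = TRUE)) {
    stop("reference production must be >= 0")
  }
  out
}

#' Read a national reference series from CSV
#'
#' @param path CSV with columns `country_code`, `product`, `year`,
#'   `production`.
#' @return A validated reference tibble.
#' @export
read_reference_table <- function(path) {
  tbl <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("country_code", "product", "year", "production")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  national_series(tbl$country_code, tbl$product, tbl$year, tbl$production)
}

#' Correlate national totals with a reference series
#'
#' Pearson correlation over exactly matching years, per (country, product).
#' The correlation is reported as missing, with a reason, when fewer than
#' `min_years` overlapping years exist or when either series is constant over
#' the overlap.
#'
#' @param national Output of [national_annual_production()].
#' @param reference A reference tibble ([national_series()] layout).
#' @param min_years Minimum overlapping years required (default 5).
#' @param use_log Correlate log-transformed production (both series must be
#'   positive over the overlap); default FALSE (raw values).
#' @return A tibble with `country_code`, `product`, `n_years`, `r`, `reason`
#'   (NA when r is defined). The median r over defined cells is attached as
#'   attribute `"median_r"`.
#' @export
correlate_with_reference <- function(national, reference, min_years = 5L,
                                     use_log = FALSE) {
  cells <- dplyr::distinct(national, .data$country_code, .data$product)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(k) {
    cc <- cells$country_code[k]; pp <- cells$product[k]
    a <- national[national$country_code == cc & national$product == pp, ]
    b <- reference[reference$country_code == cc & reference$product == pp, ]
    m <- dplyr::inner_join(a, b, by = "year", suffix = c("_hs", "_ref"))
    m <- m[!is.na(m$production_hs) & !is.na(m$production_ref), ]
    n <- nrow(m)
    if (n < min_years) {
      return(tibble::tibble(country_code = cc, product = pp, n_years = n,
                            r = NA_real_, reason = "insufficient overlap"))
    }
    x <- m$production_hs; y <- m$production_ref
    if (use_log) {
      if (any(x <= 0) || any(y <= 0)) {
        return(tibble::tibble(country_code = cc, product = pp, n_years = n,
                              r = NA_real_,
                              reason = "non-positive values under log"))
      }
      x <- log(x); y <- log(y)
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(country_code = cc, product = pp, n_years = n,
                            r = NA_real_, reason = "constant series"))
    }
    tibble::tibble(country_code = cc, product = pp, n_years = n,
                   r = stats::cor(x, y), reason = NA_character_)
  }))
  attr(out, "median_r") <- stats::median(out$r, na.rm = TRUE)
  out
}

#' Median correlation across (country, product) cells
#'
#' @param cor_table Output of [correlate_with_reference()].
#' @param products Optional subset of products (e.g. the grain crops).
#' @return Median Pearson r over cells with a defined correlation.
#' @export
median_correlation <- function(cor_table, products = NULL) {
  if (!is.null(products)) {
    cor_table <- cor_table[cor_table$product %in% products, ]
  }
  stats::median(cor_table$r, na.rm = TRUE)
}
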