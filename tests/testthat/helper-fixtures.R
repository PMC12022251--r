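# Shared in-code fixtures. Everything is generated at test time; nothing is
# read from checked-in data files.

# Minimal single-series record table with internally consistent yield.
series_records <- function(years, production, area,
                           fnid = "XX2T01", product = "maize",
                           season = "Main", system = "none") {
  yield <- ifelse(!is.na(area) & area > 0 & !is.na(production),
                  production / area, NA_real_)
  crop_records(
    fnid = fnid, country = "Testland", country_code = "XX",
    admin_1 = "P1", admin_2 = fnid, product = product, season_name = season,
    planting_year = as.integer(years), planting_month = 4L,
    harvest_year = as.integer(years), harvest_month = 10L,
    crop_production_system = system, qc_flag = 0L,
    area = area, production = production, yield = yield,
    validate = FALSE
  )
}

# Random valid record collections for round-trip property tests.
random_records <- function(n, seed) {
  set.seed(seed)
  area <- round(runif(n, 10, 5000), 3)
  production <- round(area * runif(n, 0.2, 4), 3)
  yield <- production / area
  # punch holes: missing values stay missing, never zero
  area[runif(n) < 0.15] <- NA
  production[runif(n) < 0.15] <- NA
  yield[is.na(area) | is.na(production)] <- NA
  crop_records(
    fnid = sprintf("XX2U%02d", sample(1:8, n, replace = TRUE)),
    country = "Testland", country_code = "XX",
    admin_1 = sample(c("P1", "P2"), n, replace = TRUE),
    admin_2 = ifelse(runif(n) < 0.2, NA_character_, "D1"),
    product = sample(c("maize", "millet", "rice"), n, replace = TRUE),
    season_name = sample(c("Main", "Short rains"), n, replace = TRUE),
    planting_year = 2000L, planting_month = 4L,
    harvest_year = sample(2000:2015, n, replace = TRUE), harvest_month = 10L,
    crop_production_system = "none",
    qc_flag = sample(0:2, n, replace = TRUE),
    area = area, production = production, yield = yield,
    validate = FALSE
  )
}

expect_series_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$years, b$years)
  expect_equal(a$production, b$production, tolerance = tol)
  expect_equal(a$area, b$area, tolerance = tol)
  expect_equal(a$yield, b$yield, tolerance = tol)
}
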