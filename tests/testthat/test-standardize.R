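test_that("sub-crop aggregation sums statistics and recomputes yield", {
  rec <- dplyr::bind_rows(
    series_records(2000, production = 10, area = 5, product = "pearl millet"),
    series_records(2000, production = 2, area = 2, product = "finger millet")
  )
  out <- aggregate_subcrops(rec, crop_mapping(
    c("pearl millet", "finger millet"), c("millet", "millet")))
  expect_identical(nrow(out), 1L)
  expect_equal(out$production, 12)
  expect_equal(out$area, 7)
  expect_equal(out$yield, 12 / 7)
})

test_that("identity mapping leaves statistics unchanged and missing skips", {
  rec <- dplyr::bind_rows(
    series_records(2000:2001, production = c(3, 4), area = c(2, 2)),
    series_records(2000, production = NA, area = NA, product = "rice")
  )
  out <- aggregate_subcrops(rec, crop_mapping(character(0), character(0)))
  expect_equal(sort(out$production), c(3, 4))
  expect_true(is.na(out$production[out$product == "rice"]))

  # one sub-crop missing production, the other reports 4
  rec2 <- dplyr::bind_rows(
    series_records(2000, production = NA, area = 3, product = "white maize"),
    series_records(2000, production = 4, area = 2, product = "yellow maize")
  )
  out2 <- aggregate_subcrops(rec2, crop_mapping(
    c("white maize", "yellow maize"), c("maize", "maize")))
  expect_equal(out2$production, 4)
  expect_equal(out2$area, 5)
})

test_that("strict sub-crop aggregation requires a total mapping", {
  rec <- series_records(2000, production = 1, area = 1, product = "fonio")
  expect_error(
    aggregate_subcrops(rec, crop_mapping("millet", "millet"), strict = TRUE),
    "fonio")
})

test_that("normalised Gaussian smoothing preserves constants and renormalises", {
  const <- stat_series(2000:2010, production = rep(7, 11))
  est <- smoothed_production(const)
  expect_equal(est$expected_production, rep(7, 11))

  single <- stat_series(c(2000L, 2001L, 2002L),
                        production = c(NA, 9, NA))
  est1 <- smoothed_production(single)
  expect_equal(est1$expected_production, rep(9, 3))

  # symmetric neighbours: the unobserved midpoint is the plain average
  gap <- stat_series(2000:2002, production = c(10, NA, 30))
  est2 <- smoothed_production(gap)
  expect_equal(est2$expected_production[2], 20)
  expect_true(est2$expected_production[1] < 20)
  expect_true(est2$expected_production[3] > 20)
})

test_that("coverage gate admits the majority subunit and blocks the minority", {
  # smoothed climatologies 60 and 40 -> shares 0.6 / 0.4
  rec <- dplyr::bind_rows(
    series_records(2000:2004, production = c(60, 60, 55, 60, NA),
                   area = c(30, 30, 27, 30, NA), fnid = "F1"),
    series_records(2000:2004, production = c(40, 40, NA, NA, 40),
                   area = c(20, 20, NA, NA, 20), fnid = "F2")
  )
  agg <- aggregate_admin(rec, c(F1 = "C1", F2 = "C1"))
  by_year <- function(y) agg[agg$harvest_year == y, ]
  expect_equal(by_year(2002)$production, 55)   # 0.6-share unit alone: kept
  expect_true(is.na(by_year(2004)$production)) # 0.4-share unit alone: gated
  expect_equal(by_year(2000)$production, 100)  # full reporting: exact sum
  expect_equal(by_year(2000)$yield, 100 / 50)
  cov <- attr(agg, "coverage")
  expect_equal(cov$coverage[cov$year == 2000], 1)
})

test_that("aggregates are exact sums of reporting members, never inflated", {
  sc <- make_scenario(scenario_config(seed = 6, n_outliers = 0, n_runs = 0))
  rec <- sc$series$records
  mapping <- stats::setNames(rec$admin_1, rec$fnid)
  mapping <- mapping[!duplicated(names(mapping))]
  agg <- aggregate_admin(rec, mapping)
  manual <- rec %>%
    dplyr::group_by(.data$admin_1, .data$product, .data$harvest_year) %>%
    dplyr::summarise(production = sum(production), .groups = "drop")
  j <- dplyr::inner_join(
    agg, manual,
    by = c(fnid = "admin_1", "product", "harvest_year"),
    suffix = c("_agg", "_manual"))
  expect_equal(j$production_agg, j$production_manual)
  # yield * area = production wherever defined
  ok <- !is.na(agg$yield) & !is.na(agg$area) & !is.na(agg$production)
  expect_equal(agg$yield[ok] * agg$area[ok], agg$production[ok],
               tolerance = 1e-9)
})

test_that("lowering min_coverage never turns an observed aggregate missing", {
  rec <- dplyr::bind_rows(
    series_records(2000:2004, production = c(60, NA, 55, NA, NA),
                   area = c(30, NA, 27, NA, NA), fnid = "F1"),
    series_records(2000:2004, production = c(40, 40, NA, NA, 40),
                   area = c(20, 20, NA, NA, 20), fnid = "F2")
  )
  um <- c(F1 = "C1", F2 = "C1")
  strict <- aggregate_admin(rec, um, coverage = coverage_params(0.9))
  loose <- aggregate_admin(rec, um, coverage = coverage_params(0.3))
  j <- dplyr::inner_join(strict, loose, by = c("fnid", "product",
                                               "harvest_year"),
                         suffix = c("_strict", "_loose"))
  expect_true(all(is.na(j$production_loose[is.na(j$production_loose)])))
  expect_true(all(!is.na(j$production_loose[!is.na(j$production_strict)])))
})

test_that("orphan fine units are an error", {
  rec <- series_records(2000, production = 1, area = 1, fnid = "F9")
  expect_error(aggregate_admin(rec, c(F1 = "C1")), "F9")
})
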