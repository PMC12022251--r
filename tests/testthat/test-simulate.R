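test_that("fixed seed gives byte-identical scenarios", {
  a <- make_scenario(scenario_config(seed = 9, boundary_event = "split"))
  b <- make_scenario(scenario_config(seed = 9, boundary_event = "split"))
  expect_identical(a$series$records, b$series$records)
  expect_identical(a$series$truth_flags, b$series$truth_flags)
  expect_identical(a$raster$values, b$raster$values)
  expect_identical(lapply(a$vintages$new$geometry, unlist),
                   lapply(b$vintages$new$geometry, unlist))
  c_ <- make_scenario(scenario_config(seed = 10, boundary_event = "split"))
  expect_false(identical(a$series$records$yield, c_$series$records$yield))
})

test_that("generated tables pass strict schema validation", {
  for (ev in c("none", "split", "merge", "reorganize")) {
    sc <- make_scenario(scenario_config(seed = 3, boundary_event = ev))
    expect_identical(nrow(validate_crop_records(sc$series$records)), 0L,
                     info = ev)
    path <- withr::local_tempfile(fileext = ".csv")
    write_crop_table(sc$series$records, path)
    expect_silent(read_crop_table(path, strict = TRUE))
  }
})

test_that("constructed vintages realise the declared event geometrically", {
  split <- make_admin_vintages(scenario_config(boundary_event = "split"))
  expect_identical(split$truth$case, "A")
  halves <- split$new$geometry[match(split$truth$new_fnids, split$new$fnid)]
  old_sq <- split$old$geometry[[match(split$truth$old_fnids, split$old$fnid)]]
  expect_equal(geom_area(halves[[1]]) + geom_area(halves[[2]]),
               geom_area(old_sq))
  expect_equal(intersection_area(halves[[1]], halves[[2]]), 0)

  reorg <- make_admin_vintages(scenario_config(boundary_event = "reorganize"))
  expect_identical(reorg$truth$case, "B")
  # interior strips straddle two old squares
  g2 <- reorg$new$geometry[[match("XX2R02", reorg$new$fnid)]]
  olds <- reorg$old$geometry[match(reorg$truth$old_fnids, reorg$old$fnid)]
  overlaps <- vapply(olds, function(o) intersection_area(g2, o), numeric(1))
  expect_identical(sum(overlaps > 0), 2L)

  none <- make_admin_vintages(scenario_config(boundary_event = "none"))
  expect_length(none$truth, 0)
})

test_that("zero-noise, no-injection series are exactly linear and consistent", {
  crops <- tibble::tibble(product = "maize", mean_yield = 2, trend = 0.05,
                          cv = 1e-12)
  sc <- make_crop_series(scenario_config(seed = 1, crops = crops,
                                         n_outliers = 0, n_runs = 0,
                                         n_admin1 = 1, n_admin2_per1 = 1))
  y <- sc$records$yield
  d2 <- diff(diff(y))
  expect_lt(max(abs(d2)), 1e-9)
  expect_equal(sc$records$production, sc$records$yield * sc$records$area,
               tolerance = 1e-12)
})

test_that("reporting coverage schedule drops unit-years at the given rate", {
  full <- make_crop_series(scenario_config(seed = 12, n_outliers = 0,
                                           n_runs = 0))
  part <- make_crop_series(scenario_config(seed = 12, n_outliers = 0,
                                           n_runs = 0, reporting_prob = 0.6))
  expect_lt(nrow(part$records), nrow(full$records))
  frac <- nrow(part$records) / nrow(full$records)
  expect_gt(frac, 0.4); expect_lt(frac, 0.8)
  # truth table stays aligned with surviving records
  expect_identical(nrow(part$truth_flags), nrow(part$records))
})

test_that("cropland raster options: constant, random-seeded, zero region", {
  cfg <- scenario_config(seed = 2)
  r1 <- make_cropland_raster(cfg)
  expect_true(all(r1$values == 1))
  cfg_r <- scenario_config(seed = 2, cropland = "random")
  r2 <- make_cropland_raster(cfg_r)
  r3 <- make_cropland_raster(cfg_r)
  expect_identical(r2$values, r3$values)
  r0 <- make_cropland_raster(scenario_config(cropland = 0))
  expect_equal(zonal_cropland_area(r0, rect_geometry(0, 0, 10, 10)), 0)
})

test_that("scenario files round-trip through the pipeline formats", {
  sc <- make_scenario(scenario_config(seed = 14, boundary_event = "reorganize"))
  dir <- withr::local_tempdir()
  paths <- write_scenario(sc, dir)
  expect_true(all(file.exists(paths)))
  rec <- read_crop_table(paths["records"], strict = TRUE)
  expect_identical(nrow(rec), nrow(sc$series$records))
  old <- read_boundaries(paths["boundaries_old"])
  expect_identical(sort(old$fnid), sort(sc$vintages$old$fnid))
  r <- read_cropland_raster(paths["cropland"])
  expect_equal(r$values, sc$raster$values)
  # every record fnid joins exactly one unit of the matching vintage
  new <- read_boundaries(paths["boundaries_new"])
  all_units <- c(old$fnid, new$fnid)
  expect_true(all(rec$fnid %in% all_units))
  rec_old <- read_crop_table(paths["records_old"])
  expect_true(all(table(match(rec_old$fnid, old$fnid)) > 0))
  expect_identical(anyDuplicated(old$fnid), 0L)
})
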