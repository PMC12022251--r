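make_square_vintages <- function() {
  old <- admin_units(
    fnid = c("E1", "K1"),
    geometry = list(rect_geometry(0, 0, 10, 10), rect_geometry(10, 0, 20, 10)),
    vintage = "old")
  new <- admin_units(
    fnid = c("E1n", "E2n", "K1"),
    geometry = list(rect_geometry(0, 0, 5, 10), rect_geometry(5, 0, 10, 10),
                    rect_geometry(10, 0, 20, 10)),
    vintage = "new")
  list(old = old, new = new)
}

test_that("identical vintages produce zero events", {
  v <- make_square_vintages()
  ch <- detect_boundary_changes(v$old, v$old)
  expect_length(ch$events, 0)
  expect_identical(nrow(ch$passthrough), 2L)
  expect_true(all(ch$passthrough$area_change == 0))
})

test_that("a square split into two tiling halves is one Case A event", {
  v <- make_square_vintages()
  ch <- detect_boundary_changes(v$old, v$new)
  expect_length(ch$events, 1)
  e <- ch$events[[1]]
  expect_identical(e$case, "A")
  expect_identical(e$direction, "split")
  expect_identical(e$old_fnids, "E1")
  expect_setequal(e$new_fnids, c("E1n", "E2n"))
  # the unchanged neighbour passes through
  expect_identical(ch$passthrough$old_fnid, "K1")
})

test_that("shifted internal borders are one Case B event", {
  old <- admin_units(
    fnid = c("F1", "F2", "F3"),
    geometry = lapply(0:2, function(k) {
      rect_geometry(k * 10, 0, (k + 1) * 10, 10)
    }), vintage = "old")
  new <- admin_units(
    fnid = sprintf("G%d", 1:4),
    geometry = lapply(0:3, function(k) {
      rect_geometry(k * 7.5, 0, (k + 1) * 7.5, 10)
    }), vintage = "new")
  ch <- detect_boundary_changes(old, new)
  expect_length(ch$events, 1)
  expect_identical(ch$events[[1]]$case, "B")
})

test_that("units below the 10% area-change trigger pass through unmodified", {
  old <- admin_units(fnid = "U1", geometry = list(rect_geometry(0, 0, 10, 10)),
                     vintage = "old")
  # 8% smaller: under the trigger
  new <- admin_units(fnid = "U1b",
                     geometry = list(rect_geometry(0, 0, 9.2, 10)),
                     vintage = "new")
  ch <- detect_boundary_changes(old, new)
  expect_length(ch$events, 0)
  expect_identical(ch$passthrough$new_fnid, "U1b")
  # 12% smaller: at/above the trigger
  new2 <- admin_units(fnid = "U1c",
                      geometry = list(rect_geometry(0, 0, 8.8, 10)),
                      vintage = "new")
  ch2 <- detect_boundary_changes(old, new2)
  expect_length(ch2$events, 1)
})

test_that("Case A shares follow post-split mean production per crop", {
  v <- make_square_vintages()
  ch <- detect_boundary_changes(v$old, v$new)
  new_rec <- dplyr::bind_rows(
    series_records(2011:2013, production = c(30, 28, 32), area = c(10, 10, 10),
                   fnid = "E1n"),
    series_records(2011:2013, production = c(90, 92, 88), area = c(30, 30, 30),
                   fnid = "E2n")
  )
  plan <- build_case_a_plan(ch$events[[1]], new_rec)
  expect_equal(plan$share[plan$new_fnid == "E1n"], 0.25)
  expect_equal(plan$share[plan$new_fnid == "E2n"], 0.75)
  expect_equal(sum(plan$share), 1)

  # equal means give symmetric shares; single unit gives share 1
  eq_rec <- dplyr::bind_rows(
    series_records(2011:2012, production = c(50, 60), area = c(10, 10),
                   fnid = "E1n"),
    series_records(2011:2012, production = c(60, 50), area = c(10, 10),
                   fnid = "E2n"))
  plan_eq <- build_case_a_plan(ch$events[[1]], eq_rec)
  expect_equal(plan_eq$share, c(0.5, 0.5))
})

test_that("Case A application conserves totals and yields exactly", {
  v <- make_square_vintages()
  ch <- detect_boundary_changes(v$old, v$new)
  new_rec <- dplyr::bind_rows(
    series_records(2011, production = 30, area = 10, fnid = "E1n"),
    series_records(2011, production = 90, area = 30, fnid = "E2n"))
  plan <- build_case_a_plan(ch$events[[1]], new_rec)
  old <- stat_series(2000:2001, production = c(100, 120),
                     area = c(50, 60), yield = c(2, 2),
                     key = list(fnid = "E1", product = "maize",
                                season_name = "Main",
                                crop_production_system = "none"))
  out <- apply_case_a(plan, old, "maize")
  expect_equal(out$E1n$production, c(25, 30))
  expect_equal(out$E2n$production, c(75, 90))
  expect_equal(out$E1n$production + out$E2n$production, old$production,
               tolerance = 1e-9)
  expect_equal(out$E1n$area + out$E2n$area, old$area, tolerance = 1e-9)
  expect_equal(out$E1n$yield, old$yield)
  expect_equal(out$E2n$yield, old$yield)
})

test_that("missing old years propagate to all Case A outputs", {
  v <- make_square_vintages()
  ch <- detect_boundary_changes(v$old, v$new)
  new_rec <- dplyr::bind_rows(
    series_records(2011, production = 30, area = 10, fnid = "E1n"),
    series_records(2011, production = 90, area = 30, fnid = "E2n"))
  plan <- build_case_a_plan(ch$events[[1]], new_rec)
  old <- stat_series(2000:2002, production = c(100, NA, 120),
                     key = list(fnid = "E1", product = "maize",
                                season_name = "Main",
                                crop_production_system = "none"))
  out <- apply_case_a(plan, old, "maize")
  expect_true(is.na(out$E1n$production[2]))
  expect_true(is.na(out$E2n$production[2]))
})

test_that("Case B weights are cropland-overlap ratios in [0, 1]", {
  old <- admin_units(
    fnid = c("F1", "F2"),
    geometry = list(rect_geometry(0, 0, 10, 10), rect_geometry(10, 0, 20, 10)),
    vintage = "old")
  new <- admin_units(
    fnid = c("G1", "G2"),
    geometry = list(rect_geometry(0, 0, 4, 10), rect_geometry(4, 0, 20, 10)),
    vintage = "new")
  raster <- cropland_raster(matrix(1, 10, 20))
  ch <- detect_boundary_changes(old, new)
  expect_identical(ch$events[[1]]$case, "B")
  plan <- build_case_b_plan(ch$events[[1]], raster)
  w <- function(n, o) plan$weight[plan$new_fnid == n & plan$old_fnid == o]
  expect_equal(w("G1", "F1"), 0.4)
  expect_equal(w("G2", "F1"), 0.6)
  expect_equal(w("G2", "F2"), 1)
  expect_length(w("G1", "F2"), 0)  # disjoint pair dropped
  expect_true(all(plan$weight >= 0 & plan$weight <= 1))
})

test_that("Case B application is the weighted sum with missing propagation", {
  plan <- structure(
    tibble::tibble(new_fnid = "G", old_fnid = c("F1", "F2"),
                   weight = c(0.4, 0.2), source = "cropland"),
    class = c("calibration_plan", class(tibble::tibble())), case = "B")
  mk <- function(fnid, prod) {
    stat_series(2000:2001, production = prod, area = prod / 2,
                key = list(fnid = fnid, product = "maize",
                           season_name = "Main",
                           crop_production_system = "none"))
  }
  out <- apply_case_b(plan, list(F1 = mk("F1", c(50, NA)),
                                 F2 = mk("F2", c(30, 30))))
  expect_equal(out$G$production[1], 50 * 0.4 + 30 * 0.2)  # 26 mt
  expect_true(is.na(out$G$production[2]))                 # missing contributor
  expect_equal(out$G$yield[1], 2)                         # prod/area recomputed
})

test_that("conservation: exact under tiling, closed-form defect otherwise", {
  old <- admin_units(
    fnid = c("F1", "F2", "F3"),
    geometry = lapply(0:2, function(k) rect_geometry(k * 10, 0, (k + 1) * 10, 10)),
    vintage = "old")
  new_tiling <- admin_units(
    fnid = sprintf("G%d", 1:4),
    geometry = lapply(0:3, function(k) rect_geometry(k * 7.5, 0, (k + 1) * 7.5, 10)),
    vintage = "new")
  raster <- cropland_raster(matrix(1, 10, 30))
  old_rec <- dplyr::bind_rows(lapply(c("F1", "F2", "F3"), function(f) {
    series_records(2000:2004, production = c(100, 110, 90, 105, 95),
                   area = c(50, 55, 45, 52, 47), fnid = f)
  }))
  new_rec <- dplyr::bind_rows(lapply(sprintf("G%d", 1:4), function(f) {
    series_records(2010, production = 75, area = 40, fnid = f)
  }))
  cal <- calibrate_records(old_rec, new_rec, old, new_tiling, raster)
  cons <- cal$conservation
  expect_true(all(cons$tiling_ok))
  expect_lt(max(cons$rel_discrepancy, na.rm = TRUE), 1e-6)

  # drop a sliver: the last strip is 2 units short; F3 loses weight 0.2
  new_sliver <- admin_units(
    fnid = sprintf("G%d", 1:4),
    geometry = c(lapply(0:2, function(k) rect_geometry(k * 7.5, 0, (k + 1) * 7.5, 10)),
                 list(rect_geometry(22.5, 0, 28, 10))),
    vintage = "new")
  ch <- detect_boundary_changes(old, new_sliver)
  plan <- build_case_b_plan(ch$events[[1]], raster)
  wsum_f3 <- sum(plan$weight[plan$old_fnid == "F3"])
  expect_equal(wsum_f3, 0.8)
  series <- stats::setNames(
    lapply(c("F1", "F2", "F3"), function(f) {
      stat_series(2000, production = 100, area = 50,
                  key = list(fnid = f, product = "maize",
                             season_name = "Main",
                             crop_production_system = "none"))
    }), c("F1", "F2", "F3"))
  out <- apply_case_b(plan, series)
  total_after <- sum(vapply(out, function(s) s$production[1], numeric(1)))
  expect_equal(300 - total_after, 100 * (1 - wsum_f3), tolerance = 1e-6)
})

test_that("a merge with conserved outer boundary sums the old series", {
  old <- admin_units(
    fnid = c("M1", "M2"),
    geometry = list(rect_geometry(0, 0, 10, 10), rect_geometry(10, 0, 20, 10)),
    vintage = "old")
  new <- admin_units(fnid = "M", geometry = list(rect_geometry(0, 0, 20, 10)),
                     vintage = "new")
  ch <- detect_boundary_changes(old, new)
  expect_identical(ch$events[[1]]$case, "A")
  expect_identical(ch$events[[1]]$direction, "merge")
  old_rec <- dplyr::bind_rows(
    series_records(2000:2001, production = c(10, 12), area = c(5, 6),
                   fnid = "M1"),
    series_records(2000:2001, production = c(30, 28), area = c(10, 10),
                   fnid = "M2"))
  cal <- calibrate_records(old_rec, old_rec[0, ], old, new)
  merged <- cal$records[cal$records$fnid == "M", ]
  expect_equal(sort(merged$production), c(40, 40))
  expect_lt(max(cal$conservation$rel_discrepancy, na.rm = TRUE), 1e-12)
})

test_that("end-to-end split recovers the ground-truth proportional series", {
  sc <- make_scenario(scenario_config(seed = 21, boundary_event = "split",
                                      n_outliers = 0, n_runs = 0))
  cal <- calibrate_records(sc$series$records_old, sc$series$records_new,
                           sc$vintages$old, sc$vintages$new, sc$raster)
  truth <- sc$series$truth_shares
  old_split <- sc$series$records_old[
    sc$series$records_old$fnid == "XX2U10", ]
  for (k in seq_len(nrow(truth))) {
    got <- cal$records[cal$records$fnid == truth$new_fnid[k] &
                         cal$records$harvest_year < sc$config$event_year, ]
    j <- dplyr::inner_join(
      got, old_split,
      by = c("product", "season_name", "crop_production_system",
             "harvest_year"), suffix = c("_new", "_old"))
    expect_identical(nrow(j), nrow(old_split))
    expect_equal(j$production_new, j$production_old * truth$share[k],
                 tolerance = 1e-12)
    expect_equal(j$yield_new, j$yield_old, tolerance = 1e-12)
  }
  expect_lt(max(cal$conservation$rel_discrepancy, na.rm = TRUE), 1e-9)
})

test_that("identity vintages calibrate to a byte-equal no-op", {
  sc <- make_scenario(scenario_config(seed = 5, n_outliers = 0, n_runs = 0))
  cal <- calibrate_records(sc$series$records, sc$series$records[0, ],
                           sc$vintages$old, sc$vintages$new)
  expect_length(cal$changes$events, 0)
  reord <- dplyr::arrange(cal$records, fnid, product, harvest_year)
  orig <- dplyr::arrange(sc$series$records, fnid, product, harvest_year)
  expect_identical(reord$production, orig$production)
  expect_identical(reord$area, orig$area)
  expect_identical(reord$yield, orig$yield)
})
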