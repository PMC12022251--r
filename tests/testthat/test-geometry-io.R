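test_that("polygon areas and intersections are exact on integer grids", {
  a <- rect_geometry(0, 0, 10, 10)
  b <- rect_geometry(5, 0, 15, 10)
  expect_equal(geom_area(a), 100)
  expect_equal(intersection_area(a, b), 50)
  expect_equal(geom_area(geom_union(list(a, b))), 150)
  expect_equal(intersection_area(a, rect_geometry(20, 0, 30, 10)), 0)
})

test_that("holes subtract from area", {
  outer <- rect_geometry(0, 0, 10, 10)
  inner <- rect_geometry(2, 2, 4, 4)
  donut <- polyclip::polyclip(outer, inner, op = "minus")
  expect_equal(geom_area(donut), 100 - 4)
})

test_that("bowtie polygons are repaired, not silently accepted", {
  bow <- list(list(x = c(0, 2, 0, 2), y = c(0, 0, 2, 2)))
  r <- repair_geometry(bow)
  expect_true(r$repaired)
  expect_equal(geom_area(r$geometry), 2)  # two unit triangles
  expect_warning(
    admin_units(fnid = "B1", geometry = list(bow)),
    "repaired"
  )
})

test_that("duplicate fnid within a vintage is an error naming the fnid", {
  g <- list(rect_geometry(0, 0, 1, 1), rect_geometry(1, 0, 2, 1))
  expect_error(admin_units(fnid = c("A1", "A1"), geometry = g), "A1")
})

test_that("GeoPackage round-trips units, attributes and CRS", {
  units <- admin_units(
    fnid = sprintf("XX2U%02d", 1:4),
    geometry = list(rect_geometry(0, 0, 10, 10), rect_geometry(10, 0, 20, 10),
                    rect_geometry(0, 10, 10, 20), rect_geometry(10, 10, 20, 20)),
    country_code = "XX", level = 2L, vintage = "old",
    crs = "custom-laea")
  path <- withr::local_tempfile(fileext = ".gpkg")
  write_boundaries(units, path)
  back <- read_boundaries(path)
  expect_s3_class(back, "admin_units")
  expect_identical(back$fnid, units$fnid)
  expect_identical(back$vintage, units$vintage)
  expect_identical(attr(back, "crs"), "custom-laea")
  for (i in 1:4) {
    expect_equal(geom_area(back$geometry[[i]]), 100)
    expect_equal(intersection_area(back$geometry[[i]], units$geometry[[i]]),
                 100)
  }
})

test_that("GeoJSON round-trips geometry including holes", {
  outer <- rect_geometry(0, 0, 10, 10)
  donut <- polyclip::polyclip(outer, rect_geometry(4, 4, 6, 6), op = "minus")
  units <- admin_units(fnid = c("A", "B"),
                       geometry = list(donut, rect_geometry(10, 0, 20, 10)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_boundaries(units, path)
  back <- read_boundaries(path)
  expect_equal(geom_area(back$geometry[[1]]), 96)
  expect_equal(geom_area(back$geometry[[2]]), 100)
})

test_that("boundary readers reject missing fnid and empty layers", {
  path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       path, auto_unbox = TRUE)
  expect_error(read_boundaries(path), "empty")
})

test_that("ASCII grid raster round-trips values, origin and CRS", {
  m <- matrix(c(1, 2, NA, 0.25), 2, 2)
  r <- cropland_raster(m, xmin = 5, ymin = -3, cellsize = 2, crs = "laea-1")
  path <- withr::local_tempfile(fileext = ".asc")
  write_cropland_raster(r, path)
  back <- read_cropland_raster(path)
  expect_equal(back$values, m)
  expect_equal(back$xmin, 5)
  expect_equal(back$ymin, -3)
  expect_equal(back$cellsize, 2)
  expect_identical(back$crs, "laea-1")
})

test_that("zonal cropland area: exact cover, partial cells, disjoint, CRS", {
  r <- cropland_raster(matrix(1, 10, 10))  # 1 ha per 1x1 cell
  expect_equal(zonal_cropland_area(r, rect_geometry(0, 0, 5, 5)), 25)
  # polygon covering the left half of a 10-cell column: 10 half cells
  expect_equal(zonal_cropland_area(r, rect_geometry(0, 0, 0.5, 10)), 5)
  expect_warning(
    z <- zonal_cropland_area(r, rect_geometry(100, 100, 110, 110)),
    "disjoint")
  expect_equal(z, 0)
  expect_error(
    zonal_cropland_area(r, rect_geometry(0, 0, 1, 1), crs = "other"),
    "CRS mismatch")
})

test_that("zonal area is additive over disjoint geometries", {
  set.seed(5)
  vals <- matrix(runif(100, 0, 2), 10, 10)
  r <- cropland_raster(vals)
  for (k in 1:5) {
    x <- sort(runif(3, 0, 10))
    a <- rect_geometry(x[1], 0, x[2], 7.3)
    b <- rect_geometry(x[2], 0, x[3], 7.3)
    ab <- rect_geometry(x[1], 0, x[3], 7.3)
    expect_equal(zonal_cropland_area(r, a) + zonal_cropland_area(r, b),
                 zonal_cropland_area(r, ab), tolerance = 1e-6)
  }
})
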