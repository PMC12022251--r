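# Boundary layer I/O: GeoPackage (SQLite + WKB geometry blobs) and GeoJSON.
#
# The GeoPackage codec is intentionally minimal but standard-conforming:
# little-endian WKB Polygon/MultiPolygon payloads wrapped in the GPKG binary
# header, plus the three mandatory metadata tables, so files interoperate
# with mainstream GIS software. Only 2D polygonal geometry is supported,
# which is all an administrative boundary vintage needs.

# ---- WKB codec -------------------------------------------------------------

wkb_write_ring <- function(ring, con) {
  n <- length(ring$x)
  writeBin(as.integer(n + 1L), con, size = 4, endian = "little")
  for (i in seq_len(n)) {
    writeBin(c(ring$x[i], ring$y[i]), con, size = 8, endian = "little")
  }
  writeBin(c(ring$x[1], ring$y[1]), con, size = 8, endian = "little")
}

# Group rings into polygons: positive (outer) rings become polygon shells,
# negative rings become holes of the shell containing their first vertex.
rings_to_polygons <- function(geom) {
  norm <- polyclip::polysimplify(geom, filltype = "nonzero")
  sgn <- vapply(norm, ring_signed_area, numeric(1))
  outers <- norm[sgn > 0]
  holes <- norm[sgn < 0]
  polys <- lapply(outers, function(o) list(o))
  for (h in holes) {
    placed <- FALSE
    for (k in seq_along(polys)) {
      if (point_in_ring(h$x[1], h$y[1], polys[[k]][[1]])) {
        polys[[k]] <- c(polys[[k]], list(h))
        placed <- TRUE
        break
      }
    }
    if (!placed) warning("hole ring not contained in any outer ring; dropped")
  }
  polys
}

point_in_ring <- function(px, py, ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

geom_to_wkb <- function(geom) {
  polys <- rings_to_polygons(geom)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(as.raw(1L), con)                                  # little endian
  writeBin(6L, con, size = 4, endian = "little")             # MultiPolygon
  writeBin(length(polys), con, size = 4, endian = "little")
  for (p in polys) {
    writeBin(as.raw(1L), con)
    writeBin(3L, con, size = 4, endian = "little")           # Polygon
    writeBin(length(p), con, size = 4, endian = "little")
    for (ring in p) wkb_write_ring(ring, con)
  }
  rawConnectionValue(con)
}

wkb_reader <- function(raw_vec) {
  pos <- 1L
  list(
    byte = function() {
      b <- raw_vec[pos]; pos <<- pos + 1L; as.integer(b)
    },
    u32 = function(endian) {
      v <- readBin(raw_vec[pos:(pos + 3L)], "integer", size = 4,
                   endian = endian)
      pos <<- pos + 4L; v
    },
    dbl = function(n, endian) {
      v <- readBin(raw_vec[pos:(pos + 8L * n - 1L)], "double", size = 8,
                   n = n, endian = endian)
      pos <<- pos + 8L * n; v
    },
    skip = function(n) pos <<- pos + as.integer(n),
    pos = function() pos
  )
}

wkb_read_geometry <- function(rd) {
  endian <- if (rd$byte() == 1L) "little" else "big"
  type <- rd$u32(endian) %% 1000L
  if (type == 3L) {
    list(wkb_read_polygon_rings(rd, endian))
  } else if (type == 6L) {
    n <- rd$u32(endian)
    lapply(seq_len(n), function(i) {
      e2 <- if (rd$byte() == 1L) "little" else "big"
      t2 <- rd$u32(e2) %% 1000L
      if (t2 != 3L) stop("unsupported WKB member geometry type: ", t2)
      wkb_read_polygon_rings(rd, e2)
    })
  } else {
    stop("unsupported WKB geometry type: ", type,
         " (only Polygon and MultiPolygon are handled)")
  }
}

wkb_read_polygon_rings <- function(rd, endian) {
  nring <- rd$u32(endian)
  rings <- vector("list", nring)
  for (k in seq_len(nring)) {
    npt <- rd$u32(endian)
    xy <- rd$dbl(2L * npt, endian)
    x <- xy[seq(1L, by = 2L, length.out = npt)]
    y <- xy[seq(2L, by = 2L, length.out = npt)]
    # drop the closing vertex; normalise orientation: shell CCW, holes CW
    x <- x[-npt]; y <- y[-npt]
    ring <- list(x = x, y = y)
    want_positive <- (k == 1L)
    if ((ring_signed_area(ring) > 0) != want_positive) {
      ring <- list(x = rev(x), y = rev(y))
    }
    rings[[k]] <- ring
  }
  rings
}

wkb_to_geom <- function(raw_vec) {
  rd <- wkb_reader(raw_vec)
  polys <- wkb_read_geometry(rd)
  do.call(c, polys)
}

# ---- GPKG binary blob wrapper ---------------------------------------------

gpkg_blob <- function(geom, srs_id = 0L) {
  header <- c(
    as.raw(c(0x47, 0x50)),       # "GP"
    as.raw(0x00),                # version
    as.raw(0x01)                 # flags: little-endian srs_id, no envelope
  )
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.integer(srs_id), con, size = 4, endian = "little")
  writeBin(geom_to_wkb(geom), con)
  rawConnectionValue(con)
}

gpkg_blob_parse <- function(raw_vec) {
  if (length(raw_vec) < 8L || raw_vec[1] != as.raw(0x47) ||
      raw_vec[2] != as.raw(0x50)) {
    stop("not a GeoPackage geometry blob")
  }
  flags <- as.integer(raw_vec[4])
  envelope <- bitwAnd(bitwShiftR(flags, 1L), 7L)
  env_bytes <- c(0L, 32L, 48L, 48L, 64L)[envelope + 1L]
  offset <- 8L + env_bytes
  wkb_to_geom(raw_vec[(offset + 1L):length(raw_vec)])
}

# ---- GeoPackage read/write -------------------------------------------------

#' Write administrative boundaries to a GeoPackage
#'
#' @param units An [admin_units] table.
#' @param path Output `.gpkg` path.
#' @param layer Feature table name.
#' @return `path`, invisibly.
#' @export
write_boundaries_gpkg <- function(units, path, layer = "admin_units") {
  stopifnot(inherits(units, "admin_units"))
  crs <- units_crs(units)
  if (file.exists(path)) unlink(path)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  DBI::dbExecute(con, "PRAGMA application_id = 1196444487")
  DBI::dbExecute(con, "PRAGMA user_version = 10300")
  DBI::dbExecute(con, "
    CREATE TABLE gpkg_spatial_ref_sys (
      srs_name TEXT NOT NULL, srs_id INTEGER NOT NULL PRIMARY KEY,
      organization TEXT NOT NULL, organization_coordsys_id INTEGER NOT NULL,
      definition TEXT NOT NULL, description TEXT)")
  DBI::dbExecute(con, "
    INSERT INTO gpkg_spatial_ref_sys VALUES
      ('Undefined cartesian SRS', -1, 'NONE', -1, 'undefined', NULL),
      ('Undefined geographic SRS', 0, 'NONE', 0, 'undefined', NULL)")
  DBI::dbExecute(con,
    "INSERT INTO gpkg_spatial_ref_sys VALUES (:n, 99001, 'LOCAL', 99001, :d, NULL)",
    params = list(n = crs, d = crs))
  DBI::dbExecute(con, "
    CREATE TABLE gpkg_contents (
      table_name TEXT NOT NULL PRIMARY KEY, data_type TEXT NOT NULL,
      identifier TEXT UNIQUE, description TEXT DEFAULT '',
      last_change DATETIME, min_x DOUBLE, min_y DOUBLE,
      max_x DOUBLE, max_y DOUBLE, srs_id INTEGER)")
  DBI::dbExecute(con, "
    CREATE TABLE gpkg_geometry_columns (
      table_name TEXT NOT NULL, column_name TEXT NOT NULL,
      geometry_type_name TEXT NOT NULL, srs_id INTEGER NOT NULL,
      z TINYINT NOT NULL, m TINYINT NOT NULL,
      PRIMARY KEY (table_name, column_name))")
  bb <- Reduce(function(a, g) {
    b <- geom_bbox(g)
    c(min(a[1], b[1]), min(a[2], b[2]), max(a[3], b[3]), max(a[4], b[4]))
  }, units$geometry, c(Inf, Inf, -Inf, -Inf))
  DBI::dbExecute(con, "
    INSERT INTO gpkg_contents VALUES
      (:t, 'features', :t, 'administrative boundary vintage',
       strftime('%Y-%m-%dT%H:%M:%fZ','now'), :x0, :y0, :x1, :y1, 99001)",
    params = list(t = layer, x0 = bb[1], y0 = bb[2], x1 = bb[3], y1 = bb[4]))
  DBI::dbExecute(con,
    "INSERT INTO gpkg_geometry_columns VALUES (:t, 'geom', 'MULTIPOLYGON', 99001, 0, 0)",
    params = list(t = layer))
  DBI::dbExecute(con, sprintf("
    CREATE TABLE \"%s\" (
      fid INTEGER PRIMARY KEY AUTOINCREMENT, geom BLOB,
      fnid TEXT NOT NULL, country_code TEXT, level INTEGER,
      name TEXT, vintage TEXT)", layer))
  feat <- data.frame(
    fid = seq_len(nrow(units)),
    fnid = units$fnid, country_code = units$country_code,
    level = units$level, name = units$name, vintage = units$vintage,
    stringsAsFactors = FALSE
  )
  feat$geom <- I(lapply(units$geometry, gpkg_blob, srs_id = 99001L))
  DBI::dbWriteTable(con, layer, feat, append = TRUE)
  invisible(path)
}

read_boundaries_gpkg <- function(path, layer = NULL) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  on.exit(DBI::dbDisconnect(con))
  gc_tbl <- DBI::dbGetQuery(con, "SELECT * FROM gpkg_geometry_columns")
  if (nrow(gc_tbl) == 0) stop("GeoPackage has no geometry layers: ", path)
  if (is.null(layer)) layer <- gc_tbl$table_name[1]
  gc_row <- gc_tbl[gc_tbl$table_name == layer, , drop = FALSE]
  if (nrow(gc_row) == 0) stop("layer not found in GeoPackage: ", layer)
  srs <- DBI::dbGetQuery(con,
    "SELECT srs_name FROM gpkg_spatial_ref_sys WHERE srs_id = :s",
    params = list(s = gc_row$srs_id[1]))
  crs <- if (nrow(srs) > 0) srs$srs_name[1] else "unknown"
  rows <- DBI::dbGetQuery(con, sprintf("SELECT * FROM \"%s\"", layer))
  if (nrow(rows) == 0) stop("empty boundary layer: ", layer)
  if (!"fnid" %in% names(rows)) {
    stop("boundary layer '", layer, "' has no 'fnid' attribute")
  }
  geom_col <- gc_row$column_name[1]
  geoms <- lapply(rows[[geom_col]], gpkg_blob_parse)
  list(rows = rows, geoms = geoms, crs = crs)
}

# ---- GeoJSON read/write ----------------------------------------------------

geom_to_geojson_coords <- function(geom) {
  polys <- rings_to_polygons(geom)
  lapply(polys, function(p) {
    lapply(p, function(ring) {
      n <- length(ring$x)
      coords <- Map(function(x, y) c(x, y),
                    c(ring$x, ring$x[1]), c(ring$y, ring$y[1]))
      coords
    })
  })
}

geojson_coords_to_geom <- function(coords, type) {
  polys <- if (identical(type, "Polygon")) list(coords) else coords
  rings <- list()
  for (p in polys) {
    for (k in seq_along(p)) {
      m <- do.call(rbind, lapply(p[[k]], function(pt) as.numeric(pt[1:2])))
      n <- nrow(m)
      if (all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
      ring <- list(x = m[, 1], y = m[, 2])
      want_positive <- (k == 1L)
      if ((ring_signed_area(ring) > 0) != want_positive) {
        ring <- list(x = rev(ring$x), y = rev(ring$y))
      }
      rings <- c(rings, list(ring))
    }
  }
  rings
}

write_boundaries_geojson <- function(units, path) {
  stopifnot(inherits(units, "admin_units"))
  features <- lapply(seq_len(nrow(units)), function(i) {
    list(
      type = "Feature",
      properties = list(
        fnid = units$fnid[i], country_code = units$country_code[i],
        level = units$level[i], name = units$name[i],
        vintage = units$vintage[i]
      ),
      geometry = list(
        type = "MultiPolygon",
        coordinates = geom_to_geojson_coords(units$geometry[[i]])
      )
    )
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = units_crs(units))),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_boundaries_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (length(fc$features) == 0) stop("empty boundary layer: ", path)
  crs <- tryCatch(fc$crs$properties$name, error = function(e) NULL)
  if (is.null(crs)) crs <- "unknown"
  rows <- dplyr::bind_rows(lapply(fc$features, function(f) {
    p <- f$properties
    tibble(
      fnid = p$fnid %||% NA_character_,
      country_code = p$country_code %||% NA_character_,
      level = as.integer(p$level %||% NA_integer_),
      name = p$name %||% NA_character_,
      vintage = p$vintage %||% NA_character_
    )
  }))
  if (all(is.na(rows$fnid))) stop("boundary layer has no 'fnid' attribute")
  geoms <- lapply(fc$features, function(f) {
    geojson_coords_to_geom(f$geometry$coordinates, f$geometry$type)
  })
  list(rows = rows, geoms = geoms, crs = crs)
}

# ---- unified entry points --------------------------------------------------

#' Read administrative boundaries
#'
#' Reads one boundary vintage from a GeoPackage (`.gpkg`) or GeoJSON
#' (`.geojson`/`.json`) file into an [admin_units] table. Geometries are
#' repaired to validity where trivially repairable (self-intersection
#' decomposition); irreparable geometries abort with the offending `fnid`.
#' The coordinate reference is auto-detected from file metadata and carried
#' as a declared string.
#'
#' @param path Path to a `.gpkg`, `.geojson` or `.json` file.
#' @param layer GeoPackage layer name (default: first geometry layer).
#' @param vintage Optional vintage selector: keep only features whose
#'   `vintage` attribute matches; also used as the vintage label when the
#'   file carries none.
#' @return An [admin_units] tibble.
#' @export
read_boundaries <- function(path, layer = NULL, vintage = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    gpkg = read_boundaries_gpkg(path, layer),
    geojson = ,
    json = read_boundaries_geojson(path),
    stop("unsupported boundary format: .", ext,
         " (use .gpkg or .geojson)")
  )
  rows <- raw$rows
  geoms <- raw$geoms
  if (!is.null(vintage) && "vintage" %in% names(rows) &&
      !all(is.na(rows$vintage))) {
    keep <- rows$vintage == vintage
    if (!any(keep)) stop("no features with vintage '", vintage, "'")
    rows <- rows[keep, , drop = FALSE]
    geoms <- geoms[keep]
  }
  vint <- rows$vintage
  if (is.null(vint) || all(is.na(vint))) {
    vint <- if (is.null(vintage)) "v1" else vintage
  }
  admin_units(
    fnid = as.character(rows$fnid),
    geometry = geoms,
    country_code = if ("country_code" %in% names(rows)) rows$country_code else "XX",
    level = if ("level" %in% names(rows) && !all(is.na(rows$level))) rows$level else 2L,
    name = if ("name" %in% names(rows)) rows$name else as.character(rows$fnid),
    vintage = vint,
    crs = raw$crs
  )
}

#' Write administrative boundaries
#'
#' Counterpart of [read_boundaries()]; the format is chosen from the file
#' extension (`.gpkg` or `.geojson`).
#'
#' @param units An [admin_units] table.
#' @param path Output path.
#' @param layer Layer name for GeoPackage output.
#' @return `path`, invisibly.
#' @export
write_boundaries <- function(units, path, layer = "admin_units") {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    gpkg = write_boundaries_gpkg(units, path, layer),
    geojson = ,
    json = write_boundaries_geojson(units, path),
    stop("unsupported boundary format: .", ext)
  )
}
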