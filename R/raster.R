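# Cropland raster: a regular planar grid of cropland area (hectares) per
# cell, the ancillary surface for dasymetric Case B weights. Stored row 1 =
# northernmost row, matching the Esri ASCII grid convention used for I/O.

#' Cropland raster
#'
#' @param values Numeric matrix of cropland area per cell (ha); row 1 is the
#'   top (maximum y) row. Values must be finite and non-negative (NA allowed,
#'   treated as no data = no cropland).
#' @param xmin,ymin Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length in coordinate units (square cells).
#' @param crs Declared planar coordinate reference string.
#' @return An object of class `cropland_raster`.
#' @export
cropland_raster <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                            crs = "local-equal-area") {
  stopifnot(is.matrix(values), is.numeric(values), cellsize > 0)
  if (any(values < 0, na.rm = TRUE) || any(is.infinite(values))) {
    stop("cropland cell values must be finite and >= 0")
  }
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, crs = crs),
    class = "cropland_raster"
  )
}

#' @export
print.cropland_raster <- function(x, ...) {
  cat("<cropland_raster> ", nrow(x$values), "x", ncol(x$values),
      " cells of ", x$cellsize, " units, origin (", x$xmin, ", ", x$ymin,
      "), crs: ", x$crs, "\n", sep = "")
  invisible(x)
}

raster_extent <- function(r) {
  c(xmin = r$xmin, ymin = r$ymin,
    xmax = r$xmin + ncol(r$values) * r$cellsize,
    ymax = r$ymin + nrow(r$values) * r$cellsize)
}

#' Read a cropland raster from an Esri ASCII grid
#'
#' @param path Path to an `.asc` file (header keys ncols, nrows, xllcorner,
#'   yllcorner, cellsize, optional NODATA_value; rows listed north to south).
#' @param crs Declared coordinate reference of the grid (ASCII grids carry
#'   none; defaults to a sidecar `.prj`-style text file if present).
#' @return A [cropland_raster].
#' @export
read_cropland_raster <- function(path, crs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing_keys <- setdiff(need, names(hdr))
  if (length(missing_keys) > 0) {
    stop("ASCII grid header missing: ", paste(missing_keys, collapse = ", "))
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows)
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  if (is.null(crs)) {
    prj <- paste0(tools::file_path_sans_ext(path), ".prj")
    crs <- if (file.exists(prj)) trimws(readLines(prj, warn = FALSE)[1])
           else "unknown"
  }
  cropland_raster(m, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
                  cellsize = hdr$cellsize, crs = crs)
}

#' Write a cropland raster as an Esri ASCII grid
#'
#' @param raster A [cropland_raster].
#' @param path Output `.asc` path. The declared CRS is written to a sidecar
#'   `.prj` text file.
#' @return `path`, invisibly.
#' @export
write_cropland_raster <- function(raster, path) {
  stopifnot(inherits(raster, "cropland_raster"))
  m <- raster$values
  m[is.na(m)] <- -9999
  hdr <- c(
    paste("ncols", ncol(raster$values)),
    paste("nrows", nrow(raster$values)),
    paste("xllcorner", format(raster$xmin, digits = 17)),
    paste("yllcorner", format(raster$ymin, digits = 17)),
    paste("cellsize", format(raster$cellsize, digits = 17)),
    "NODATA_value -9999"
  )
  body <- apply(m, 1, function(row) {
    paste(format(row, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(c(hdr, body), path)
  writeLines(raster$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Cropland area within a polygon
#'
#' Exact-overlay zonal statistic: each grid cell contributes its cropland
#' area multiplied by the fraction of the cell covered by the polygon, with
#' the covered fraction computed by exact polygon-cell intersection (not
#' centre-point sampling), so small units and slivers are measured correctly.
#'
#' @param raster A [cropland_raster].
#' @param geometry A polygon geometry (list of rings) in the same CRS as the
#'   raster.
#' @param crs Declared CRS of `geometry`; checked against the raster's.
#'   Defaults to the raster CRS (caller asserts they match).
#' @return Cropland area in hectares (>= 0). A geometry disjoint from the
#'   raster extent returns 0 with a warning.
#' @export
zonal_cropland_area <- function(raster, geometry, crs = raster$crs) {
  stopifnot(inherits(raster, "cropland_raster"))
  check_same_crs(raster$crs, crs, "raster and geometry")
  if (length(geometry) == 0) return(0)
  ext <- raster_extent(raster)
  bb <- geom_bbox(geometry)
  if (!bbox_overlaps(ext, bb)) {
    warning("geometry is disjoint from the raster extent; zonal area is 0")
    return(0)
  }
  cs <- raster$cellsize
  nr <- nrow(raster$values); nc <- ncol(raster$values)
  c0 <- max(1L, floor((bb["xmin"] - raster$xmin) / cs) + 1L)
  c1 <- min(nc, ceiling((bb["xmax"] - raster$xmin) / cs))
  ymax <- ext["ymax"]
  r0 <- max(1L, floor((ymax - bb["ymax"]) / cs) + 1L)
  r1 <- min(nr, ceiling((ymax - bb["ymin"]) / cs))
  if (c1 < c0 || r1 < r0) return(0)
  cell_area <- cs * cs
  total <- 0
  for (r in r0:r1) {
    ylo <- ymax - r * cs
    yhi <- ylo + cs
    for (cc in c0:c1) {
      v <- raster$values[r, cc]
      if (is.na(v) || v == 0) next
      xlo <- raster$xmin + (cc - 1L) * cs
      cell <- rect_geometry(xlo, ylo, xlo + cs, yhi)
      frac <- intersection_area(cell, geometry) / cell_area
      if (frac > 0) total <- total + v * frac
    }
  }
  total
}
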