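#' @import rlang
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

# Planar polygon kernel.
#
# A geometry is a list of rings in the polyclip convention: each ring is
# list(x = <numeric>, y = <numeric>) with implicit ring closure. Outer rings
# carry positive signed area, holes negative, once normalised through the
# clipping library. Multi-part geometries are simply several outer rings in
# the same list. All coordinates are assumed planar (equal-area); the CRS is
# tracked as a declared string on container objects, never reprojected.

#' Build a rectangular ring
#'
#' Convenience constructor for axis-aligned rectangle geometries, the building
#' block of gridded administrative fixtures and raster cells.
#'
#' @param xmin,ymin,xmax,ymax Rectangle corners (planar units).
#' @return A geometry: a one-ring list usable wherever the package expects a
#'   polygon.
#' @export
rect_geometry <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  list(list(
    x = c(xmin, xmax, xmax, xmin),
    y = c(ymin, ymin, ymax, ymax)
  ))
}

ring_signed_area <- function(ring) {
  n <- length(ring$x)
  if (n < 3) return(0)
  j <- c(2:n, 1L)
  sum(ring$x * ring$y[j] - ring$x[j] * ring$y) / 2
}

#' Area of a planar geometry
#'
#' Signed shoelace area summed over rings after orientation normalisation,
#' so holes subtract and multi-part geometries add.
#'
#' @param geom A geometry (list of rings).
#' @return Area in squared coordinate units (non-negative).
#' @export
geom_area <- function(geom) {
  if (length(geom) == 0) return(0)
  norm <- polyclip::polysimplify(geom, filltype = "nonzero")
  if (length(norm) == 0) return(0)
  sum(vapply(norm, ring_signed_area, numeric(1)))
}

#' Intersection of two geometries
#'
#' @param a,b Geometries (lists of rings).
#' @return The intersection geometry (possibly empty list).
#' @export
geom_intersection <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero")
}

#' Area of the intersection of two geometries
#' @param a,b Geometries.
#' @return Non-negative area.
#' @export
intersection_area <- function(a, b) {
  if (!bbox_overlaps(geom_bbox(a), geom_bbox(b))) return(0)
  geom_area(geom_intersection(a, b))
}

#' Union of a list of geometries
#' @param geoms List of geometries.
#' @return A single geometry covering the union.
#' @export
geom_union <- function(geoms) {
  geoms <- geoms[lengths(geoms) > 0]
  if (length(geoms) == 0) return(list())
  Reduce(function(a, b) polyclip::polyclip(a, b, op = "union",
                                           fillA = "nonzero", fillB = "nonzero"),
         geoms)
}

geom_bbox <- function(geom) {
  if (length(geom) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
  xs <- unlist(lapply(geom, `[[`, "x"))
  ys <- unlist(lapply(geom, `[[`, "y"))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

bbox_overlaps <- function(a, b) {
  !(is.na(a[1]) || is.na(b[1]) ||
      a["xmax"] <= b["xmin"] || b["xmax"] <= a["xmin"] ||
      a["ymax"] <= b["ymin"] || b["ymax"] <= a["ymin"])
}

# A ring is degenerate/invalid when self-intersecting (signed area of the
# simplified decomposition differs from the raw shoelace) or empty. The
# repair convention mirrors the zero-buffer trick: re-express the point set
# under the nonzero fill rule.
geom_is_valid <- function(geom) {
  if (length(geom) == 0) return(FALSE)
  # signed sum: holes (opposite orientation) subtract; a self-intersecting
  # bowtie collapses towards zero and so differs from its simplification
  raw <- abs(sum(vapply(geom, ring_signed_area, numeric(1))))
  if (raw <= 0) return(FALSE)
  norm <- polyclip::polysimplify(geom, filltype = "nonzero")
  simp <- sum(vapply(norm, ring_signed_area, numeric(1)))
  # tolerance above the clipping library's coordinate-snapping resolution;
  # genuine self-intersections change the simplified area by far more
  isTRUE(abs(raw - simp) <= 1e-6 * max(raw, simp))
}

#' Repair a geometry to validity
#'
#' Self-intersecting rings (e.g. bowties) are decomposed into simple rings
#' under the nonzero fill rule, the planar analogue of the zero-width buffer
#' repair. Geometries that remain empty after repair are reported as
#' irreparable.
#'
#' @param geom A geometry.
#' @return A list with `geometry` (repaired, possibly empty) and `repaired`
#'   (logical: TRUE when the input needed fixing).
#' @export
repair_geometry <- function(geom) {
  if (geom_is_valid(geom)) {
    return(list(geometry = geom, repaired = FALSE))
  }
  norm <- polyclip::polysimplify(geom, filltype = "nonzero")
  list(geometry = norm, repaired = TRUE)
}

#' Administrative unit table
#'
#' Builds the canonical container for one boundary vintage: a tibble with one
#' row per unit, a list-column of planar polygon geometries, and the declared
#' coordinate reference carried as an attribute. Geometries must be valid (or
#' trivially repairable) and unit identifiers unique within the vintage.
#'
#' @param fnid Character vector of unique geographic unit identifiers.
#' @param geometry List of geometries (lists of rings), one per unit.
#' @param country_code ISO 3166-1 alpha-2 code (recycled).
#' @param level Administrative level, 1 or 2 (recycled).
#' @param name Human-readable unit name; defaults to `fnid`.
#' @param vintage Label for the validity interval of this boundary
#'   representation (recycled).
#' @param crs Declared coordinate reference (a string). Must be planar and
#'   equal-area for any area computation to be meaningful.
#' @return A tibble of class `admin_units`.
#' @export
admin_units <- function(fnid, geometry, country_code = "XX", level = 2L,
                        name = fnid, vintage = "v1",
                        crs = "local-equal-area") {
  stopifnot(is.character(fnid), is.list(geometry),
            length(fnid) == length(geometry))
  if (anyDuplicated(fnid)) {
    dup <- unique(fnid[duplicated(fnid)])
    stop("duplicate fnid within one vintage: ", paste(dup, collapse = ", "))
  }
  repaired <- character(0)
  rejected <- character(0)
  geometry <- lapply(seq_along(geometry), function(i) {
    r <- repair_geometry(geometry[[i]])
    if (r$repaired) repaired <<- c(repaired, fnid[i])
    if (length(r$geometry) == 0 || geom_area(r$geometry) <= 0) {
      rejected <<- c(rejected, fnid[i])
    }
    r$geometry
  })
  if (length(rejected) > 0) {
    stop("empty or irreparable geometry for fnid: ",
         paste(rejected, collapse = ", "))
  }
  if (length(repaired) > 0) {
    warning("repaired invalid geometry for fnid: ",
            paste(repaired, collapse = ", "))
  }
  out <- tibble(
    fnid = fnid,
    country_code = rep_len(country_code, length(fnid)),
    level = rep_len(as.integer(level), length(fnid)),
    name = rep_len(name, length(fnid)),
    vintage = rep_len(vintage, length(fnid)),
    geometry = geometry
  )
  attr(out, "crs") <- crs
  class(out) <- c("admin_units", class(out))
  out
}

#' @export
print.admin_units <- function(x, ...) {
  cat("<admin_units> ", nrow(x), " units, vintage ",
      paste(unique(x$vintage), collapse = "/"),
      ", crs: ", attr(x, "crs"), "\n", sep = "")
  NextMethod()
}

units_crs <- function(units) {
  crs <- attr(units, "crs")
  if (is.null(crs)) "unknown" else crs
}

check_same_crs <- function(a_crs, b_crs, what = "layers") {
  if (!identical(a_crs, b_crs)) {
    stop("CRS mismatch between ", what, ": '", a_crs, "' vs '", b_crs,
         "'. Supply both in the same planar equal-area reference.")
  }
  invisible(TRUE)
}
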