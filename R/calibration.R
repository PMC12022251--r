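# Boundary calibration: detect administrative reorganizations between two
# boundary vintages, classify each as Case A (outer boundary conserved, pure
# split or merge: redistribute by post-change mean production shares, which
# leaves yield untouched) or Case B (boundary areas altered: dasymetric
# transfer by cropland-overlap weights), apply the calibration to the
# old-vintage series so that the whole record lands on the current units,
# and verify conservation of totals.

# ---- detection -------------------------------------------------------------

union_find_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Detect and classify boundary changes between two vintages
#'
#' Units whose best-matching counterpart (by intersection area) changes area
#' by less than `area_change_threshold` are passed through 1:1 without
#' calibration. The remaining units are grouped into connected components of
#' the geometric-intersection graph, and each component is classified:
#'
#' * Case A - the union of new geometries coincides with the union of old
#'   geometries (symmetric-difference area at most `sliver_tol` of the union)
#'   AND the component is a pure split (each new unit inside a single old
#'   unit) or a pure merge (each old unit inside a single new unit);
#' * Case B - anything else (internal borders shifted, areas altered).
#'
#' @param old_units,new_units [admin_units] tables in a common planar
#'   equal-area CRS.
#' @param area_change_threshold Relative area change (|new - old| / old) at
#'   or above which a unit participates in calibration (default 0.10).
#' @param sliver_tol Fraction of area treated as a negligible sliver in the
#'   outer-boundary and containment tests (default 0.01).
#' @return An object of class `boundary_changes`: a list with `events` (list
#'   of change events, each carrying `case`, `direction`, `old_fnids`,
#'   `new_fnids`, unit tables and per-unit area-change proportions) and
#'   `passthrough` (tibble of 1:1 old-to-new mappings needing no
#'   calibration).
#' @export
detect_boundary_changes <- function(old_units, new_units,
                                    area_change_threshold = 0.10,
                                    sliver_tol = 0.01) {
  stopifnot(inherits(old_units, "admin_units"),
            inherits(new_units, "admin_units"))
  if (nrow(old_units) == 0 || nrow(new_units) == 0) {
    stop("empty boundary vintage")
  }
  check_same_crs(units_crs(old_units), units_crs(new_units), "vintages")
  n_old <- nrow(old_units); n_new <- nrow(new_units)
  a_old <- vapply(old_units$geometry, geom_area, numeric(1))
  a_new <- vapply(new_units$geometry, geom_area, numeric(1))
  inter <- matrix(0, n_old, n_new)
  for (i in seq_len(n_old)) {
    for (j in seq_len(n_new)) {
      inter[i, j] <- intersection_area(old_units$geometry[[i]],
                                       new_units$geometry[[j]])
    }
  }
  # 1:1 pass-through: mutual best match with sub-threshold area change
  best_new <- apply(inter, 1, which.max)
  best_old <- apply(inter, 2, which.max)
  pass_old <- logical(n_old); pass_new <- logical(n_new)
  pass_rows <- list()
  for (i in seq_len(n_old)) {
    j <- best_new[i]
    if (inter[i, j] <= 0 || best_old[j] != i) next
    change <- abs(a_new[j] - a_old[i]) / a_old[i]
    if (change < area_change_threshold) {
      pass_old[i] <- TRUE; pass_new[j] <- TRUE
      pass_rows[[length(pass_rows) + 1L]] <- tibble::tibble(
        old_fnid = old_units$fnid[i], new_fnid = new_units$fnid[j],
        area_change = change)
    }
  }
  passthrough <- dplyr::bind_rows(pass_rows)
  if (nrow(passthrough) == 0) {
    passthrough <- tibble::tibble(old_fnid = character(0),
                                  new_fnid = character(0),
                                  area_change = numeric(0))
  }
  rem_old <- which(!pass_old); rem_new <- which(!pass_new)
  events <- list()
  if (length(rem_old) > 0 && length(rem_new) > 0) {
    # connected components over the bipartite intersection graph
    ids <- c(paste0("o", rem_old), paste0("n", rem_new))
    parent <- union_find_new(length(ids))
    idx_of <- stats::setNames(seq_along(ids), ids)
    for (i in rem_old) {
      for (j in rem_new) {
        min_a <- min(a_old[i], a_new[j])
        if (inter[i, j] > sliver_tol * min_a) {
          parent <- uf_union(parent, idx_of[paste0("o", i)],
                             idx_of[paste0("n", j)])
        }
      }
    }
    roots <- vapply(seq_along(ids), function(k) uf_find(parent, k), integer(1))
    for (root in unique(roots)) {
      comp <- ids[roots == root]
      oi <- as.integer(sub("^o", "", comp[startsWith(comp, "o")]))
      nj <- as.integer(sub("^n", "", comp[startsWith(comp, "n")]))
      if (length(oi) == 0 || length(nj) == 0) next  # unit vanished/appeared
      u_old <- geom_union(old_units$geometry[oi])
      u_new <- geom_union(new_units$geometry[nj])
      area_u_old <- geom_area(u_old); area_u_new <- geom_area(u_new)
      inter_u <- intersection_area(u_old, u_new)
      union_area <- area_u_old + area_u_new - inter_u
      symdiff <- area_u_old + area_u_new - 2 * inter_u
      outer_conserved <- symdiff <= sliver_tol * union_area
      pure_split <- all(vapply(nj, function(j) {
        max(inter[oi, j]) >= (1 - sliver_tol) * a_new[j]
      }, logical(1)))
      pure_merge <- all(vapply(oi, function(i) {
        max(inter[i, nj]) >= (1 - sliver_tol) * a_old[i]
      }, logical(1)))
      case <- if (outer_conserved && (pure_split || pure_merge)) "A" else "B"
      direction <- if (case == "B") "reorganize"
        else if (pure_split && length(nj) >= length(oi)) "split" else "merge"
      events[[length(events) + 1L]] <- list(
        case = case,
        direction = direction,
        old_fnids = old_units$fnid[oi],
        new_fnids = new_units$fnid[nj],
        old_units = old_units[oi, ],
        new_units = new_units[nj, ],
        area_change = stats::setNames(
          vapply(oi, function(i) {
            j <- best_new[i]
            abs(a_new[j] - a_old[i]) / a_old[i]
          }, numeric(1)),
          old_units$fnid[oi]),
        intersection_areas = {
          m <- inter[oi, nj, drop = FALSE]
          dimnames(m) <- list(old_units$fnid[oi], new_units$fnid[nj])
          m
        }
      )
    }
  }
  structure(list(events = events, passthrough = passthrough),
            class = "boundary_changes")
}

#' @export
print.boundary_changes <- function(x, ...) {
  cat("<boundary_changes> ", length(x$events), " event(s), ",
      nrow(x$passthrough), " pass-through unit(s)\n", sep = "")
  for (e in x$events) {
    cat("  Case ", e$case, " (", e$direction, "): [",
        paste(e$old_fnids, collapse = ", "), "] -> [",
        paste(e$new_fnids, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

# ---- Case A ----------------------------------------------------------------

#' Build a Case A calibration plan
#'
#' For an area-conserving split, the old-unit series is divided among the new
#' units in proportion to their mean quantity produced after the change,
#' computed per crop so that shares reflect each crop's distinct production
#' geography. Means are taken over the post-change years common to all new
#' units' reporting when that intersection is non-empty, else per-unit means
#' with a warning. A new unit that never reports a crop (or an all-zero
#' crop) falls back to cropland-area shares for that crop, with a warning.
#' For a pure merge the plan is the degenerate inverse: the new unit receives
#' the sum of the old series and no shares are needed.
#'
#' @param event A Case A event from [detect_boundary_changes()].
#' @param new_records Crop records observed on the new (post-change) units.
#' @param raster Optional [cropland_raster] used for the cropland-share
#'   fallback.
#' @return A `calibration_plan`: tibble with columns `product`, `new_fnid`,
#'   `share`, `source` ("production" or "cropland"); shares sum to 1 per
#'   product.
#' @export
build_case_a_plan <- function(event, new_records, raster = NULL) {
  stopifnot(event$case == "A")
  if (event$direction == "merge") {
    plan <- tibble::tibble(product = NA_character_,
                           new_fnid = event$new_fnids[1],
                           share = 1, source = "merge")
    return(structure(plan, class = c("calibration_plan", class(plan)),
                     case = "A", direction = "merge", event = event))
  }
  new_ids <- event$new_fnids
  rec <- dplyr::filter(new_records, .data$fnid %in% new_ids)
  products <- unique(rec$product)
  cropland_shares <- function() {
    if (is.null(raster)) {
      stop("cropland raster required for Case A fallback shares ",
           "(a new unit never reports this crop)")
    }
    a <- vapply(seq_along(new_ids), function(k) {
      zonal_cropland_area(raster, event$new_units$geometry[[k]])
    }, numeric(1))
    if (sum(a) == 0) {
      a <- vapply(event$new_units$geometry, geom_area, numeric(1))
    }
    a / sum(a)
  }
  plan <- dplyr::bind_rows(lapply(products, function(p) {
    rp <- rec[rec$product == p & !is.na(rec$production), ]
    # annual production per new unit (seasons/systems summed within year)
    ann <- rp %>%
      dplyr::group_by(.data$fnid, .data$harvest_year) %>%
      dplyr::summarise(production = sum(.data$production), .groups = "drop")
    have <- split(ann$harvest_year, ann$fnid)
    if (!all(new_ids %in% names(have))) {
      warning("new unit(s) never report product '", p,
              "'; falling back to cropland-area shares")
      sh <- cropland_shares()
      return(tibble::tibble(product = p, new_fnid = new_ids, share = sh,
                            source = "cropland"))
    }
    common <- Reduce(intersect, have)
    if (length(common) > 0) {
      ann <- ann[ann$harvest_year %in% common, ]
    } else {
      warning("no common post-change reporting years for product '", p,
              "'; using per-unit means")
    }
    means <- vapply(new_ids, function(u) {
      mean(ann$production[ann$fnid == u])
    }, numeric(1))
    if (sum(means) == 0) {
      warning("all new units report zero production for product '", p,
              "'; falling back to cropland-area shares")
      return(tibble::tibble(product = p, new_fnid = new_ids,
                            share = cropland_shares(), source = "cropland"))
    }
    tibble::tibble(product = p, new_fnid = new_ids,
                   share = unname(means / sum(means)), source = "production")
  }))
  structure(plan, class = c("calibration_plan", class(plan)),
            case = "A", direction = "split", event = event)
}

#' Apply a Case A plan to an old-unit series
#'
#' Multiplies production and area of the old series by each new unit's share,
#' so per-year totals are conserved exactly and every new unit inherits the
#' old unit's yield unchanged. Missing years propagate to all new units.
#'
#' @param plan A Case A `calibration_plan` from [build_case_a_plan()].
#' @param old_series A [stat_series] of the old unit for one product.
#' @param product Product name used to select shares from the plan.
#' @return A named list of [stat_series], one per new unit.
#' @export
apply_case_a <- function(plan, old_series, product = NULL) {
  stopifnot(attr(plan, "case") == "A")
  if (attr(plan, "direction") == "merge") {
    stop("a merge event needs no per-unit shares; use calibrate_records()")
  }
  rows <- if (is.null(product)) {
    plan[!duplicated(plan$new_fnid), ]
  } else {
    plan[plan$product == product, ]
  }
  if (nrow(rows) == 0) stop("plan has no shares for product: ", product)
  if (abs(sum(rows$share) - 1) > 1e-9) {
    stop("Case A shares must sum to 1 (got ", sum(rows$share), ")")
  }
  out <- lapply(seq_len(nrow(rows)), function(k) {
    s <- rows$share[k]
    prod <- old_series$production * s
    area <- old_series$area * s
    yield <- ifelse(!is.na(area) & area > 0 & !is.na(prod),
                    prod / area, old_series$yield)
    key <- old_series$key
    if (!is.null(key)) key$fnid <- rows$new_fnid[k]
    stat_series(old_series$years, production = prod, area = area,
                yield = yield, key = key)
  })
  stats::setNames(out, rows$new_fnid)
}

# ---- Case B ----------------------------------------------------------------

#' Build a Case B calibration plan
#'
#' Dasymetric transfer weights: for each (new unit, intersecting old unit j)
#' pair, w = cropland(new intersect old_j) / cropland(old_j), extracted from
#' the cropland raster by exact zonal overlay. Weights are crop-independent
#' and lie in [0, 1]; an old unit with zero cropland falls back to plain
#' polygon-area ratios with a warning. Disjoint pairs are dropped.
#'
#' @param event A Case B event from [detect_boundary_changes()].
#' @param raster A [cropland_raster] covering all old and new geometries.
#' @return A `calibration_plan`: tibble with columns `new_fnid`, `old_fnid`,
#'   `weight`, `source`.
#' @export
build_case_b_plan <- function(event, raster) {
  stopifnot(event$case == "B", inherits(raster, "cropland_raster"))
  old_ids <- event$old_fnids
  new_ids <- event$new_fnids
  old_crop <- vapply(seq_along(old_ids), function(i) {
    zonal_cropland_area(raster, event$old_units$geometry[[i]])
  }, numeric(1))
  rows <- list()
  for (i in seq_along(old_ids)) {
    gi <- event$old_units$geometry[[i]]
    area_fallback <- old_crop[i] == 0
    if (area_fallback) {
      warning("old unit ", old_ids[i],
              " has zero cropland; using polygon-area ratios")
    }
    denom <- if (area_fallback) geom_area(gi) else old_crop[i]
    for (j in seq_along(new_ids)) {
      gj <- event$new_units$geometry[[j]]
      common <- geom_intersection(gi, gj)
      if (length(common) == 0) next
      numer <- if (area_fallback) geom_area(common)
               else zonal_cropland_area(raster, common)
      if (numer <= 0) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        new_fnid = new_ids[j], old_fnid = old_ids[i],
        weight = min(numer / denom, 1),
        source = if (area_fallback) "polygon-area" else "cropland")
    }
  }
  plan <- dplyr::bind_rows(rows)
  structure(plan, class = c("calibration_plan", class(plan)),
            case = "B", event = event)
}

#' Apply a Case B plan to old-unit series
#'
#' X_new(t) = sum_j w_j X_j(t) for production and area, yield recomputed. If
#' any contributing old unit (weight > 0) is missing at t, the output at t is
#' missing: a partial sum would silently underestimate the new unit.
#'
#' @param plan A Case B `calibration_plan`.
#' @param old_series Named list of [stat_series], one per old fnid appearing
#'   in the plan.
#' @return Named list of [stat_series], one per new unit in the plan.
#' @export
apply_case_b <- function(plan, old_series) {
  stopifnot(attr(plan, "case") == "B")
  new_ids <- unique(plan$new_fnid)
  all_years <- sort(unique(unlist(lapply(old_series, `[[`, "years"))))
  out <- lapply(new_ids, function(u) {
    rows <- plan[plan$new_fnid == u, ]
    missing_contrib <- setdiff(rows$old_fnid, names(old_series))
    if (length(missing_contrib) > 0) {
      stop("no series supplied for contributing old unit(s): ",
           paste(missing_contrib, collapse = ", "))
    }
    combine <- function(stat) {
      vapply(all_years, function(t) {
        total <- 0
        for (k in seq_len(nrow(rows))) {
          s <- old_series[[rows$old_fnid[k]]]
          pos <- match(t, s$years)
          v <- if (is.na(pos)) NA_real_ else s[[stat]][pos]
          if (is.na(v)) return(NA_real_)   # any missing contributor => missing
          total <- total + rows$weight[k] * v
        }
        total
      }, numeric(1))
    }
    prod <- combine("production")
    area <- combine("area")
    yield <- ifelse(!is.na(area) & area > 0 & !is.na(prod),
                    prod / area, NA_real_)
    key <- old_series[[rows$old_fnid[1]]]$key
    if (!is.null(key)) key$fnid <- u
    stat_series(all_years, production = prod, area = area, yield = yield,
                key = key)
  })
  stats::setNames(out, new_ids)
}

# ---- conservation ----------------------------------------------------------

#' Verify conservation of totals across a calibration
#'
#' Compares, per year and product, the total production and area summed over
#' the event's old units before calibration with the totals over the new
#' units after. Case A conserves exactly (shares sum to 1); Case B conserves
#' iff the new units tile the cropland of every old unit (per-old-unit
#' weights sum to 1), and otherwise loses exactly the untiled weight fraction
#' of each old series.
#'
#' @param before Records (or list of [stat_series]) on the old units.
#' @param after Records (or list of [stat_series]) on the new units.
#' @param plan The `calibration_plan` used.
#' @param tol Relative tolerance for the per-old-unit tiling check.
#' @return A tibble with one row per (product, year, statistic):
#'   `total_before`, `total_after`, `rel_discrepancy`, and the event-level
#'   logical `tiling_ok`.
#' @export
verify_conservation <- function(before, after, plan, tol = 1e-9) {
  totals <- function(x) {
    if (inherits(x, "data.frame")) {
      x %>%
        dplyr::group_by(.data$product, year = .data$harvest_year) %>%
        dplyr::summarise(
          production = if (all(is.na(.data$production))) NA_real_
                       else sum(.data$production, na.rm = TRUE),
          area = if (all(is.na(.data$area))) NA_real_
                 else sum(.data$area, na.rm = TRUE),
          .groups = "drop")
    } else {
      dplyr::bind_rows(lapply(x, function(s) {
        tibble::tibble(
          product = if (!is.null(s$key$product)) s$key$product else "all",
          year = s$years, production = s$production, area = s$area)
      })) %>%
        dplyr::group_by(.data$product, .data$year) %>%
        dplyr::summarise(
          production = if (all(is.na(.data$production))) NA_real_
                       else sum(.data$production, na.rm = TRUE),
          area = if (all(is.na(.data$area))) NA_real_
                 else sum(.data$area, na.rm = TRUE),
          .groups = "drop")
    }
  }
  tiling_ok <- if (identical(attr(plan, "case"), "B")) {
    wsum <- plan %>%
      dplyr::group_by(.data$old_fnid) %>%
      dplyr::summarise(w = sum(.data$weight), .groups = "drop")
    all(abs(wsum$w - 1) <= 1e-6)
  } else {
    TRUE
  }
  b <- totals(before); a <- totals(after)
  cmp <- dplyr::full_join(
    tidyr::pivot_longer(b, c("production", "area"),
                        names_to = "statistic", values_to = "total_before"),
    tidyr::pivot_longer(a, c("production", "area"),
                        names_to = "statistic", values_to = "total_after"),
    by = c("product", "year", "statistic"))
  cmp$rel_discrepancy <- ifelse(
    is.na(cmp$total_before) | is.na(cmp$total_after),
    NA_real_,
    abs(cmp$total_after - cmp$total_before) /
      pmax(abs(cmp$total_before), 1e-12))
  cmp$tiling_ok <- tiling_ok
  cmp
}

# ---- record-level orchestration --------------------------------------------

#' Calibrate old-vintage records onto the current boundary vintage
#'
#' End-to-end wrapper: detects boundary changes, builds the Case A or Case B
#' plan for every event, applies it to the old-vintage records, relabels
#' pass-through units, and returns the calibrated records together with the
#' conservation report and a human-readable change log.
#'
#' @param old_records Records keyed to old-vintage fnids (the pre-change
#'   period).
#' @param new_records Records keyed to new-vintage fnids (the post-change
#'   period); used to estimate Case A shares and passed through unchanged.
#' @param old_units,new_units The two boundary vintages.
#' @param raster [cropland_raster] for Case B weights and Case A fallbacks
#'   (optional when all events are Case A without fallback).
#' @param area_change_threshold,sliver_tol See [detect_boundary_changes()].
#' @return A list with `records` (calibrated old period + new period, all on
#'   new-vintage fnids), `conservation` (report tibble), `changes` (the
#'   detected `boundary_changes`), and `log` (character vector).
#' @export
calibrate_records <- function(old_records, new_records, old_units, new_units,
                              raster = NULL, area_change_threshold = 0.10,
                              sliver_tol = 0.01) {
  changes <- detect_boundary_changes(old_units, new_units,
                                     area_change_threshold, sliver_tol)
  log <- character(0)
  out_old <- list()
  reports <- list()
  handled <- character(0)

  # pass-through: relabel fnid, statistics byte-identical
  pt <- changes$passthrough
  if (nrow(pt) > 0) {
    relabel <- stats::setNames(pt$new_fnid, pt$old_fnid)
    keep <- old_records[old_records$fnid %in% pt$old_fnid, ]
    keep$fnid <- unname(relabel[keep$fnid])
    out_old[[length(out_old) + 1L]] <- keep
    handled <- c(handled, pt$old_fnid)
    log <- c(log, sprintf("pass-through (<%.0f%% area change): %s",
                          100 * area_change_threshold,
                          paste(pt$old_fnid, "->", pt$new_fnid,
                                collapse = "; ")))
  }

  for (e in changes$events) {
    ev_records <- old_records[old_records$fnid %in% e$old_fnids, ]
    handled <- c(handled, e$old_fnids)
    if (nrow(ev_records) == 0) next
    series <- records_to_series(ev_records)
    meta <- ev_records[!duplicated(ev_records[c("product", "season_name",
                                                "crop_production_system",
                                                "harvest_year")]), ]
    if (e$case == "A" && e$direction != "merge") {
      plan <- build_case_a_plan(e, new_records, raster)
      log <- c(log, sprintf(
        "Case A split [%s] -> [%s]: production shares per crop",
        paste(e$old_fnids, collapse = ","),
        paste(e$new_fnids, collapse = ",")))
      calibrated <- list()
      for (s in series) {
        p <- s$key$product
        if (!p %in% plan$product) {
          # product never observed post-change: fall back within the plan
          pl <- tibble::tibble(product = p, new_fnid = e$new_fnids,
                               share = case_a_fallback_shares(e, raster),
                               source = "cropland")
          plan2 <- structure(pl, class = class(plan),
                             case = "A", direction = "split", event = e)
          log <- c(log, sprintf(
            "  product '%s' unobserved post-change: cropland shares", p))
          calibrated <- c(calibrated, apply_case_a(plan2, s, p))
        } else {
          calibrated <- c(calibrated, apply_case_a(plan, s, p))
        }
      }
      after <- series_list_to_records(calibrated, meta)
      out_old[[length(out_old) + 1L]] <- after
      reports[[length(reports) + 1L]] <-
        dplyr::mutate(verify_conservation(ev_records, after, plan),
                      case = "A")
    } else if (e$case == "A") {  # merge: new series = sum of old series
      log <- c(log, sprintf("Case A merge [%s] -> %s: summed series",
                            paste(e$old_fnids, collapse = ","),
                            e$new_fnids[1]))
      merged <- merge_series(series, e$new_fnids[1])
      after <- series_list_to_records(merged, meta)
      out_old[[length(out_old) + 1L]] <- after
      plan <- structure(tibble::tibble(), case = "A", direction = "merge")
      reports[[length(reports) + 1L]] <-
        dplyr::mutate(verify_conservation(ev_records, after, plan),
                      case = "A")
    } else {
      if (is.null(raster)) {
        stop("Case B event [", paste(e$old_fnids, collapse = ","),
             "] requires a cropland raster")
      }
      plan <- build_case_b_plan(e, raster)
      log <- c(log, sprintf(
        "Case B [%s] -> [%s]: cropland-overlap weights",
        paste(e$old_fnids, collapse = ","),
        paste(e$new_fnids, collapse = ",")))
      # apply per (product, season, system) across the old units
      key_of <- function(s) paste(s$key$product, s$key$season_name,
                                  s$key$crop_production_system, sep = "\r")
      by_key <- split(series, vapply(series, key_of, character(1)))
      calibrated <- list()
      for (grp in by_key) {
        named <- stats::setNames(grp, vapply(grp, function(s) s$key$fnid,
                                             character(1)))
        sub_plan <- plan[plan$old_fnid %in% names(named), ]
        sub_plan <- structure(sub_plan, class = class(plan),
                              case = "B", event = e)
        calibrated <- c(calibrated, apply_case_b(sub_plan, named))
      }
      after <- series_list_to_records(calibrated, meta)
      out_old[[length(out_old) + 1L]] <- after
      reports[[length(reports) + 1L]] <-
        dplyr::mutate(verify_conservation(ev_records, after, plan),
                      case = "B")
    }
  }

  untouched <- old_records[!old_records$fnid %in% handled, ]
  if (nrow(untouched) > 0) {
    log <- c(log, sprintf(
      "units with no counterpart left on old fnids: %s",
      paste(unique(untouched$fnid), collapse = ", ")))
  }
  records <- dplyr::bind_rows(c(out_old, list(untouched, new_records)))
  conservation <- if (length(reports) > 0) dplyr::bind_rows(reports)
                  else tibble::tibble()
  list(records = records, conservation = conservation,
       changes = changes, log = log)
}

case_a_fallback_shares <- function(event, raster) {
  if (!is.null(raster)) {
    a <- vapply(event$new_units$geometry, function(g) {
      zonal_cropland_area(raster, g)
    }, numeric(1))
    if (sum(a) > 0) return(a / sum(a))
  }
  a <- vapply(event$new_units$geometry, geom_area, numeric(1))
  a / sum(a)
}

merge_series <- function(series, new_fnid) {
  key_of <- function(s) paste(s$key$product, s$key$season_name,
                              s$key$crop_production_system, sep = "\r")
  by_key <- split(series, vapply(series, key_of, character(1)))
  out <- lapply(by_key, function(grp) {
    yrs <- sort(unique(unlist(lapply(grp, `[[`, "years"))))
    combine <- function(stat) {
      vapply(yrs, function(t) {
        vals <- vapply(grp, function(s) {
          pos <- match(t, s$years)
          if (is.na(pos)) NA_real_ else s[[stat]][pos]
        }, numeric(1))
        if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
      }, numeric(1))
    }
    prod <- combine("production")
    area <- combine("area")
    yield <- ifelse(!is.na(area) & area > 0 & !is.na(prod),
                    prod / area, NA_real_)
    key <- grp[[1]]$key
    key$fnid <- new_fnid
    stat_series(yrs, production = prod, area = area, yield = yield, key = key)
  })
  unname(out)
}

# Rebuild record rows from calibrated series, inheriting per-(product,
# season, system, year) metadata (months, country fields) from the source
# records of the event.
series_list_to_records <- function(series_list, meta) {
  rows <- dplyr::bind_rows(lapply(series_list, function(s) {
    tibble::tibble(
      fnid = s$key$fnid,
      product = s$key$product,
      season_name = s$key$season_name,
      crop_production_system = s$key$crop_production_system,
      harvest_year = s$years,
      production = s$production, area = s$area, yield = s$yield
    )
  }))
  rows <- rows[!(is.na(rows$production) & is.na(rows$area) &
                   is.na(rows$yield)), ]
  meta_cols <- meta %>%
    dplyr::select("product", "season_name", "crop_production_system",
                  "harvest_year", "country", "country_code",
                  "planting_year", "planting_month", "harvest_month") %>%
    dplyr::distinct(.data$product, .data$season_name,
                    .data$crop_production_system, .data$harvest_year,
                    .keep_all = TRUE)
  out <- dplyr::left_join(
    rows, meta_cols,
    by = c("product", "season_name", "crop_production_system",
           "harvest_year"))
  out$admin_1 <- out$fnid
  out$admin_2 <- NA_character_
  out$qc_flag <- 0L
  dplyr::select(out, dplyr::all_of(crop_table_columns()))
}
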