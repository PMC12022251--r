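# Pipeline orchestration: quality control -> standardization -> boundary
# calibration -> validation, as one reproducible run with a manifest that
# records the configuration snapshot, input checksums, and per-stage record
# counts. Identical config and inputs give identical outputs.

#' Pipeline configuration
#'
#' Either build in code or load from a YAML file with the same field names.
#' Inputs may be given as file paths (`crop_table`, `boundaries_old`,
#' `boundaries_new`, `cropland`, `reference`, `crop_table_old`/`_new`) or
#' passed as in-memory objects to [run_pipeline()] directly.
#'
#' @param crop_table Path to the input crop CSV (16-column schema), or NULL
#'   when records are passed in memory.
#' @param stages Named logical list toggling `qc`, `standardize`,
#'   `calibrate`, `validate` (each defaults to on when its inputs exist).
#' @param qc A [qc_params()] list.
#' @param smoothing A [smoothing_params()] list.
#' @param coverage A [coverage_params()] list.
#' @param crop_map Optional [crop_mapping()] (or 2-column CSV path) for
#'   sub-crop re-aggregation.
#' @param unit_map Optional named vector (or 2-column CSV path) for
#'   fine-to-coarse aggregation.
#' @param boundaries_old,boundaries_new Paths to the two boundary vintages.
#' @param crop_table_old,crop_table_new Paths to the records of each
#'   reporting period when calibration is run from files.
#' @param cropland Path to the cropland ASCII grid.
#' @param reference Path to the national reference CSV.
#' @param area_change_threshold Calibration trigger (default 0.10).
#' @param min_years Validation overlap rule (default 5).
#' @param out_dir Optional directory for the harmonized CSV, conservation
#'   report, validation report and manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(crop_table = NULL, stages = list(),
                            qc = qc_params(), smoothing = smoothing_params(),
                            coverage = coverage_params(), crop_map = NULL,
                            unit_map = NULL, boundaries_old = NULL,
                            boundaries_new = NULL, crop_table_old = NULL,
                            crop_table_new = NULL, cropland = NULL,
                            reference = NULL, area_change_threshold = 0.10,
                            min_years = 5L, out_dir = NULL) {
  structure(
    list(crop_table = crop_table, stages = stages, qc = qc,
         smoothing = smoothing, coverage = coverage, crop_map = crop_map,
         unit_map = unit_map, boundaries_old = boundaries_old,
         boundaries_new = boundaries_new, crop_table_old = crop_table_old,
         crop_table_new = crop_table_new, cropland = cropland,
         reference = reference,
         area_change_threshold = area_change_threshold,
         min_years = as.integer(min_years), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()] arguments
#'   (numeric parameter groups given as nested maps).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (nm in intersect(names(y), names(cfg))) {
    if (nm %in% c("qc", "smoothing", "coverage")) next
    cfg[[nm]] <- y[[nm]]
  }
  if (!is.null(y$qc)) cfg$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$smoothing)) cfg$smoothing <- do.call(smoothing_params, y$smoothing)
  if (!is.null(y$coverage)) cfg$coverage <- do.call(coverage_params, y$coverage)
  cfg
}

stage_enabled <- function(config, stage, default) {
  v <- config$stages[[stage]]
  if (is.null(v)) default else isTRUE(v)
}

file_checksums <- function(paths) {
  paths <- unlist(paths[!vapply(paths, is.null, logical(1))])
  paths <- paths[vapply(paths, function(p) is.character(p) && file.exists(p),
                        logical(1))]
  if (length(paths) == 0) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the harmonization pipeline
#'
#' Applies the enabled stages in the fixed order quality control ->
#' standardization -> boundary calibration -> validation, and assembles a run
#' manifest whose per-stage record counts reconcile (records out of stage k =
#' records into stage k + 1). With all stages disabled the output is a
#' schema-validated copy of the input.
#'
#' @param config A [pipeline_config()] or path to its YAML form.
#' @param records Optional in-memory records (overrides `config$crop_table`).
#' @param old_units,new_units Optional in-memory boundary vintages.
#' @param raster Optional in-memory [cropland_raster].
#' @param reference Optional in-memory reference tibble.
#' @param records_old,records_new Optional in-memory period tables for
#'   calibration; when absent and calibration is enabled, `records` is split
#'   by membership of its fnids in the two vintages.
#' @return A list with `records` (harmonized table), `conservation`,
#'   `validation`, `changes` and `manifest`. Any stage failure aborts with
#'   the stage name; the partial manifest is attached to the error condition.
#' @export
run_pipeline <- function(config, records = NULL, old_units = NULL,
                         new_units = NULL, raster = NULL, reference = NULL,
                         records_old = NULL, records_new = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cropharmony")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1))],
    input_checksums = file_checksums(config[c(
      "crop_table", "crop_table_old", "crop_table_new", "boundaries_old",
      "boundaries_new", "cropland", "reference")]),
    stages = list()
  )
  fail <- function(stage, e) {
    cond <- simpleError(paste0("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e)))
    cond$manifest <- manifest
    stop(cond)
  }
  run_stage <- function(stage, n_in, expr) {
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    manifest$stages[[stage]] <<- c(list(records_in = n_in),
                                   res$counts %||% list(),
                                   list(records_out = nrow(res$records)))
    res
  }

  # ---- load ----
  if (is.null(records)) {
    if (is.null(config$crop_table)) stop("no input records supplied")
    records <- read_crop_table(config$crop_table, strict = FALSE)
  }
  manifest$stages$load <- list(records_in = nrow(records),
                               records_out = nrow(records))
  viol <- validate_crop_records(records)
  if (nrow(viol) > 0) {
    warning("input records carry ", nrow(viol), " schema violation(s)")
  }

  # ---- qc ----
  if (stage_enabled(config, "qc", TRUE)) {
    st <- run_stage("qc", nrow(records), {
      out <- apply_qc(records, config$qc)
      list(records = out,
           counts = list(flagged_outlier = sum(out$qc_flag == 1L),
                         flagged_low_variance = sum(out$qc_flag == 2L)))
    })
    records <- st$records
  }

  # ---- standardize ----
  do_std <- stage_enabled(config, "standardize",
                          !is.null(config$crop_map) || !is.null(config$unit_map))
  if (do_std) {
    st <- run_stage("standardize", nrow(records), {
      out <- records
      if (!is.null(config$crop_map)) {
        cm <- config$crop_map
        if (is.character(cm) && length(cm) == 1 && file.exists(cm)) {
          cm <- crop_mapping(readr::read_csv(cm, show_col_types = FALSE))
        }
        out <- aggregate_subcrops(out, cm)
      }
      missing_created <- 0L
      if (!is.null(config$unit_map)) {
        um <- config$unit_map
        if (is.character(um) && length(um) == 1 && file.exists(um)) {
          um <- readr::read_csv(um, show_col_types = FALSE)
        }
        out <- aggregate_admin(out, um, coverage = config$coverage,
                               smoothing = config$smoothing)
        cov <- attr(out, "coverage")
        missing_created <- sum(cov$coverage < config$coverage$min_coverage)
      }
      list(records = out, counts = list(missing_created = missing_created))
    })
    records <- st$records
  }

  # ---- calibrate ----
  have_vintages <- (!is.null(old_units) || !is.null(config$boundaries_old)) &&
    (!is.null(new_units) || !is.null(config$boundaries_new))
  conservation <- NULL
  changes <- NULL
  if (stage_enabled(config, "calibrate", have_vintages)) {
    st <- run_stage("calibrate", nrow(records), {
      if (is.null(old_units)) old_units <- read_boundaries(config$boundaries_old)
      if (is.null(new_units)) new_units <- read_boundaries(config$boundaries_new)
      if (is.null(raster) && !is.null(config$cropland)) {
        raster <- read_cropland_raster(config$cropland)
      }
      if (is.null(records_old) && !is.null(config$crop_table_old)) {
        records_old <- apply_qc(read_crop_table(config$crop_table_old),
                                config$qc)
      }
      if (is.null(records_new) && !is.null(config$crop_table_new)) {
        records_new <- apply_qc(read_crop_table(config$crop_table_new),
                                config$qc)
      }
      if (is.null(records_old)) {
        in_old <- records$fnid %in% old_units$fnid &
          !records$fnid %in% new_units$fnid
        records_old <- records[in_old, ]
        records_new <- records[!in_old, ]
      }
      cal <- calibrate_records(records_old, records_new, old_units,
                               new_units, raster,
                               config$area_change_threshold)
      list(records = cal$records,
           counts = list(events = length(cal$changes$events)),
           cal = cal)
    })
    records <- st$records
    conservation <- st$cal$conservation
    changes <- st$cal$changes
  }

  # ---- validate ----
  validation <- NULL
  if (stage_enabled(config, "validate",
                    !is.null(reference) || !is.null(config$reference))) {
    st <- run_stage("validate", nrow(records), {
      if (is.null(reference)) reference <- read_reference_table(config$reference)
      nat <- national_annual_production(records)
      cor_tbl <- correlate_with_reference(nat, reference,
                                          min_years = config$min_years)
      list(records = records,
           counts = list(cells = nrow(cor_tbl),
                         defined_r = sum(!is.na(cor_tbl$r))),
           validation = cor_tbl)
    })
    validation <- st$validation
  }

  result <- list(records = records, conservation = conservation,
                 validation = validation, changes = changes,
                 manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_crop_table(records, file.path(config$out_dir, "harmonized.csv"))
    if (!is.null(conservation) && nrow(conservation) > 0) {
      readr::write_csv(conservation,
                       file.path(config$out_dir, "conservation_report.csv"),
                       na = "")
    }
    if (!is.null(validation)) {
      readr::write_csv(validation,
                       file.path(config$out_dir, "validation_report.csv"),
                       na = "")
    }
    strip_classes <- function(x) {
      if (is.list(x)) lapply(unclass(x), strip_classes) else x
    }
    jsonlite::write_json(strip_classes(manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
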