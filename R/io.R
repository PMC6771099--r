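ADMISSION_COLS <- c("residence_unit", "hospital_unit", "diagnosis_group", "year")
UNIT_COLS <- c("unit_id", "name", "lat", "lon", "population", "beds",
               "designated_region", "micro_region")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Read admission records
#'
#' Reads a CSV of hospitalization records (one row per admission) and keeps
#' the rows matching the configured diagnosis code and, if set, year.
#' Required columns: `residence_unit`, `hospital_unit`, `diagnosis_group`,
#' `year`.
#'
#' @param path Path to the admissions CSV (comma-separated, UTF-8, header
#'   row mandatory).
#' @param config A [study_config()]; its `diagnosis_filter` and
#'   `year_filter` select the records retained.
#' @param quiet Suppress the retained/filtered count message.
#'
#' @return A data frame of admission records with attributes `n_raw` (rows
#'   read) and `n_filtered_out` (rows removed by the diagnosis/year filter).
#' @seealso [read_units()], [validate_dataset()]
#' @export
read_admissions <- function(path, config = study_config(), quiet = FALSE) {
  if (!file.exists(path)) stop("admissions file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", strip.white = TRUE,
                  fileEncoding = "UTF-8")
  check_columns(raw, ADMISSION_COLS, "admissions CSV")
  raw <- raw[ADMISSION_COLS]

  year <- suppressWarnings(as.integer(raw$year))
  bad <- which(is.na(year) | year <= 0 |
                 !nzchar(raw$residence_unit) | !nzchar(raw$hospital_unit))
  if (length(bad) > 0L) {
    stop(sprintf("admissions CSV: unreadable or invalid row(s): %s",
                 paste(head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  raw$year <- year

  keep <- raw$diagnosis_group == config$diagnosis_filter
  if (!is.null(config$year_filter)) keep <- keep & raw$year == config$year_filter
  records <- raw[keep, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "n_raw") <- nrow(raw)
  attr(records, "n_filtered_out") <- nrow(raw) - nrow(records)
  if (!quiet) {
    message(sprintf("read_admissions: %d of %d rows retained (%d filtered out)",
                    nrow(records), nrow(raw), nrow(raw) - nrow(records)))
  }
  records
}

#' Write admission records
#'
#' Companion writer to [read_admissions()]; the round trip preserves the
#' record sequence.
#'
#' @param records Data frame of admission records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path) {
  check_columns(records, ADMISSION_COLS, "admission records")
  write.csv(records[ADMISSION_COLS], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the unit attribute table
#'
#' Reads the per-municipality attribute table: identifier, name, centroid
#' latitude/longitude (decimal degrees), resident population, hospital bed
#' count, and the designated-region and micro-region memberships (empty
#' string when the unit lies outside the designated region). All row-level
#' invariants (unique ids, coordinate ranges, non-negative counts) are
#' checked on read.
#'
#' @param path Path to the units CSV.
#' @return A data frame with columns `unit_id`, `name`, `lat`, `lon`,
#'   `population`, `beds`, `designated_region`, `micro_region`.
#' @export
read_units <- function(path) {
  if (!file.exists(path)) stop("units file not found: ", path, call. = FALSE)
  units <- read.csv(path, colClasses = "character", strip.white = TRUE,
                    fileEncoding = "UTF-8")
  check_columns(units, UNIT_COLS, "units CSV")
  units <- units[UNIT_COLS]
  for (col in c("lat", "lon")) units[[col]] <- as.numeric(units[[col]])
  for (col in c("population", "beds")) units[[col]] <- as.numeric(units[[col]])
  validate_units(units)
  rownames(units) <- NULL
  units
}

validate_units <- function(units) {
  if (anyDuplicated(units$unit_id)) {
    dup <- unique(units$unit_id[duplicated(units$unit_id)])
    stop("units table: duplicate unit_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(units$unit_id))) stop("units table: empty unit_id", call. = FALSE)
  if (any(is.na(units$lat)) || any(units$lat < -90) || any(units$lat > 90)) {
    stop("units table: latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(is.na(units$lon)) || any(units$lon < -180) || any(units$lon > 180)) {
    stop("units table: longitude out of range [-180, 180]", call. = FALSE)
  }
  if (any(is.na(units$population)) || any(units$population < 0)) {
    stop("units table: population must be >= 0", call. = FALSE)
  }
  if (any(is.na(units$beds)) || any(units$beds < 0)) {
    stop("units table: beds must be >= 0", call. = FALSE)
  }
  invisible(units)
}

#' Write the unit attribute table
#' @param units Unit table as returned by [read_units()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_units <- function(units, path) {
  check_columns(units, UNIT_COLS, "units table")
  write.csv(units[UNIT_COLS], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate admission records against the unit table
#'
#' Cross-checks the two inputs before any matrix is built: every residence
#' and hospital identifier must resolve to a known unit. In `"strict"` mode
#' (default) unknown identifiers abort the run; in `"lenient"` mode the
#' offending records are dropped and reported. Units that appear in the
#' table but in no record are listed as inactive — an observation, not an
#' error.
#'
#' @param records Admission records ([read_admissions()]).
#' @param units Unit table ([read_units()]).
#' @param mode `"strict"` or `"lenient"`.
#' @param quiet Suppress the lenient-mode drop message.
#'
#' @return A list with `records` (clean records) and `report`, a list with
#'   `n_records`, `unknown_units` (offending identifiers), `n_dropped`,
#'   `inactive_units` and `mode`. Write it with [write_validation_report()].
#' @export
validate_dataset <- function(records, units, mode = c("strict", "lenient"),
                             quiet = FALSE) {
  mode <- match.arg(mode)
  check_columns(records, ADMISSION_COLS, "admission records")
  known <- units$unit_id
  bad <- !(records$residence_unit %in% known) | !(records$hospital_unit %in% known)
  unknown_ids <- sort(unique(c(
    setdiff(records$residence_unit, known),
    setdiff(records$hospital_unit, known)
  )))
  if (any(bad) && mode == "strict") {
    stop("validate_dataset: records reference unknown unit id(s): ",
         paste(unknown_ids, collapse = ", "),
         " (use mode = \"lenient\" to drop them)", call. = FALSE)
  }
  clean <- records[!bad, , drop = FALSE]
  rownames(clean) <- NULL
  if (any(bad) && !quiet) {
    message(sprintf("validate_dataset: dropped %d record(s) with unknown unit ids",
                    sum(bad)))
  }
  active <- unique(c(clean$residence_unit, clean$hospital_unit))
  list(
    records = clean,
    report = list(
      mode = mode,
      n_records = nrow(records),
      unknown_units = unknown_ids,
      n_dropped = sum(bad),
      inactive_units = sort(setdiff(known, active))
    )
  )
}

#' Write a validation report as JSON
#' @param report The `report` element of [validate_dataset()]'s result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
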