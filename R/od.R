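#' Origin-destination matrix constructor
#'
#' Wraps a square non-negative integer matrix of patient counts, rows
#' indexed by residence unit (origin) and columns by hospitalization unit
#' (destination), together with filter provenance.
#'
#' @param counts Square numeric matrix with identical row and column names.
#' @param filter_applied Character description of any origin filter already
#'   applied, or `NULL`.
#' @param dropped Number of records removed by filtering.
#' @return An object of class `od_matrix`.
#' @export
od_matrix <- function(counts, filter_applied = NULL, dropped = 0L) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (is.null(rownames(counts)) || !identical(rownames(counts), colnames(counts))) {
    stop("od_matrix: counts must carry identical row and column names", call. = FALSE)
  }
  if (any(counts < 0)) stop("od_matrix: negative counts", call. = FALSE)
  structure(
    list(counts = counts, unit_ids = rownames(counts),
         filter_applied = filter_applied, dropped = as.integer(dropped)),
    class = "od_matrix"
  )
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("Origin-destination matrix: %d units, %d patients (%d cross-border)\n",
              length(x$unit_ids), sum(x$counts),
              sum(x$counts) - sum(diag(x$counts))))
  if (!is.null(x$filter_applied)) cat("  filter:", x$filter_applied, "\n")
  if (x$dropped > 0L) cat("  records dropped by filter:", x$dropped, "\n")
  invisible(x)
}

#' Units acting as hospital destinations
#'
#' @param od An `od_matrix`.
#' @return Unit ids with positive column sums (at least one admission).
#' @export
hospital_units <- function(od) {
  od$unit_ids[colSums(od$counts) > 0]
}

#' Build the origin-destination matrix from admission records
#'
#' Entry (i, j) counts the patients residing in unit i hospitalized in
#' unit j; the grand total equals the number of records. The matrix is
#' square over all units in the unit table, so units without flows appear
#' as zero rows/columns.
#'
#' @param records Admission records (validated against `units`).
#' @param units Unit table; defines the matrix order.
#' @return An [od_matrix()].
#' @export
build_od_matrix <- function(records, units) {
  check_columns(records, c("residence_unit", "hospital_unit"), "admission records")
  ids <- units$unit_id
  unknown <- sort(unique(c(
    setdiff(records$residence_unit, ids),
    setdiff(records$hospital_unit, ids)
  )))
  if (length(unknown) > 0L) {
    stop("build_od_matrix: records reference unknown unit id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(records$residence_unit, levels = ids),
                  factor(records$hospital_unit, levels = ids))
  counts <- matrix(as.integer(counts), nrow = length(ids),
                   dimnames = list(ids, ids))
  od_matrix(counts)
}

#' Drop origins with insignificant flows into the study hospitals
#'
#' Zeroes the rows of origins whose total flow into `hospital_set` does
#' not exceed `min_sent` ("more than" is strict: an origin sending exactly
#' `min_sent` patients is removed). Origins that are themselves members of
#' `hospital_set` are always retained. With `per_edge = TRUE` the rule is
#' instead applied to each origin-hospital edge separately.
#'
#' @param od An [od_matrix()].
#' @param hospital_set Unit ids of the study hospitals (defaults to all
#'   units with admissions).
#' @param min_sent Strict threshold; default 5.
#' @param per_edge Apply the threshold per edge rather than per origin.
#' @return A filtered [od_matrix()] with provenance in `filter_applied`
#'   and the removed patient count in `dropped`.
#' @export
apply_origin_filter <- function(od, hospital_set = hospital_units(od),
                                min_sent = 5L, per_edge = FALSE) {
  stopifnot(inherits(od, "od_matrix"))
  if (!all(hospital_set %in% od$unit_ids)) {
    stop("apply_origin_filter: hospital_set contains unknown unit ids", call. = FALSE)
  }
  counts <- od$counts
  before <- sum(counts)
  if (per_edge) {
    sub <- counts[, hospital_set, drop = FALSE]
    sub[sub <= min_sent & !(rownames(counts) %in% hospital_set)] <- 0L
    counts[, hospital_set] <- sub
    rule <- sprintf("edges into {%d hospitals} with count <= %d zeroed",
                    length(hospital_set), min_sent)
  } else {
    sent <- rowSums(counts[, hospital_set, drop = FALSE])
    drop_rows <- sent <= min_sent & !(rownames(counts) %in% hospital_set)
    counts[drop_rows, ] <- 0L
    rule <- sprintf("origins sending <= %d patients into {%d hospitals} removed (%d origins)",
                    min_sent, length(hospital_set), sum(drop_rows))
  }
  od_matrix(counts, filter_applied = rule,
            dropped = od$dropped + before - sum(counts))
}

#' Migration intensity in the origin
#'
#' Converts counts into the proportion of each origin's cases going to
#' each destination (row-normalized OD matrix). Origins with no cases have
#' undefined rows (`NA`), flagged in the `undefined_origins` attribute.
#'
#' @param od An [od_matrix()].
#' @return A numeric matrix of proportions; defined rows sum to 1.
#' @export
migration_intensity <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  totals <- rowSums(od$counts)
  out <- od$counts / ifelse(totals > 0, totals, NA_real_)
  attr(out, "undefined_origins") <- od$unit_ids[totals == 0]
  out
}

#' Cross-border admission summary
#'
#' For the residents of `scope`, counts total hospitalizations, those in a
#' municipality different from the residence (cross-border), and the
#' cross-border proportion.
#'
#' @param od An [od_matrix()].
#' @param scope Unit ids whose residents are summarized.
#' @return A list with `total`, `cross_border`, `proportion_pct`
#'   (percentage, full precision) and `proportion_pct_1dp` (rounded to one
#'   decimal, the reporting convention).
#' @export
cross_border_summary <- function(od, scope = od$unit_ids) {
  stopifnot(inherits(od, "od_matrix"))
  if (length(scope) == 0L) stop("cross_border_summary: empty scope", call. = FALSE)
  if (!all(scope %in% od$unit_ids)) {
    stop("cross_border_summary: scope contains unknown unit ids", call. = FALSE)
  }
  total <- sum(od$counts[scope, , drop = FALSE])
  local <- sum(od$counts[cbind(scope, scope)])
  cb <- total - local
  pct <- if (total > 0) 100 * cb / total else NA_real_
  list(total = total, cross_border = cb,
       proportion_pct = pct,
       proportion_pct_1dp = round(pct, 1))
}

#' Delineate the functional region
#'
#' The functional (data-derived) region is the union of the designated
#' units and every outside origin that sends more than `min_sent` patients
#' into the designated hospitals — the region the flows actually draw, as
#' opposed to the administrative one.
#'
#' @param od An [od_matrix()].
#' @param designated_hospitals Hospital unit ids of the designated region.
#' @param min_sent Strict flow threshold (default 5, i.e. at least 6).
#' @param designated_units All units of the designated region (defaults to
#'   `designated_hospitals`).
#' @return Sorted character vector of unit ids.
#' @export
delineate_functional_region <- function(od, designated_hospitals,
                                        min_sent = 5L,
                                        designated_units = designated_hospitals) {
  stopifnot(inherits(od, "od_matrix"))
  if (!all(designated_hospitals %in% od$unit_ids)) {
    stop("delineate_functional_region: unknown hospital unit ids", call. = FALSE)
  }
  sent <- rowSums(od$counts[, designated_hospitals, drop = FALSE])
  senders <- od$unit_ids[sent > min_sent]
  sort(union(designated_units, senders))
}

#' Write an OD matrix to CSV
#'
#' Writes the long form (origin, destination, count; non-zero entries
#' only) or the labelled square matrix, plus a JSON sidecar with the
#' filter provenance.
#'
#' @param od An [od_matrix()].
#' @param path Output CSV path.
#' @param format `"long"` or `"matrix"`.
#' @param sidecar Write `<path>.json` with provenance (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_od_matrix <- function(od, path, format = c("long", "matrix"),
                            sidecar = TRUE) {
  format <- match.arg(format)
  if (format == "long") {
    idx <- which(od$counts > 0, arr.ind = TRUE)
    long <- data.frame(
      origin = od$unit_ids[idx[, 1]],
      destination = od$unit_ids[idx[, 2]],
      count = od$counts[idx]
    )
    long <- long[order(long$origin, long$destination), , drop = FALSE]
    write.csv(long, path, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(data.frame(origin = od$unit_ids, od$counts, check.names = FALSE),
              path, row.names = FALSE, quote = FALSE)
  }
  if (sidecar) {
    jsonlite::write_json(
      list(filter_applied = od$filter_applied %||% "none",
           dropped = od$dropped, total = sum(od$counts)),
      paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
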