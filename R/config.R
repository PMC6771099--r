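#' Study configuration
#'
#' Bundles the analysis parameters shared across the pipeline: which
#' diagnosis code and year to keep, the minimum-flow filter for origins,
#' the sufficiency threshold applied to the LIFO/LOFI pair, the sphere
#' radius used for centroid distances, and the seed for any stochastic
#' step.
#'
#' @param diagnosis_filter Diagnosis code kept by [read_admissions()]
#'   (exact string match on the `diagnosis_group` column). Default `"XV"`,
#'   the ICD-10 chapter for pregnancy, childbirth and the puerperium.
#' @param year_filter Integer year to keep, or `NULL` for all years.
#' @param min_sent_patients Origins sending this many patients or fewer
#'   into the study hospitals are dropped ("more than" is strict, so the
#'   default 5 keeps origins sending at least 6).
#' @param sufficiency_threshold Percentage both LIFO and LOFI must
#'   strictly exceed for a unit or set to be labelled sufficient.
#' @param earth_radius_km Sphere radius for great-circle distances, in km.
#' @param random_seed Integer seed for stochastic steps.
#'
#' @return An object of class `study_config`.
#' @examples
#' study_config(year_filter = 2012)
#' @export
study_config <- function(diagnosis_filter = "XV",
                         year_filter = NULL,
                         min_sent_patients = 5L,
                         sufficiency_threshold = 75,
                         earth_radius_km = 6371.0088,
                         random_seed = 1L) {
  stopifnot(
    is.character(diagnosis_filter), length(diagnosis_filter) == 1L,
    is.null(year_filter) || (is.numeric(year_filter) && length(year_filter) == 1L),
    is.numeric(min_sent_patients), min_sent_patients >= 0,
    is.numeric(sufficiency_threshold),
    sufficiency_threshold > 0, sufficiency_threshold < 100,
    is.numeric(earth_radius_km), earth_radius_km > 0
  )
  structure(
    list(
      diagnosis_filter = diagnosis_filter,
      year_filter = if (is.null(year_filter)) NULL else as.integer(year_filter),
      min_sent_patients = as.integer(min_sent_patients),
      sufficiency_threshold = as.numeric(sufficiency_threshold),
      earth_radius_km = as.numeric(earth_radius_km),
      random_seed = as.integer(random_seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  diagnosis filter     :", x$diagnosis_filter, "\n")
  cat("  year filter          :", if (is.null(x$year_filter)) "(all years)" else x$year_filter, "\n")
  cat("  min sent patients    : >", x$min_sent_patients, "\n")
  cat("  sufficiency threshold: >", x$sufficiency_threshold, "%\n")
  cat("  earth radius         :", x$earth_radius_km, "km\n")
  cat("  random seed          :", x$random_seed, "\n")
  invisible(x)
}
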