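#' LIFO and LOFI coefficients for a unit or unit set
#'
#' Elzinga-Hogarty market-delineation coefficients, treating `subject` as
#' a single aggregate:
#'
#' * LIFO ("little in from outside") = (1 - inflow / H) x 100, where H is
#'   the total hospitalizations occurring inside the subject and inflow
#'   the part of H contributed by residents of outside units. Undefined
#'   when H = 0 (no hospital activity).
#' * LOFI ("little out from inside") = (1 - outflow / R) x 100, where R is
#'   the total hospitalizations of the subject's residents and outflow the
#'   part of R occurring outside. Undefined when R = 0.
#'
#' Flows are aggregated before the ratio: the coefficients of a set are
#' not averages of its members' coefficients.
#'
#' @param od An [od_matrix()].
#' @param subject Non-empty set of unit ids.
#' @return Named numeric vector `c(lifo = , lofi = )`, in percent;
#'   `NA` where undefined.
#' @examples
#' # a town treating 66 of its 100 resident patients locally, receiving
#' # nobody from outside: LIFO 100, LOFI 66
#' m <- matrix(c(66, 34, 0, 0), 2, 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' lifo_lofi(od_matrix(m), "A")
#' @export
lifo_lofi <- function(od, subject) {
  stopifnot(inherits(od, "od_matrix"))
  if (length(subject) == 0L) stop("lifo_lofi: empty subject", call. = FALSE)
  if (!all(subject %in% od$unit_ids)) {
    stop("lifo_lofi: subject contains unknown unit ids", call. = FALSE)
  }
  counts <- od$counts
  outside <- setdiff(od$unit_ids, subject)

  H <- sum(counts[, subject, drop = FALSE])
  inflow <- sum(counts[outside, subject, drop = FALSE])
  lifo <- if (H > 0) (1 - inflow / H) * 100 else NA_real_

  R <- sum(counts[subject, , drop = FALSE])
  outflow <- sum(counts[subject, outside, drop = FALSE])
  lofi <- if (R > 0) (1 - outflow / R) * 100 else NA_real_

  c(lifo = lifo, lofi = lofi)
}

#' Classify sufficiency from a LIFO/LOFI pair
#'
#' A subject is `"Sufficient"` only when both coefficients are defined and
#' both strictly exceed the threshold on their unrounded values (reports
#' print rounded percentages, but the decision never uses them). If either
#' coefficient is undefined the label is `"Undefined"`; otherwise
#' `"Insufficient"`.
#'
#' @param lifo_pct,lofi_pct Percentages in `[0, 100]` or `NA`.
#' @param threshold_pct Strict threshold, default 75.
#' @return `"Sufficient"`, `"Insufficient"` or `"Undefined"`.
#' @export
classify_sufficiency <- function(lifo_pct, lofi_pct, threshold_pct = 75) {
  stopifnot(threshold_pct > 0, threshold_pct < 100)
  if (is.na(lifo_pct) || is.na(lofi_pct)) return("Undefined")
  if (lifo_pct > threshold_pct && lofi_pct > threshold_pct) "Sufficient" else "Insufficient"
}

suff_row <- function(od, subject, label_subject, level, threshold_pct) {
  co <- lifo_lofi(od, subject)
  data.frame(
    subject = label_subject,
    level = level,
    n_units = length(subject),
    lifo_pct = unname(co["lifo"]),
    lofi_pct = unname(co["lofi"]),
    lifo_rounded = round(unname(co["lifo"])),
    lofi_rounded = round(unname(co["lofi"])),
    label = classify_sufficiency(co["lifo"], co["lofi"], threshold_pct),
    stringsAsFactors = FALSE
  )
}

#' Hierarchical sufficiency table
#'
#' Reproduces the classic three-level sufficiency report: one row per
#' municipality with hospitalization (positive column sum — units with
#' beds but no admissions are excluded), one aggregate row per
#' micro-region, and one per designated region. Percentages are carried at
#' full precision with rounded companions for display.
#'
#' @param od An [od_matrix()].
#' @param units Unit table; `micro_region` and `designated_region` must be
#'   populated for the designated units.
#' @param threshold_pct Strict sufficiency threshold, default 75.
#' @return Data frame with columns `subject`, `level` (`municipality`,
#'   `micro_region`, `region`), `n_units`, `lifo_pct`, `lofi_pct`,
#'   `lifo_rounded`, `lofi_rounded`, `label`.
#' @export
sufficiency_table <- function(od, units, threshold_pct = 75) {
  stopifnot(inherits(od, "od_matrix"))
  ids <- intersect(units$unit_id, od$unit_ids)
  with_hosp <- ids[colSums(od$counts[, ids, drop = FALSE]) > 0]

  rows <- lapply(with_hosp, function(u)
    suff_row(od, u, u, "municipality", threshold_pct))

  micro <- units$micro_region[match(ids, units$unit_id)]
  for (m in sort(unique(micro[nzchar(micro)]))) {
    members <- ids[!is.na(micro) & micro == m]
    rows <- c(rows, list(suff_row(od, members, m, "micro_region", threshold_pct)))
  }

  region <- units$designated_region[match(ids, units$unit_id)]
  for (r in sort(unique(region[nzchar(region)]))) {
    members <- ids[!is.na(region) & region == r]
    rows <- c(rows, list(suff_row(od, members, r, "region", threshold_pct)))
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Successive enlargement of a sufficiency area
#'
#' Iterative delimitation of a self-sufficient area: starting from
#' `seed_set`, while the current set fails the paired LIFO/LOFI criterion,
#' add the outside unit with the strongest link to the set and re-test.
#' The default link measure is the total exchanged flow (patients sent
#' into plus received from the set); alternatives are in-flow only or
#' centroid distance to the set. Ties break lexicographically by unit id.
#' The procedure stops when the set is sufficient, when no outside unit
#' has a positive exchange (distance ranking excepted), or when all units
#' are absorbed.
#'
#' @param od An [od_matrix()].
#' @param seed_set Non-empty initial set of unit ids.
#' @param threshold_pct Strict sufficiency threshold, default 75.
#' @param rank_by Candidate ranking: `"exchange"` (default), `"inflow"`,
#'   or `"distance"` (nearest centroid; requires `units`).
#' @param units Unit table, only needed for `rank_by = "distance"`.
#' @param radius_km Sphere radius for the distance ranking.
#' @return A list with `final_set` (unit ids), `label` (the final
#'   classification) and `trace`, a data frame with one row per evaluated
#'   set (`step`, `added` — `NA` for the seed row —, `lifo_pct`,
#'   `lofi_pct`, `label`).
#' @examples
#' m <- matrix(c(66, 34, 0, 0, 50, 0, 0, 10, 40), 3, 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' frech_enlarge(od_matrix(m), "A")
#' @export
frech_enlarge <- function(od, seed_set, threshold_pct = 75,
                          rank_by = c("exchange", "inflow", "distance"),
                          units = NULL, radius_km = 6371.0088) {
  stopifnot(inherits(od, "od_matrix"))
  rank_by <- match.arg(rank_by)
  if (length(seed_set) == 0L) stop("frech_enlarge: empty seed set", call. = FALSE)
  if (!all(seed_set %in% od$unit_ids)) {
    stop("frech_enlarge: seed set contains unknown unit ids", call. = FALSE)
  }
  if (rank_by == "distance" && is.null(units)) {
    stop("frech_enlarge: rank_by = \"distance\" requires the unit table", call. = FALSE)
  }

  current <- sort(unique(seed_set))
  trace <- list()
  step <- 0L
  added <- NA_character_
  repeat {
    co <- lifo_lofi(od, current)
    label <- classify_sufficiency(co["lifo"], co["lofi"], threshold_pct)
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, added = added,
      lifo_pct = unname(co["lifo"]), lofi_pct = unname(co["lofi"]),
      label = label, stringsAsFactors = FALSE)
    if (label == "Sufficient") break
    outside <- setdiff(od$unit_ids, current)
    if (length(outside) == 0L) break
    score <- switch(rank_by,
      exchange = rowSums(od$counts[outside, current, drop = FALSE]) +
                 colSums(od$counts[current, outside, drop = FALSE]),
      inflow   = rowSums(od$counts[outside, current, drop = FALSE]),
      distance = {
        io <- match(outside, units$unit_id)
        ic <- match(current, units$unit_id)
        d <- geosphere::distm(cbind(units$lon[io], units$lat[io]),
                              cbind(units$lon[ic], units$lat[ic]),
                              fun = geosphere::distHaversine) * radius_km / 6378137
        -apply(d, 1L, min)  # nearest first
      })
    if (rank_by != "distance" && max(score) <= 0) break
    # max score, ties lexicographic: outside is not sorted, so sort first
    ord <- order(-score, outside)
    added <- outside[ord[1L]]
    current <- sort(c(current, added))
    step <- step + 1L
  }
  co <- lifo_lofi(od, current)
  list(final_set = current,
       label = classify_sufficiency(co["lifo"], co["lofi"], threshold_pct),
       trace = do.call(rbind, trace))
}

#' Write a sufficiency table to CSV
#' @param tab Result of [sufficiency_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sufficiency_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an enlargement trace as JSON
#' @param enlargement Result of [frech_enlarge()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_enlargement_trace <- function(enlargement, path) {
  jsonlite::write_json(
    list(final_set = enlargement$final_set, label = enlargement$label,
         trace = enlargement$trace),
    path, auto_unbox = TRUE, pretty = TRUE, dataframe = "rows", na = "null")
  invisible(path)
}
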