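#' Great-circle distance between two points
#'
#' Haversine distance on a sphere. Municipal centroids stand in for true
#' patient locations, so sub-kilometre ellipsoidal corrections are
#' pointless at this scale; the radius is configurable all the same.
#'
#' @param a,b Points as `c(lat, lon)` in decimal degrees.
#' @param radius_km Sphere radius in km (default 6371.0088, the IUGG mean
#'   Earth radius).
#' @return Distance in km.
#' @examples
#' haversine_km(c(0, 0), c(0, 1))  # one degree of longitude at the equator
#' @export
haversine_km <- function(a, b, radius_km = 6371.0088) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  if (any(!is.finite(c(a, b))) ||
      abs(a[1]) > 90 || abs(b[1]) > 90 || abs(a[2]) > 180 || abs(b[2]) > 180) {
    stop("haversine_km: invalid coordinates", call. = FALSE)
  }
  # geosphere wants (lon, lat) and works in the radius' own unit
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]), r = radius_km)
}

#' Pairwise centroid distance matrix for a unit table
#'
#' @param units Unit table ([read_units()]).
#' @param radius_km Sphere radius in km.
#' @return Symmetric matrix of km distances with unit ids as dimnames.
#' @export
unit_distances_km <- function(units, radius_km = 6371.0088) {
  pts <- cbind(units$lon, units$lat)
  d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 6378137 * radius_km
  dimnames(d) <- list(units$unit_id, units$unit_id)
  d
}

#' Displacement statistics: hub-bound versus other cross-border flows
#'
#' Mean centroid distance travelled by patients who leave their residence
#' municipality, split between flows ending at the hub and all other
#' cross-border flows. Means are weighted by patient counts; self-flows
#' (zero displacement by construction) are excluded.
#'
#' @param od An [od_matrix()].
#' @param units Unit table with centroids for every matrix unit.
#' @param hub Unit id of the hub.
#' @param radius_km Sphere radius in km.
#' @return A list with `hub_mean_km`, `other_mean_km` (NA when the
#'   corresponding flow class is empty, flagged in `undefined`),
#'   `hub_patients`, `other_patients`.
#' @export
displacement_stats <- function(od, units, hub, radius_km = 6371.0088) {
  stopifnot(inherits(od, "od_matrix"))
  if (!hub %in% od$unit_ids) stop("displacement_stats: unknown hub: ", hub, call. = FALSE)
  if (!all(od$unit_ids %in% units$unit_id)) {
    stop("displacement_stats: units table lacks some matrix units", call. = FALSE)
  }
  d <- unit_distances_km(units, radius_km)[od$unit_ids, od$unit_ids]
  off <- od$counts
  diag(off) <- 0L
  idx <- which(off > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(list(hub_mean_km = NA_real_, other_mean_km = NA_real_,
                hub_patients = 0L, other_patients = 0L,
                undefined = c("hub", "other")))
  }
  w <- off[idx]
  dist_km <- d[idx]
  to_hub <- od$unit_ids[idx[, 2]] == hub
  hub_mean <- if (any(to_hub)) weighted.mean(dist_km[to_hub], w[to_hub]) else NA_real_
  other_mean <- if (any(!to_hub)) weighted.mean(dist_km[!to_hub], w[!to_hub]) else NA_real_
  list(hub_mean_km = hub_mean, other_mean_km = other_mean,
       hub_patients = sum(w[to_hub]), other_patients = sum(w[!to_hub]),
       undefined = c(if (!any(to_hub)) "hub", if (!any(!to_hub)) "other"))
}

#' Expected births per unit
#'
#' Reference column for reports: the number of births each unit's
#' population would produce at the regional crude birth rate.
#'
#' @param units Unit table.
#' @param regional_birth_rate Births per inhabitant per year.
#' @return Data frame with `unit_id` and `expected_births`.
#' @export
expected_births <- function(units, regional_birth_rate) {
  stopifnot(regional_birth_rate > 0)
  data.frame(unit_id = units$unit_id,
             expected_births = units$population * regional_birth_rate)
}

#' Catchment area of a destination, by intensity quartile
#'
#' The catchment of a destination is the set of origins sending it
#' patients, graded by migration intensity (the share of the origin's
#' cases going there). Quartile boundaries are the 25/50/75 percentiles
#' of the observed intensities (linear interpolation), computed per
#' destination; intensities tied with a boundary fall in the lower
#' quartile, so a fully degenerate catchment is all Q1.
#'
#' @param od An [od_matrix()].
#' @param destination Unit id with positive in-flow.
#' @return Object of class `catchment_map`: data frame with `origin`,
#'   `intensity`, `quartile` (`"Q1"`..`"Q4"`, Q4 = highest), plus the
#'   destination and boundaries as attributes.
#' @export
catchment_quartiles <- function(od, destination) {
  stopifnot(inherits(od, "od_matrix"))
  if (!destination %in% od$unit_ids) {
    stop("catchment_quartiles: unknown destination: ", destination, call. = FALSE)
  }
  inflow <- od$counts[, destination]
  if (sum(inflow) == 0) {
    stop("catchment_quartiles: destination has no in-flow: ", destination,
         call. = FALSE)
  }
  origins <- od$unit_ids[inflow > 0]
  intensity <- inflow[origins] / rowSums(od$counts)[origins]
  q <- quantile(intensity, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  quartile <- paste0("Q", findInterval(intensity, q, left.open = TRUE) + 1L)
  out <- data.frame(origin = origins, intensity = unname(intensity),
                    quartile = quartile, row.names = NULL)
  attr(out, "destination") <- destination
  attr(out, "boundaries") <- q
  class(out) <- c("catchment_map", "data.frame")
  out
}

#' Export a catchment map
#'
#' Writes the catchment as CSV and/or GeoJSON (point features at origin
#' centroids with `intensity` and `quartile` properties).
#'
#' @param catchment A [catchment_quartiles()] result.
#' @param units Unit table with centroids (needed for GeoJSON).
#' @param csv Optional CSV path.
#' @param geojson Optional GeoJSON path.
#' @return Invisibly, the paths written.
#' @export
write_catchment <- function(catchment, units = NULL, csv = NULL, geojson = NULL) {
  if (!is.null(csv)) {
    out <- as.data.frame(catchment)
    out$destination <- attr(catchment, "destination")
    write.csv(out, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(geojson)) {
    if (is.null(units)) stop("write_catchment: GeoJSON export needs the unit table",
                             call. = FALSE)
    i <- match(catchment$origin, units$unit_id)
    features <- lapply(seq_len(nrow(catchment)), function(k) {
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(units$lon[i[k]], units$lat[i[k]])),
        properties = list(origin = catchment$origin[k],
                          destination = attr(catchment, "destination"),
                          intensity = catchment$intensity[k],
                          quartile = catchment$quartile[k])
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = features),
                         geojson, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(csv = csv, geojson = geojson))
}
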