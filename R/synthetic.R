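#' Define a synthetic patient-flow scenario
#'
#' Parameterizes the gravity-model simulator that emulates the structure
#' of a hub-dominated hospital region: a universe of `n_units`
#' municipalities of which `n_designated` (the ones nearest the hub) form
#' the designated administrative region, subdivided into
#' `n_micro_regions` angular sectors around the hub; a dominant hub
#' holding most beds and about half of the designated population;
#' birth-rate driven case volumes; and distance-decayed destination
#' choice with local- and hub-preference multipliers.
#'
#' Destination choice follows
#' `u_ij = beds_j^gamma * exp(-d_ij / delta) * lambda^[j = i] * eta^[j = hub]`,
#' normalized per origin (see [gravity_probabilities()]).
#'
#' @param n_units Total number of municipalities.
#' @param n_designated Units in the designated region (nearest the hub).
#' @param n_micro_regions Angular sectors partitioning the designated units.
#' @param hub_unit Identifier of the hub (ids are `U01`, `U02`, ...).
#' @param hub_bed_share Fraction of all beds held by the hub (default 0.75).
#' @param hub_pop_share Hub share of the designated-region population
#'   (default 0.52).
#' @param population_range Min/max inhabitants; populations are
#'   log-uniform in this range.
#' @param birth_rate Births per inhabitant per year (default 0.015).
#' @param episodes_per_birth Hospitalization episodes per birth (>= 1;
#'   default 1.1, since puerperium admissions exceed births).
#' @param attraction_exponent Gamma, exponent on destination bed counts.
#' @param decay_scale_km Delta, e-folding distance of the exponential
#'   decay, in km.
#' @param local_preference Lambda >= 1, multiplier on the home
#'   municipality when it has beds.
#' @param hub_preference Eta >= 1, multiplier on the hub.
#' @param beds_per_1000 Total bed supply per 1000 inhabitants.
#' @param bed_unit_fraction Fraction of non-hub units that operate
#'   hospitals (sampled with probability proportional to population).
#' @param bounding_box Named list `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` for centroid sampling.
#' @param year Calendar year stamped on generated records.
#' @param seed Integer seed; geometry and sampling are fully reproducible.
#'
#' @return Object of class `synthetic_scenario`.
#' @seealso [scenario_preset()], [generate_units()], [generate_admissions()]
#' @export
synthetic_scenario <- function(n_units = 60L,
                               n_designated = 26L,
                               n_micro_regions = 3L,
                               hub_unit = "U01",
                               hub_bed_share = 0.75,
                               hub_pop_share = 0.52,
                               population_range = c(2000, 120000),
                               birth_rate = 0.015,
                               episodes_per_birth = 1.1,
                               attraction_exponent = 1,
                               decay_scale_km = 15,
                               local_preference = 30,
                               hub_preference = 4,
                               beds_per_1000 = 2.46,
                               bed_unit_fraction = 0.5,
                               bounding_box = list(lat_min = -21.95, lat_max = -20.45,
                                                   lon_min = -48.65, lon_max = -47.05),
                               year = 2012L,
                               seed = 1L) {
  stopifnot(
    n_units >= 1, n_designated >= 1, n_designated <= n_units,
    n_micro_regions >= 1, n_micro_regions <= n_designated,
    hub_bed_share > 0, hub_bed_share <= 1,
    hub_pop_share > 0, hub_pop_share < 1,
    length(population_range) == 2L, population_range[1] > 0,
    population_range[2] >= population_range[1],
    birth_rate > 0, episodes_per_birth >= 1,
    decay_scale_km > 0, local_preference >= 1, hub_preference >= 1,
    beds_per_1000 > 0, bed_unit_fraction >= 0, bed_unit_fraction <= 1,
    all(c("lat_min", "lat_max", "lon_min", "lon_max") %in% names(bounding_box))
  )
  structure(
    list(n_units = as.integer(n_units), n_designated = as.integer(n_designated),
         n_micro_regions = as.integer(n_micro_regions), hub_unit = hub_unit,
         hub_bed_share = hub_bed_share, hub_pop_share = hub_pop_share,
         population_range = as.numeric(population_range),
         birth_rate = birth_rate, episodes_per_birth = episodes_per_birth,
         attraction_exponent = attraction_exponent,
         decay_scale_km = decay_scale_km,
         local_preference = local_preference, hub_preference = hub_preference,
         beds_per_1000 = beds_per_1000, bed_unit_fraction = bed_unit_fraction,
         bounding_box = bounding_box, year = as.integer(year),
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' Preset scenarios
#'
#' `"drs13-like"` is the package default: 60 municipalities, 26
#' designated, three micro-regions, a hub with 75% of the beds and 52% of
#' the designated population. `"toy3"` is a minimal closed three-unit
#' system for examples and tests.
#'
#' @param name `"drs13-like"` or `"toy3"`.
#' @param seed Optional seed override.
#' @return A [synthetic_scenario()].
#' @export
scenario_preset <- function(name = c("drs13-like", "toy3"), seed = NULL) {
  name <- match.arg(name)
  sc <- switch(name,
    "drs13-like" = synthetic_scenario(),
    "toy3" = synthetic_scenario(
      n_units = 3L, n_designated = 3L, n_micro_regions = 1L,
      population_range = c(4000, 12000), hub_bed_share = 0.6,
      hub_pop_share = 0.5)
  )
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  sc
}

#' Read / write a scenario as JSON
#'
#' @param path JSON file path.
#' @return `read_scenario()` returns a [synthetic_scenario()];
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$bounding_box <- as.list(raw$bounding_box)
  do.call(synthetic_scenario, raw)
}

#' @rdname read_scenario
#' @param scenario A [synthetic_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# per-origin RNG sub-stream: deterministic in (scenario seed, unit id), so
# adding units to a scenario does not perturb existing origins' draws
origin_seed <- function(seed, unit_id) {
  chars <- utf8ToInt(unit_id)
  h <- sum(chars * seq_along(chars)) * 131
  as.integer((as.numeric(seed) * 1000003 + h) %% 2147483647)
}

#' Generate a synthetic unit table
#'
#' Samples `n_units` municipal centroids uniformly in the bounding box
#' (the hub is pinned to the box centre, emulating a centrally located
#' referral city), log-uniform populations, and a bed supply of
#' `beds_per_1000` per 1000 inhabitants of which the hub holds
#' `hub_bed_share`; the remainder is split, proportionally to population,
#' among a population-weighted random subset of the other units, so small
#' municipalities typically have no hospital. The `n_designated` units
#' nearest the hub form the designated region (`D1`), partitioned into
#' micro-regions (`M1`...) by angular sector around the hub; the hub
#' joins the sector of its nearest designated neighbour. Deterministic
#' under the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A unit table (see [read_units()]).
#' @export
generate_units <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  n <- sc$n_units
  ids <- sprintf("U%0*d", max(2L, nchar(n)), seq_len(n))
  if (!sc$hub_unit %in% ids) {
    stop("generate_units: hub_unit ", sc$hub_unit,
         " is not among the generated ids", call. = FALSE)
  }
  set.seed(sc$seed)
  bb <- sc$bounding_box
  lat <- runif(n, bb$lat_min, bb$lat_max)
  lon <- runif(n, bb$lon_min, bb$lon_max)
  hub <- match(sc$hub_unit, ids)
  lat[hub] <- (bb$lat_min + bb$lat_max) / 2
  lon[hub] <- (bb$lon_min + bb$lon_max) / 2

  pop <- round(exp(runif(n, log(sc$population_range[1]),
                         log(sc$population_range[2]))))

  units <- data.frame(
    unit_id = ids, name = paste("Municipality", ids),
    lat = lat, lon = lon, population = pop, beds = 0,
    designated_region = "", micro_region = "",
    stringsAsFactors = FALSE
  )

  d_hub <- unit_distances_km(units)[, sc$hub_unit]
  designated <- ids[order(d_hub)][seq_len(sc$n_designated)]
  units$designated_region[ids %in% designated] <- "D1"

  # hub population pinned to its share of the designated-region total
  others <- setdiff(designated, sc$hub_unit)
  if (length(others) > 0L) {
    units$population[hub] <- round(
      sc$hub_pop_share / (1 - sc$hub_pop_share) *
        sum(units$population[ids %in% others]))
  }

  total_beds <- round(sc$beds_per_1000 / 1000 * sum(units$population))
  hub_beds <- round(sc$hub_bed_share * total_beds)
  units$beds[hub] <- hub_beds
  rest <- total_beds - hub_beds
  if (rest > 0 && n > 1L) {
    n_bed <- max(1L, round(sc$bed_unit_fraction * (n - 1L)))
    cand <- setdiff(seq_len(n), hub)
    chosen <- sample(cand, min(n_bed, length(cand)),
                     prob = units$population[cand])
    share <- units$population[chosen] / sum(units$population[chosen])
    beds <- floor(rest * share)
    left <- rest - sum(beds)
    if (left > 0) {
      top <- order(rest * share - beds, decreasing = TRUE)[seq_len(left)]
      beds[top] <- beds[top] + 1L
    }
    units$beds[chosen] <- beds
  }

  # micro-regions: angular sectors around the hub, cut at angle quantiles
  # so the sectors hold near-equal numbers of designated units
  di <- match(others, ids)
  if (length(di) > 0L) {
    ang <- atan2(units$lat[di] - units$lat[hub], units$lon[di] - units$lon[hub])
    if (sc$n_micro_regions == 1L) {
      sector <- rep(1L, length(di))
    } else {
      br <- quantile(ang, probs = seq(0, 1, length.out = sc$n_micro_regions + 1L),
                     type = 7, names = FALSE)
      br[1] <- -pi - 1e-9; br[length(br)] <- pi + 1e-9
      sector <- findInterval(ang, br, rightmost.closed = TRUE)
      sector <- pmin(pmax(sector, 1L), sc$n_micro_regions)
    }
    units$micro_region[di] <- paste0("M", sector)
    nearest <- di[which.min(d_hub[di])]
    units$micro_region[hub] <- units$micro_region[nearest]
  } else {
    units$micro_region[hub] <- "M1"
  }
  units
}

#' Gravity-model destination probabilities
#'
#' For each origin i and each destination j with beds, the unnormalized
#' attractiveness is
#' `u_ij = beds_j^gamma * exp(-d_ij / delta) * lambda^[j = i] * eta^[j = hub]`
#' with `d_ij` the haversine centroid distance; probabilities are the
#' row-normalized `u`. Units without beds are valid origins but never
#' destinations.
#'
#' @param scenario A [synthetic_scenario()] (supplies gamma, delta,
#'   lambda, eta and the hub id).
#' @param units Unit table, typically from [generate_units()].
#' @return Matrix of probabilities, one row per unit (origin), one column
#'   per unit with beds; each row sums to 1.
#' @export
gravity_probabilities <- function(scenario, units) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dest <- units$unit_id[units$beds > 0]
  if (length(dest) == 0L) {
    stop("gravity_probabilities: no unit has beds", call. = FALSE)
  }
  d <- unit_distances_km(units)[, dest, drop = FALSE]
  beds <- units$beds[match(dest, units$unit_id)]
  u <- sweep(exp(-d / scenario$decay_scale_km), 2L,
             beds^scenario$attraction_exponent, `*`)
  if (scenario$hub_unit %in% dest) {
    u[, scenario$hub_unit] <- u[, scenario$hub_unit] * scenario$hub_preference
  }
  for (j in dest) {
    if (j %in% rownames(u)) u[j, j] <- u[j, j] * scenario$local_preference
  }
  u / rowSums(u)
}

#' Generate synthetic admission records
#'
#' Each origin produces `round(population * birth_rate *
#' episodes_per_birth)` hospitalization episodes, whose destinations are
#' drawn from the origin's gravity probabilities. Draws use a per-origin
#' RNG sub-stream derived from the scenario seed and the unit id, so runs
#' are reproducible and insensitive to the presence of other units.
#'
#' @param scenario A [synthetic_scenario()].
#' @param units Unit table from [generate_units()].
#' @return Data frame of admission records (`residence_unit`,
#'   `hospital_unit`, `diagnosis_group` = `"XV"`, `year`).
#' @export
generate_admissions <- function(scenario, units) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  p <- gravity_probabilities(scenario, units)
  dest_ids <- colnames(p)
  n_cases <- round(units$population * scenario$birth_rate *
                     scenario$episodes_per_birth)
  parts <- vector("list", nrow(units))
  for (i in seq_len(nrow(units))) {
    ni <- n_cases[i]
    if (ni <= 0) next
    set.seed(origin_seed(scenario$seed, units$unit_id[i]))
    hosp <- sample(dest_ids, ni, replace = TRUE, prob = p[units$unit_id[i], ])
    parts[[i]] <- data.frame(
      residence_unit = rep(units$unit_id[i], ni),
      hospital_unit = hosp,
      diagnosis_group = "XV",
      year = scenario$year,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(residence_unit = character(), hospital_unit = character(),
                      diagnosis_group = character(), year = integer())
  }
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: units plus admissions in one call.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `units` and `records`.
#' @export
generate_dataset <- function(scenario) {
  units <- generate_units(scenario)
  list(units = units, records = generate_admissions(scenario, units))
}
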