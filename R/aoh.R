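#' Potential Area of Habitat for one species
#'
#' A grid cell contributes habitat iff it lies in the species' range AND
#' its habitat class is in the species' suitable set AND its elevation
#' lies within the species' elevational limits. On a contributing cell,
#' the part inside the restorable mask contributes in proportion to the
#' unit's restorable area, and the remainder (cell area minus restorable
#' area) counts as habitat outside the restoration area. Current AOH is
#' by convention the potential AOH outside the restoration area.
#'
#' @param species An `ncp_species`.
#' @param landscape An `ncp_landscape`.
#' @return A list with `aoh_in_restoration` (km2), `aoh_outside` (km2,
#'   the current AOH), and `per_unit_aoh` (km2 vector over all units:
#'   in-restoration habitat each unit would add if fully restored).
#' @export
compute_potential_aoh <- function(species, landscape) {
  stopifnot(inherits(species, "ncp_species"), inherits(landscape, "ncp_landscape"))
  units <- landscape$units
  n <- nrow(units)
  if (any(species$range_units < 1L | species$range_units > n)) {
    stop("species range extends outside the grid", call. = FALSE)
  }
  idx <- cbind(units$row, units$col)
  hab <- landscape$habitat_class[idx]
  elev <- landscape$elevation[idx]
  in_range <- logical(n)
  in_range[species$range_units] <- TRUE
  suitable <- in_range &
    hab %in% species$habitat_classes &
    elev >= species$elev_min & elev <= species$elev_max
  restorable_km2 <- units$restorable_area / 100  # ha -> km2
  per_unit <- ifelse(suitable, restorable_km2, 0)
  outside <- ifelse(suitable, landscape$grid$cell_area_km2 - restorable_km2, 0)
  list(aoh_in_restoration = sum(per_unit),
       aoh_outside = sum(outside),
       per_unit_aoh = per_unit)
}

#' Preliminary habitat restoration target (area-based protocol)
#'
#' Area-based target protocol inspired by the IUCN Red List criteria:
#' species whose potential and current AOH are both below the 2,200 km2
#' floor take their full potential AOH as the preliminary target; all
#' other species take `min(max(2200, 0.8 * potential_aoh), 1e6)` km2.
#' All areas in km2. Vectorized over species.
#'
#' @param potential_aoh,current_aoh Non-negative areas (km2).
#' @return Preliminary target area (km2), always in \[0, 1e6\].
#' @export
preliminary_target <- function(potential_aoh, current_aoh) {
  if (any(potential_aoh < 0) || any(current_aoh < 0)) {
    stop("AOH areas must be non-negative", call. = FALSE)
  }
  small <- potential_aoh < 2200 & current_aoh < 2200
  ifelse(small, potential_aoh, pmin(pmax(2200, 0.8 * potential_aoh), 1e6))
}

#' Habitat restoration target after deducting current AOH
#'
#' The area of new habitat restoration must create for the species:
#' the preliminary target minus the habitat it already has, floored at
#' zero. Vectorized.
#'
#' @param preliminary,current_aoh Non-negative areas (km2).
#' @return Restoration target (km2).
#' @export
restoration_target <- function(preliminary, current_aoh) {
  if (any(preliminary < 0) || any(current_aoh < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  pmax(0, preliminary - current_aoh)
}

#' Species target table
#'
#' Applies [compute_potential_aoh()], [preliminary_target()] and
#' [restoration_target()] to every species and flags the subset kept for
#' the optimization (those for which restoration would create additional
#' habitat beyond `min_additional`).
#'
#' @param species_list List of `ncp_species`.
#' @param landscape An `ncp_landscape`.
#' @param min_additional Minimum restoration target (km2) to keep a
#'   species in the optimization subset; default 0 keeps every species
#'   with any positive target, however tiny.
#' @return A data frame with one row per species: `species_id`,
#'   `potential_aoh`, `current_aoh`, `preliminary_target`,
#'   `restoration_target`, `in_subset`; the per-unit AOH vectors are
#'   attached as the `per_unit_aoh` attribute (units x species matrix).
#' @export
species_target_table <- function(species_list, landscape, min_additional = 0) {
  aoh <- lapply(species_list, compute_potential_aoh, landscape = landscape)
  aoh_in <- vapply(aoh, `[[`, numeric(1), "aoh_in_restoration")
  aoh_out <- vapply(aoh, `[[`, numeric(1), "aoh_outside")
  potential <- aoh_in + aoh_out
  prelim <- preliminary_target(potential, aoh_out)
  target <- restoration_target(prelim, aoh_out)
  records <- data.frame(
    species_id = vapply(species_list, `[[`, character(1), "species_id"),
    potential_aoh = potential,
    current_aoh = aoh_out,
    preliminary_target = prelim,
    restoration_target = target
  )
  records <- select_species_subset(records, min_additional = min_additional)
  per_unit <- vapply(aoh, `[[`, numeric(n_units(landscape)), "per_unit_aoh")
  if (is.null(dim(per_unit))) per_unit <- matrix(per_unit, nrow = n_units(landscape))
  colnames(per_unit) <- records$species_id
  attr(records, "per_unit_aoh") <- per_unit
  records
}

#' Flag the species kept for optimization
#'
#' Marks `in_subset = restoration_target > min_additional`. The default
#' threshold of 0 retains every species for which restoration creates
#' any additional habitat.
#'
#' @param records A species target data frame (see
#'   [species_target_table()]).
#' @param min_additional Threshold in km2.
#' @return `records` with an `in_subset` logical column.
#' @export
select_species_subset <- function(records, min_additional = 0) {
  records$in_subset <- records$restoration_target > min_additional
  records
}
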