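new_ncp_feature <- function(feature_id, kind, contributions, target,
                            unit_label, degenerate = FALSE) {
  stopifnot(kind %in% c("climate", "species", "societal"))
  if (any(contributions < 0)) stop("feature contributions must be >= 0", call. = FALSE)
  if (target < 0) stop("feature target must be >= 0", call. = FALSE)
  structure(list(feature_id = feature_id, kind = kind,
                 contributions = contributions, target = target,
                 unit_label = unit_label, degenerate = degenerate),
            class = "ncp_feature")
}

#' @export
print.ncp_feature <- function(x, ...) {
  cat(sprintf("<ncp_feature> %s (%s): target %.4g %s over %d units%s\n",
              x$feature_id, x$kind, x$target, x$unit_label,
              length(x$contributions),
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Climate NCP feature: 30-year carbon accumulation
#'
#' Each unit contributes its carbon sequestration rate (tC/ha/yr) times
#' the accrual horizon times its restorable area (ha), i.e. the carbon
#' stock accumulated over the first `horizon_years` of natural forest
#' regrowth if the unit were fully restored. Units with a missing carbon
#' rate contribute 0 tC but remain in the problem (they are assumed to
#' deliver the other NCP). The target is the maximum possible NCP: the
#' sum of all contributions.
#'
#' @param landscape An `ncp_landscape`.
#' @param horizon_years Accrual horizon in years (default 30).
#' @return An `ncp_feature` of kind `"climate"` (tC). If every rate is
#'   missing or zero the feature is flagged `degenerate`.
#' @export
climate_feature <- function(landscape, horizon_years = 30) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  units <- landscape$units
  rate <- ifelse(is.na(units$carbon_rate), 0, units$carbon_rate)
  r <- rate * horizon_years * units$restorable_area
  new_ncp_feature("climate", "climate", r, sum(r), "tC",
                  degenerate = sum(r) == 0)
}

#' Societal NCP feature: people reliant on forests
#'
#' Per unit, each need's count (livelihoods, energy, housing material)
#' is weighted by the unit's rural/urban population split
#' (`rural_weight * rural_fraction + urban_weight * (1 - rural_fraction)`),
#' and the unit's contribution is the mean of the three weighted counts.
#' Units with missing people counts contribute 0 persons but remain in
#' the problem. The target is the sum of all contributions.
#'
#' @param landscape An `ncp_landscape`.
#' @param rural_weight,urban_weight Reliance weights in \[0, 1\] applied
#'   to the rural and urban population shares (default 1 and 0.2:
#'   full reliance for rural populations, partial for urban).
#' @return An `ncp_feature` of kind `"societal"` (persons).
#' @export
societal_feature <- function(landscape, rural_weight = 1, urban_weight = 0.2) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  if (rural_weight < 0 || rural_weight > 1 || urban_weight < 0 || urban_weight > 1) {
    stop("rural/urban weights must be in [0, 1]", call. = FALSE)
  }
  units <- landscape$units
  w <- rural_weight * units$rural_fraction + urban_weight * (1 - units$rural_fraction)
  counts <- cbind(units$people_livelihoods, units$people_energy, units$people_housing)
  counts[is.na(counts)] <- 0
  r <- w * rowMeans(counts)
  new_ncp_feature("societal", "societal", r, sum(r), "persons",
                  degenerate = sum(r) == 0)
}

#' Species NCP features from the optimization subset
#'
#' One feature per species in the subset: contributions are the per-unit
#' in-restoration AOH (km2 of suitable habitat the unit would add if
#' fully restored) and the target is the species' habitat restoration
#' target. A species whose target exceeds its total deliverable habitat
#' is kept (its shortfall absorbs the unreachable part) but flagged.
#'
#' @param records Species target table from [species_target_table()]
#'   (its `per_unit_aoh` attribute supplies the contribution vectors).
#' @param subset_only Keep only rows with `in_subset = TRUE` (default).
#' @return A list of `ncp_feature` objects of kind `"species"` (km2).
#' @export
species_features <- function(records, subset_only = TRUE) {
  per_unit <- attr(records, "per_unit_aoh")
  if (is.null(per_unit)) stop("records lack the per_unit_aoh attribute", call. = FALSE)
  keep <- if (subset_only) which(records$in_subset) else seq_len(nrow(records))
  lapply(keep, function(i) {
    f <- new_ncp_feature(records$species_id[i], "species",
                         per_unit[, i], records$restoration_target[i], "km2")
    if (f$target > sum(f$contributions) + 1e-9) {
      warning(sprintf("species %s: target %.4g km2 exceeds deliverable habitat %.4g km2 (shortfall will absorb it)",
                      f$feature_id, f$target, sum(f$contributions)), call. = FALSE)
    }
    f
  })
}

#' Assemble the full NCP feature stack
#'
#' Combines the climate feature, the societal feature, and the species
#' features into the stack the optimization consumes: a units x features
#' contribution matrix plus per-feature targets and kinds.
#'
#' @param climate,societal Single `ncp_feature`s (or `NULL` to omit).
#' @param species List of species `ncp_feature`s (possibly empty).
#' @return An `ncp_feature_stack`: list with `rij` (units x J matrix),
#'   `targets`, `kinds`, `ids` (length-J vectors), `n_species`.
#' @export
assemble_features <- function(climate, societal, species = list()) {
  feats <- c(if (!is.null(climate)) list(climate),
             if (!is.null(societal)) list(societal),
             species)
  if (length(feats) == 0) stop("no features to assemble", call. = FALSE)
  n <- unique(vapply(feats, function(f) length(f$contributions), integer(1)))
  if (length(n) != 1L) stop("features disagree on the number of units", call. = FALSE)
  rij <- vapply(feats, `[[`, numeric(n), "contributions")
  if (is.null(dim(rij))) rij <- matrix(rij, nrow = n)
  ids <- vapply(feats, `[[`, character(1), "feature_id")
  colnames(rij) <- ids
  structure(list(rij = rij,
                 targets = vapply(feats, `[[`, numeric(1), "target"),
                 kinds = vapply(feats, `[[`, character(1), "kind"),
                 ids = ids,
                 n_species = sum(vapply(feats, `[[`, character(1), "kind") == "species")),
            class = "ncp_feature_stack")
}

#' @export
print.ncp_feature_stack <- function(x, ...) {
  cat(sprintf("<ncp_feature_stack> %d features over %d units (%d climate, %d societal, %d species)\n",
              length(x$ids), nrow(x$rij),
              sum(x$kinds == "climate"), sum(x$kinds == "societal"), x$n_species))
  invisible(x)
}

#' Build the feature stack straight from a landscape and species list
#'
#' Convenience wrapper: computes the species target table, keeps the
#' optimization subset, and assembles climate + societal + species
#' features with the default horizons and weights.
#'
#' @inheritParams species_target_table
#' @inheritParams climate_feature
#' @inheritParams societal_feature
#' @return A list with `stack` (the `ncp_feature_stack`) and `records`
#'   (the species target table).
#' @export
build_feature_stack <- function(landscape, species_list, min_additional = 0,
                                horizon_years = 30, rural_weight = 1,
                                urban_weight = 0.2) {
  records <- species_target_table(species_list, landscape, min_additional)
  stack <- assemble_features(
    climate = climate_feature(landscape, horizon_years),
    societal = societal_feature(landscape, rural_weight, urban_weight),
    species = species_features(records)
  )
  list(stack = stack, records = records)
}
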