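#' Configuration for the synthetic landscape generator
#'
#' Bundles every tunable of the synthetic landscape: grid geometry, the
#' spatial-autocorrelation length scales of the continuous fields, the
#' missing-data fractions for the carbon and societal layers, the
#' demographic calibration targets, and the species-generation knobs.
#' Defaults encode the study conditions the analysis assumes: a
#' 50 x 50 grid of 10 km cells, 56 forest-dependent species, 20
#' subjurisdictions, 4.6% of units without a carbon rate, 0.15% without
#' people counts, and national population-weighted means of 34.2%
#' socioeconomically disadvantaged people and 48.9% women.
#'
#' @param nrow,ncol Grid dimensions (cells); must be >= 1.
#' @param cell_side_km Cell edge length in km (cell area is
#'   `cell_side_km^2` km2, i.e. 10,000 ha for the default 10 km cells).
#' @param n_species Number of species range maps to generate.
#' @param n_subjur Number of subjurisdictions tessellating the grid.
#' @param n_habitat_classes Number of categorical habitat classes.
#' @param missing_carbon_frac Fraction of planning units whose carbon
#'   rate is missing (`NA`); exactly `round(frac * n_units)` units.
#' @param missing_people_frac Fraction of units whose people counts are
#'   missing (`NA`); exactly `round(frac * n_units)` units.
#' @param carbon_length_scale,people_length_scale,elev_length_scale,habitat_length_scale
#'   Spatial-autocorrelation length scales in cell units (Gaussian
#'   kernel smoothing of white noise); 0 means spatially independent.
#' @param carbon_rate_meanlog,carbon_rate_sdlog Log-normal marginal
#'   parameters of the carbon sequestration rate field (tC/ha/yr).
#' @param people_mean Named or unnamed length-3 vector of mean persons
#'   per unit reliant on forests for livelihoods, energy, and housing.
#' @param people_sdlog Log-scale spread of the people-count fields.
#' @param rural_beta Length-2 shape parameters of the Beta distribution
#'   of the per-unit rural population fraction.
#' @param restorable_beta Length-2 Beta shape parameters of the
#'   restorable fraction of each cell's area.
#' @param elev_max_m Approximate upper bound of the elevation field (m).
#' @param target_disadvantaged,target_women Calibration targets for the
#'   population-weighted national mean fraction of socioeconomically
#'   disadvantaged people and of women, both in (0, 1).
#' @param species_range_frac Length-2 vector: min and max species range
#'   size as a fraction of the number of grid cells.
#' @param species_viable_share Share of species constructed so that
#'   their range, habitat preferences and elevational limits guarantee
#'   nonzero potential AOH inside the restorable mask.
#'
#' @return An object of class `ncp_generator_config` (a validated list).
#' @seealso [generate_landscape()], [read_generator_config()]
#' @export
generator_config <- function(nrow = 50L,
                             ncol = 50L,
                             cell_side_km = 10,
                             n_species = 56L,
                             n_subjur = 20L,
                             n_habitat_classes = 6L,
                             missing_carbon_frac = 0.046,
                             missing_people_frac = 0.0015,
                             carbon_length_scale = 5,
                             people_length_scale = 5,
                             elev_length_scale = 8,
                             habitat_length_scale = 6,
                             carbon_rate_meanlog = log(3),
                             carbon_rate_sdlog = 0.5,
                             people_mean = c(livelihoods = 112, energy = 632, housing = 192),
                             people_sdlog = 0.8,
                             rural_beta = c(6.5, 3.5),
                             restorable_beta = c(2, 4),
                             elev_max_m = 3000,
                             target_disadvantaged = 0.342,
                             target_women = 0.489,
                             species_range_frac = c(0.03, 0.15),
                             species_viable_share = 1.0) {
  cfg <- list(
    nrow = as.integer(nrow), ncol = as.integer(ncol),
    cell_side_km = cell_side_km,
    n_species = as.integer(n_species), n_subjur = as.integer(n_subjur),
    n_habitat_classes = as.integer(n_habitat_classes),
    missing_carbon_frac = missing_carbon_frac,
    missing_people_frac = missing_people_frac,
    carbon_length_scale = carbon_length_scale,
    people_length_scale = people_length_scale,
    elev_length_scale = elev_length_scale,
    habitat_length_scale = habitat_length_scale,
    carbon_rate_meanlog = carbon_rate_meanlog,
    carbon_rate_sdlog = carbon_rate_sdlog,
    people_mean = unname(people_mean),
    people_sdlog = people_sdlog,
    rural_beta = unname(rural_beta),
    restorable_beta = unname(restorable_beta),
    elev_max_m = elev_max_m,
    target_disadvantaged = target_disadvantaged,
    target_women = target_women,
    species_range_frac = unname(species_range_frac),
    species_viable_share = species_viable_share
  )
  class(cfg) <- "ncp_generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stop_if <- function(bad, key, why) {
    if (bad) stop(sprintf("invalid generator config: '%s' %s", key, why), call. = FALSE)
  }
  stop_if(cfg$nrow < 1L || cfg$ncol < 1L, "nrow/ncol", "must be >= 1")
  stop_if(cfg$cell_side_km <= 0, "cell_side_km", "must be > 0")
  stop_if(cfg$n_species < 0L, "n_species", "must be >= 0")
  stop_if(cfg$n_subjur < 1L, "n_subjur", "must be >= 1")
  stop_if(cfg$n_subjur > cfg$nrow * cfg$ncol, "n_subjur", "exceeds number of cells")
  stop_if(cfg$n_habitat_classes < 1L, "n_habitat_classes", "must be >= 1")
  for (key in c("missing_carbon_frac", "missing_people_frac", "species_viable_share")) {
    stop_if(cfg[[key]] < 0 || cfg[[key]] > 1, key, "must be in [0, 1]")
  }
  for (key in c("target_disadvantaged", "target_women")) {
    stop_if(cfg[[key]] <= 0 || cfg[[key]] >= 1, key, "must be in (0, 1)")
  }
  for (key in c("carbon_length_scale", "people_length_scale",
                "elev_length_scale", "habitat_length_scale")) {
    stop_if(cfg[[key]] < 0, key, "must be >= 0")
  }
  stop_if(length(cfg$people_mean) != 3L || any(cfg$people_mean < 0),
          "people_mean", "must be 3 non-negative counts")
  stop_if(length(cfg$rural_beta) != 2L || any(cfg$rural_beta <= 0),
          "rural_beta", "must be 2 positive shapes")
  stop_if(length(cfg$restorable_beta) != 2L || any(cfg$restorable_beta <= 0),
          "restorable_beta", "must be 2 positive shapes")
  stop_if(length(cfg$species_range_frac) != 2L ||
            any(cfg$species_range_frac <= 0) ||
            cfg$species_range_frac[1] > cfg$species_range_frac[2] ||
            cfg$species_range_frac[2] > 1,
          "species_range_frac", "must be increasing fractions in (0, 1]")
  cfg
}

#' Read / write a generator configuration as YAML
#'
#' The YAML file holds any subset of [generator_config()]'s arguments;
#' unknown keys are rejected by name so typos surface immediately.
#'
#' @param path Path to a YAML file.
#' @return `read_generator_config()` returns an `ncp_generator_config`;
#'   `write_generator_config()` returns `path` invisibly.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()  # empty file: all defaults
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown generator config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(generator_config, raw)
}

#' @rdname read_generator_config
#' @param config An `ncp_generator_config`.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "ncp_generator_config"))
  # 17 significant digits: doubles survive the YAML round trip exactly
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' Stable hash of a configuration (used in run manifests)
#' @param config An `ncp_generator_config` or any R object.
#' @return A character scalar hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
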