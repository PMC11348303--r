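#' Run the full prioritization pipeline
#'
#' Generate (or accept) a landscape, generate species, assemble the NCP
#' feature stack, sweep the plan schemes over budget increments, and
#' derive accumulation curves, selection frequencies, cessation budgets,
#' and the distributional-equity report. With the defaults (four plans,
#' 100 increments) this solves the full 400-problem experiment.
#'
#' @param config An [generator_config()].
#' @param seed Integer seed driving every random draw (landscape and
#'   species seeds are derived from it).
#' @param plans List of `ncp_plan`s (default all four schemes).
#' @param increments Budget increments (default 100).
#' @param decision_mode,weight_mode Passed to [build_problem()].
#' @param equity_budgets Budget percentages for the equity report.
#' @param outdir Optional output directory; when given, all result
#'   tables are written as CSV with a YAML manifest (see
#'   [write_run_outputs()]).
#' @return An `ncp_run`: list with `landscape`, `species`, `records`
#'   (species target table), `stack`, `sweeps`, `curves`, `frequency`,
#'   `equity`, `cessation`, `n_problems`, `seed`, `config`.
#' @export
run_pipeline <- function(config = generator_config(), seed = 1L,
                         plans = all_plans(), increments = 100L,
                         decision_mode = "proportional",
                         weight_mode = "group-equal",
                         equity_budgets = c(10, 25, 50, 75, 100),
                         outdir = NULL) {
  seed <- as.integer(seed)
  landscape <- generate_landscape(config, seed)
  species <- generate_species(landscape, config$n_species, seed + 1000L)
  fs <- build_feature_stack(landscape, species)
  sweeps <- run_sweep(landscape, fs$stack, plans, increments,
                      decision_mode, weight_mode)
  curves <- do.call(rbind, lapply(sweeps, accumulation_curves))
  frequency <- do.call(rbind, lapply(sweeps, function(s) {
    cbind(plan = s$plan_name, s$frequency)
  }))
  cessation <- data.frame(
    plan = vapply(sweeps, `[[`, character(1), "plan_name"),
    cessation_budget_pct = vapply(sweeps, `[[`, numeric(1), "cessation_budget_pct"))
  equity <- equity_report(sweeps, fs$stack, landscape, equity_budgets)
  run <- structure(
    list(landscape = landscape, species = species, records = fs$records,
         stack = fs$stack, sweeps = sweeps, curves = curves,
         frequency = frequency, equity = equity, cessation = cessation,
         n_problems = sum(vapply(sweeps, `[[`, integer(1), "n_problems")),
         seed = seed, config = config),
    class = "ncp_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' @export
print.ncp_run <- function(x, ...) {
  cat(sprintf("<ncp_run> seed %d: %d problems (%d plans x %d budgets), %d features over %d units\n",
              x$seed, x$n_problems, length(x$sweeps),
              length(x$sweeps[[1]]$budget_pct), length(x$stack$ids),
              n_units(x$landscape)))
  for (i in seq_len(nrow(x$cessation))) {
    if (!is.na(x$cessation$cessation_budget_pct[i])) {
      cat(sprintf("  %s ceases at %.4g%% of the restoration area\n",
                  x$cessation$plan[i], x$cessation$cessation_budget_pct[i]))
    }
  }
  invisible(x)
}

write_csv_ <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Write landscape layers as a plain-text bundle
#'
#' Exports the landscape as CSV on the common grid: one per-unit table
#' (restorable area, carbon rate, people counts, rural fraction,
#' subjurisdiction id), the elevation and habitat-class rasters as
#' row x col CSV grids, the subjurisdiction table, and the generator
#' config as YAML. [read_landscape()] restores the object losslessly up
#' to CSV numeric round-trip.
#'
#' @param landscape An `ncp_landscape`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_(landscape$units, file.path(dir, "units.csv"))
  write_csv_(landscape$subjurisdictions, file.path(dir, "subjurisdictions.csv"))
  utils::write.table(landscape$elevation, file.path(dir, "elevation.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(landscape$habitat_class, file.path(dir, "habitat_class.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(seed = landscape$seed,
                        config = unclass(landscape$config),
                        config_hash = config_hash(landscape$config)),
                   file.path(dir, "landscape.yaml"), precision = 17)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yaml"))
  config <- do.call(generator_config, meta$config[names(meta$config) %in%
                                                    names(formals(generator_config))])
  units <- utils::read.csv(file.path(dir, "units.csv"))
  sj <- utils::read.csv(file.path(dir, "subjurisdictions.csv"))
  elev <- as.matrix(utils::read.csv(file.path(dir, "elevation.csv"), header = FALSE))
  hab <- as.matrix(utils::read.csv(file.path(dir, "habitat_class.csv"), header = FALSE))
  dimnames(elev) <- NULL
  dimnames(hab) <- NULL
  storage.mode(hab) <- "integer"
  structure(list(config = config, seed = as.integer(meta$seed),
                 grid = list(nrow = config$nrow, ncol = config$ncol,
                             cell_side_km = config$cell_side_km,
                             cell_area_km2 = config$cell_side_km^2,
                             cell_area_ha = config$cell_side_km^2 * 100),
                 units = units, elevation = elev, habitat_class = hab,
                 subjurisdictions = sj),
            class = "ncp_landscape")
}

#' Write species specifications as CSV
#'
#' One row per species (id, habitat classes, elevational limits) plus a
#' long-format range table (species_id, unit_id).
#'
#' @param species List of `ncp_species`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_species <- function(species, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- data.frame(
    species_id = vapply(species, `[[`, character(1), "species_id"),
    habitat_classes = vapply(species, function(s) paste(s$habitat_classes, collapse = ";"),
                             character(1)),
    elev_min = vapply(species, `[[`, numeric(1), "elev_min"),
    elev_max = vapply(species, `[[`, numeric(1), "elev_max"))
  write_csv_(tab, file.path(dir, "species.csv"))
  ranges <- do.call(rbind, lapply(species, function(s) {
    data.frame(species_id = s$species_id, unit_id = s$range_units)
  }))
  write_csv_(ranges, file.path(dir, "species_ranges.csv"))
  invisible(dir)
}

#' Write all result tables of a run, with a manifest
#'
#' Writes the curves, selection-frequency, equity, cessation, and
#' species-target tables as tidy CSV, the landscape and species bundles,
#' and a YAML manifest listing every file with the seed and config hash.
#'
#' @param run An `ncp_run` from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_run_outputs <- function(run, outdir) {
  stopifnot(inherits(run, "ncp_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, basename(path))
  add(write_csv_(run$curves, file.path(outdir, "curves.csv")))
  add(write_csv_(run$frequency, file.path(outdir, "selection_frequency.csv")))
  add(write_csv_(run$equity, file.path(outdir, "equity.csv")))
  add(write_csv_(run$cessation, file.path(outdir, "cessation.csv")))
  recs <- run$records
  attr(recs, "per_unit_aoh") <- NULL
  add(write_csv_(recs, file.path(outdir, "species_targets.csv")))
  write_landscape(run$landscape, file.path(outdir, "landscape"))
  write_species(run$species, file.path(outdir, "species"))
  manifest <- list(seed = run$seed,
                   config_hash = config_hash(run$config),
                   n_problems = run$n_problems,
                   weight_mode = run$sweeps[[1]]$weight_mode,
                   decision_mode = run$sweeps[[1]]$decision_mode,
                   files = c(files,
                             file.path("landscape", c("units.csv", "subjurisdictions.csv",
                                                      "elevation.csv", "habitat_class.csv",
                                                      "landscape.yaml")),
                             file.path("species", c("species.csv", "species_ranges.csv"))))
  path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
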