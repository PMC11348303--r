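# Hand-built landscape with fully specified layers, for deterministic
# unit tests. All vectors are per-unit in row-major unit order.
make_test_landscape <- function(nrow, ncol, cell_side_km = 10,
                                restorable_area = NULL, carbon_rate = NULL,
                                people = NULL, rural_fraction = NULL,
                                subjur_id = NULL, elevation = NULL,
                                habitat_class = NULL, subjur = NULL,
                                n_habitat_classes = 3L) {
  n <- nrow * ncol
  cell_area_ha <- cell_side_km^2 * 100
  unit_id <- seq_len(n)
  row <- (unit_id - 1L) %/% ncol + 1L
  col <- (unit_id - 1L) %% ncol + 1L
  if (is.null(restorable_area)) restorable_area <- rep(cell_area_ha / 2, n)
  if (is.null(carbon_rate)) carbon_rate <- rep(2, n)
  if (is.null(people)) people <- matrix(10, n, 3)
  if (is.null(rural_fraction)) rural_fraction <- rep(1, n)
  if (is.null(subjur_id)) subjur_id <- rep(1L, n)
  if (is.null(elevation)) elevation <- matrix(500, nrow, ncol)
  if (is.null(habitat_class)) habitat_class <- matrix(1L, nrow, ncol)
  if (is.null(subjur)) {
    ids <- sort(unique(subjur_id))
    subjur <- data.frame(subjur_id = ids, population = rep(1000, length(ids)),
                         frac_disadvantaged = rep(0.3, length(ids)),
                         frac_women = rep(0.5, length(ids)))
  }
  cfg <- generator_config(nrow = nrow, ncol = ncol, cell_side_km = cell_side_km,
                          n_species = 1L, n_subjur = nrow(subjur),
                          n_habitat_classes = n_habitat_classes)
  structure(list(config = cfg, seed = 0L,
                 grid = list(nrow = nrow, ncol = ncol,
                             cell_side_km = cell_side_km,
                             cell_area_km2 = cell_side_km^2,
                             cell_area_ha = cell_area_ha),
                 units = data.frame(unit_id = unit_id, row = row, col = col,
                                    restorable_area = restorable_area,
                                    carbon_rate = carbon_rate,
                                    people_livelihoods = people[, 1],
                                    people_energy = people[, 2],
                                    people_housing = people[, 3],
                                    rural_fraction = rural_fraction,
                                    subjur_id = subjur_id),
                 elevation = elevation, habitat_class = habitat_class,
                 subjurisdictions = subjur),
            class = "ncp_landscape")
}

make_test_species <- function(range_units, habitat_classes = 1L,
                              elev_min = 0, elev_max = 10000,
                              species_id = "spTEST") {
  structure(list(species_id = species_id, range_units = as.integer(range_units),
                 habitat_classes = habitat_classes,
                 elev_min = elev_min, elev_max = elev_max),
            class = "ncp_species")
}

# Independent brute-force AOH oracle: explicit cell-by-cell scan of the
# triple condition (range membership, habitat suitability, elevation
# window), written without reusing any package internals.
aoh_bruteforce <- function(species, landscape) {
  units <- landscape$units
  aoh_in <- 0
  aoh_out <- 0
  for (i in seq_len(nrow(units))) {
    if (!(units$unit_id[i] %in% species$range_units)) next
    hab <- landscape$habitat_class[units$row[i], units$col[i]]
    if (!(hab %in% species$habitat_classes)) next
    elev <- landscape$elevation[units$row[i], units$col[i]]
    if (elev < species$elev_min || elev > species$elev_max) next
    rest_km2 <- units$restorable_area[i] / 100
    aoh_in <- aoh_in + rest_km2
    aoh_out <- aoh_out + (landscape$grid$cell_area_km2 - rest_km2)
  }
  list(aoh_in = aoh_in, aoh_out = aoh_out)
}

# Build an ncp_problem directly with arbitrary weights, bypassing the
# plan-scheme weighting (which has its own tests).
make_test_problem <- function(rij, targets, weights, costs, budget,
                              decision_mode = "proportional") {
  rij <- as.matrix(rij)
  structure(list(rij = rij, targets = targets, weights = weights,
                 kinds = rep("climate", length(targets)),
                 ids = paste0("f", seq_along(targets)),
                 costs = costs, budget = budget,
                 decision_mode = decision_mode, plan_name = "test",
                 weight_mode = "group-equal"),
            class = "ncp_problem")
}

# Random solver-vs-oracle instances.
random_binary_problem <- function(n_max = 12L) {
  n <- sample(3:n_max, 1)
  j <- sample(1:3, 1)
  rij <- matrix(round(stats::runif(n * j, 0, 10), 3), n, j)
  costs <- round(stats::runif(n, 0.5, 1.5), 3)
  targets <- round(stats::runif(j, 0.3, 1.3) * colSums(rij), 3)
  weights <- round(stats::runif(j, 0.1, 1), 3)
  budget <- round(stats::runif(1, 0.2, 0.9) * sum(costs), 3)
  make_test_problem(rij, targets, weights, costs, budget, "binary")
}

random_single_feature_problem <- function(n_max = 50L) {
  n <- sample(5:n_max, 1)
  r <- round(stats::runif(n, 0, 10), 3)
  costs <- round(stats::runif(n, 0.2, 2), 3)
  target <- round(stats::runif(1, 0.3, 1.2) * sum(r), 3)
  budget <- round(stats::runif(1, 0.1, 0.9) * sum(costs), 3)
  make_test_problem(matrix(r, ncol = 1), target, 1, costs, budget, "proportional")
}

small_config <- function(...) {
  generator_config(nrow = 8, ncol = 8, n_species = 4, n_subjur = 3,
                   n_habitat_classes = 3, ...)
}
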