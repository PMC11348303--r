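#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state so generators are deterministic
# for a given seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# 1-D "open" convolution of x with kernel k (odd length), trimmed to
# length(x); paired with a ones-convolution for edge renormalization.
conv1 <- function(x, k) {
  h <- (length(k) - 1L) / 2L
  y <- stats::convolve(x, rev(k), type = "open")
  y[(h + 1L):(h + length(x))]
}

#' Spatially autocorrelated Gaussian field via kernel-smoothed white noise
#'
#' Draws iid standard-normal noise on the grid and smooths it with a
#' separable Gaussian kernel of standard deviation `length_scale` (in
#' cell units), renormalizing at the edges, then standardizes the result
#' to zero mean and unit variance. `length_scale = 0` returns the raw
#' white noise, i.e. a spatially independent field. Consumes the current
#' RNG stream (call after `set.seed()` for reproducibility).
#'
#' @param nrow,ncol Grid dimensions.
#' @param length_scale Smoothing kernel sd in cell units (>= 0).
#' @return A `nrow x ncol` numeric matrix with mean 0 and sd 1.
#' @export
gaussian_field <- function(nrow, ncol, length_scale) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow = nrow, ncol = ncol)
  if (length_scale > 0) {
    half <- max(1L, ceiling(3 * length_scale))
    k <- stats::dnorm(seq(-half, half), sd = length_scale)
    ones_r <- conv1(rep(1, ncol), k)
    ones_c <- conv1(rep(1, nrow), k)
    z <- t(apply(z, 1L, function(r) conv1(r, k) / ones_r))
    if (ncol == 1L) z <- matrix(z, nrow = nrow)  # apply drops dims
    z <- apply(z, 2L, function(cl) conv1(cl, k) / ones_c)
    z <- matrix(z, nrow = nrow)
  }
  s <- stats::sd(z)
  if (s == 0) s <- 1
  (z - mean(z)) / s
}

# Mean correlation between rook-adjacent cell pairs; a light-weight
# Moran's-I-style diagnostic used by the generator's tests.
neighbor_correlation <- function(mat) {
  horiz <- cbind(as.vector(mat[, -ncol(mat), drop = FALSE]),
                 as.vector(mat[, -1, drop = FALSE]))
  vert <- cbind(as.vector(mat[-nrow(mat), , drop = FALSE]),
                as.vector(mat[-1, , drop = FALSE]))
  pairs <- rbind(horiz, vert)
  stats::cor(pairs[, 1], pairs[, 2])
}

#' Generate a synthetic restoration landscape
#'
#' Builds a planning-unit grid carrying everything the prioritization
#' needs: per-unit restorable area (the unit's cost), a spatially
#' autocorrelated carbon sequestration rate field with a configured
#' fraction of missing cells, per-unit counts of people reliant on
#' forests for livelihoods, energy, and housing material (with their own
#' missing fraction and a Beta-distributed rural split), an elevation
#' raster, a categorical habitat-class raster, and a nearest-centroid
#' tessellation into subjurisdictions whose disadvantaged/women
#' fractions are calibrated so the population-weighted national means
#' hit the configured targets exactly.
#'
#' Missingness is an explicit `NA` sentinel distinct from zero: units
#' without a carbon rate (or people counts) stay in every optimization
#' problem and are assumed to deliver the other NCP. Exactly
#' `round(frac * n_units)` units are missing per layer, placed in
#' spatially contiguous clusters (lowest values of an independent
#' autocorrelated field).
#'
#' @param config An [generator_config()] object.
#' @param seed Integer seed; the same seed always yields an identical
#'   landscape.
#' @return An object of class `ncp_landscape`: a list with elements
#'   `config`, `seed`, `grid` (dimensions and cell areas), `units` (one
#'   row per planning unit), `elevation` and `habitat_class` matrices,
#'   and `subjurisdictions`.
#' @export
generate_landscape <- function(config = generator_config(), seed = 1L) {
  stopifnot(inherits(config, "ncp_generator_config"))
  validate_generator_config(config)
  nr <- config$nrow
  nc <- config$ncol
  n <- nr * nc
  cell_area_km2 <- config$cell_side_km^2
  cell_area_ha <- cell_area_km2 * 100

  l <- with_seed(seed, {
    unit_id <- seq_len(n)
    row <- (unit_id - 1L) %/% nc + 1L
    col <- (unit_id - 1L) %% nc + 1L
    idx <- cbind(row, col)

    restorable_frac <- stats::rbeta(n, config$restorable_beta[1], config$restorable_beta[2])
    restorable_area <- restorable_frac * cell_area_ha

    carbon_z <- gaussian_field(nr, nc, config$carbon_length_scale)
    carbon_rate <- stats::qlnorm(stats::pnorm(carbon_z[idx]),
                                 meanlog = config$carbon_rate_meanlog,
                                 sdlog = config$carbon_rate_sdlog)
    k_carbon <- round(config$missing_carbon_frac * n)
    if (k_carbon > 0) {
      miss_field <- gaussian_field(nr, nc, config$carbon_length_scale)
      miss_units <- order(miss_field[idx], unit_id)[seq_len(k_carbon)]
      carbon_rate[miss_units] <- NA_real_
    }

    need_names <- c("livelihoods", "energy", "housing")
    people <- matrix(NA_real_, nrow = n, ncol = 3L,
                     dimnames = list(NULL, need_names))
    for (j in 1:3) {
      z <- gaussian_field(nr, nc, config$people_length_scale)
      mu <- log(config$people_mean[j]) - config$people_sdlog^2 / 2
      people[, j] <- stats::qlnorm(stats::pnorm(z[idx]), mu, config$people_sdlog)
    }
    k_people <- round(config$missing_people_frac * n)
    if (k_people > 0) {
      miss_field <- gaussian_field(nr, nc, config$people_length_scale)
      miss_units <- order(miss_field[idx], unit_id)[seq_len(k_people)]
      people[miss_units, ] <- NA_real_
    }

    rural_fraction <- stats::rbeta(n, config$rural_beta[1], config$rural_beta[2])

    elev_z <- gaussian_field(nr, nc, config$elev_length_scale)
    elevation <- config$elev_max_m * stats::pnorm(elev_z)

    hab_z <- gaussian_field(nr, nc, config$habitat_length_scale)
    breaks <- stats::quantile(hab_z, probs = seq(0, 1, length.out = config$n_habitat_classes + 1L))
    habitat_class <- matrix(
      pmin(config$n_habitat_classes,
           pmax(1L, findInterval(hab_z, breaks, rightmost.closed = TRUE))),
      nrow = nr, ncol = nc)
    storage.mode(habitat_class) <- "integer"

    centroids <- sort(sample.int(n, config$n_subjur))
    crow <- (centroids - 1L) %/% nc + 1L
    ccol <- (centroids - 1L) %% nc + 1L
    d2 <- outer(row, crow, function(a, b) (a - b)^2) +
      outer(col, ccol, function(a, b) (a - b)^2)
    subjur_id <- max.col(-d2, ties.method = "first")

    pop_z <- gaussian_field(nr, nc, config$people_length_scale)
    unit_pop <- stats::qlnorm(stats::pnorm(pop_z[idx]), log(2000), 0.9)
    population <- round(as.vector(tapply(unit_pop, factor(subjur_id, levels = seq_len(config$n_subjur)), sum)))
    population[is.na(population)] <- 0

    frac_disadvantaged <- stats::rbeta(config$n_subjur, 2, 3.8)
    frac_women <- stats::rbeta(config$n_subjur, 0.489 * 300, 0.511 * 300)

    units <- data.frame(
      unit_id = unit_id, row = row, col = col,
      restorable_area = restorable_area,
      carbon_rate = carbon_rate,
      people_livelihoods = people[, 1],
      people_energy = people[, 2],
      people_housing = people[, 3],
      rural_fraction = rural_fraction,
      subjur_id = subjur_id
    )
    subjurisdictions <- data.frame(
      subjur_id = seq_len(config$n_subjur),
      population = population,
      frac_disadvantaged = frac_disadvantaged,
      frac_women = frac_women
    )
    structure(
      list(config = config, seed = as.integer(seed),
           grid = list(nrow = nr, ncol = nc,
                       cell_side_km = config$cell_side_km,
                       cell_area_km2 = cell_area_km2,
                       cell_area_ha = cell_area_ha),
           units = units,
           elevation = elevation,
           habitat_class = habitat_class,
           subjurisdictions = subjurisdictions),
      class = "ncp_landscape")
  })

  calibrate_subjurisdictions(l,
                             target_disadvantaged = config$target_disadvantaged,
                             target_women = config$target_women)
}

#' @export
print.ncp_landscape <- function(x, ...) {
  cat(sprintf("<ncp_landscape> %d x %d grid (%g km cells), %d units, %d subjurisdictions, seed %d\n",
              x$grid$nrow, x$grid$ncol, x$grid$cell_side_km,
              nrow(x$units), nrow(x$subjurisdictions), x$seed))
  cat(sprintf("  restorable area: %.0f ha total; carbon missing in %d units; people missing in %d units\n",
              sum(x$units$restorable_area),
              sum(is.na(x$units$carbon_rate)),
              sum(is.na(x$units$people_livelihoods))))
  invisible(x)
}

#' Number of planning units in a landscape
#' @param landscape An `ncp_landscape`.
#' @return Integer count.
#' @export
n_units <- function(landscape) nrow(landscape$units)

# Shift-and-clip calibration of a fraction vector so that its
# population-weighted mean equals `target` exactly: bracket the additive
# shift by root finding, then polish with one exact linear solve on the
# unclipped set (clipped entries contribute their bound).
calibrate_fractions <- function(frac, pop, target) {
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  total_pop <- sum(pop)
  if (total_pop <= 0) stop("total population must be positive", call. = FALSE)
  wmean <- function(delta) {
    sum(pop * pmin(1, pmax(0, frac + delta))) / total_pop
  }
  delta <- stats::uniroot(function(d) wmean(d) - target,
                          interval = c(-1, 1), tol = 1e-13)$root
  g <- frac + delta
  free <- g > 0 & g < 1
  pop_free <- sum(pop[free])
  if (pop_free > 0) {
    delta <- (target * total_pop - sum(pop[g >= 1]) - sum(pop[free] * frac[free])) / pop_free
  }
  out <- pmin(1, pmax(0, frac + delta))
  achieved <- sum(pop * out) / total_pop
  if (abs(achieved - target) > 1e-9) {
    stop(sprintf(paste0("calibration infeasible: achieved population-weighted mean %.6f ",
                        "!= target %.6f (fractions pinned at their bounds)"),
                 achieved, target), call. = FALSE)
  }
  out
}

#' Calibrate subjurisdiction demographics to national means
#'
#' Rescales the subjurisdictions' disadvantaged and/or women fractions
#' (additive shift, clipped to \[0, 1\], then an exact re-balancing step
#' on the unclipped set) so that the population-weighted national mean
#' equals the requested target to within 1e-9 (machine precision in
#' practice). The operation is idempotent: re-calibrating to the same
#' target leaves the landscape unchanged.
#'
#' @param landscape An `ncp_landscape`.
#' @param target_disadvantaged,target_women Targets in (0, 1), or `NULL`
#'   to leave that attribute untouched.
#' @return The landscape with calibrated subjurisdiction fractions.
#' @export
calibrate_subjurisdictions <- function(landscape,
                                       target_disadvantaged = NULL,
                                       target_women = NULL) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  sj <- landscape$subjurisdictions
  for (spec in list(list(col = "frac_disadvantaged", target = target_disadvantaged),
                    list(col = "frac_women", target = target_women))) {
    if (is.null(spec$target)) next
    if (spec$target <= 0 || spec$target >= 1) {
      stop("calibration target must be in (0, 1)", call. = FALSE)
    }
    sj[[spec$col]] <- calibrate_fractions(sj[[spec$col]], sj$population, spec$target)
  }
  landscape$subjurisdictions <- sj
  landscape
}
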