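# Grow a contiguous (rook-adjacency) blob of `size` cells starting from
# a random cell, by repeatedly annexing a uniformly chosen frontier cell.
grow_blob <- function(nr, nc, size) {
  n <- nr * nc
  size <- min(size, n)
  start <- sample.int(n, 1L)
  in_blob <- logical(n)
  in_blob[start] <- TRUE
  frontier <- integer(0)
  neighbors <- function(id) {
    r <- (id - 1L) %/% nc + 1L
    cl <- (id - 1L) %% nc + 1L
    out <- integer(0)
    if (r > 1L) out <- c(out, id - nc)
    if (r < nr) out <- c(out, id + nc)
    if (cl > 1L) out <- c(out, id - 1L)
    if (cl < nc) out <- c(out, id + 1L)
    out
  }
  frontier <- neighbors(start)
  while (sum(in_blob) < size && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    frontier <- frontier[frontier != pick]
    if (in_blob[pick]) next
    in_blob[pick] <- TRUE
    nb <- neighbors(pick)
    frontier <- unique(c(frontier, nb[!in_blob[nb]]))
  }
  which(in_blob)
}

#' Generate synthetic species with contiguous ranges
#'
#' Each species is defined the way Area-of-Habitat mapping defines one:
#' a contiguous geographic range (a blob of grid cells), a set of
#' suitable habitat classes, and elevational limits. A configurable
#' share of species (`config$species_viable_share`) is constructed to be
#' "viable": its habitat set includes classes actually present in its
#' range and its elevational window covers part of the range, so its
#' potential AOH inside the restorable mask is nonzero. The remaining
#' species draw preferences freely and may have empty habitat.
#'
#' @param landscape An `ncp_landscape`.
#' @param n_species Number of species (>= 1); rejected if it exceeds the
#'   number of grid cells.
#' @param seed Integer seed (deterministic ranges for a fixed seed).
#' @return A list of `ncp_species` objects, each with fields
#'   `species_id`, `range_units` (integer unit ids), `habitat_classes`,
#'   `elev_min`, `elev_max`.
#' @export
generate_species <- function(landscape, n_species = landscape$config$n_species,
                             seed = landscape$seed + 1000L) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  n_species <- as.integer(n_species)
  nr <- landscape$grid$nrow
  nc <- landscape$grid$ncol
  n <- nr * nc
  if (n_species < 1L) stop("n_species must be >= 1", call. = FALSE)
  if (n_species > n) {
    stop(sprintf("n_species (%d) exceeds grid capacity (%d cells)", n_species, n),
         call. = FALSE)
  }
  cfg <- landscape$config
  hab_mat <- landscape$habitat_class
  elev_mat <- landscape$elevation
  units <- landscape$units
  idx <- cbind(units$row, units$col)
  hab_by_unit <- hab_mat[idx]
  elev_by_unit <- elev_mat[idx]
  n_viable <- round(cfg$species_viable_share * n_species)

  with_seed(seed, {
    lapply(seq_len(n_species), function(s) {
      size <- round(stats::runif(1, cfg$species_range_frac[1], cfg$species_range_frac[2]) * n)
      size <- max(1L, size)
      range_units <- grow_blob(nr, nc, size)
      elev_in_range <- elev_by_unit[range_units]
      if (s <= n_viable) {
        # anchor preferences on one in-range cell with restorable area so
        # potential AOH inside the restorable mask is guaranteed nonzero
        restorable_here <- range_units[units$restorable_area[range_units] > 0]
        anchor_unit <- if (length(restorable_here) > 0) {
          restorable_here[sample.int(length(restorable_here), 1L)]
        } else range_units[sample.int(length(range_units), 1L)]
        anchor <- hab_by_unit[anchor_unit]
        extra <- sample.int(cfg$n_habitat_classes,
                            sample.int(min(2L, cfg$n_habitat_classes), 1L) - 1L)
        habitat_classes <- sort(unique(c(anchor, extra)))
        qs <- stats::quantile(elev_in_range, c(0.05, 0.95), names = FALSE)
        elev_min <- min(qs[1], elev_by_unit[anchor_unit])
        elev_max <- max(qs[2], elev_by_unit[anchor_unit])
      } else {
        habitat_classes <- sort(sample.int(cfg$n_habitat_classes,
                                           sample.int(min(3L, cfg$n_habitat_classes), 1L)))
        e <- sort(stats::runif(2, 0, cfg$elev_max_m))
        elev_min <- e[1]
        elev_max <- e[2]
      }
      structure(list(species_id = sprintf("sp%03d", s),
                     range_units = range_units,
                     habitat_classes = habitat_classes,
                     elev_min = elev_min, elev_max = elev_max),
                class = "ncp_species")
    })
  })
}

#' @export
print.ncp_species <- function(x, ...) {
  cat(sprintf("<ncp_species> %s: range %d cells, habitat {%s}, elevation [%.0f, %.0f] m\n",
              x$species_id, length(x$range_units),
              paste(x$habitat_classes, collapse = ","), x$elev_min, x$elev_max))
  invisible(x)
}
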