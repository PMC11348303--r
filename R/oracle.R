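#' Brute-force optimum for small or single-feature problems
#'
#' Independent verification oracle for [solve_problem()]. Two regimes:
#' binary problems with at most `max_units` units are solved by
#' exhaustive enumeration of all within-budget subsets; proportional
#' problems with exactly one weighted feature are solved by the
#' fractional-knapsack greedy (fill units in decreasing `r_i / c_i`
#' ratio, zero-cost contributing units first), which is provably optimal
#' for the LP. Anything else is rejected.
#'
#' @param problem An `ncp_problem`.
#' @param max_units Enumeration cap for binary mode (default 12).
#' @return The optimal objective value (scalar).
#' @export
brute_force_objective <- function(problem, max_units = 12L) {
  stopifnot(inherits(problem, "ncp_problem"))
  n <- length(problem$costs)
  active <- which(problem$weights > 0 & problem$targets > 0)
  if (problem$decision_mode == "binary") {
    if (n > max_units) {
      stop(sprintf("binary enumeration limited to %d units (got %d)", max_units, n),
           call. = FALSE)
    }
    best <- Inf
    for (mask in 0:(2^n - 1)) {
      sel <- as.numeric(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0)
      if (sum(sel * problem$costs) > problem$budget + 1e-9) next
      delivered <- drop(crossprod(problem$rij, sel))
      obj <- sum(problem$weights[active] *
                   pmax(0, problem$targets[active] - delivered[active]) /
                   problem$targets[active])
      if (obj < best) best <- obj
    }
    if (!is.finite(best)) stop("no feasible subset (budget < 0?)", call. = FALSE)
    return(best)
  }
  if (length(active) != 1L) {
    stop("proportional oracle requires exactly one weighted feature", call. = FALSE)
  }
  j <- active
  r <- problem$rij[, j]
  costs <- problem$costs
  x <- numeric(n)
  x[costs == 0 & r > 0] <- 1  # free units first
  budget <- problem$budget
  ord <- order(-(r / ifelse(costs == 0, Inf, costs)), seq_len(n))
  for (i in ord) {
    if (budget <= 0) break
    if (costs[i] == 0 || r[i] <= 0) next
    take <- min(1, budget / costs[i])
    x[i] <- take
    budget <- budget - take * costs[i]
  }
  delivered <- sum(x * r)
  problem$weights[j] * max(0, problem$targets[j] - delivered) / problem$targets[j]
}

#' Per-NCP delivery metrics of a solution
#'
#' Summarizes what a solution delivers for each NCP: total climate NCP
#' (tC), total societal NCP (persons), and the biodiversity value NCP as
#' the proportion of species features whose habitat restoration target
#' is met (`delivered_j >= t_j` within tolerance).
#'
#' @param solution An `ncp_solution` with `status == "optimal"`.
#' @param stack The `ncp_feature_stack` the problem was built from.
#' @param tol Relative tolerance for the target-met test (default 1e-6).
#' @return A list with `climate_tC`, `societal_persons`,
#'   `biodiversity_fraction` (NA when there are no species features),
#'   and `species_met` (integer count).
#' @export
ncp_metrics <- function(solution, stack, tol = 1e-6) {
  stopifnot(inherits(solution, "ncp_solution"), inherits(stack, "ncp_feature_stack"))
  if (solution$status != "optimal") {
    stop("metrics require an optimal solution (got status '", solution$status, "')",
         call. = FALSE)
  }
  delivered <- solution$delivered
  kinds <- stack$kinds
  sp <- which(kinds == "species")
  met <- sum(delivered[sp] >= stack$targets[sp] - tol * pmax(1, stack$targets[sp]))
  list(climate_tC = sum(delivered[kinds == "climate"]),
       societal_persons = sum(delivered[kinds == "societal"]),
       biodiversity_fraction = if (length(sp) > 0) met / length(sp) else NA_real_,
       species_met = as.integer(met))
}
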