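#' Run a plan x budget sweep
#'
#' Solves one optimization problem per (plan, budget increment): budget
#' level b (1..increments) means `B = b / increments * sum(costs)` ha of
#' restorable area. With the four plan schemes and 100 increments this
#' is the full 400-problem experiment. Any non-optimal solver status
#' aborts the sweep naming the offending (plan, budget). Each problem is
#' independent and deterministic, so results do not depend on execution
#' order; per plan, all budgets are dispatched to the solver backend in
#' a single batched call.
#'
#' @param landscape An `ncp_landscape` (supplies unit costs: restorable
#'   area in ha).
#' @param stack An `ncp_feature_stack`.
#' @param plans List of `ncp_plan`s (default: all four schemes).
#' @param increments Number of evenly spaced budget levels (default 100,
#'   i.e. 1%, 2%, ..., 100% of total restorable area).
#' @param decision_mode,weight_mode Passed to [build_problem()].
#' @param cessation_tol Objective tolerance for [detect_cessation()].
#' @return A list of `ncp_sweep` objects, one per plan, each with
#'   `plan_name`, `budget_pct`, `budgets` (ha), `solutions`,
#'   `objectives`, `delivered` (J x budgets matrix), `metrics` (one row
#'   per budget), `frequency`, `cessation_budget_pct`, `n_problems`.
#' @export
run_sweep <- function(landscape, stack, plans = all_plans(), increments = 100L,
                      decision_mode = "proportional",
                      weight_mode = "group-equal",
                      cessation_tol = 1e-6) {
  stopifnot(inherits(landscape, "ncp_landscape"), inherits(stack, "ncp_feature_stack"))
  increments <- as.integer(increments)
  if (increments < 1L) stop("increments must be >= 1", call. = FALSE)
  costs <- landscape$units$restorable_area
  total <- sum(costs)
  budget_pct <- seq_len(increments) / increments * 100
  budgets <- budget_pct / 100 * total
  budgets[increments] <- total  # guard against round-off above the cap

  lapply(plans, function(plan) {
    problems <- lapply(budgets, function(b) {
      build_problem(stack, costs, b, plan, decision_mode, weight_mode)
    })
    solutions <- solve_problem_set(problems)
    bad <- which(vapply(solutions, function(s) s$status != "optimal", logical(1)))
    if (length(bad) > 0) {
      stop(sprintf("sweep aborted: plan '%s' at budget %.1f%% returned status '%s' (%s)",
                   plan$name, budget_pct[bad[1]], solutions[[bad[1]]]$status,
                   solutions[[bad[1]]]$message), call. = FALSE)
    }
    delivered <- vapply(solutions, `[[`, numeric(length(stack$targets)), "delivered")
    if (is.null(dim(delivered))) delivered <- matrix(delivered, nrow = length(stack$targets))
    rownames(delivered) <- stack$ids
    metrics <- do.call(rbind, lapply(solutions, function(s) {
      m <- ncp_metrics(s, stack)
      data.frame(climate_tC = m$climate_tC, societal_persons = m$societal_persons,
                 biodiversity_fraction = m$biodiversity_fraction,
                 species_met = m$species_met)
    }))
    metrics <- cbind(budget_pct = budget_pct, metrics)
    sweep <- structure(
      list(plan_name = plan$name, budget_pct = budget_pct, budgets = budgets,
           solutions = solutions,
           objectives = vapply(solutions, `[[`, numeric(1), "objective"),
           delivered = delivered, metrics = metrics,
           stack_kinds = stack$kinds, stack_targets = stack$targets,
           n_problems = length(solutions), weight_mode = weight_mode,
           decision_mode = decision_mode),
      class = "ncp_sweep")
    sweep$frequency <- selection_frequency(sweep)
    sweep$cessation_budget_pct <- detect_cessation(sweep, tol = cessation_tol)
    sweep
  })
}

#' @export
print.ncp_sweep <- function(x, ...) {
  cat(sprintf("<ncp_sweep> %s: %d budgets (%.4g..%.4g%%), cessation %s\n",
              x$plan_name, x$n_problems, min(x$budget_pct), max(x$budget_pct),
              if (is.na(x$cessation_budget_pct)) "none"
              else sprintf("at %.4g%%", x$cessation_budget_pct)))
  invisible(x)
}

#' NCP accumulation curves of a sweep
#'
#' For each NCP, the delivered fraction of the maximum deliverable as a
#' function of the budget: climate and societal delivery are divided by
#' their landscape totals (the sum of all contributions), biodiversity
#' is already the fraction of species whose target is met. An NCP whose
#' maximum deliverable is zero is reported as `NA` (undefined), never
#' as 0/0.
#'
#' @param sweep An `ncp_sweep`.
#' @return A tidy data frame: `plan`, `budget_pct`, `ncp`, `delivered`,
#'   `fraction`.
#' @export
accumulation_curves <- function(sweep) {
  stopifnot(inherits(sweep, "ncp_sweep"))
  kinds <- sweep$stack_kinds
  max_climate <- sum(sweep$stack_targets[kinds == "climate"])
  max_societal <- sum(sweep$stack_targets[kinds == "societal"])
  climate <- colSums(sweep$delivered[kinds == "climate", , drop = FALSE])
  societal <- colSums(sweep$delivered[kinds == "societal", , drop = FALSE])
  rows <- list(
    data.frame(plan = sweep$plan_name, budget_pct = sweep$budget_pct,
               ncp = "climate", delivered = climate,
               fraction = if (max_climate > 0) climate / max_climate else NA_real_),
    data.frame(plan = sweep$plan_name, budget_pct = sweep$budget_pct,
               ncp = "societal", delivered = societal,
               fraction = if (max_societal > 0) societal / max_societal else NA_real_),
    data.frame(plan = sweep$plan_name, budget_pct = sweep$budget_pct,
               ncp = "biodiversity",
               delivered = sweep$metrics$species_met,
               fraction = sweep$metrics$biodiversity_fraction)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Selection frequency of planning units over a sweep
#'
#' How often each unit enters the optimal solution across the budget
#' levels: `count` is the number of budgets at which
#' `x_i >= inclusion_threshold` (the thresholded map), `fractional` is
#' `sum_b x_i^(b)` (the fractional-sum alternative); both are emitted.
#'
#' @param sweep An `ncp_sweep`.
#' @param inclusion_threshold Threshold on the decision proportion
#'   (default 0.5).
#' @return A data frame: `unit_id`, `count` (0..n budgets),
#'   `fractional`.
#' @export
selection_frequency <- function(sweep, inclusion_threshold = 0.5) {
  stopifnot(inherits(sweep, "ncp_sweep"))
  xs <- vapply(sweep$solutions, `[[`, numeric(length(sweep$solutions[[1]]$x)), "x")
  if (is.null(dim(xs))) xs <- matrix(xs, ncol = length(sweep$solutions))
  data.frame(unit_id = seq_len(nrow(xs)),
             count = as.integer(rowSums(xs >= inclusion_threshold)),
             fractional = rowSums(xs))
}

#' Cessation budget of a plan
#'
#' The smallest budget level at which the plan's weighted objective
#' drops to (numerical) zero, i.e. all its targets are met and further
#' budget changes nothing for that plan. `NA` if the objective never
#' reaches the tolerance (e.g. an unreachable target keeps the
#' shortfall bounded away from zero).
#'
#' @param sweep An `ncp_sweep`.
#' @param tol Absolute objective tolerance (default 1e-6).
#' @return Budget percentage (scalar) or `NA`.
#' @export
detect_cessation <- function(sweep, tol = 1e-6) {
  stopifnot(inherits(sweep, "ncp_sweep"))
  hit <- which(sweep$objectives <= tol)
  if (length(hit) == 0) NA_real_ else sweep$budget_pct[hit[1]]
}
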