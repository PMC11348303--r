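#' Plan schemes
#'
#' The four restoration plan types are weight assignments over the NCP
#' features: single-NCP plans (carbon-centric, biodiversity-centric,
#' people-centric) weight only their own NCP, the integrated plan
#' weights all NCP. Under the default group-equal rule each NCP group
#' receives total weight 1, so the N species features are weighted 1/N
#' each and no group can dominate by feature count; the feature-equal
#' alternative gives every feature (including every species) weight 1.
#'
#' @param name One of `"carbon-centric"`, `"biodiversity-centric"`,
#'   `"people-centric"`, `"integrated"`.
#' @return An object of class `ncp_plan`.
#' @export
plan_scheme <- function(name = c("carbon-centric", "biodiversity-centric",
                                 "people-centric", "integrated")) {
  name <- match.arg(name)
  structure(list(name = name), class = "ncp_plan")
}

#' @rdname plan_scheme
#' @return `all_plans()` returns the list of all four plan schemes.
#' @export
all_plans <- function() {
  lapply(c("carbon-centric", "biodiversity-centric", "people-centric",
           "integrated"), plan_scheme)
}

#' @export
print.ncp_plan <- function(x, ...) {
  cat(sprintf("<ncp_plan> %s\n", x$name))
  invisible(x)
}

# Weight vector for a plan over a feature stack.
plan_weights <- function(plan, stack, weight_mode = c("group-equal", "feature-equal")) {
  weight_mode <- match.arg(weight_mode)
  kinds <- stack$kinds
  n_sp <- max(1L, stack$n_species)
  w_species <- if (weight_mode == "group-equal") 1 / n_sp else 1
  switch(plan$name,
         "carbon-centric" = as.numeric(kinds == "climate"),
         "people-centric" = as.numeric(kinds == "societal"),
         "biodiversity-centric" = ifelse(kinds == "species", 1 / n_sp, 0),
         "integrated" = ifelse(kinds == "species", w_species, 1))
}

#' Build one optimization problem
#'
#' Assembles a budget-constrained minimum weighted proportional
#' shortfall instance: minimize `sum_j w_j * y_j / t_j` subject to
#' `sum_i x_i r_ij + y_j >= t_j` for every feature j, the budget
#' constraint `sum_i x_i c_i <= B`, `0 <= x_i <= 1` and `y_j >= 0`.
#' Weights follow the plan scheme; features with a zero target are
#' dropped from the objective (their proportional shortfall is
#' undefined) but their delivery is still reported.
#'
#' @param stack An `ncp_feature_stack`.
#' @param unit_costs Per-unit cost vector `c_i` (ha of restorable area).
#' @param budget Budget `B` in the same units as `unit_costs`; must lie
#'   in `[0, sum(unit_costs)]`.
#' @param plan An `ncp_plan` (or plan name).
#' @param decision_mode `"proportional"` (continuous x in \[0, 1\], the
#'   default) or `"binary"` (x in \{0, 1\}, a MILP).
#' @param weight_mode `"group-equal"` (default) or `"feature-equal"`;
#'   see [plan_scheme()].
#' @return An `ncp_problem`: list with `rij`, `targets`, `weights`,
#'   `kinds`, `ids`, `costs`, `budget`, `decision_mode`, `plan_name`,
#'   `weight_mode`.
#' @export
build_problem <- function(stack, unit_costs, budget, plan,
                          decision_mode = c("proportional", "binary"),
                          weight_mode = c("group-equal", "feature-equal")) {
  stopifnot(inherits(stack, "ncp_feature_stack"))
  decision_mode <- match.arg(decision_mode)
  weight_mode <- match.arg(weight_mode)
  if (is.character(plan)) plan <- plan_scheme(plan)
  if (length(unit_costs) != nrow(stack$rij)) {
    stop("unit_costs length must match the number of units", call. = FALSE)
  }
  if (any(unit_costs < 0)) stop("unit costs must be >= 0", call. = FALSE)
  if (budget < 0) stop("budget must be >= 0", call. = FALSE)
  if (budget > sum(unit_costs) + 1e-9) {
    stop(sprintf("budget (%.6g) exceeds total restorable area (%.6g)",
                 budget, sum(unit_costs)), call. = FALSE)
  }
  w <- plan_weights(plan, stack, weight_mode)
  w[stack$targets <= 0] <- 0
  if (all(w == 0)) {
    stop("problem has no feature with positive weight and positive target",
         call. = FALSE)
  }
  structure(list(rij = stack$rij, targets = stack$targets, weights = w,
                 kinds = stack$kinds, ids = stack$ids,
                 costs = unit_costs, budget = budget,
                 decision_mode = decision_mode, plan_name = plan$name,
                 weight_mode = weight_mode),
            class = "ncp_problem")
}

#' @export
print.ncp_problem <- function(x, ...) {
  cat(sprintf("<ncp_problem> %s (%s, %s): %d units, %d features (%d weighted), budget %.4g / %.4g\n",
              x$plan_name, x$decision_mode, x$weight_mode,
              length(x$costs), length(x$targets), sum(x$weights > 0),
              x$budget, sum(x$costs)))
  invisible(x)
}

#' Evaluate the weighted proportional shortfall of a decision vector
#'
#' Computes `sum_j w_j * max(0, t_j - sum_i x_i r_ij) / t_j` over the
#' problem's weighted features, i.e. the objective value any feasible
#' `x` attains. Used for cross-plan dominance comparisons.
#'
#' @param problem An `ncp_problem` (supplies weights and targets).
#' @param x Decision vector in \[0, 1\] per unit.
#' @return Scalar objective value.
#' @export
shortfall_objective <- function(problem, x) {
  delivered <- drop(crossprod(problem$rij, x))
  active <- problem$weights > 0
  sum(problem$weights[active] *
        pmax(0, problem$targets[active] - delivered[active]) /
        problem$targets[active])
}
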