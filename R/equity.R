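#' Beneficiaries of a solution's societal NCP, by demographic group
#'
#' Apportions the societal NCP delivered by a solution to demographic
#' groups: the total is `sum_i x_i r_i` over the societal contributions,
#' and each unit's beneficiaries are split by its subjurisdiction's
#' fractions of socioeconomically disadvantaged people and of women.
#' Fractional restoration delivers fractional benefit (proportional to
#' `x_i`); the two group fractions are independent marginals.
#'
#' @param solution An optimal `ncp_solution`.
#' @param societal_feature The societal `ncp_feature` (supplies `r_i`).
#' @param landscape The `ncp_landscape` (supplies subjurisdiction
#'   membership and demographic fractions).
#' @return A list with `total`, `disadvantaged`, `women` (persons).
#' @export
beneficiaries <- function(solution, societal_feature, landscape) {
  stopifnot(inherits(solution, "ncp_solution"),
            inherits(societal_feature, "ncp_feature"),
            inherits(landscape, "ncp_landscape"))
  if (societal_feature$kind != "societal") {
    stop("beneficiaries() needs the societal feature", call. = FALSE)
  }
  if (solution$status != "optimal") {
    stop("beneficiaries require an optimal solution", call. = FALSE)
  }
  units <- landscape$units
  sj <- landscape$subjurisdictions
  pos <- match(units$subjur_id, sj$subjur_id)
  if (anyNA(pos)) {
    stop("planning unit mapped to an unknown subjurisdiction", call. = FALSE)
  }
  served <- solution$x * societal_feature$contributions
  list(total = sum(served),
       disadvantaged = sum(served * sj$frac_disadvantaged[pos]),
       women = sum(served * sj$frac_women[pos]))
}

#' National population-weighted demographic averages
#'
#' @param landscape An `ncp_landscape` with populated subjurisdictions.
#' @return A list with `frac_disadvantaged` and `frac_women`, the
#'   population-weighted means over subjurisdictions.
#' @export
national_average <- function(landscape) {
  stopifnot(inherits(landscape, "ncp_landscape"))
  sj <- landscape$subjurisdictions
  pop <- sum(sj$population)
  if (pop <= 0) stop("total population is zero", call. = FALSE)
  list(frac_disadvantaged = sum(sj$population * sj$frac_disadvantaged) / pop,
       frac_women = sum(sj$population * sj$frac_women) / pop)
}

#' Distributional-equity report across plans and budgets
#'
#' For each plan and each requested budget level, reports the societal
#' NCP beneficiaries, the share of them who are socioeconomically
#' disadvantaged or women, and whether each share sits above the
#' population-weighted national average. When a biodiversity-centric
#' sweep with a cessation budget is present, reports are additionally
#' grouped into the phases within and beyond that cessation budget.
#'
#' @param sweeps List of `ncp_sweep`s (one per plan).
#' @param stack The `ncp_feature_stack` used for the sweeps (supplies
#'   the societal contributions).
#' @param landscape The `ncp_landscape`.
#' @param budgets_of_interest Budget percentages to report; each is
#'   matched to the nearest available sweep budget (with a message when
#'   they differ). Empty input yields an empty report.
#' @return A data frame: `plan`, `budget_pct`, `phase`,
#'   `total_beneficiaries`, `disadvantaged_beneficiaries`,
#'   `women_beneficiaries`, `frac_disadvantaged`, `frac_women`,
#'   `national_frac_disadvantaged`, `national_frac_women`,
#'   `above_average_disadvantaged`, `above_average_women`.
#' @export
equity_report <- function(sweeps, stack, landscape,
                          budgets_of_interest = c(10, 25, 50, 75, 100)) {
  stopifnot(inherits(stack, "ncp_feature_stack"), inherits(landscape, "ncp_landscape"))
  empty <- data.frame(plan = character(), budget_pct = numeric(),
                      phase = character(),
                      total_beneficiaries = numeric(),
                      disadvantaged_beneficiaries = numeric(),
                      women_beneficiaries = numeric(),
                      frac_disadvantaged = numeric(), frac_women = numeric(),
                      national_frac_disadvantaged = numeric(),
                      national_frac_women = numeric(),
                      above_average_disadvantaged = logical(),
                      above_average_women = logical())
  if (length(budgets_of_interest) == 0) return(empty)
  j_soc <- which(stack$kinds == "societal")
  if (length(j_soc) != 1L) stop("feature stack must contain one societal feature", call. = FALSE)
  soc <- new_ncp_feature(stack$ids[j_soc], "societal", stack$rij[, j_soc],
                         stack$targets[j_soc], "persons")
  nat <- national_average(landscape)
  cessation <- NA_real_
  for (s in sweeps) {
    if (s$plan_name == "biodiversity-centric") cessation <- s$cessation_budget_pct
  }
  rows <- lapply(sweeps, function(sweep) {
    do.call(rbind, lapply(budgets_of_interest, function(b) {
      k <- which.min(abs(sweep$budget_pct - b))
      if (abs(sweep$budget_pct[k] - b) > 1e-9) {
        message(sprintf("equity_report: budget %.4g%% not in sweep '%s'; using nearest %.4g%%",
                        b, sweep$plan_name, sweep$budget_pct[k]))
      }
      ben <- beneficiaries(sweep$solutions[[k]], soc, landscape)
      frac_dis <- if (ben$total > 0) ben$disadvantaged / ben$total else NA_real_
      frac_wom <- if (ben$total > 0) ben$women / ben$total else NA_real_
      data.frame(plan = sweep$plan_name, budget_pct = sweep$budget_pct[k],
                 phase = if (is.na(cessation)) "all"
                         else if (sweep$budget_pct[k] <= cessation) "within_cessation"
                         else "beyond_cessation",
                 total_beneficiaries = ben$total,
                 disadvantaged_beneficiaries = ben$disadvantaged,
                 women_beneficiaries = ben$women,
                 frac_disadvantaged = frac_dis, frac_women = frac_wom,
                 national_frac_disadvantaged = nat$frac_disadvantaged,
                 national_frac_women = nat$frac_women,
                 above_average_disadvantaged = !is.na(frac_dis) && frac_dis > nat$frac_disadvantaged,
                 above_average_women = !is.na(frac_wom) && frac_wom > nat$frac_women)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
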