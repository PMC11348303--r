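# Locate the python interpreter used for the HiGHS backend.
backend_python <- function() {
  py <- getOption("forestNCP.python", Sys.which("python"))
  if (!nzchar(py)) {
    stop("no 'python' interpreter found on the PATH; the LP backend needs ",
         "Python with numpy and scipy >= 1.9", call. = FALSE)
  }
  py
}

backend_script <- function() {
  path <- system.file("python", "lp_backend.py", package = "forestNCP")
  if (!nzchar(path)) stop("lp_backend.py not found in the installed package", call. = FALSE)
  path
}

# Low-level batched solve. `instances` is a list of lists with fields
# costs (n), targets (J), rij (n x J matrix), problems (list of lists
# with weights, budget, binary). One python subprocess per call; all
# instances and problems are solved in that single call.
backend_solve <- function(instances) {
  payload <- list(instances = lapply(instances, function(inst) {
    list(costs = inst$costs,
         targets = inst$targets,
         rij = t(inst$rij),  # serialize as J rows over units
         problems = lapply(inst$problems, function(p) {
           list(weights = p$weights, budget = p$budget,
                binary = isTRUE(p$binary))
         }))
  }))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, digits = NA, auto_unbox = TRUE)
  status <- system2(backend_python(), c(backend_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("LP backend failed (exit ", code, "):\n",
         paste(status, collapse = "\n"), call. = FALSE)
  }
  jsonlite::fromJSON(fout, simplifyVector = FALSE)$instances
}

new_solution <- function(problem, raw) {
  if (!identical(raw$status, "optimal")) {
    return(structure(list(x = rep(NA_real_, length(problem$costs)),
                          shortfalls = rep(NA_real_, length(problem$targets)),
                          delivered = rep(NA_real_, length(problem$targets)),
                          objective = NA_real_, status = "error",
                          message = raw$message %||% "solver failure",
                          plan_name = problem$plan_name,
                          budget = problem$budget),
                     class = "ncp_solution"))
  }
  x <- as.numeric(unlist(raw$x))
  delivered <- drop(crossprod(problem$rij, x))
  names(delivered) <- problem$ids
  shortfalls <- pmax(0, problem$targets - delivered)
  names(shortfalls) <- problem$ids
  objective <- shortfall_objective(problem, x)
  solver_obj <- as.numeric(raw$objective)
  if (abs(objective - solver_obj) > 1e-6 * max(1, abs(solver_obj))) {
    warning(sprintf("recomputed objective %.10g differs from solver objective %.10g",
                    objective, solver_obj), call. = FALSE)
  }
  structure(list(x = x, shortfalls = shortfalls, delivered = delivered,
                 objective = objective, status = "optimal", message = "",
                 plan_name = problem$plan_name, budget = problem$budget),
            class = "ncp_solution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve one prioritization problem
#'
#' Solves the minimum weighted proportional shortfall program with the
#' HiGHS solver (linear program in proportional mode; mixed-integer
#' program in binary mode). The solve is deterministic for a fixed
#' problem; residual degeneracy is resolved by the input unit ordering.
#' Solver failures surface as a solution with `status = "error"` and the
#' solver's message, never as a silent partial result.
#'
#' @param problem An `ncp_problem` from [build_problem()].
#' @return An `ncp_solution`: list with `x` (decision vector),
#'   `shortfalls` (`y_j = max(0, t_j - delivered_j)` for every feature,
#'   weighted or not), `delivered` (per-feature `sum_i x_i r_ij`),
#'   `objective`, `status`, `plan_name`, `budget`.
#' @export
solve_problem <- function(problem) {
  solve_problem_set(list(problem))[[1]]
}

#' Solve a set of problems sharing one feature stack in a single batch
#'
#' All problems must share identical contribution matrices, targets and
#' costs (e.g. one plan x many budgets); they are dispatched to the
#' backend in one subprocess call.
#'
#' @param problems List of `ncp_problem`s.
#' @return List of `ncp_solution`s, in input order.
#' @export
solve_problem_set <- function(problems) {
  stopifnot(length(problems) > 0)
  lapply(problems, function(p) stopifnot(inherits(p, "ncp_problem")))
  p1 <- problems[[1]]
  shared <- all(vapply(problems, function(p) {
    identical(p$rij, p1$rij) && identical(p$targets, p1$targets) &&
      identical(p$costs, p1$costs)
  }, logical(1)))
  if (shared) {
    inst <- list(costs = p1$costs, targets = p1$targets, rij = p1$rij,
                 problems = lapply(problems, function(p) {
                   list(weights = p$weights, budget = p$budget,
                        binary = p$decision_mode == "binary")
                 }))
    raw <- backend_solve(list(inst))[[1]]$solutions
    return(Map(new_solution, problems, raw))
  }
  instances <- lapply(problems, function(p) {
    list(costs = p$costs, targets = p$targets, rij = p$rij,
         problems = list(list(weights = p$weights, budget = p$budget,
                              binary = p$decision_mode == "binary")))
  })
  raw <- backend_solve(instances)
  Map(function(p, inst) new_solution(p, inst$solutions[[1]]), problems, raw)
}

#' @export
print.ncp_solution <- function(x, ...) {
  if (x$status != "optimal") {
    cat(sprintf("<ncp_solution> %s @ budget %.4g: %s (%s)\n",
                x$plan_name, x$budget, x$status, x$message))
  } else {
    cat(sprintf("<ncp_solution> %s @ budget %.4g: objective %.6g, %d units selected (x > 0.5)\n",
                x$plan_name, x$budget, x$objective, sum(x$x > 0.5)))
  }
  invisible(x)
}
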