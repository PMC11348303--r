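small_sweep_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      l <- generate_landscape(generator_config(nrow = 10, ncol = 10,
                                               n_species = 5, n_subjur = 4,
                                               species_viable_share = 1),
                              seed = 21)
      sp <- generate_species(l, n_species = 5, seed = 211)
      st <- build_feature_stack(l, sp)$stack
      cache <<- list(l = l, st = st,
                     sweeps = run_sweep(l, st, increments = 10L))
    }
    cache
  }
})

test_that("the sweep solves one problem per plan and budget", {
  fx <- small_sweep_fixture()
  expect_length(fx$sweeps, 4)
  expect_true(all(vapply(fx$sweeps, `[[`, integer(1), "n_problems") == 10L))
  one <- run_sweep(fx$l, fx$st, plans = list(plan_scheme("carbon-centric")),
                   increments = 1L)
  expect_length(one, 1)
  expect_equal(one[[1]]$n_problems, 1L)
  expect_equal(one[[1]]$budget_pct, 100)

  five <- run_sweep(fx$l, fx$st, plans = list(plan_scheme("people-centric")),
                    increments = 5L)
  expect_equal(five[[1]]$budget_pct, c(20, 40, 60, 80, 100))
})

test_that("budget constraints hold at every sweep point", {
  fx <- small_sweep_fixture()
  costs <- fx$l$units$restorable_area
  for (sw in fx$sweeps) {
    for (k in seq_along(sw$solutions)) {
      spend <- sum(sw$solutions[[k]]$x * costs)
      expect_lte(spend, sw$budgets[k] * (1 + 1e-6))
    }
  }
})

test_that("accumulation curves are tidy and bounded", {
  fx <- small_sweep_fixture()
  curves <- do.call(rbind, lapply(fx$sweeps, accumulation_curves))
  expect_named(curves, c("plan", "budget_pct", "ncp", "delivered", "fraction"))
  expect_equal(nrow(curves), 4 * 10 * 3)
  expect_true(all(curves$fraction >= -1e-9 & curves$fraction <= 1 + 1e-9))
})

test_that("a zero-maximum NCP yields an undefined curve, not 0/0", {
  l <- generate_landscape(generator_config(nrow = 5, ncol = 5, n_species = 2,
                                           n_subjur = 2, species_viable_share = 1),
                          seed = 30)
  l$units$carbon_rate[] <- 0  # degenerate climate layer
  sp <- generate_species(l, n_species = 2, seed = 301)
  st <- build_feature_stack(l, sp)$stack
  sw <- run_sweep(l, st, plans = list(plan_scheme("people-centric")),
                  increments = 2L)
  curves <- accumulation_curves(sw[[1]])
  expect_true(all(is.na(curves$fraction[curves$ncp == "climate"])))
  expect_false(anyNA(curves$fraction[curves$ncp == "societal"]))
})

test_that("selection frequency counts thresholded and fractional inclusion", {
  xs <- c(rep(1, 7), rep(0.2, 3))  # one unit across a 10-budget sweep
  fake <- structure(list(solutions = lapply(xs, function(v) list(x = c(v, 0)))),
                    class = "ncp_sweep")
  freq <- selection_frequency(fake)
  expect_equal(freq$count, c(7L, 0L))
  expect_equal(freq$fractional, c(7.6, 0))

  fx <- small_sweep_fixture()
  for (sw in fx$sweeps) {
    expect_true(all(sw$frequency$count >= 0 & sw$frequency$count <= 10))
    expect_true(all(sw$frequency$fractional >= -1e-9 &
                      sw$frequency$fractional <= 10 + 1e-9))
  }
})

test_that("cessation detection finds the first zero-objective budget", {
  fake <- structure(list(objectives = c(0.8, 0.4, 1e-9, 0, 0),
                         budget_pct = c(20, 40, 60, 80, 100)),
                    class = "ncp_sweep")
  expect_equal(detect_cessation(fake), 60)
  expect_equal(detect_cessation(fake, tol = Inf), 20)  # degenerate tolerance
  never <- structure(list(objectives = rep(0.5, 3), budget_pct = c(1, 2, 3)),
                     class = "ncp_sweep")
  expect_true(is.na(detect_cessation(never)))
})

test_that("an unreachable target keeps the shortfall bounded away from zero", {
  l <- generate_landscape(generator_config(nrow = 5, ncol = 5, n_species = 1,
                                           n_subjur = 2, species_viable_share = 1),
                          seed = 31)
  sp <- generate_species(l, n_species = 1, seed = 311)
  rec <- species_target_table(sp, l)
  per_unit <- attr(rec, "per_unit_aoh")
  rec$restoration_target <- sum(per_unit) * 2  # beyond deliverable habitat
  rec$in_subset <- TRUE
  attr(rec, "per_unit_aoh") <- per_unit
  st <- suppressWarnings(assemble_features(climate_feature(l), societal_feature(l),
                                           species_features(rec)))
  sw <- run_sweep(l, st, plans = list(plan_scheme("biodiversity-centric")),
                  increments = 4L)
  expect_true(is.na(sw[[1]]$cessation_budget_pct))
  expect_true(all(sw[[1]]$objectives >= 0.5 - 1e-9))
})

test_that("plan dominance holds on the sweep objectives", {
  fx <- small_sweep_fixture()
  costs <- fx$l$units$restorable_area
  by_plan <- setNames(fx$sweeps, vapply(fx$sweeps, `[[`, character(1), "plan_name"))
  for (target_plan in names(by_plan)) {
    for (k in seq_along(by_plan[[target_plan]]$budget_pct)) {
      prob <- build_problem(fx$st, costs, by_plan[[target_plan]]$budgets[k],
                            target_plan)
      own <- shortfall_objective(prob, by_plan[[target_plan]]$solutions[[k]]$x)
      for (other_plan in setdiff(names(by_plan), target_plan)) {
        other <- shortfall_objective(prob, by_plan[[other_plan]]$solutions[[k]]$x)
        expect_lte(own, other + 1e-6)
      }
    }
  }
})

test_that("sweep results are independent of execution order", {
  fx <- small_sweep_fixture()
  again <- run_sweep(fx$l, fx$st, plans = rev(all_plans()), increments = 10L)
  names1 <- vapply(fx$sweeps, `[[`, character(1), "plan_name")
  names2 <- vapply(again, `[[`, character(1), "plan_name")
  for (nm in names1) {
    s1 <- fx$sweeps[[which(names1 == nm)]]
    s2 <- again[[which(names2 == nm)]]
    expect_identical(s1$objectives, s2$objectives)
    expect_identical(s1$frequency, s2$frequency)
  }
})

test_that("nestedness of consecutive priorities is measured, not asserted", {
  # Jaccard similarity between consecutive budgets' selected sets: a
  # diagnostic of the 'nested priorities' narrative, expected high for
  # single-feature plans but not guaranteed by independent LP solves.
  fx <- small_sweep_fixture()
  sw <- fx$sweeps[[which(vapply(fx$sweeps, `[[`, character(1), "plan_name") ==
                           "carbon-centric")]]
  jac <- vapply(seq_len(length(sw$solutions) - 1), function(k) {
    a <- sw$solutions[[k]]$x >= 0.5
    b <- sw$solutions[[k + 1]]$x >= 0.5
    if (sum(a | b) == 0) return(1)
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_true(all(jac >= 0 & jac <= 1))
})
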