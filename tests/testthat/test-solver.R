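test_that("plan schemes set the weights the plan type prescribes", {
  l <- generate_landscape(small_config(species_viable_share = 1), seed = 6)
  sp <- generate_species(l, n_species = 4, seed = 61)
  st <- build_feature_stack(l, sp)$stack
  costs <- l$units$restorable_area
  b <- sum(costs) / 2

  carbon <- build_problem(st, costs, b, "carbon-centric")
  expect_equal(sum(carbon$weights > 0), 1)
  expect_equal(carbon$weights[st$kinds == "climate"], 1)

  people <- build_problem(st, costs, b, "people-centric")
  expect_equal(which(people$weights > 0), which(st$kinds == "societal"))

  n_sp <- st$n_species
  bio <- build_problem(st, costs, b, "biodiversity-centric")
  expect_equal(unique(bio$weights[st$kinds == "species"]), 1 / n_sp)
  expect_equal(sum(bio$weights), 1)

  integ <- build_problem(st, costs, b, "integrated")
  expect_equal(sum(integ$weights[st$kinds == "species"]), 1)
  expect_equal(sum(integ$weights), 3)

  integ_fe <- build_problem(st, costs, b, "integrated", weight_mode = "feature-equal")
  expect_true(all(integ_fe$weights == 1))

  expect_error(build_problem(st, costs, sum(costs) * 1.01, "integrated"),
               "exceeds total")
  expect_error(build_problem(st, costs, -1, "integrated"), ">= 0")
})

test_that("zero-target features are dropped from the objective", {
  f_ok <- forestNCP:::new_ncp_feature("climate", "climate", c(1, 2), 3, "tC")
  f_zero <- forestNCP:::new_ncp_feature("societal", "societal", c(0, 0), 0, "persons")
  st <- assemble_features(f_ok, f_zero)
  p <- build_problem(st, c(1, 1), 1, "integrated")
  expect_equal(p$weights[2], 0)
  # a plan whose only NCP has a zero target cannot be built
  expect_error(build_problem(st, c(1, 1), 1, "people-centric"), "positive weight")
})

test_that("a small LP reproduces the enumerated optimum", {
  # 3 units, c = (1,1,1), one feature r = (3,2,1), t = 6, B = 2:
  # best pair is units 1+2, shortfall 1, objective 1/6
  p <- make_test_problem(matrix(c(3, 2, 1), 3, 1), 6, 1, c(1, 1, 1), 2)
  s <- solve_problem(p)
  expect_equal(s$status, "optimal")
  expect_equal(s$objective, 1 / 6, tolerance = 1e-8)
  expect_equal(s$x, c(1, 1, 0), tolerance = 1e-7)
  expect_equal(unname(s$shortfalls), 1, tolerance = 1e-7)
  expect_equal(brute_force_objective(make_test_problem(
    matrix(c(3, 2, 1), 3, 1), 6, 1, c(1, 1, 1), 2, "binary")), 1 / 6)
})

test_that("full and empty budgets hit their closed-form solutions", {
  l <- generate_landscape(small_config(), seed = 13)
  sp <- generate_species(l, n_species = 3, seed = 131)
  st <- build_feature_stack(l, sp)$stack
  costs <- l$units$restorable_area

  pf <- build_problem(st, costs, sum(costs), "integrated")
  sf <- solve_problem(pf)
  expect_equal(sf$status, "optimal")
  expect_lt(sf$objective, 1e-6)  # all targets attainable at full budget
  rel_short <- sf$shortfalls[st$kinds != "species"] /
    pmax(1, st$targets[st$kinds != "species"])
  expect_lt(max(rel_short), 1e-6)

  p0 <- build_problem(st, costs, 0, "integrated")
  s0 <- solve_problem(p0)
  expect_equal(s0$x, rep(0, length(costs)), tolerance = 1e-9)
  expect_equal(unname(s0$shortfalls), st$targets, tolerance = 1e-9)
  expect_equal(s0$objective, sum(p0$weights[p0$weights > 0]), tolerance = 1e-9)
})

test_that("binary solutions match exhaustive enumeration", {
  set.seed(301)
  problems <- replicate(100, random_binary_problem(), simplify = FALSE)
  solutions <- solve_problem_set(problems)
  for (k in seq_along(problems)) {
    s <- solutions[[k]]
    expect_equal(s$status, "optimal")
    expect_true(all(abs(s$x - round(s$x)) < 1e-9))  # integrality
    expect_lte(sum(s$x * problems[[k]]$costs), problems[[k]]$budget + 1e-6)
    oracle <- brute_force_objective(problems[[k]])
    expect_equal(s$objective, oracle,
                 tolerance = 1e-6 * max(1, abs(oracle)))
  }
})

test_that("proportional single-feature solutions match the greedy knapsack", {
  set.seed(302)
  problems <- replicate(100, random_single_feature_problem(), simplify = FALSE)
  solutions <- solve_problem_set(problems)
  for (k in seq_along(problems)) {
    s <- solutions[[k]]
    expect_equal(s$status, "optimal")
    expect_true(all(s$x >= -1e-9 & s$x <= 1 + 1e-9))
    expect_lte(sum(s$x * problems[[k]]$costs), problems[[k]]$budget + 1e-6)
    oracle <- brute_force_objective(problems[[k]])
    expect_equal(s$objective, oracle,
                 tolerance = 1e-6 * max(1, abs(oracle)))
  }
})

test_that("the oracle rejects instances outside its regimes", {
  big <- make_test_problem(matrix(1, 13, 1), 5, 1, rep(1, 13), 4, "binary")
  expect_error(brute_force_objective(big), "12 units")
  multi <- make_test_problem(matrix(1, 4, 2), c(2, 2), c(1, 1), rep(1, 4), 2)
  expect_error(brute_force_objective(multi), "one weighted feature")
})

test_that("nothing-deliverable problems cost the full weight regardless of budget", {
  p <- make_test_problem(matrix(0, 4, 2), c(5, 3), c(0.4, 0.6), rep(1, 4), 2,
                         "binary")
  expect_equal(brute_force_objective(p), 1)
  s <- solve_problem(p)
  expect_equal(s$objective, 1, tolerance = 1e-9)
})

test_that("solves are deterministic and consistent between call paths", {
  set.seed(303)
  p <- random_binary_problem()
  p$decision_mode <- "proportional"
  s1 <- solve_problem(p)
  s2 <- solve_problem(p)
  expect_identical(s1$x, s2$x)
  s3 <- solve_problem_set(list(p, p))
  expect_identical(s3[[1]]$x, s1$x)
  expect_identical(s3[[2]]$x, s1$x)
})

test_that("NCP metrics summarize delivery per kind", {
  l <- generate_landscape(small_config(species_viable_share = 1), seed = 17)
  sp <- generate_species(l, n_species = 4, seed = 171)
  st <- build_feature_stack(l, sp)$stack
  costs <- l$units$restorable_area

  s_full <- solve_problem(build_problem(st, costs, sum(costs), "integrated"))
  m_full <- ncp_metrics(s_full, st)
  expect_equal(m_full$biodiversity_fraction, 1)  # all targets attainable
  expect_equal(m_full$climate_tC, sum(st$targets[st$kinds == "climate"]),
               tolerance = 1e-6)

  s_0 <- solve_problem(build_problem(st, costs, 0, "integrated"))
  m_0 <- ncp_metrics(s_0, st)
  expect_equal(m_0$climate_tC, 0, tolerance = 1e-9)
  expect_equal(m_0$societal_persons, 0, tolerance = 1e-9)

  # reporting convention: 43 of 56 met prints as 76.8%
  expect_equal(round(43 / 56 * 100, 1), 76.8)
})
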