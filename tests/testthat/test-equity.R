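fake_solution <- function(x) {
  structure(list(x = x, status = "optimal"), class = "ncp_solution")
}

test_that("beneficiaries are apportioned by x_i and subjurisdiction fractions", {
  sj <- data.frame(subjur_id = 1:2, population = c(500, 500),
                   frac_disadvantaged = c(0.1, 0.5), frac_women = c(0.4, 0.6))
  l <- make_test_landscape(1, 2, subjur_id = c(1L, 2L), subjur = sj)
  soc <- forestNCP:::new_ncp_feature("societal", "societal", c(100, 300), 400,
                                     "persons")
  ben <- beneficiaries(fake_solution(c(1, 0.5)), soc, l)
  expect_equal(ben$total, 250)
  expect_equal(ben$disadvantaged, 100 * 0.1 + 150 * 0.5)  # 85
  expect_equal(ben$disadvantaged / ben$total, 0.34)
  expect_equal(ben$women, 100 * 0.4 + 150 * 0.6)

  ben0 <- beneficiaries(fake_solution(c(0, 0)), soc, l)
  expect_equal(ben0$total, 0)
  expect_equal(ben0$disadvantaged, 0)
  expect_equal(ben0$women, 0)
})

test_that("uniform demographic fractions reproduce themselves exactly", {
  set.seed(71)
  n_sub <- 5
  sj <- data.frame(subjur_id = 1:n_sub, population = sample(100:1000, n_sub),
                   frac_disadvantaged = rep(0.3123456789, n_sub),
                   frac_women = rep(0.5, n_sub))
  l <- make_test_landscape(4, 4, subjur_id = sample(1:n_sub, 16, replace = TRUE),
                           subjur = sj)
  soc <- forestNCP:::new_ncp_feature("societal", "societal",
                                     stats::runif(16, 0, 100), 1, "persons")
  for (i in 1:5) {
    x <- stats::runif(16)
    ben <- beneficiaries(fake_solution(x), soc, l)
    expect_equal(ben$disadvantaged / ben$total, 0.3123456789, tolerance = 1e-12)
    expect_equal(ben$women / ben$total, 0.5, tolerance = 1e-12)
  }
})

test_that("group beneficiaries partition the total exactly", {
  set.seed(72)
  sj <- data.frame(subjur_id = 1:3, population = c(10, 20, 30),
                   frac_disadvantaged = c(0.2, 0.5, 0.9),
                   frac_women = c(0.4, 0.5, 0.6))
  l <- make_test_landscape(3, 3, subjur_id = rep(1:3, 3), subjur = sj)
  soc <- forestNCP:::new_ncp_feature("societal", "societal",
                                     stats::runif(9, 0, 50), 1, "persons")
  x <- stats::runif(9)
  ben <- beneficiaries(fake_solution(x), soc, l)
  sj_flip <- sj
  sj_flip$frac_disadvantaged <- 1 - sj$frac_disadvantaged
  l_flip <- l
  l_flip$subjurisdictions <- sj_flip
  ben_flip <- beneficiaries(fake_solution(x), soc, l_flip)
  expect_equal(ben$disadvantaged + ben_flip$disadvantaged, ben$total)
})

test_that("national averages are population-weighted means", {
  sj1 <- data.frame(subjur_id = 1L, population = 100,
                    frac_disadvantaged = 0.27, frac_women = 0.51)
  l1 <- make_test_landscape(1, 1, subjur_id = 1L, subjur = sj1)
  expect_equal(national_average(l1)$frac_disadvantaged, 0.27)
  expect_equal(national_average(l1)$frac_women, 0.51)

  sj2 <- data.frame(subjur_id = 1:2, population = c(100, 100),
                    frac_disadvantaged = c(0.2, 0.4), frac_women = c(0.4, 0.6))
  l2 <- make_test_landscape(1, 2, subjur_id = c(1L, 2L), subjur = sj2)
  expect_equal(national_average(l2)$frac_disadvantaged, 0.3)

  sj0 <- data.frame(subjur_id = 1L, population = 0,
                    frac_disadvantaged = 0.3, frac_women = 0.5)
  l0 <- make_test_landscape(1, 1, subjur_id = 1L, subjur = sj0)
  expect_error(national_average(l0), "population")
})

test_that("reports are invariant to subjurisdiction relabeling", {
  sj <- data.frame(subjur_id = 1:3, population = c(10, 20, 30),
                   frac_disadvantaged = c(0.2, 0.5, 0.9),
                   frac_women = c(0.4, 0.5, 0.6))
  l <- make_test_landscape(3, 3, subjur_id = rep(1:3, each = 3), subjur = sj)
  soc <- forestNCP:::new_ncp_feature("societal", "societal", rep(10, 9), 90,
                                     "persons")
  x <- seq(0.1, 0.9, by = 0.1)
  ben <- beneficiaries(fake_solution(x), soc, l)
  # relabel 1,2,3 -> 30,10,20 consistently everywhere
  relab <- c(30L, 10L, 20L)
  l2 <- l
  l2$units$subjur_id <- relab[l$units$subjur_id]
  l2$subjurisdictions$subjur_id <- relab
  ben2 <- beneficiaries(fake_solution(x), soc, l2)
  expect_equal(ben, ben2)
})

test_that("units with unknown subjurisdictions are rejected", {
  sj <- data.frame(subjur_id = 1L, population = 100,
                   frac_disadvantaged = 0.3, frac_women = 0.5)
  l <- make_test_landscape(1, 2, subjur_id = c(1L, 9L), subjur = sj)
  soc <- forestNCP:::new_ncp_feature("societal", "societal", c(1, 1), 2, "persons")
  expect_error(beneficiaries(fake_solution(c(1, 1)), soc, l), "unknown subjurisdiction")
})

test_that("high-reliance units in disadvantaged subjurisdictions tilt the people plan", {
  # covariance fixture: subjur 1 (frac 0.6) holds all the forest-reliant
  # people; subjur 2 (frac 0.1) holds none to speak of
  sj <- data.frame(subjur_id = 1:2, population = c(1000, 1000),
                   frac_disadvantaged = c(0.6, 0.1), frac_women = c(0.5, 0.5))
  people <- matrix(1, 8, 3)
  people[1:4, ] <- 500
  l <- make_test_landscape(2, 4, subjur_id = rep(1:2, each = 4L),
                           people = people, subjur = sj)
  st <- assemble_features(climate_feature(l), societal_feature(l))
  sweeps <- run_sweep(l, st, plans = list(plan_scheme("people-centric")),
                      increments = 2L)
  rep50 <- equity_report(sweeps, st, l, budgets_of_interest = 50)
  nat <- national_average(l)
  expect_equal(rep50$national_frac_disadvantaged, nat$frac_disadvantaged)
  expect_gt(rep50$frac_disadvantaged, nat$frac_disadvantaged)
  expect_true(rep50$above_average_disadvantaged)
})

test_that("equity reports cover each plan and requested budget", {
  l <- generate_landscape(generator_config(nrow = 6, ncol = 6, n_species = 2,
                                           n_subjur = 3, species_viable_share = 1),
                          seed = 73)
  sp <- generate_species(l, n_species = 2, seed = 731)
  st <- build_feature_stack(l, sp)$stack
  sweeps <- run_sweep(l, st, increments = 4L)
  rep_all <- equity_report(sweeps, st, l, budgets_of_interest = c(25, 50, 100))
  expect_equal(nrow(rep_all), 4 * 3)
  expect_true(all(rep_all$disadvantaged_beneficiaries <= rep_all$total_beneficiaries + 1e-9))
  expect_true(all(rep_all$women_beneficiaries <= rep_all$total_beneficiaries + 1e-9))
  expect_true(all(rep_all$phase %in% c("within_cessation", "beyond_cessation", "all")))

  expect_equal(nrow(equity_report(sweeps, st, l, budgets_of_interest = numeric(0))), 0)

  expect_message(equity_report(sweeps, st, l, budgets_of_interest = 33),
                 "nearest")
})
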