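test_that("initial population matches the 2000 demographic anchors", {
  pop <- synthesize_initial_population(200000, seed = 1)
  expect_equal(mean(pop$age), 35.8, tolerance = 0.5 / 35.8)
  expect_equal(mean(pop$sex == 1L), 0.491, tolerance = 0.02 / 0.491)
  expect_true(all(pop$age >= 0 & pop$age <= 100))
  expect_true(all(pop$state == 1L))
  one <- synthesize_initial_population(1, seed = 7)
  expect_equal(nrow(one), 1L)
  expect_true(one$age >= 0 && one$age <= 100)
  expect_error(synthesize_initial_population(0), ">= 1")
})

test_that("population synthesis is seed-deterministic and seed-stable", {
  a <- synthesize_initial_population(50000, seed = 3)
  b <- synthesize_initial_population(50000, seed = 3)
  expect_identical(a, b)
  # two seeds draw from the same age distribution (two-sample KS distance)
  x <- synthesize_initial_population(100000, seed = 1)$age
  y <- synthesize_initial_population(100000, seed = 2)$age
  grid <- 0:100
  ks <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
  expect_lt(ks, 0.01)
})

test_that("parametric life table has the intended shape", {
  lt <- make_life_table()
  expect_gte(life_expectancy(lt), 75)
  expect_lte(life_expectancy(lt), 80)
  expect_equal(unname(lt[101, ]), c(1, 1))
  expect_true(all(lt >= 0 & lt <= 1))
  # nondecreasing beyond age 30, and steeply age-graded
  expect_true(all(diff(lt[31:101, "male"]) >= 0))
  expect_true(all(diff(lt[31:101, "female"]) >= 0))
  expect_gt(lt["80", "male"], lt["40", "male"])
  # null hazards: everyone survives to the terminal age
  lt0 <- make_life_table(list(male = c(A = 0, B = 0, c = 0, q0 = 0),
                              female = c(A = 0, B = 0, c = 0, q0 = 0)))
  expect_true(all(lt0[1:100, ] == 0))
  expect_warning(make_life_table(list(
    male = c(A = 0.5, B = 1e-2, c = 0.12, q0 = 0),
    female = c(A = 0.5, B = 1e-2, c = 0.12, q0 = 0))), "clamped")
})

test_that("entrant batches scale by person weight and are unbiased", {
  ser <- data.frame(year = 2001, births = 4e6, net_migrants = 1e6,
                    target_population = NA)
  adult_mig <- data.frame(age_lo = 18, age_hi = 40, weight = 1)
  set.seed(1)
  b <- annual_entrants(ser, 2001, person_weight = 100,
                       migrant_ages = adult_mig)
  expect_equal(nrow(b), 50000L)
  expect_equal(sum(b$age == 0L), 40000L)
  expect_true(all(b$age[b$age > 0] >= 18 & b$age[b$age > 0] <= 40))
  # fractional expectations: stochastic rounding is unbiased
  set.seed(2)
  counts <- replicate(200, nrow(annual_entrants(ser, 2001, 300,
                                                inputs_std$migrant_ages)))
  expect_equal(mean(counts), 5e6 / 300, tolerance = 1.5 / (5e6 / 300))
  # empty year
  ser0 <- data.frame(year = 2001, births = 0, net_migrants = 0,
                     target_population = NA)
  expect_equal(nrow(annual_entrants(ser0, 2001, 100,
                                    inputs_std$migrant_ages)), 0L)
  expect_error(annual_entrants(ser, 1999, 100, inputs_std$migrant_ages),
               "outside")
})

test_that("survival fixtures have registry-like shapes", {
  fx <- make_survival_fixtures()
  expect_length(fx$hcc, 11)
  expect_true(all(diff(fx$hcc) <= 0))
  expect_gt(fx$hcc[1], fx$hcc[6])
  surv5 <- prod(1 - fx$hcc[1:5])
  expect_gte(surv5, 0.10)
  expect_lte(surv5, 0.30)
  expect_equal(dim(fx$lt), c(3L, 11L))
  expect_gte(fx$lt["65+", "1"], fx$lt["18-49", "1"])
  # elevated first-year mortality, then a plateau
  expect_true(all(fx$lt[, "0"] > fx$lt[, "5"]))
  expect_true(all(fx$lt >= 0 & fx$lt <= 1))
})
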