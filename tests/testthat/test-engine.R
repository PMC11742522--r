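test_that("destination distributions reproduce the transition table", {
  d <- destination_distribution("masld", params_t1, fib = 3, mash = TRUE)
  expect_equal(d, c(mash_f2 = 0.1269, mash_f4 = 0.0779, hcc = 0.0011,
                    stay = 1 - 0.1269 - 0.0779 - 0.0011))
  d <- destination_distribution("dc", params_t1)
  expect_equal(d, c(hcc = 0.0011, lt = 0.0062, stay = 0.9927))
  # children cannot acquire MASLD
  d <- destination_distribution("none", params_t1, age = 10,
                                incidence = 0.05)
  expect_equal(d, c(stay = 1))
  # every row is an exact probability distribution
  for (mash in c(FALSE, TRUE)) for (f in 0:4) {
    d <- destination_distribution("masld", params_t1, fib = f, mash = mash,
                                  incidence = 0.02)
    expect_true(all(d >= 0))
    expect_equal(sum(d), 1)
  }
  for (s in c("none", "hcc", "lt"))
    expect_equal(sum(destination_distribution(s, params_t1,
                                              incidence = 0.02)), 1)
  # the MASH switch exists only at fibrosis 0-2
  Tm <- masldsim:::survivor_transition_matrix(params_t1, 0)
  for (f in 3:4) {
    expect_equal(Tm[masldsim:::o_masl(f), masldsim:::o_mash(f)], 0)
    expect_equal(Tm[masldsim:::o_mash(f), masldsim:::o_masl(f)], 0)
  }
  for (f in 0:2) {
    expect_equal(Tm[masldsim:::o_masl(f), masldsim:::o_mash(f)], 0.0060)
    expect_equal(Tm[masldsim:::o_mash(f), masldsim:::o_masl(f)], 0.0130)
  }
})

test_that("mortality composes background and liver causes independently", {
  fx <- make_survival_fixtures()
  M <- build_transition_matrix(params_t1, qx = 0.01, fixtures = fx)
  dc <- masldsim:::O_DC
  expect_equal(M[dc, "liver_death"] + M[dc, "other_death"],
               1 - (1 - 0.01 * 1.15) * (1 - 0.0734))
  expect_equal(M[dc, "liver_death"], 0.0734)
  M <- build_transition_matrix(params_t1, qx = 0.004, fixtures = fx)
  f2 <- masldsim:::o_masl(2)
  expect_equal(M[f2, "liver_death"] + M[f2, "other_death"], 0.0046)
  M <- build_transition_matrix(params_t1, qx = 0, fixtures = fx)
  expect_equal(M["none", "liver_death"] + M["none", "other_death"], 0)
  # engine agrees statistically with the closed form
  pop <- cohort_pop(20000, "dc", age = 40)
  res <- run_closed(pop, 1, qx = 0.01, seed = 5)
  p_tot <- 1 - (1 - 0.0115) * (1 - 0.0734)
  se <- sqrt(p_tot * (1 - p_tot) / 20000)
  expect_lt(abs(sum(res$occ[2, 35:36]) - p_tot), 3 * se)
  se_liv <- sqrt(0.0734 * (1 - 0.0734) / 20000)
  expect_lt(abs(res$occ[2, 35] - 0.0734), 3 * se_liv)
})

test_that("one cycle moves a MASH F3 cohort at the table rates", {
  pop <- cohort_pop(100000, "masld", fib = 3, mash = TRUE, age = 40)
  res <- run_closed(pop, 1, qx = 0, seed = 11)
  occ <- res$occ[2, ]
  for (chk in list(c(masldsim:::o_mash(4), 0.0779),
                   c(masldsim:::o_mash(2), 0.1269),
                   c(masldsim:::o_hcc(0), 0.0011))) {
    p <- chk[2]
    se <- sqrt(p * (1 - p) / 100000)
    expect_lt(abs(occ[chk[1]] - p), 3 * se)
  }
})

test_that("agents age into incidence eligibility at 18", {
  pop <- cohort_pop(2000, "none", age = 10)
  res <- run_closed(pop, 5, qx = 0, incidence = 0.9, seed = 1)
  expect_equal(res$occ[6, 1], 1)  # ages 10 -> 15: still no steatosis
  pop <- cohort_pop(2000, "none", age = 17)
  res <- run_closed(pop, 2, qx = 0, incidence = 1, seed = 1)
  expect_equal(res$occ[2, 1], 1)  # age 17 at the first cycle: ineligible
  expect_equal(res$occ[3, 2], 1)  # age 18 at the second: all acquire
})

test_that("death states are absorbing and mass is conserved", {
  mc <- mixed_cohort(20000)
  res <- run_closed(mc$pop, 20, qx = 0.01, incidence = 0.02, seed = 2)
  dead <- rowSums(res$occ[, 35:36])
  expect_true(all(diff(dead) >= 0))
  expect_equal(rowSums(res$occ), rep(1, 21))
  # survivor count matches the dead complement exactly
  expect_equal(sum(res$pop$state <= 5L) / nrow(res$pop),
               1 - dead[21])
})

test_that("open-population accounting identity holds every cycle", {
  sim <- masld_simulate(masld_scenario(n_agents = 5000, seeds = 1),
                        inputs = inputs_std)
  lg <- sim$logs[[1]]
  expect_equal(lg$alive_end,
               lg$alive_start - lg$deaths + lg$entrants)
  expect_equal(nrow(lg), 50L)
})

test_that("a disease-free model stays disease-free", {
  sim <- masld_simulate(masld_scenario(n_agents = 2000, seeds = 1,
                                       end_year = 2010),
                        schedule = zero_schedule, init = NA,
                        inputs = inputs_std)
  expect_true(all(sim$summary$masld_prev == 0))
  expect_true(all(sim$summary$dc_count == 0))
})

test_that("runs are bit-identical given the same seed", {
  sc <- masld_scenario(n_agents = 3000, seeds = 4, end_year = 2015)
  a <- masld_simulate(sc, inputs = inputs_std)
  b <- masld_simulate(sc, inputs = inputs_std)
  expect_identical(a$summary, b$summary)
  c <- masld_simulate(masld_scenario(n_agents = 3000, seeds = 5,
                                     end_year = 2015),
                      inputs = inputs_std)
  expect_false(identical(a$summary, c$summary))
})
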