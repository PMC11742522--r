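test_that("transition matrix is row-stochastic with absorbing deaths", {
  fx <- make_survival_fixtures()
  for (cfg in list(c(0, 0), c(0.02, 0.01), c(0.5, 0.05))) {
    M <- build_transition_matrix(params_t1, incidence = cfg[1],
                                 qx = cfg[2], fixtures = fx)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-12 * ncol(M))
    expect_true(all(M >= 0))
    expect_equal(M["liver_death", "liver_death"], 1)
    expect_equal(M["other_death", "other_death"], 1)
  }
  # table entries appear verbatim in the MASH F4 row (no mortality)
  M <- build_transition_matrix(params_t1, qx = 0, fixtures = fx)
  f4 <- masldsim:::o_mash(4)
  expect_equal(M[f4, masldsim:::o_mash(3)], 0.0766)
  expect_equal(M[f4, masldsim:::O_DC], 0.0268)
  expect_equal(M[f4, masldsim:::o_hcc(0)], 0.0022)
})

test_that("null parameters freeze the chain (duration bins still advance)", {
  p0 <- params_t1
  p0$values[setdiff(masldsim:::PARAM_NAMES, "hr_masld")] <- 0
  p0$values[["hr_masld"]] <- 1
  p0$lo[] <- NA; p0$hi[] <- NA
  fx <- make_survival_fixtures()
  fx$hcc[] <- 0; fx$lt[] <- 0
  M <- build_transition_matrix(p0, incidence = 0, qx = 0, fixtures = fx)
  expect_equal(unname(diag(M)[1:12]), rep(1, 12))
  expect_equal(M[masldsim:::o_hcc(3), masldsim:::o_hcc(4)], 1)
  expect_equal(M[masldsim:::o_lt(10), masldsim:::o_lt(10)], 1)
})

test_that("expectation iteration reproduces closed-form path sums", {
  fx <- make_survival_fixtures()
  M <- build_transition_matrix(params_t1, qx = 0, fixtures = fx)
  init <- numeric(36); init[masldsim:::o_masl(0)] <- 1
  expect_equal(run_expectation(init, M, 0)[1, ], setNames(init,
               colnames(M)))
  occ <- run_expectation(init, M, 1)
  expect_equal(unname(occ[2, masldsim:::o_masl(1)]), 0.0662)
  # two-step HCC mass from MASH F2: only path is F2 -> F3 -> HCC
  init <- numeric(36); init[masldsim:::o_mash(2)] <- 1
  occ <- run_expectation(init, M, 2)
  expect_equal(unname(sum(occ[3, masldsim:::o_hcc(0:10)])),
               0.0907 * 0.0011)
  expect_error(run_expectation(init, M, -1), ">= 0")
})

test_that("probability mass is conserved over 50 cycles", {
  fx <- make_survival_fixtures()
  M <- build_transition_matrix(params_t1, incidence = 0.02, qx = 0.01,
                               fixtures = fx)
  init <- rep(1 / 34, 36); init[35:36] <- 0
  occ <- run_expectation(init, M, 50)
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-10)
})

test_that("quasi-stationary stage distribution behaves as an eigenmode", {
  qs <- quasi_stationary_stage_distribution(params_t1, "masl")
  expect_equal(sum(qs), 1)
  expect_gt(qs[["f0"]], qs[["f4"]])
  # a symmetric birth-death chain has a uniform quasi-stationary law
  sym <- apply_overrides(params_t1, c(
    masl_f0_to_f1 = 0.05, masl_f1_to_f0 = 0.05, masl_f1_to_f2 = 0.05,
    masl_f2_to_f1 = 0.05, masl_f2_to_f3 = 0.05, masl_f3_to_f2 = 0.05,
    masl_f3_to_f4 = 0.05, masl_f4_to_f3 = 0.05,
    mash_onset = 0, f3_to_hcc = 0, f4_to_dc = 0, f4_to_hcc = 0))
  expect_equal(unname(quasi_stationary_stage_distribution(sym, "masl")),
               rep(0.2, 5), tolerance = 1e-8)
  broken <- apply_overrides(params_t1, c(masl_f1_to_f2 = 0))
  expect_error(quasi_stationary_stage_distribution(broken, "masl"),
               "reducible")
})

test_that("duration-weighted initial mix is milder than quasi-stationary", {
  dw <- duration_weighted_stage_distribution(params_t1)
  expect_equal(sum(dw), 1)
  stage <- dw[1:5] + dw[6:10]
  qs <- quasi_stationary_stage_distribution(params_t1, "masl")
  expect_gt(stage[1], qs[["f0"]])   # more F0
  expect_lt(stage[5], qs[["f4"]])   # less cirrhosis
  expect_true(all(diff(stage) < 0)) # monotone decline across stages
})

test_that("deterministic projector matches the stochastic engine", {
  sc <- masld_scenario(n_agents = 100000, seeds = 1, end_year = 2015)
  sim <- masld_simulate(sc, inputs = inputs_std)
  proj <- project_expectation(params_t1,
                              build_incidence_schedule("base"),
                              sim$init, inputs_std, end_year = 2015)
  expect_equal(sim$summary$masld_prev, proj$masld_prev, tolerance = 0.02)
  expect_equal(sim$summary$total_pop, proj$total_pop, tolerance = 0.005)
  expect_equal(sim$summary$mash_prev, proj$mash_prev, tolerance = 0.06)
})
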