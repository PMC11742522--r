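test_that("incidence schedules obey the scenario plateau rules", {
  base <- build_incidence_schedule("base")
  expect_equal(base$mat[, "2040"], base$mat[, "2030"])
  expect_equal(base$mat[, "2050"], base$mat[, "2030"])
  expect_true(all(base$mat[, "2030"] > base$mat[, "2029"]))
  best <- build_incidence_schedule("best_case")
  expect_equal(best$mat[, "2030"], best$mat[, "2014"])
  worst <- build_incidence_schedule("worst_case")
  expect_true(all(apply(worst$mat, 1, function(r) all(diff(r) > 0))))
  flat <- build_incidence_schedule("base", slope = 0)
  expect_true(all(flat$mat == flat$mat[, 1]))
  expect_error(build_incidence_schedule("base", level = 0.5, slope = 0.02),
               "\\[0, 1\\]")
})

test_that("back-calculation recovers a known initial state", {
  sched <- build_incidence_schedule("base")
  truth <- masld_initial_state(0.25, 0.20, params_t1)
  fwd <- project_expectation(params_t1, sched, truth, inputs_std,
                             end_year = 2015)
  anchors <- data.frame(
    name = c("masld_prevalence", "mash_share"),
    year_start = c(2015, 2012), year_end = c(2015, 2012),
    value = c(extract_target_stat(fwd, "masld_prevalence", 2015),
              extract_target_stat(fwd, "mash_share", 2012)),
    weight = 1, tolerance = 0.5)
  rec <- back_calculate_initial_state(anchors, sched, params_t1,
                                      inputs_std)
  expect_equal(rec$p0, 0.25, tolerance = 0.01 / 0.25)
  expect_equal(rec$mash_share, 0.20, tolerance = 0.02 / 0.20)
  ach <- attr(rec, "anchors_achieved")
  expect_equal(unname(ach["masld_prevalence"]), anchors$value[1],
               tolerance = 0.02 / anchors$value[1])
  # fixed point: anchors equal to the model's unforced output return the
  # starting state unchanged (up to solver tolerance)
  rec2 <- back_calculate_initial_state(anchors, sched, params_t1,
                                       inputs_std, mash_share0 = 0.20)
  expect_equal(rec2$p0, 0.25, tolerance = 0.01 / 0.25)
})

test_that("baseline calibration hits the bundled anchors", {
  cb <- calibrate_baseline(rounds = 3)
  expect_true(cb$converged)
  expect_true(all(abs(cb$anchors$achieved - cb$anchors$target) < 0.1))
  # prevalence rises through the anchor era, as in the validation series
  r <- project_expectation(params_t1, cb$schedule, cb$init, inputs_std,
                           end_year = 2030)
  expect_true(all(diff(r$masld_prev[r$year >= 2001]) > 0))
})

test_that("common-random-number loss is deterministic and improvable", {
  sc <- masld_scenario(n_agents = 20000, seeds = 1, end_year = 2010)
  tgt <- data.frame(name = "masld_prevalence", year_start = 2010,
                    year_end = 2010, value = 30, weight = 1,
                    tolerance = 1)
  a <- calibrate_model(character(0), NULL, tgt, sc, params_t1, inputs_std)
  b <- calibrate_model(character(0), NULL, tgt, sc, params_t1, inputs_std)
  expect_identical(a$loss, b$loss)
  expect_true(a$converged)
  expect_error(calibrate_model("no_such", list(no_such = c(0, 1)), tgt, sc,
                               params_t1, inputs_std), "unknown")
})

test_that("a free parameter moves the loss downhill to the target", {
  # truth run with an inflated transplant rate; refit from the base value
  sc <- masld_scenario(n_agents = 50000, seeds = 1, end_year = 2015)
  truth <- apply_overrides(params_t1, c(lt_rate = 0.015))
  init <- masld_initial_state(1, 0.2, truth)  # all-MASLD cohort: many DC/HCC
  sim <- masld_simulate(sc, truth, schedule = zero_schedule, init = init,
                        inputs = inputs_std)
  tgt <- data.frame(name = "cumulative_lt", year_start = 2001,
                    year_end = 2015,
                    value = extract_target_stat(sim$summary,
                                                "cumulative_lt", 2001, 2015),
                    weight = 1, tolerance = NA)
  fit <- calibrate_model("lt_rate", list(lt_rate = c(0.001, 0.03)), tgt,
                         masld_scenario(n_agents = 50000, seeds = 2,
                                        end_year = 2015),
                         params_t1, inputs_std, schedule = zero_schedule,
                         init = init, seed = 1)
  expect_lte(fit$loss, fit$start_loss)
  expect_true(fit$converged)
  expect_equal(unname(fit$par[["lt_rate"]]), 0.015,
               tolerance = 0.25)
})
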