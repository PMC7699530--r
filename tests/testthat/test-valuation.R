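test_that("cycle utilities follow the state weights and first-year increments", {
  expect_equal(cycle_utility("early", "exercise", 0), 0.888)
  expect_equal(cycle_utility("early", "usual_care", 0), 0.838)
  expect_equal(cycle_utility("early", "exercise", 1), 0.818)
  expect_equal(cycle_utility("locoregional", "usual_care", 5), 0.670)
  expect_equal(cycle_utility("distant", "exercise", 3), 0.640)
  expect_equal(cycle_utility("distant", "exercise", 3, is_terminal_brc = TRUE), 0.514)
  expect_equal(cycle_utility("death_brc", "exercise", 2), 0)
  expect_equal(cycle_utility("death_other", "usual_care", 9), 0)
})

test_that("first-cycle cost of an intact early-stage cohort adds up row by row", {
  model <- cea_model(parameters = zeroed_parameters(),
                     life_table = flat_life_table(0))
  trace <- run_cohort(model, "exercise")
  s0 <- followup_cost(model$followup, 1)
  expect_equal(
    cycle_cost(trace, 0, model, "exercise"),
    1344 + s0 + 10850 + 2170 + 2538
  )
  # usual care: no intervention cost
  trace_uc <- run_cohort(model, "usual_care")
  expect_equal(
    cycle_cost(trace_uc, 0, model, "usual_care"),
    s0 + 10850 + 2170 + 2538
  )
  # out-of-pocket stops after the second cycle
  expect_equal(
    cycle_cost(trace, 2, model, "exercise"),
    followup_cost(model$followup, 3) + 10850 + 2170
  )
})

test_that("a dead cohort accrues nothing", {
  model <- cea_model(
    parameters = zeroed_parameters(),
    life_table = flat_life_table(1),
    settings = cea_settings(min_alive = 0)
  )
  trace <- run_cohort(model, "exercise")
  expect_equal(cycle_cost(trace, 10, model, "exercise"), 0)
  out <- accrue_outcomes(trace, model)
  expect_equal(out$qaly[out$cycle == 10], 0)
  expect_equal(out$ly[out$cycle == 10], 0)
})

test_that("transition flows are priced with the one-time recurrence bundles", {
  # 10% of the cohort moves early -> distant in the first cycle
  p <- zeroed_parameters()
  p <- set_param(p, "p_early_distant", 0.1)
  p <- set_param(p, "p_early_local", 1e-6)
  model <- cea_model(
    parameters = p, life_table = flat_life_table(0),
    settings = cea_settings(trial_window_years = 0)
  )
  trace <- run_cohort(model, "usual_care")
  expect_equal(trace$f_new_distant[1], 0.1, tolerance = 1e-4)
  got <- cycle_cost(trace, 0, model, "usual_care")
  expo_early <- 1 - trace$f_new_distant[1] / 2 - trace$f_new_local[1] / 2
  expected <- expo_early * (followup_cost(model$followup, 1) + 10850 + 2170 + 2538) +
    trace$f_new_distant[1] * (27677 + 34719 + 56419) +
    trace$f_new_local[1] * (8679 + 22785 + 29295)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("zero rules annihilate and a zero discount rate is the identity", {
  p <- default_parameters()
  cost_rows <- p$name[p$unit == "AU$"]
  util_rows <- p$name[p$unit == "utility"]
  for (nm in cost_rows) p <- set_param(p, nm, 0, 0, 0)
  for (nm in util_rows) p <- set_param(p, nm, 0, 0, 0)
  model <- cea_model(parameters = p, followup = make_followup_schedule(c(0)))
  tot <- run_arm(model, "exercise")
  expect_equal(tot$cost, 0)
  expect_equal(tot$qaly, 0)
  expect_gt(tot$ly, 0)

  m0 <- cea_model(settings = cea_settings(discount_rate = 0))
  out <- accrue_outcomes(run_cohort(m0, "usual_care"), m0)
  expect_equal(out$cost, out$cost_disc)
  expect_equal(outcome_totals(out)$qaly, sum(out$qaly))
})

test_that("QALYs never exceed life-years, with equality at full utility", {
  model <- default_model()
  for (arm in model_arms()) {
    out <- accrue_outcomes(run_cohort(model, arm), model)
    expect_true(all(out$qaly <= out$ly + 1e-12))
    tot <- outcome_totals(out)
    expect_lte(tot$qaly_disc, tot$ly_disc)
  }
  p <- default_parameters()
  for (nm in c("u_early", "u_local", "u_distant", "u_terminal")) {
    p <- set_param(p, nm, 1, 1, 1)
  }
  for (nm in c("u_add_exercise", "u_add_usual")) p <- set_param(p, nm, 0, 0, 0)
  m1 <- cea_model(parameters = p)
  out1 <- accrue_outcomes(run_cohort(m1, "exercise"), m1)
  expect_equal(out1$qaly, out1$ly, tolerance = 1e-9)
})

test_that("end-of-life costs are paid exactly once per death, by cause", {
  p <- default_parameters()
  zero_rows <- setdiff(p$name[p$unit == "AU$"], c("cost_eol_brc", "cost_eol_other"))
  for (nm in zero_rows) p <- set_param(p, nm, 0, 0, 0)
  model <- cea_model(parameters = p, followup = make_followup_schedule(c(0)),
                     settings = cea_settings(discount_rate = 0))
  trace <- run_cohort(model, "usual_care")
  tot <- outcome_totals(accrue_outcomes(trace, model))
  # the fractions ever dying, read off the final occupancy, price the totals
  final <- trace[nrow(trace), ]
  expect_equal(
    tot$cost,
    final$death_brc * 25475 + final$death_other * 12122,
    tolerance = 1e-6
  )
})

test_that("lifetime cost is monotone in every cost input", {
  base <- default_parameters()
  model0 <- cea_model(parameters = base)
  c0 <- run_arm(model0, "exercise")$cost_disc
  cost_rows <- base$name[base$unit == "AU$"]
  for (nm in cost_rows) {
    p <- set_param(base, nm, get_param(base, nm) * 1.1)
    c1 <- run_arm(cea_model(parameters = p), "exercise")$cost_disc
    expect_gte(c1, c0)
  }
})
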