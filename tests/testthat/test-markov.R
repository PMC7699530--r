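test_that("transition matrices are proper stochastic matrices in and out of the trial window", {
  model <- default_model()
  for (arm in model_arms()) {
    for (spec in list(c(53, 1), c(55, 3), c(60, 8), c(75, 23), c(99, 47))) {
      m <- build_transition_matrix(model, arm, age = spec[1], cycle_index = spec[2])
      expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
      expect_true(all(m >= 0 & m <= 1))
      # absorbing death states, no way back into the early state
      expect_equal(unname(m["death_brc", ]), c(0, 0, 0, 1, 0))
      expect_equal(unname(m["death_other", ]), c(0, 0, 0, 0, 1))
      expect_equal(unname(m[2:5, "early"]), rep(0, 4))
    }
  }
})

test_that("the early-stage row switches from trial to literature probabilities after the window", {
  model <- cea_model(life_table = flat_life_table(0.01))
  m <- build_transition_matrix(model, "exercise", age = 62, cycle_index = 10)
  expect_equal(m["early", "locoregional"], 0.007)
  expect_equal(m["early", "distant"], 0.018)
  expect_equal(m["early", "death_brc"], 0)
  expect_equal(m["early", "death_other"], 0.01)
  expect_equal(m["early", "early"], 1 - (0.018 + 0.007 + 0.01))
  expect_equal(m["distant", "death_brc"], 0.230)

  # inside the window: arm-specific totals split in the 0.007:0.018 ratio,
  # and other-cause mortality is the larger of life table and trial value
  m0 <- build_transition_matrix(model, "usual_care", age = 52, cycle_index = 0)
  expect_equal(m0["early", "locoregional"] + m0["early", "distant"], 0.0076)
  expect_equal(m0["early", "locoregional"] / m0["early", "distant"], 0.007 / 0.018)
  expect_equal(m0["early", "death_brc"], 0.0096)
  expect_equal(m0["early", "death_other"], 0.01) # life table 0.01 > trial 0.0047
  m0x <- build_transition_matrix(model, "exercise", age = 52, cycle_index = 0)
  expect_equal(m0x["early", "death_brc"], 0.0059)
})

test_that("a fully inert parameter set gives the identity matrix and a frozen cohort", {
  model <- cea_model(parameters = zeroed_parameters(),
                     life_table = flat_life_table(0))
  m <- build_transition_matrix(model, "exercise", age = 60, cycle_index = 3)
  expect_equal(unname(m), diag(5))
  trace <- run_cohort(model, "exercise")
  expect_true(all(trace$early == 1))
  expect_true(all(trace[, c("locoregional", "distant", "death_brc", "death_other")] == 0))
})

test_that("competing exits above one are rejected with the offending state named", {
  p <- set_param(default_parameters(), "p_death_distant", 0.95, 0.9, 0.99)
  model <- cea_model(parameters = p, life_table = flat_life_table(0.2))
  expect_error(
    build_transition_matrix(model, "exercise", age = 60, cycle_index = 10),
    "distant"
  )
})

test_that("a forced one-cycle death gives half a life-year under the half-cycle correction", {
  model <- cea_model(
    parameters = zeroed_parameters(),
    life_table = flat_life_table(1),
    settings = cea_settings(horizon_age = 53)
  )
  trace <- run_cohort(model, "usual_care")
  expect_equal(nrow(trace), 1)
  expect_equal(trace$death_other, 1)
  expect_equal(life_years(trace, 0), 0.5)
})

test_that("cohort occupancy is conserved and absorption is monotone on the default run", {
  model <- default_model()
  for (arm in model_arms()) {
    trace <- run_cohort(model, arm)
    occ <- as.matrix(trace[, health_states()])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= 0))
    dead <- trace$death_brc + trace$death_other
    expect_true(all(diff(dead) >= -1e-12))
    expect_true(all(diff(trace$death_brc) >= -1e-12))
  }
})

test_that("discounting follows the closed form and life-years decrease with the rate", {
  expect_equal(exercea:::discount_factors(0:5, 0.05), 1 / 1.05^(0:5))
  expect_equal(exercea:::discount_factors(1, 0.05), 0.952381, tolerance = 1e-6)
  trace <- run_cohort(default_model(), "exercise")
  expect_gte(life_years(trace, 0), life_years(trace, 0.05))
  expect_error(life_years(trace, -0.01), "non-negative")
})

test_that("raising any single exit probability never increases discounted life-years", {
  base <- default_parameters()
  model0 <- cea_model(parameters = base)
  ly0 <- life_years(run_cohort(model0, "usual_care"), 0.05)
  bumps <- c("p_early_distant", "p_local_distant", "p_death_distant",
             "p_death_local", "p_brc_death_usual", "p_nonbrc_death_usual")
  for (nm in bumps) {
    p <- set_param(base, nm, min(get_param(base, nm) + 0.05, 0.99))
    ly <- life_years(run_cohort(cea_model(parameters = p), "usual_care"), 0.05)
    expect_lte(ly, ly0 + 1e-12)
  }
})

test_that("the microsimulation oracle agrees with the cohort trace", {
  # moderate n here; the full-scale check lives in the acceptance suite
  model <- default_model()
  n <- 50000
  sim <- microsimulate(model, "usual_care", n, n_cycles = 20, seed = 99)
  trace <- run_cohort(model, "usual_care")
  for (cy in c(1, 5, 20)) {
    p_cohort <- unlist(trace[trace$cycle == cy - 1, health_states()])
    mcse <- sqrt(pmax(p_cohort * (1 - p_cohort), 1e-8) / n)
    expect_true(all(abs(sim[cy, ] - p_cohort) < 3 * mcse + 1e-9),
                info = paste("cycle", cy))
  }
})
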