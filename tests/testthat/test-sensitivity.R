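test_that("an all-fixed parameter set gives a degenerate PSA", {
  p <- default_parameters()
  p$family <- "fixed"
  model <- cea_model(parameters = p)
  psa <- run_psa(model, n = 45, seed = 5)
  expect_equal(psa$n, 45)
  expect_equal(length(unique(psa$draws$dcost)), 1)
  s <- psa$summary
  expect_equal(s$lower[s$quantity == "dcost"], s$upper[s$quantity == "dcost"])
  # and it reproduces the deterministic base case exactly
  bc <- run_base_case(model)
  expect_equal(mean(psa$draws$dcost), bc$incremental[bc$quantity == "cost"])
})

test_that("identical seeds give bit-identical PSA results", {
  model <- default_model()
  a <- run_psa(model, n = 25, seed = 42)
  b <- run_psa(model, n = 25, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_identical(a$parameter_draws, b$parameter_draws)
  c <- run_psa(model, n = 25, seed = 43)
  expect_false(identical(a$draws, c$draws))
})

test_that("PSA parameter draws converge to the table means", {
  model <- default_model()
  set.seed(8)
  draws <- sample_parameters(model$parameters, 5000)
  p <- model$parameters
  for (j in seq_len(nrow(p))) {
    if (p$family[j] == "fixed") next
    x <- draws[, p$name[j]]
    mcse <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - p$mean[j]), 3 * mcse + 1e-12)
  }
})

test_that("per-draw totals line up with independently re-run cohorts", {
  model <- default_model()
  psa <- run_psa(model, n = 5, seed = 21)
  for (i in c(1, 4)) {
    values <- unlist(psa$parameter_draws[i, ])
    ex <- run_arm(model, "exercise", values)
    expect_equal(psa$draws$cost_exercise[i], ex$cost_disc)
    expect_equal(psa$draws$qaly_exercise[i], ex$qaly_disc)
    expect_equal(psa$draws$ly_exercise[i], ex$ly)
  }
})

test_that("raising usual-care recurrence raises the mean QALY gain", {
  model <- default_model()
  dq <- vapply(c(0.0033, 0.0076, 0.0150), function(pin) {
    m <- model
    m$parameters <- set_param(m$parameters, "p_recurrence_usual", pin)
    psa <- run_psa(m, n = 150, seed = 77)
    mean(psa$draws$dqaly)
  }, numeric(1))
  expect_true(all(diff(dq) > 0))
})

test_that("a parameter with no pathway influence leaves the tornado flat", {
  p <- default_parameters()
  # close the locoregional state entirely: its treatment cost cannot matter
  p <- set_param(p, "p_early_local", 0, 0, 0)
  model <- cea_model(parameters = p)
  ow <- run_owsa(model, parameters = "cost_local_recurrence", mode = "deterministic")
  expect_equal(ow$icer_low, ow$icer_high, tolerance = 1e-9)
  expect_equal(ow$icer_low, attr(ow, "base_icer"), tolerance = 1e-9)
})

test_that("tornado entries are sorted widest first and inputs echo the bounds", {
  model <- default_model()
  ow <- run_owsa(
    model,
    parameters = c("u_add_exercise", "p_brc_death_usual", "cost_oop_annual"),
    mode = "deterministic"
  )
  expect_equal(nrow(ow), 3)
  expect_true(all(diff(ow$width) <= 0))
  row <- ow[ow$parameter == "p_brc_death_usual", ]
  expect_equal(row$low, 0.0046)
  expect_equal(row$high, 0.0176)
  expect_error(run_owsa(model, parameters = "no_such_param"), "no_such_param")
})

test_that("resampled one-way analyses respond to the pinned bound", {
  model <- default_model()
  ow <- run_owsa(model, parameters = "p_recurrence_exercise",
                 mode = "resample", n = 120, seed = 9)
  # high recurrence in the exercise arm erodes its advantage
  expect_gt(ow$icer_high, ow$icer_low)
})

test_that("varying the starting age moves the whole cohort", {
  model <- default_model()
  ow <- run_owsa(model, parameters = "start_age", mode = "deterministic")
  expect_false(isTRUE(all.equal(ow$icer_low, ow$icer_high)))
  m44 <- model
  m44$parameters <- set_param(m44$parameters, "start_age", 44)
  m44$settings$start_age <- 44
  expect_gt(run_arm(m44, "exercise")$ly, run_arm(model, "exercise")$ly)
})
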