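test_that("rate-to-probability conversion matches the closed form and rejects bad input", {
  expect_equal(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.1, 1), 1 - exp(-0.1))
  expect_equal(rate_to_probability(0.1, 2), 1 - exp(-0.2))
  expect_equal(rate_to_probability(0.1, 1), 0.095163, tolerance = 1e-5)
  expect_lt(rate_to_probability(5), 1)
  expect_error(rate_to_probability(-0.1), "non-negative")
  expect_error(rate_to_probability(0.1, 0), "positive")
})

test_that("survival-to-annual-probability matches the closed form", {
  expect_equal(survival_to_annual_probability(1, 10), 0)
  expect_equal(survival_to_annual_probability(0.25, 2), 0.5)
  # the annual breast-cancer death probability implied by 49% 10-year survival
  expect_equal(survival_to_annual_probability(0.49, 10), 0.0688, tolerance = 1e-3)
  expect_error(survival_to_annual_probability(0, 10), "certain death")
  expect_equal(survival_to_annual_probability(0, 10, allow_certain_death = TRUE), 1)
  expect_error(survival_to_annual_probability(0.5, 0), "positive")
})

test_that("rate and survival conversions are mutually consistent", {
  for (r in c(0.01, 0.1, 0.5, 1.3)) {
    for (T in c(0.5, 1, 5, 10)) {
      expect_equal(
        survival_to_annual_probability(exp(-r * T), T),
        rate_to_probability(r, 1),
        tolerance = 1e-10
      )
    }
  }
})

test_that("beta method-of-moments fit reproduces the requested mean and sd", {
  s <- fit_sampler(0.5, 0.402, 0.598, "beta")
  expect_equal(s$family, "beta")
  expect_equal(s$mean, 0.5, tolerance = 1e-6)
  fitted_sd <- sqrt(s$shape1 * s$shape2 /
    ((s$shape1 + s$shape2)^2 * (s$shape1 + s$shape2 + 1)))
  expect_equal(fitted_sd, (0.598 - 0.402) / (2 * qnorm(0.975)), tolerance = 1e-6)
})

test_that("fixed family yields a degenerate sampler", {
  s <- fit_sampler(1344, 1344, 1344, "fixed")
  expect_identical(unique(s$sample(50)), 1344)
  expect_identical(unique(s$quantile(c(0.1, 0.9))), 1344)
})

test_that("lognormal fit hits the arithmetic mean exactly", {
  s <- fit_sampler(2538, 797, 9079, "lognormal")
  expect_equal(exp(s$meanlog + s$sdlog^2 / 2), 2538, tolerance = 1e-9)
})

test_that("incompatible beta variance falls back to uniform with a warning", {
  expect_warning(s <- fit_sampler(0.02, 0, 0.56, "beta"), "uniform")
  expect_equal(s$family, "uniform")
  draws <- s$sample(1000)
  expect_true(all(draws >= 0 & draws <= 0.56))
})

test_that("sampled draws respect family support and converge to the table means", {
  set.seed(41)
  n <- 1e5
  cases <- list(
    list(spec = c(0.818, 0.718, 0.918), family = "beta", lo = 0, hi = 1),
    list(spec = c(27677, 24900, 30434), family = "gamma", lo = 0, hi = Inf),
    list(spec = c(2538, 797, 9079), family = "lognormal", lo = 0, hi = Inf)
  )
  for (cs in cases) {
    s <- fit_sampler(cs$spec[1], cs$spec[2], cs$spec[3], cs$family)
    draws <- s$sample(n)
    expect_true(all(draws > cs$lo & draws < cs$hi))
    mcse <- sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - cs$spec[1]), 3 * mcse)
  }
})

test_that("the default parameter table is complete and internally consistent", {
  p <- default_parameters()
  expect_silent(validate_parameters(p))
  expect_equal(nrow(p), 31)
  expect_true(all(p$low <= p$mean & p$mean <= p$high))
  expect_equal(get_param(p, "cost_intervention"), 1344)
  expect_equal(get_param(p, "u_early"), 0.818)
  expect_equal(get_param(p, "start_age"), 52)
})

test_that("validation names the offending or missing rows", {
  p <- default_parameters()
  expect_error(validate_parameters(p[p$name != "p_recurrence_usual", ]),
               "p_recurrence_usual")
  bad <- set_param(p, "u_early", 1.2, 1.1, 1.3)
  expect_error(validate_parameters(bad), "u_early")
  bad2 <- p
  bad2$low[bad2$name == "cost_eol_brc"] <- 1e9
  expect_error(validate_parameters(bad2), "cost_eol_brc")
})

test_that("comonotonic arm pairs share quantiles while marginals are untouched", {
  p <- default_parameters()
  set.seed(7)
  d <- sample_parameters(p, 400)
  # paired trial parameters move together
  expect_gt(cor(d[, "p_brc_death_exercise"], d[, "p_brc_death_usual"]), 0.99)
  # rank correlation is exactly 1 under a shared quantile
  expect_equal(cor(d[, "u_add_exercise"], d[, "u_add_usual"], method = "spearman"), 1)
  # unrelated parameters do not
  expect_lt(abs(cor(d[, "u_early"], d[, "cost_eol_brc"])), 0.2)
  set.seed(7)
  d2 <- sample_parameters(p, 400, arm_correlation = "independent")
  expect_lt(abs(cor(d2[, "p_brc_death_exercise"], d2[, "p_brc_death_usual"])), 0.25)
})
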