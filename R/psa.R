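#' Probabilistic sensitivity analysis
#'
#' Draws `n` joint parameter vectors from the fitted uncertainty
#' distributions (independent across parameters; common parameters shared
#' between arms, trial-based parameters arm-specific), runs both arms'
#' cohorts on each draw, and records per-draw lifetime totals and
#' incremental (cost, QALY, life-year) triples. Draws producing an invalid
#' transition matrix (competing exits above 1) are rejected and re-sampled;
#' the count is recorded. Identical seeds reproduce identical results.
#'
#' @param model A [cea_model()].
#' @param n Number of Monte Carlo iterations (default from the model
#'   settings, 5000).
#' @param seed Integer seed for reproducibility.
#' @param arm_correlation Joint sampling of the trial-based arm pairs:
#'   `"comonotonic"` (default; shared quantile, preserving the trial's
#'   relative effect while its level varies — see [sample_parameters()])
#'   or `"independent"`.
#' @return An object of class `psa_results`: list with `draws` (tibble of
#'   per-draw arm totals and increments `dcost`, `dqaly`, `dly`, `dly_disc`),
#'   `summary` (see [incremental_summary()]), `seed`, `n`,
#'   `rejected` (resampled draw count) and `wtp_threshold`. Incremental
#'   costs and QALYs are discounted; `dly` is undiscounted (the convention
#'   of the headline life-year results) with the discounted variant kept
#'   alongside.
#' @examples
#' \donttest{
#' psa <- run_psa(cea_model(), n = 200, seed = 1)
#' glance(psa)
#' }
#' @export
run_psa <- function(model, n = model$settings$psa_iterations, seed = NULL,
                    arm_correlation = c("comonotonic", "independent")) {
  arm_correlation <- match.arg(arm_correlation)
  if (!is.null(seed)) set.seed(seed)
  s <- model$settings
  params <- model$parameters
  draws <- sample_parameters(params, n, arm_correlation)
  n_max <- floor(s$horizon_age - s$start_age)
  qx_all <- mortality_at(model$life_table, s$start_age + seq_len(n_max) - 1)
  fu_all <- followup_cost(model$followup, seq_len(n_max))

  res <- matrix(NA_real_, n, 12)
  rejected <- 0L
  for (i in seq_len(n)) {
    repeat {
      values <- draws[i, ]
      ok <- tryCatch(
        {
          ex <- arm_totals_core(values, qx_all, fu_all, "exercise", s)
          uc <- arm_totals_core(values, qx_all, fu_all, "usual_care", s)
          TRUE
        },
        exercea_invalid_matrix = function(e) FALSE
      )
      if (ok) break
      rejected <- rejected + 1L
      draws[i, ] <- sample_parameters(params, 1, arm_correlation)
    }
    res[i, ] <- c(
      ex$cost_disc, ex$qaly_disc, ex$ly, ex$ly_disc,
      uc$cost_disc, uc$qaly_disc, uc$ly, uc$ly_disc,
      ex$cost_disc - uc$cost_disc, ex$qaly_disc - uc$qaly_disc,
      ex$ly - uc$ly, ex$ly_disc - uc$ly_disc
    )
  }
  colnames(res) <- c(
    "cost_exercise", "qaly_exercise", "ly_exercise", "ly_disc_exercise",
    "cost_usual_care", "qaly_usual_care", "ly_usual_care", "ly_disc_usual_care",
    "dcost", "dqaly", "dly", "dly_disc"
  )
  draws_tbl <- bind_cols(tibble(iteration = seq_len(n)), as_tibble(res))
  out <- list(
    draws = draws_tbl,
    parameter_draws = as_tibble(draws),
    summary = incremental_summary(draws_tbl),
    seed = seed, n = n, rejected = rejected,
    wtp_threshold = s$wtp_threshold
  )
  class(out) <- "psa_results"
  out
}

#' @export
print.psa_results <- function(x, ...) {
  cat("<psa_results>", x$n, "Monte Carlo iterations")
  if (!is.null(x$seed)) cat(", seed", x$seed)
  if (x$rejected > 0) cat(",", x$rejected, "draws re-sampled")
  cat("\n")
  g <- glance(x)
  cat(sprintf(
    "  mean dCost AU$%.0f, dQALY %.3f, dLY %.3f\n",
    g$dcost, g$dqaly, g$dly
  ))
  cat(sprintf(
    "  ICER AU$%.0f/QALY, AU$%.0f/LY; P(CE at AU$%s/QALY) = %.1f%%\n",
    g$icer_qaly, g$icer_ly, format(x$wtp_threshold, big.mark = ","),
    100 * g$p_ce_qaly
  ))
  invisible(x)
}

#' Tidy per-draw PSA results
#'
#' @param x A `psa_results` object.
#' @param ... Unused.
#' @return The per-draw tibble of arm totals and increments.
#' @export
tidy.psa_results <- function(x, ...) {
  x$draws
}

#' One-row PSA summary
#'
#' @param x A `psa_results` object.
#' @param ... Unused.
#' @return A one-row tibble: per-arm means, mean increments, mean-based
#'   ICERs (AU$/QALY and AU$/LY, with discounted costs/QALYs and
#'   undiscounted life-years), and the probability of cost-effectiveness at
#'   the model's willingness-to-pay threshold per QALY (`p_ce_qaly`) and
#'   per life-year (`p_ce_ly`).
#' @export
glance.psa_results <- function(x, ...) {
  d <- x$draws
  wtp <- x$wtp_threshold
  tibble(
    n = x$n,
    cost_exercise = mean(d$cost_exercise),
    cost_usual_care = mean(d$cost_usual_care),
    qaly_exercise = mean(d$qaly_exercise),
    qaly_usual_care = mean(d$qaly_usual_care),
    ly_exercise = mean(d$ly_exercise),
    ly_usual_care = mean(d$ly_usual_care),
    dcost = mean(d$dcost),
    dqaly = mean(d$dqaly),
    dly = mean(d$dly),
    icer_qaly = mean(d$dcost) / mean(d$dqaly),
    icer_ly = mean(d$dcost) / mean(d$dly),
    p_ce_qaly = mean(net_monetary_benefit(d$dcost, d$dqaly, wtp) > 0),
    p_ce_ly = mean(net_monetary_benefit(d$dcost, d$dly, wtp) > 0),
    rejected = x$rejected
  )
}

#' Deterministic base-case run
#'
#' Evaluates both arms at the parameter means and lays the results out as
#' the familiar three-row incremental table (costs, QALYs, life-years, then
#' the two ICERs). Costs and QALYs are discounted at the model's rate;
#' life-years are reported undiscounted.
#'
#' @param model A [cea_model()].
#' @return A tibble with columns `quantity`, `exercise`, `usual_care`,
#'   `incremental`.
#' @examples
#' run_base_case(cea_model())
#' @export
run_base_case <- function(model) {
  ex <- run_arm(model, "exercise")
  uc <- run_arm(model, "usual_care")
  icer_q <- icer(ex$cost_disc - uc$cost_disc, ex$qaly_disc - uc$qaly_disc)
  icer_l <- icer(ex$cost_disc - uc$cost_disc, ex$ly - uc$ly)
  tibble(
    quantity = c("cost", "qaly", "ly", "icer_qaly", "icer_ly"),
    exercise = c(ex$cost_disc, ex$qaly_disc, ex$ly, NA, NA),
    usual_care = c(uc$cost_disc, uc$qaly_disc, uc$ly, NA, NA),
    incremental = c(
      ex$cost_disc - uc$cost_disc,
      ex$qaly_disc - uc$qaly_disc,
      ex$ly - uc$ly,
      if (is.numeric(icer_q)) icer_q else NA_real_,
      if (is.numeric(icer_l)) icer_l else NA_real_
    )
  )
}
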