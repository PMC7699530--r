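#' Run settings for the cohort model
#'
#' Collects the scalar run settings: starting age 52 (the trial cohort's
#' mean age at diagnosis), yearly cycles, 5% annual discount rate, a
#' lifetime horizon (age 100 or when less than 0.1% of the cohort remains
#' alive, whichever comes first), 5000 probabilistic iterations and a
#' willingness-to-pay threshold of AU$50,000 per QALY. Trial-based
#' arm-specific probabilities govern the first `trial_window_years` cycles
#' (the 8-year follow-up); literature and life-table values apply
#' thereafter.
#'
#' @param start_age Cohort age at model entry, years.
#' @param discount_rate Annual discount rate applied to costs, QALYs and
#'   life-years (fraction, `>= 0`).
#' @param cycle_length Cycle length in years (the model is built around 1).
#' @param horizon_age Age at which the run stops regardless of survival.
#' @param min_alive Stop once the living fraction falls below this.
#' @param trial_window_years Number of initial cycles governed by the
#'   arm-specific trial probabilities.
#' @param psa_iterations Default number of Monte Carlo draws.
#' @param wtp_threshold Willingness to pay, AU$ per unit effect.
#' @param half_cycle `"endpoints"` applies the half-cycle correction to the
#'   first and last cycles only (the default); `"trapezoid"` averages
#'   start- and end-of-cycle occupancy in every cycle.
#' @param early_costs_annual Accrue early-stage productivity and carer
#'   costs annually for early-state occupants (default) rather than once.
#' @return A list of class `cea_settings`.
#' @export
cea_settings <- function(start_age = 52,
                         discount_rate = 0.05,
                         cycle_length = 1,
                         horizon_age = 100,
                         min_alive = 0.001,
                         trial_window_years = 8,
                         psa_iterations = 5000,
                         wtp_threshold = 50000,
                         half_cycle = c("endpoints", "trapezoid"),
                         early_costs_annual = TRUE) {
  half_cycle <- match.arg(half_cycle)
  if (discount_rate < 0) abort("`discount_rate` must be non-negative.")
  if (horizon_age <= start_age) abort("`horizon_age` must exceed `start_age`.")
  if (cycle_length != 1) abort("The cohort engine is defined for yearly cycles (`cycle_length = 1`).")
  structure(
    list(
      start_age = start_age, discount_rate = discount_rate,
      cycle_length = cycle_length, horizon_age = horizon_age,
      min_alive = min_alive, trial_window_years = trial_window_years,
      psa_iterations = psa_iterations, wtp_threshold = wtp_threshold,
      half_cycle = half_cycle, early_costs_annual = early_costs_annual
    ),
    class = "cea_settings"
  )
}

#' Assemble a cost-utility model
#'
#' Bundles the validated parameter table, the life table, the follow-up-care
#' cost schedule and the run settings into a single model object consumed by
#' [run_cohort()], [run_base_case()], [run_psa()] and [run_owsa()].
#'
#' @param parameters Parameter tibble (default [default_parameters()]).
#' @param life_table Age-indexed annual death probabilities (default the
#'   bundled Gompertz fixture, [make_life_table()]).
#' @param followup Follow-up-care cost schedule (default
#'   [make_followup_schedule()]).
#' @param settings Run settings from [cea_settings()].
#' @return A list of class `cea_model`.
#' @examples
#' model <- cea_model()
#' trace <- run_cohort(model, arm = "exercise")
#' @export
cea_model <- function(parameters = default_parameters(),
                      life_table = make_life_table(),
                      followup = make_followup_schedule(),
                      settings = cea_settings()) {
  validate_parameters(parameters)
  if (!all(c("age", "qx") %in% names(life_table))) {
    abort("`life_table` needs columns `age` and `qx`.")
  }
  if (any(life_table$qx < 0 | life_table$qx > 1)) {
    abort("Life-table probabilities must lie in [0, 1].")
  }
  covered <- seq(floor(settings$start_age), ceiling(settings$horizon_age) - 1)
  if (!all(covered %in% life_table$age)) {
    abort("`life_table` must cover every age from `start_age` to `horizon_age - 1`.")
  }
  if (!all(c("year", "cost") %in% names(followup))) {
    abort("`followup` needs columns `year` and `cost`.")
  }
  # start_age in the parameter table and the settings must agree; the
  # parameter row exists so one-way analyses can vary it over 44-60.
  sa <- parameters$mean[parameters$name == "start_age"]
  if (length(sa) == 1 && sa != settings$start_age) {
    settings$start_age <- sa
  }
  structure(
    list(
      parameters = parameters, life_table = life_table,
      followup = followup, settings = settings
    ),
    class = "cea_model"
  )
}

#' @export
print.cea_model <- function(x, ...) {
  s <- x$settings
  cat("<cea_model> five-state Markov cohort cost-utility model\n")
  cat(sprintf(
    "  start age %s, horizon age %s, discount %.1f%%/yr, trial window %d yr\n",
    s$start_age, s$horizon_age, 100 * s$discount_rate, s$trial_window_years
  ))
  cat(sprintf(
    "  %d parameters; life table ages %d-%d; WTP AU$%s/QALY\n",
    nrow(x$parameters), min(x$life_table$age), max(x$life_table$age),
    format(s$wtp_threshold, big.mark = ",")
  ))
  invisible(x)
}
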