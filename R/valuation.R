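#' Utility weight for a health state in a given cycle
#'
#' Early-stage disease carries the baseline utility (0.818) plus the
#' trial-observed arm-specific increment (exercise +0.070, usual care
#' +0.020) in the first cycle only — the quality-of-life benefit is not
#' assumed to persist beyond the trial observation. Locoregional and
#' distant recurrence carry 0.670 and 0.640; cohort members in their final
#' year before breast-cancer death carry the terminal-disease weight 0.514
#' (`is_terminal_brc`); the death states carry 0.
#'
#' @param state One of [health_states()].
#' @param arm `"exercise"` or `"usual_care"`.
#' @param cycle_index 0-based cycle.
#' @param is_terminal_brc Is this the weight for the fraction dying of
#'   breast cancer this cycle?
#' @param values Named parameter vector (defaults to the table means).
#' @return Utility weight in `[0, 1]`.
#' @examples
#' cycle_utility("early", "exercise", 0)  # 0.888
#' cycle_utility("locoregional", "usual_care", 5)  # 0.67
#' @export
cycle_utility <- function(state, arm, cycle_index, is_terminal_brc = FALSE,
                          values = parameter_means(default_parameters())) {
  state <- match.arg(state, health_states())
  arm <- match_arm(arm)
  if (state %in% c("death_brc", "death_other")) return(0)
  if (is_terminal_brc) return(values[["u_terminal"]])
  switch(state,
    early = {
      u <- values[["u_early"]]
      if (cycle_index == 0) {
        u <- u + if (arm == "exercise") values[["u_add_exercise"]] else values[["u_add_usual"]]
      }
      min(u, 1)
    },
    locoregional = values[["u_local"]],
    distant = values[["u_distant"]]
  )
}

# Per-cycle reward streams from plain occupancy/flow matrices (columns in
# the canonical state/flow order). Shared by accrue_outcomes() and the
# Monte Carlo loop. `fu` is the follow-up cost per cycle, pre-looked-up.
value_core <- function(occ, flows, cycles, ages, values, arm, s, fu) {
  n <- nrow(occ)
  occ_start <- rbind(c(1, 0, 0, 0, 0), occ[-n, , drop = FALSE])
  if (identical(s$half_cycle, "trapezoid")) {
    expo <- (occ_start + occ) / 2
    hc_rows <- seq_len(n)
  } else {
    expo <- occ
    hc_rows <- unique(c(1L, n))
    expo[hc_rows, ] <- (occ_start[hc_rows, , drop = FALSE] + occ[hc_rows, , drop = FALSE]) / 2
  }
  dying <- matrix(0, n, 3)
  dying[hc_rows, ] <- flows[hc_rows, 5:7, drop = FALSE] / 2

  early_exp <- expo[, 1]
  state_cost <- early_exp * fu
  if (s$early_costs_annual) {
    state_cost <- state_cost + early_exp * (values[["prod_early"]] + values[["carer_early"]])
  } else {
    state_cost[1] <- state_cost[1] + early_exp[1] * (values[["prod_early"]] + values[["carer_early"]])
  }
  oop <- ifelse(cycles < 2, early_exp * values[["cost_oop_annual"]], 0)
  flow_cost <-
    flows[, 1] * (values[["cost_local_recurrence"]] + values[["prod_local"]] + values[["carer_local"]]) +
    flows[, 2] * (values[["cost_distant_recurrence"]] + values[["prod_distant"]] + values[["carer_distant"]]) +
    flows[, 3] * values[["cost_eol_brc"]] +
    flows[, 4] * values[["cost_eol_other"]] +
    ifelse(ages < 65, flows[, 3] * values[["prod_premature_death"]], 0)
  one_off <- ifelse(cycles == 0 & arm == "exercise", values[["cost_intervention"]], 0)
  cost <- state_cost + oop + flow_cost + one_off

  u_inc <- if (arm == "exercise") values[["u_add_exercise"]] else values[["u_add_usual"]]
  u_early_cycle <- pmin(values[["u_early"]] + ifelse(cycles == 0, u_inc, 0), 1)
  qaly <- early_exp * u_early_cycle +
    expo[, 2] * values[["u_local"]] +
    expo[, 3] * values[["u_distant"]] -
    dying[, 1] * (u_early_cycle - values[["u_terminal"]]) -
    dying[, 2] * (values[["u_local"]] - values[["u_terminal"]]) -
    dying[, 3] * (values[["u_distant"]] - values[["u_terminal"]])

  ly <- expo[, 1] + expo[, 2] + expo[, 3]
  df <- discount_factors(cycles, s$discount_rate)
  list(cost = cost, qaly = qaly, ly = ly, df = df)
}

# Core arm evaluation used by the PSA/OWSA loops: cohort + valuation with no
# tibble construction. Returns lifetime totals.
arm_totals_core <- function(values, qx_all, fu_all, arm, s) {
  core <- cohort_core(values, qx_all, arm, s)
  cycles <- seq_len(core$n) - 1
  ages <- s$start_age + cycles
  v <- value_core(core$occ, core$flows, cycles, ages, values, arm, s, fu_all[seq_len(core$n)])
  list(
    cost = sum(v$cost), qaly = sum(v$qaly), ly = sum(v$ly),
    cost_disc = sum(v$cost * v$df), qaly_disc = sum(v$qaly * v$df),
    ly_disc = sum(v$ly * v$df)
  )
}

#' Societal cost accrued in one cycle
#'
#' Combines occupancy-based costs (follow-up care by year since diagnosis,
#' early-stage productivity and carer losses, out-of-pocket expenses in the
#' first two years for early-state occupants) with one-time transition
#' costs (treatment, productivity and carer costs of new local/distant
#' recurrences; end-of-life care by cause of death; productivity loss of
#' premature breast-cancer death while younger than 65) and the one-off
#' exercise-programme cost in cycle 0 of the exercise arm.
#'
#' @param trace A [run_cohort()] trace.
#' @param cycle_index Which cycle (0-based) to price.
#' @param model The [cea_model()] supplying the follow-up schedule.
#' @param arm Strategy arm (defaults to the trace's).
#' @param values Named parameter vector (defaults to the model means).
#' @return Undiscounted AU$ accrued that cycle per cohort member.
#' @export
cycle_cost <- function(trace, cycle_index, model, arm = attr(trace, "arm"),
                       values = NULL) {
  arm <- match_arm(arm)
  if (is.null(values)) values <- parameter_means(model$parameters)
  s <- attr(trace, "settings")
  i <- match(cycle_index, trace$cycle)
  if (is.na(i)) abort("`cycle_index` not present in the trace.")
  occ <- as.matrix(trace[, health_states()])
  flows <- as.matrix(trace[, flow_names()])
  if (any(flows < -1e-12)) abort("Negative transition flow in cost accrual.")
  fu <- followup_cost(model$followup, trace$cycle + 1)
  v <- value_core(occ, flows, trace$cycle, trace$age, values, arm, s, fu)
  v$cost[[i]]
}

#' Accrue per-cycle and lifetime outcomes over a trace
#'
#' Applies the valuation rules to every cycle of a cohort trace, producing
#' undiscounted and discounted per-cycle streams of cost, QALYs and
#' life-years, using the engine's half-cycle exposure convention and
#' discount factors `(1 + r)^(-cycle)`. The terminal-disease utility is
#' substituted for the exposure attributable to members dying of breast
#' cancer within a cycle.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param model The [cea_model()] the trace was run from.
#' @param arm Strategy arm the trace belongs to (defaults to the trace's).
#' @param values Optional named parameter vector overriding the model means.
#' @return A tibble of class `cycle_outcomes` with per-cycle columns
#'   `cost`, `qaly`, `ly` and their `_disc` variants, carrying the lifetime
#'   totals as attribute `totals` (retrievable via [outcome_totals()]).
#' @examples
#' model <- cea_model()
#' out <- run_cohort(model, "exercise") |> accrue_outcomes(model)
#' outcome_totals(out)
#' @export
accrue_outcomes <- function(trace, model, arm = attr(trace, "arm"), values = NULL) {
  arm <- match_arm(arm)
  s <- attr(trace, "settings")
  if (is.null(values)) values <- parameter_means(model$parameters)
  occ <- as.matrix(trace[, health_states()])
  flows <- as.matrix(trace[, flow_names()])
  fu <- followup_cost(model$followup, trace$cycle + 1)
  v <- value_core(occ, flows, trace$cycle, trace$age, values, arm, s, fu)
  out <- tibble(
    cycle = trace$cycle, age = trace$age,
    cost = v$cost, qaly = v$qaly, ly = v$ly,
    cost_disc = v$cost * v$df, qaly_disc = v$qaly * v$df, ly_disc = v$ly * v$df
  )
  totals <- list(
    cost = sum(out$cost), qaly = sum(out$qaly), ly = sum(out$ly),
    cost_disc = sum(out$cost_disc), qaly_disc = sum(out$qaly_disc),
    ly_disc = sum(out$ly_disc)
  )
  structure(out, totals = totals, arm = arm,
            class = c("cycle_outcomes", class(out)))
}

#' Lifetime totals of an outcome stream
#'
#' @param outcomes A `cycle_outcomes` tibble from [accrue_outcomes()].
#' @return Named list with undiscounted and discounted lifetime `cost`,
#'   `qaly` and `ly` totals.
#' @export
outcome_totals <- function(outcomes) {
  attr(outcomes, "totals")
}

#' Run one arm end to end
#'
#' Convenience wrapper: runs the cohort and accrues outcomes for one arm.
#'
#' @inheritParams run_cohort
#' @return Named list of lifetime totals (see [outcome_totals()]).
#' @export
run_arm <- function(model, arm, values = NULL) {
  trace <- run_cohort(model, arm, values)
  outcome_totals(accrue_outcomes(trace, model, arm, values))
}
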