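state_index <- function() setNames(seq_len(5), health_states())

# Core matrix assembly on a named parameter vector and a scalar life-table
# probability. Exits are summed first; the stay probability is whatever
# remains, and competing exits exceeding 1 invalidate the matrix.
transition_matrix_impl <- function(values, qx, arm, cycle_index, trial_window) {
  v <- values
  in_window <- cycle_index < trial_window
  if (in_window) {
    rec_total <- if (arm == "exercise") v[["p_recurrence_exercise"]] else v[["p_recurrence_usual"]]
    denom <- v[["p_early_local"]] + v[["p_early_distant"]]
    split_local <- if (denom > 0) v[["p_early_local"]] / denom else 0.5
    p_el <- rec_total * split_local
    p_ed <- rec_total * (1 - split_local)
    p_e_dbrc <- if (arm == "exercise") v[["p_brc_death_exercise"]] else v[["p_brc_death_usual"]]
    p_nonbrc <- if (arm == "exercise") v[["p_nonbrc_death_exercise"]] else v[["p_nonbrc_death_usual"]]
    p_e_doth <- max(qx, p_nonbrc)
  } else {
    p_el <- v[["p_early_local"]]
    p_ed <- v[["p_early_distant"]]
    p_e_dbrc <- 0
    p_e_doth <- qx
  }

  m <- matrix(0, 5, 5, dimnames = list(health_states(), health_states()))
  exits_early <- p_el + p_ed + p_e_dbrc + p_e_doth
  exits_local <- v[["p_local_distant"]] + v[["p_death_local"]] + qx
  exits_distant <- v[["p_death_distant"]] + qx
  bad <- c(early = exits_early, locoregional = exits_local, distant = exits_distant) > 1
  if (any(bad)) {
    abort(paste0(
      "Competing exit probabilities exceed 1 for state(s) ",
      paste(names(bad)[bad], collapse = ", "), " (arm ", arm,
      ", cycle ", cycle_index, ", life-table q = ", signif(qx, 4), ")."
    ), class = "exercea_invalid_matrix")
  }
  m["early", ] <- c(1 - exits_early, p_el, p_ed, p_e_dbrc, p_e_doth)
  m["locoregional", ] <- c(0, 1 - exits_local, v[["p_local_distant"]], v[["p_death_local"]], qx)
  m["distant", ] <- c(0, 0, 1 - exits_distant, v[["p_death_distant"]], qx)
  m["death_brc", "death_brc"] <- 1
  m["death_other", "death_other"] <- 1
  m
}

#' Build the one-cycle transition matrix
#'
#' Assembles the 5x5 transition probability matrix for a given arm, age and
#' cycle. During the trial window (first `trial_window_years` cycles) the
#' early-stage row uses the arm-specific trial probabilities: total
#' recurrence split between local and distant in the ratio of the common
#' literature values (0.007:0.018), breast-cancer mortality directly, and
#' other-cause mortality as the larger of the life-table probability and the
#' trial's non-breast-cancer mortality (both describe the same event, so
#' they are not added). From the cycle after the window, the early-stage row
#' reverts to the literature recurrence probabilities, breast-cancer death
#' occurs only via the recurrence states, and other-cause death follows the
#' life table. Locoregional and distant rows always use the literature
#' probabilities. Both death states are absorbing and nothing transitions
#' back into the early state.
#'
#' @param model A [cea_model()].
#' @param arm `"exercise"` or `"usual_care"`.
#' @param age Current cohort age (years) for the life-table lookup.
#' @param cycle_index 0-based cycle counter.
#' @param values Optional named vector of parameter values overriding the
#'   model means (used by the probabilistic analysis).
#' @return 5x5 numeric matrix; rows sum to 1.
#' @examples
#' m <- build_transition_matrix(cea_model(), "exercise", age = 60, cycle_index = 9)
#' rowSums(m)
#' @export
build_transition_matrix <- function(model, arm, age, cycle_index, values = NULL) {
  arm <- match_arm(arm)
  if (is.null(values)) values <- parameter_means(model$parameters)
  qx <- mortality_at(model$life_table, age)
  transition_matrix_impl(values, qx, arm, cycle_index, model$settings$trial_window_years)
}

# Numeric engine core shared by run_cohort() and the Monte Carlo loop:
# propagates the occupancy row vector and records post-transition occupancy
# and within-cycle flows as plain matrices.
cohort_core <- function(values, qx_all, arm, s) {
  n_max <- length(qx_all)
  occ <- matrix(NA_real_, n_max, 5)
  flows <- matrix(0, n_max, 7)
  cur <- c(1, 0, 0, 0, 0)
  n_run <- 0
  for (t in seq_len(n_max) - 1) {
    if (t > 0 && sum(cur[1:3]) < s$min_alive) break
    m <- transition_matrix_impl(values, qx_all[t + 1], arm, t, s$trial_window_years)
    nxt <- as.numeric(cur %*% m)
    n_run <- t + 1
    occ[n_run, ] <- nxt
    fbe <- cur[1] * m[1, 4]
    fbl <- cur[2] * m[2, 4]
    fbd <- cur[3] * m[3, 4]
    flows[n_run, ] <- c(
      cur[1] * m[1, 2],
      cur[1] * m[1, 3] + cur[2] * m[2, 3],
      fbe + fbl + fbd,
      cur[1] * m[1, 5] + cur[2] * m[2, 5] + cur[3] * m[3, 5],
      fbe, fbl, fbd
    )
    cur <- nxt
  }
  list(
    occ = occ[seq_len(n_run), , drop = FALSE],
    flows = flows[seq_len(n_run), , drop = FALSE],
    n = n_run
  )
}

flow_names <- function() {
  c("f_new_local", "f_new_distant", "f_brc_death", "f_other_death",
    "f_brc_death_early", "f_brc_death_local", "f_brc_death_distant")
}

#' Run the cohort through its lifetime
#'
#' Starts the whole cohort in the early-stage state at the starting age and
#' propagates it through yearly cycles until the horizon age or until fewer
#' than `min_alive` of the cohort remain alive. Each row of the returned
#' trace records the occupancy *after* that cycle's transition, together
#' with the within-cycle transition flows the valuation needs (new local and
#' distant recurrences, deaths by cause, and breast-cancer deaths by state
#' of origin).
#'
#' @inheritParams build_transition_matrix
#' @return A tibble of class `cohort_trace` with columns `cycle` (0-based),
#'   `age` (at cycle start), one occupancy column per health state, and flow
#'   columns `f_new_local`, `f_new_distant`, `f_brc_death`, `f_other_death`,
#'   `f_brc_death_early`, `f_brc_death_local`, `f_brc_death_distant`.
#'   Attributes: `start` (initial occupancy), `arm`, `settings`.
#' @export
run_cohort <- function(model, arm, values = NULL) {
  arm <- match_arm(arm)
  s <- model$settings
  if (is.null(values)) values <- parameter_means(model$parameters)
  n_max <- floor(s$horizon_age - s$start_age)
  if (n_max < 1) abort("Horizon must allow at least one cycle.")
  qx_all <- mortality_at(model$life_table, s$start_age + seq_len(n_max) - 1)
  core <- cohort_core(values, qx_all, arm, s)
  occ <- core$occ
  colnames(occ) <- health_states()
  flows <- core$flows
  colnames(flows) <- flow_names()
  trace <- bind_cols(
    tibble(
      cycle = seq_len(core$n) - 1L,
      age = s$start_age + seq_len(core$n) - 1
    ),
    as_tibble(occ),
    as_tibble(flows)
  )
  structure(
    trace,
    start = c(early = 1, locoregional = 0, distant = 0, death_brc = 0, death_other = 0),
    arm = arm, settings = s,
    class = c("cohort_trace", class(trace))
  )
}

# Exposure matrix (cycles x states) used for reward accrual: end-of-cycle
# occupancy, except the first and last cycles where start- and end-of-cycle
# occupancy are averaged (half-cycle correction). The "trapezoid" variant
# averages in every cycle.
exposure_matrix <- function(trace) {
  s <- attr(trace, "settings")
  occ_end <- as.matrix(trace[, health_states()])
  n <- nrow(occ_end)
  occ_start <- rbind(attr(trace, "start"), occ_end[-n, , drop = FALSE])
  expo <- occ_end
  if (identical(s$half_cycle, "trapezoid")) {
    expo <- (occ_start + occ_end) / 2
  } else {
    hc <- unique(c(1, n))
    expo[hc, ] <- (occ_start[hc, , drop = FALSE] + occ_end[hc, , drop = FALSE]) / 2
  }
  expo
}

discount_factors <- function(cycles, discount_rate) {
  if (discount_rate < 0) abort("`discount_rate` must be non-negative.")
  (1 + discount_rate)^(-cycles)
}

#' Discounted life-years of a cohort trace
#'
#' Sums the living exposure of every cycle, discounted at
#' `(1 + discount_rate)^(-cycle)`. Exposure follows the engine's half-cycle
#' convention: end-of-cycle occupancy except in the first and last cycles,
#' where start- and end-of-cycle occupancy are averaged.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param discount_rate Annual discount rate (`>= 0`); 0 gives undiscounted
#'   life expectancy.
#' @return Total (discounted) life-years per cohort member.
#' @export
life_years <- function(trace, discount_rate = 0.05) {
  expo <- exposure_matrix(trace)
  alive <- rowSums(expo[, living_states(), drop = FALSE])
  sum(alive * discount_factors(trace$cycle, discount_rate))
}
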