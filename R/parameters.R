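#' Convert an event rate to a transition probability
#'
#' Converts a constant event rate (events per person-year) into the
#' probability that at least one event occurs over `t` years, assuming an
#' exponential waiting time: `1 - exp(-rate * t)`.
#'
#' @param rate Non-negative event rate, events per person-year.
#' @param t Time horizon in years (default 1). Must be positive.
#' @return Probability in `[0, 1)`. Vectorised over `rate` and `t`.
#' @examples
#' rate_to_probability(0.1)        # 0.0951626
#' rate_to_probability(0.1, t = 2) # 0.1812692
#' @export
rate_to_probability <- function(rate, t = 1) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    abort("`rate` must be a non-negative finite number (events per person-year).")
  }
  if (any(!is.finite(t)) || any(t <= 0)) {
    abort("`t` must be a positive number of years.")
  }
  1 - exp(-rate * t)
}

#' Convert a T-year survival proportion to an annual death probability
#'
#' Given the proportion `surv` of a cohort still alive after `years` years,
#' returns the constant annual death probability consistent with that
#' survival: `1 - surv^(1/years)`. This is how a 10-year survival figure is
#' turned into a per-cycle probability of dying.
#'
#' @param surv Survival proportion in `(0, 1]`. An exact 0 is rejected
#'   unless `allow_certain_death = TRUE`, in which case the annual
#'   probability 1 is returned.
#' @param years Positive number of years over which `surv` was observed.
#' @param allow_certain_death Permit `surv = 0` (annual probability 1).
#' @return Annual death probability in `[0, 1]`.
#' @examples
#' survival_to_annual_probability(0.49, 10) # ~0.0688, cf. local-recurrence
#'                                          # breast-cancer mortality 0.069
#' @export
survival_to_annual_probability <- function(surv, years, allow_certain_death = FALSE) {
  if (any(!is.finite(years)) || any(years <= 0)) {
    abort("`years` must be a positive number.")
  }
  if (any(!is.finite(surv)) || any(surv < 0) || any(surv > 1)) {
    abort("`surv` must be a proportion in [0, 1].")
  }
  if (any(surv == 0) && !allow_certain_death) {
    abort(paste0(
      "`surv` = 0 implies certain death within the period; pass ",
      "`allow_certain_death = TRUE` to force an annual probability of 1."
    ))
  }
  1 - surv^(1 / years)
}

# Canonical parameter identifiers; every configuration must supply all of them.
parameter_names <- function() {
  default_parameters()$name
}

#' Model input parameters
#'
#' Returns the model's full input table: annual transition probabilities
#' from the literature, 8-year trial-based arm-specific probabilities,
#' costs (AU$ 2019/20), productivity and carer losses, health utilities,
#' and the cohort starting age. Each row carries a mean, a low and high
#' sensitivity bound (95% interval where available, otherwise +/-10%), the
#' uncertainty distribution family used in probabilistic analyses, and a
#' unit tag.
#'
#' Families follow standard practice: `beta` for probabilities and
#' utilities, `gamma` for costs and losses, `lognormal` for the heavily
#' right-skewed annual out-of-pocket cost (its bounds are multiplicative
#' around the mean), and `fixed` for the starting age, which is varied only
#' in one-way analyses.
#'
#' @return A tibble with columns `name`, `mean`, `low`, `high`, `family`,
#'   `unit` and `label`.
#' @examples
#' default_parameters()
#' @export
default_parameters <- function() {
  tribble_args <- list(
    # name,                      mean,   low,    high,   family,      unit,          label
    c("p_early_distant",         0.018,  0.016,  0.019,  "beta",      "probability", "Early stage to distant recurrence (annual)"),
    c("p_early_local",           0.007,  0.006,  0.007,  "beta",      "probability", "Early stage to local recurrence (annual)"),
    c("p_local_distant",         0.0997, 0.0897, 0.1097, "beta",      "probability", "Local recurrence to distant (annual)"),
    c("p_death_distant",         0.230,  0.207,  0.253,  "beta",      "probability", "Death from distant recurrence (annual)"),
    c("p_death_local",           0.069,  0.0621, 0.0759, "beta",      "probability", "Death from local recurrence (annual)"),
    c("p_nonbrc_death_exercise", 0.0006, 0.0000, 0.0032, "beta",      "probability", "Non-breast-cancer mortality, exercise arm (trial)"),
    c("p_nonbrc_death_usual",    0.0047, 0.0015, 0.0110, "beta",      "probability", "Non-breast-cancer mortality, usual care (trial)"),
    c("p_brc_death_exercise",    0.0059, 0.0028, 0.0109, "beta",      "probability", "Breast-cancer mortality, exercise arm (trial)"),
    c("p_brc_death_usual",       0.0096, 0.0046, 0.0176, "beta",      "probability", "Breast-cancer mortality, usual care (trial)"),
    c("p_recurrence_exercise",   0.0072, 0.0037, 0.0125, "beta",      "probability", "Breast-cancer recurrence, exercise arm (trial)"),
    c("p_recurrence_usual",      0.0076, 0.0033, 0.0150, "beta",      "probability", "Breast-cancer recurrence, usual care (trial)"),
    c("cost_intervention",       1344,   1209,   1478,   "gamma",     "AU$",         "Exercise intervention (one-off)"),
    c("cost_local_recurrence",   8679,   7811,   9547,   "gamma",     "AU$",         "Treatment of local recurrence"),
    c("cost_distant_recurrence", 27677,  24900,  30434,  "gamma",     "AU$",         "Treatment of distant recurrence"),
    c("cost_eol_brc",            25475,  22928,  28023,  "gamma",     "AU$",         "End-of-life care, breast-cancer death"),
    c("cost_eol_other",          12122,  10910,  13334,  "gamma",     "AU$",         "End-of-life care, other-cause death"),
    c("cost_oop_annual",         2538,   797,    9079,   "lognormal", "AU$",         "Out-of-pocket expenses (annual, first 2 years)"),
    c("prod_premature_death",    149909, 134918, 164900, "gamma",     "AU$",         "Productivity loss, premature breast-cancer death (<65)"),
    c("prod_distant",            34719,  31248,  38191,  "gamma",     "AU$",         "Productivity loss, distant recurrence"),
    c("prod_local",              22785,  20506,  25063,  "gamma",     "AU$",         "Productivity loss, local recurrence"),
    c("prod_early",              10850,  9765,   11935,  "gamma",     "AU$",         "Productivity loss, early stage (annual)"),
    c("carer_distant",           56419,  50777,  62061,  "gamma",     "AU$",         "Carer costs, metastatic disease"),
    c("carer_local",             29295,  26365,  32224,  "gamma",     "AU$",         "Carer costs, locoregional disease"),
    c("carer_early",             2170,   1953,   2387,   "gamma",     "AU$",         "Carer costs, early stage (annual)"),
    c("u_early",                 0.818,  0.718,  0.918,  "beta",      "utility",     "Utility, early-stage breast cancer"),
    c("u_add_exercise",          0.070,  0.040,  0.100,  "beta",      "utility",     "Additional utility, exercise arm (first year)"),
    c("u_add_usual",             0.020,  0.000,  0.060,  "beta",      "utility",     "Additional utility, usual care (first year)"),
    c("u_local",                 0.670,  0.567,  0.767,  "beta",      "utility",     "Utility, local recurrence"),
    c("u_distant",               0.640,  0.540,  0.740,  "beta",      "utility",     "Utility, distant recurrence"),
    c("u_terminal",              0.514,  0.414,  0.614,  "beta",      "utility",     "Utility, terminal breast cancer"),
    c("start_age",               52,     44,     60,     "fixed",     "years",       "Age entering the model")
  )
  out <- purrr::map_dfr(tribble_args, function(x) {
    tibble(
      name = x[[1]],
      mean = as.numeric(x[[2]]), low = as.numeric(x[[3]]), high = as.numeric(x[[4]]),
      family = x[[5]], unit = x[[6]], label = x[[7]]
    )
  })
  out
}

#' Validate a parameter table
#'
#' Checks completeness (all canonical identifiers present), ordering
#' `low <= mean <= high`, range constraints (probabilities and utilities in
#' `[0, 1]`, costs non-negative) and known distribution families. Called by
#' [cea_model()] and [load_config()]; a violation aborts with a message
#' naming the offending row.
#'
#' @param parameters A tibble as returned by [default_parameters()].
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_parameters <- function(parameters) {
  required_cols <- c("name", "mean", "low", "high", "family", "unit")
  missing_cols <- setdiff(required_cols, names(parameters))
  if (length(missing_cols) > 0) {
    abort(paste0("Parameter table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  missing <- setdiff(parameter_names(), parameters$name)
  if (length(missing) > 0) {
    abort(paste0(
      "Parameter set is incomplete; missing: ", paste(missing, collapse = ", ")
    ))
  }
  dup <- parameters$name[duplicated(parameters$name)]
  if (length(dup) > 0) {
    abort(paste0("Duplicated parameter name(s): ", paste(unique(dup), collapse = ", ")))
  }
  bad_family <- parameters$name[!parameters$family %in% c("beta", "gamma", "lognormal", "fixed")]
  if (length(bad_family) > 0) {
    abort(paste0("Unknown distribution family for: ", paste(bad_family, collapse = ", ")))
  }
  bad_order <- parameters$name[!(parameters$low <= parameters$mean & parameters$mean <= parameters$high)]
  if (length(bad_order) > 0) {
    abort(paste0("low <= mean <= high violated for: ", paste(bad_order, collapse = ", ")))
  }
  frac <- parameters$unit %in% c("probability", "utility")
  bad_frac <- parameters$name[frac & (parameters$low < 0 | parameters$high > 1)]
  if (length(bad_frac) > 0) {
    abort(paste0("Probability/utility outside [0, 1] for: ", paste(bad_frac, collapse = ", ")))
  }
  bad_cost <- parameters$name[parameters$unit == "AU$" & parameters$low < 0]
  if (length(bad_cost) > 0) {
    abort(paste0("Negative cost for: ", paste(bad_cost, collapse = ", ")))
  }
  invisible(parameters)
}

#' Extract parameter means as a named vector
#'
#' @param parameters A parameter tibble.
#' @return Named numeric vector of means, one entry per parameter.
#' @export
parameter_means <- function(parameters) {
  setNames(parameters$mean, parameters$name)
}
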