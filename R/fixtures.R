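#' Gompertz life-table fixture
#'
#' Builds the age-indexed annual all-cause death probability table the model
#' consumes. The bundled default is a Gompertz hazard
#' `q(age) = A * exp(B * age)`, capped at 0.99, with coefficients calibrated
#' so that `q(52) = 0.002` and `q(90) = 0.12` — anchor values consistent
#' with published female period life tables for Australia. It is a synthetic
#' stand-in for an official life table; substitute a real one via
#' [read_life_table()] for policy use.
#'
#' @param A,B Gompertz coefficients, both positive. Defaults come from
#'   [calibrate_gompertz()] at the anchors above.
#' @param ages Integer ages to tabulate (default 40--100).
#' @return A tibble with columns `age` and `qx` (annual death probability).
#' @examples
#' lt <- make_life_table()
#' lt[lt$age == 52, ]
#' @export
make_life_table <- function(A = NULL, B = NULL, ages = 40:100) {
  if (is.null(A) || is.null(B)) {
    coef <- calibrate_gompertz()
    if (is.null(A)) A <- coef[["A"]]
    if (is.null(B)) B <- coef[["B"]]
  }
  if (A <= 0 || B < 0) abort("Gompertz coefficients must satisfy A > 0, B >= 0.")
  q <- A * exp(B * ages)
  if (any(q > 1)) {
    abort(paste0(
      "Gompertz hazard exceeds 1 at age ", min(ages[q > 1]),
      "; narrow the age range or lower the coefficients."
    ))
  }
  tibble(age = as.integer(ages), qx = pmin(q, 0.99))
}

#' Two-point Gompertz calibration
#'
#' Solves `q(age) = A * exp(B * age)` exactly through two (age, probability)
#' anchors.
#'
#' @param age1,q1,age2,q2 Anchor ages and annual death probabilities;
#'   defaults `q(52) = 0.002`, `q(90) = 0.12`.
#' @return Named numeric vector `c(A = , B = )`.
#' @export
calibrate_gompertz <- function(age1 = 52, q1 = 0.002, age2 = 90, q2 = 0.12) {
  if (q1 <= 0 || q2 <= 0 || q1 >= 1 || q2 >= 1) abort("Anchor probabilities must lie in (0, 1).")
  if (age2 == age1) abort("Anchor ages must differ.")
  B <- log(q2 / q1) / (age2 - age1)
  A <- q1 / exp(B * age1)
  c(A = A, B = B)
}

#' Follow-up-care cost schedule fixture
#'
#' Annual breast-cancer survivor follow-up care costs (GP visits, specialist
#' reviews, mammography) by year since diagnosis, valued in the style of
#' Medicare Benefits Schedule item pricing. Surveillance is most intensive
#' in the first years after diagnosis and tapers to a constant maintenance
#' level. The schedule extends past its last specified year at the tail
#' value. The default profile (AU$ 900, 700, 500, 400, 300 for years 1--5,
#' then 250 per year) is a synthetic stand-in for an itemised schedule.
#'
#' @param profile Numeric vector of non-negative annual costs for years
#'   `1..length(profile)`; the last value is the constant tail.
#' @return A tibble with columns `year` (since diagnosis, starting at 1) and
#'   `cost` (AU$ per year), carrying the tail value as attribute `tail`.
#' @examples
#' sched <- make_followup_schedule()
#' followup_cost(sched, c(1, 10, 40))
#' @export
make_followup_schedule <- function(profile = c(900, 700, 500, 400, 300, 250)) {
  if (length(profile) == 0) abort("`profile` must contain at least one annual cost.")
  if (any(!is.finite(profile)) || any(profile < 0)) abort("Follow-up costs must be non-negative.")
  out <- tibble(year = seq_along(profile), cost = as.numeric(profile))
  attr(out, "tail") <- profile[[length(profile)]]
  out
}

#' Look up follow-up cost for given years since diagnosis
#'
#' @param schedule A schedule tibble from [make_followup_schedule()] or
#'   [read_followup_schedule()].
#' @param year Integer year(s) since diagnosis (1 = first year).
#' @return Annual cost(s), using the schedule's constant tail beyond its
#'   last specified year.
#' @export
followup_cost <- function(schedule, year) {
  if (any(year < 1)) abort("`year` counts years since diagnosis and starts at 1.")
  tail_val <- attr(schedule, "tail")
  if (is.null(tail_val)) tail_val <- schedule$cost[[nrow(schedule)]]
  idx <- match(pmin(year, max(schedule$year)), schedule$year)
  out <- schedule$cost[idx]
  out[is.na(out)] <- tail_val
  out
}

#' Annual death probability lookup
#'
#' @param life_table Tibble with columns `age` and `qx`.
#' @param age Integer age(s); ages beyond the table's range use the nearest
#'   tabulated age.
#' @return Annual all-cause death probability at each age.
#' @export
mortality_at <- function(life_table, age) {
  age <- pmin(pmax(round(age), min(life_table$age)), max(life_table$age))
  life_table$qx[match(age, life_table$age)]
}
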