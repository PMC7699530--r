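#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Returns the ratio of incremental cost to incremental effect when both
#' point the same way, and a dominance label otherwise: `"dominant"` when
#' the strategy saves money and gains effect, `"dominated"` when it costs
#' more and loses effect, `"undefined"` when the incremental effect is
#' exactly zero.
#'
#' @param delta_cost Incremental cost (AU$).
#' @param delta_effect Incremental effect (QALYs or life-years).
#' @return A number, or one of the character labels above. Vectorised
#'   (returns a list when inputs have length > 1; use [icer_numeric()] for
#'   a numeric vector with labels as signed infinities).
#' @examples
#' icer(7409, 0.35)
#' icer(-5, 0.2)     # "dominant"
#' icer(100, -0.1)   # "dominated"
#' @export
icer <- function(delta_cost, delta_effect) {
  one <- function(dc, de) {
    if (de == 0) return("undefined")
    if (dc < 0 && de > 0) return("dominant")
    if (dc > 0 && de < 0) return("dominated")
    dc / de
  }
  if (length(delta_cost) == 1 && length(delta_effect) == 1) {
    return(one(delta_cost, delta_effect))
  }
  purrr::map2(as.list(delta_cost), as.list(delta_effect), one)
}

# Numeric encoding of per-draw ICERs for ranking: dominant draws sort below
# every numeric ratio (-Inf), dominated draws above (+Inf). Draws in the
# north-west quadrant (costlier, less effective) are dominated.
icer_numeric <- function(delta_cost, delta_effect) {
  out <- delta_cost / delta_effect
  out[delta_effect == 0] <- Inf
  out[delta_cost < 0 & delta_effect > 0] <- -Inf
  out[delta_cost > 0 & delta_effect < 0] <- Inf
  out[delta_cost <= 0 & delta_effect < 0] <- Inf
  out
}

#' Percentile uncertainty interval
#'
#' The percentile method used for 95% uncertainty intervals: rank the
#' samples and remove the top and bottom `(1 - mass)/2`. With `n` samples
#' and tail fraction `a`, the interval spans the values at ranks
#' `floor(a * n) + 1` and `n - floor(a * n)`. Samples may carry dominance
#' labels: `"dominant"` ranks below every number (the cost-saving end) and
#' `"dominated"` above; a label at either end of the interval is returned
#' as-is, matching the reporting style "Dominant, AU$31,398".
#'
#' @param samples Numeric vector, possibly containing `-Inf`/`Inf` as
#'   produced by [icer_numeric()], or a list mixing numbers with the labels
#'   `"dominant"`/`"dominated"`.
#' @param mass Central probability mass (default 0.95).
#' @return List with elements `lower` and `upper` (number or label).
#' @examples
#' percentile_interval(1:40)  # lower 2, upper 39
#' @export
percentile_interval <- function(samples, mass = 0.95) {
  if (is.list(samples)) {
    samples <- vapply(samples, function(x) {
      if (identical(x, "dominant")) -Inf
      else if (identical(x, "dominated")) Inf
      else as.numeric(x)
    }, numeric(1))
  }
  n <- length(samples)
  a <- (1 - mass) / 2
  k <- floor(a * n)
  if (n < 1 || (a > 0 && k < 1)) {
    abort(paste0("Too few samples (", n, ") for a ", 100 * mass, "% percentile interval."))
  }
  sorted <- sort(samples)
  relabel <- function(x) {
    if (x == -Inf) "dominant" else if (x == Inf) "dominated" else x
  }
  list(lower = relabel(sorted[k + 1]), upper = relabel(sorted[n - k]))
}

#' Net monetary benefit
#'
#' @param delta_cost,delta_effect Incremental cost and effect (vectors).
#' @param wtp Willingness to pay per unit effect.
#' @return `wtp * delta_effect - delta_cost`.
#' @export
net_monetary_benefit <- function(delta_cost, delta_effect, wtp) {
  wtp * delta_effect - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic draws
#' with positive net monetary benefit.
#'
#' @param delta_cost,delta_effect Per-draw incremental cost and effect, or
#'   a `psa_results` object as first argument.
#' @param wtp_grid Non-negative willingness-to-pay grid (default AU$0 to
#'   100,000 in steps of 1,000).
#' @param ... Passed between methods.
#' @return A tibble with columns `wtp` and `prob_cost_effective` (and, for
#'   the `psa_results` method, an `effect` column distinguishing QALY- and
#'   life-year-based curves).
#' @examples
#' ceac(c(-10, 5, 20), c(0.1, 0.2, -0.05), wtp_grid = c(0, 100))
#' @export
ceac <- function(delta_cost, ...) UseMethod("ceac")

#' @rdname ceac
#' @export
ceac.default <- function(delta_cost, delta_effect, wtp_grid = seq(0, 100000, by = 1000), ...) {
  if (length(wtp_grid) == 0) abort("`wtp_grid` must contain at least one value.")
  if (any(wtp_grid < 0)) abort("Willingness-to-pay values must be non-negative.")
  if (length(delta_cost) < 1) abort("At least one draw is required.")
  tibble(
    wtp = wtp_grid,
    prob_cost_effective = vapply(
      wtp_grid,
      function(l) mean(net_monetary_benefit(delta_cost, delta_effect, l) > 0),
      numeric(1)
    )
  )
}

#' @rdname ceac
#' @export
ceac.psa_results <- function(delta_cost, wtp_grid = seq(0, 100000, by = 1000), ...) {
  psa <- delta_cost
  d <- psa$draws
  bind_rows(
    ceac.default(d$dcost, d$dqaly, wtp_grid) %>% mutate(effect = "qaly"),
    ceac.default(d$dcost, d$dly, wtp_grid) %>% mutate(effect = "ly")
  ) %>% select("effect", "wtp", "prob_cost_effective")
}

#' Incremental summary of paired arm totals
#'
#' Builds the incremental result (mean differences, mean-based ICERs with
#' dominance labels, percentile uncertainty intervals) from per-draw arm
#' totals. Headline ICERs divide the mean incremental cost by the mean
#' incremental effect; per-draw ICERs are used only for the uncertainty
#' interval. Consistent with the headline reporting, the life-year ICER
#' uses undiscounted life-years while costs and QALYs are discounted.
#'
#' @param draws Tibble with columns `dcost`, `dqaly`, `dly` (per-draw
#'   incremental discounted cost, discounted QALYs, undiscounted
#'   life-years).
#' @param mass Interval mass (default 0.95).
#' @return A tibble with one row per quantity (`dcost`, `dqaly`, `dly`,
#'   `icer_qaly`, `icer_ly`): point estimate (character to admit dominance
#'   labels), numeric value where defined, and interval bounds.
#' @export
incremental_summary <- function(draws, mass = 0.95) {
  mean_dc <- mean(draws$dcost)
  mean_dq <- mean(draws$dqaly)
  mean_dl <- mean(draws$dly)
  icer_q <- icer(mean_dc, mean_dq)
  icer_l <- icer(mean_dc, mean_dl)
  try_interval <- function(x) {
    tryCatch(percentile_interval(x, mass),
             error = function(e) list(lower = NA_real_, upper = NA_real_))
  }
  ui <- list(
    dcost = try_interval(draws$dcost),
    dqaly = try_interval(draws$dqaly),
    dly = try_interval(draws$dly),
    icer_qaly = try_interval(icer_numeric(draws$dcost, draws$dqaly)),
    icer_ly = try_interval(icer_numeric(draws$dcost, draws$dly))
  )
  fmt <- function(x) if (is.character(x)) x else format(x, trim = TRUE)
  tibble(
    quantity = c("dcost", "dqaly", "dly", "icer_qaly", "icer_ly"),
    estimate = c(mean_dc, mean_dq, mean_dl,
                 if (is.numeric(icer_q)) icer_q else NA_real_,
                 if (is.numeric(icer_l)) icer_l else NA_real_),
    label = c(NA, NA, NA,
              if (is.character(icer_q)) icer_q else NA,
              if (is.character(icer_l)) icer_l else NA),
    lower = purrr::map_chr(ui, ~ fmt(.x$lower)),
    upper = purrr::map_chr(ui, ~ fmt(.x$upper))
  )
}
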