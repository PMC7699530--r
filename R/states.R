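#' Health states and treatment arms
#'
#' The model distinguishes five mutually exclusive health states. Women start
#' in `early` (early-stage I/II breast cancer) and can progress to
#' `locoregional` or `distant` recurrence, die of breast cancer
#' (`death_brc`) or die of any other cause (`death_other`). The two death
#' states are absorbing, and no state transitions back into `early`.
#'
#' @return `health_states()` returns the character vector of the five state
#'   names in canonical order; `living_states()` the three non-absorbing
#'   states; `model_arms()` the two strategy labels.
#' @examples
#' health_states()
#' @export
health_states <- function() {
  c("early", "locoregional", "distant", "death_brc", "death_other")
}

#' @rdname health_states
#' @export
living_states <- function() {
  c("early", "locoregional", "distant")
}

#' @rdname health_states
#' @export
model_arms <- function() {
  c("exercise", "usual_care")
}

match_arm <- function(arm) {
  match.arg(arm, model_arms())
}
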