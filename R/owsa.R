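#' One-way (tornado) sensitivity analysis
#'
#' Pins each parameter in turn at its low and at its high bound and
#' recomputes the incremental cost per QALY. Two modes are provided:
#'
#' * `"resample"`: with the pinned parameter held fixed, every other
#'   parameter is re-drawn from its uncertainty distribution over `n`
#'   iterations and the mean-based ICER recorded (one-way analysis run as
#'   repeated simulation).
#' * `"deterministic"`: all other parameters stay at their means and a
#'   single pair of cohort runs gives the ICER.
#'
#' Pinning `start_age` re-ages the whole cohort (life-table lookups, the
#' retirement cutoff for premature-death productivity losses and the
#' horizon all move with it).
#'
#' @param model A [cea_model()].
#' @param parameters Character vector of parameter names to vary (default:
#'   every non-fixed parameter plus `start_age`).
#' @param mode `"resample"` or `"deterministic"` (see above).
#' @param n Iterations per pinned bound in `"resample"` mode.
#' @param seed Integer seed (resample mode).
#' @return A tibble of class `owsa_results`, one row per parameter, sorted
#'   by descending bar width: `parameter`, `low`, `high` (the pinned input
#'   values), `icer_low`, `icer_high` (AU$/QALY at each bound) and `width`
#'   (`|icer_high - icer_low|`), with the base-case ICER as attribute
#'   `base_icer`.
#' @examples
#' \donttest{
#' run_owsa(cea_model(), parameters = "p_recurrence_exercise",
#'          mode = "deterministic")
#' }
#' @export
run_owsa <- function(model, parameters = NULL,
                     mode = c("resample", "deterministic"),
                     n = model$settings$psa_iterations, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ptab <- model$parameters
  if (is.null(parameters)) {
    parameters <- ptab$name[ptab$family != "fixed" | ptab$name == "start_age"]
  }
  unknown <- setdiff(parameters, ptab$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }

  pinned_icer <- function(pname, value) {
    m <- model
    m$parameters$mean[m$parameters$name == pname] <- value
    if (pname == "start_age") m$settings$start_age <- value
    if (mode == "deterministic") {
      bc <- run_base_case(m)
      return(bc$incremental[bc$quantity == "icer_qaly"])
    }
    # resample mode: the pinned parameter is fixed, the rest vary
    m$parameters$family[m$parameters$name == pname] <- "fixed"
    psa <- run_psa(m, n = n)
    g <- glance(psa)
    g$icer_qaly
  }

  rows <- purrr::map_dfr(parameters, function(pname) {
    row <- ptab[ptab$name == pname, ]
    tibble(
      parameter = pname,
      low = row$low, high = row$high,
      icer_low = pinned_icer(pname, row$low),
      icer_high = pinned_icer(pname, row$high)
    )
  })
  out <- rows %>%
    mutate(width = abs(.data$icer_high - .data$icer_low)) %>%
    arrange(desc(.data$width))
  bc <- run_base_case(model)
  structure(
    out,
    base_icer = bc$incremental[bc$quantity == "icer_qaly"],
    mode = mode,
    class = c("owsa_results", class(out))
  )
}
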