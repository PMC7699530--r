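#' Write a model configuration to YAML
#'
#' Serialises the parameter table and run settings to a single YAML file:
#' one block per parameter (`name`, `mean`, `low`, `high`, `family`,
#' `unit`, `label`) plus a `settings` block. Reading the file back with
#' [load_config()] reproduces the configuration exactly (probabilities are
#' written with 6 decimals, currency with 2 — lossless for all model
#' inputs).
#'
#' @param model A [cea_model()] (or a list with `parameters` and
#'   `settings`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  params <- purrr::pmap(model$parameters, function(name, mean, low, high, family, unit, ...) {
    dots <- list(...)
    out <- list(
      name = name,
      mean = round_unit(mean, unit), low = round_unit(low, unit),
      high = round_unit(high, unit), family = family, unit = unit
    )
    if (!is.null(dots$label)) out$label <- dots$label
    out
  })
  s <- model$settings
  doc <- list(
    parameters = params,
    settings = list(
      start_age = s$start_age, discount_rate = s$discount_rate,
      cycle_length = s$cycle_length, horizon_age = s$horizon_age,
      min_alive = s$min_alive, trial_window_years = s$trial_window_years,
      psa_iterations = s$psa_iterations, wtp_threshold = s$wtp_threshold,
      half_cycle = s$half_cycle, early_costs_annual = s$early_costs_annual
    )
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

round_unit <- function(x, unit) {
  if (unit == "AU$") round(x, 2) else round(x, 6)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration written by [write_config()] (or the bundled
#' default under `inst/extdata/parameters.yaml`), validates it against the
#' full set of required parameter identifiers and all range invariants, and
#' returns a [cea_model()] using the supplied (or bundled) life table and
#' follow-up schedule. A configuration missing any identifier, or violating
#' an invariant, is refused with a message naming the gap.
#'
#' @param path Path to the YAML configuration; default the bundled file.
#' @param life_table Optional life-table tibble (default: bundled CSV).
#' @param followup Optional follow-up schedule tibble (default: bundled
#'   CSV).
#' @return A validated [cea_model()].
#' @examples
#' model <- load_config()
#' @export
load_config <- function(path = exercea_file("parameters.yaml"),
                        life_table = NULL, followup = NULL) {
  if (!file.exists(path)) abort(paste0("Configuration file not found: ", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) abort("Configuration lacks a `parameters` block.")
  parameters <- purrr::map_dfr(doc$parameters, function(p) {
    tibble(
      name = p$name %||% NA_character_,
      mean = as.numeric(p$mean), low = as.numeric(p$low), high = as.numeric(p$high),
      family = p$family %||% NA_character_, unit = p$unit %||% NA_character_,
      label = p$label %||% p$name
    )
  })
  validate_parameters(parameters)
  st <- doc$settings %||% list()
  settings <- cea_settings(
    start_age = st$start_age %||% 52,
    discount_rate = st$discount_rate %||% 0.05,
    cycle_length = st$cycle_length %||% 1,
    horizon_age = st$horizon_age %||% 100,
    min_alive = st$min_alive %||% 0.001,
    trial_window_years = st$trial_window_years %||% 8,
    psa_iterations = st$psa_iterations %||% 5000,
    wtp_threshold = st$wtp_threshold %||% 50000,
    half_cycle = st$half_cycle %||% "endpoints",
    early_costs_annual = st$early_costs_annual %||% TRUE
  )
  if (is.null(life_table)) life_table <- read_life_table()
  if (is.null(followup)) followup <- read_followup_schedule()
  cea_model(parameters, life_table, followup, settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled data file
#'
#' @param file File name under the package's `extdata` directory; empty to
#'   list the directory.
#' @return Absolute path.
#' @export
exercea_file <- function(file = "") {
  system.file("extdata", file, package = "exercea", mustWork = file != "")
}

#' Read or write a life table CSV
#'
#' Two-column CSV `age,qx` with one row per integer age.
#'
#' @param path CSV path; the bundled Gompertz fixture by default.
#' @return A life-table tibble (see [make_life_table()]).
#' @export
read_life_table <- function(path = exercea_file("life_table.csv")) {
  out <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), qx = readr::col_double()
  ))
  if (any(out$qx < 0 | out$qx > 1)) abort("Life-table `qx` must lie in [0, 1].")
  out
}

#' @rdname read_life_table
#' @param life_table Life-table tibble to serialise.
#' @export
write_life_table <- function(life_table, path) {
  readr::write_csv(life_table %>% mutate(qx = round(.data$qx, 6)), path)
  invisible(path)
}

#' Read or write a follow-up cost schedule CSV
#'
#' Two-column CSV `year,cost` (year since diagnosis starting at 1); the
#' last year's cost extends as a constant tail.
#'
#' @param path CSV path; the bundled fixture by default.
#' @return A schedule tibble (see [make_followup_schedule()]).
#' @export
read_followup_schedule <- function(path = exercea_file("followup_costs.csv")) {
  out <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), cost = readr::col_double()
  ))
  if (any(out$cost < 0)) abort("Follow-up costs must be non-negative.")
  attr(out, "tail") <- out$cost[[nrow(out)]]
  out
}

#' @rdname read_followup_schedule
#' @param schedule Schedule tibble to serialise.
#' @export
write_followup_schedule <- function(schedule, path) {
  readr::write_csv(schedule %>% mutate(cost = round(.data$cost, 2)), path)
  invisible(path)
}
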