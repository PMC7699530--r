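#' Write a full set of analysis outputs
#'
#' Serialises a run's results to plot-ready CSV files plus a JSON manifest:
#'
#' * `base_case.csv` — the three-row incremental table (costs, QALYs,
#'   life-years and ICERs) from [run_base_case()];
#' * `psa_draws.csv` — per-draw arm totals and increments (the
#'   cost-effectiveness plane);
#' * `ceac.csv` — acceptability curves per effect measure;
#' * `tornado.csv` — one-way results sorted widest bar first (if supplied);
#' * `manifest.json` — seed, iteration and rejected-draw counts, a hash of
#'   the configuration, package version and timestamp.
#'
#' Currency columns are written with 2 decimals, probabilities and effects
#' with 6; identical runs produce byte-identical CSVs (the timestamp lives
#' only in the manifest).
#'
#' @param model The [cea_model()] the results came from.
#' @param out_dir Output directory (created if absent).
#' @param base_case Tibble from [run_base_case()] (computed if `NULL`).
#' @param psa Optional `psa_results` from [run_psa()].
#' @param ceac_curve Optional CEAC tibble from [ceac()].
#' @param owsa Optional `owsa_results` from [run_owsa()].
#' @return Invisibly, the named list of files written.
#' @export
write_results <- function(model, out_dir, base_case = NULL, psa = NULL,
                          ceac_curve = NULL, owsa = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("Cannot create output directory: ", out_dir))
  }
  files <- list()
  if (is.null(base_case)) base_case <- run_base_case(model)
  files$base_case <- file.path(out_dir, "base_case.csv")
  readr::write_csv(
    base_case %>% mutate(across(c("exercise", "usual_care", "incremental"),
                                ~ round(.x, 6))),
    files$base_case
  )
  if (!is.null(psa)) {
    files$psa_draws <- file.path(out_dir, "psa_draws.csv")
    readr::write_csv(
      psa$draws %>% mutate(across(-"iteration", ~ round(.x, 6))),
      files$psa_draws
    )
  }
  if (!is.null(ceac_curve)) {
    files$ceac <- file.path(out_dir, "ceac.csv")
    readr::write_csv(
      ceac_curve %>% mutate(prob_cost_effective = round(.data$prob_cost_effective, 6)),
      files$ceac
    )
  }
  if (!is.null(owsa)) {
    files$tornado <- file.path(out_dir, "tornado.csv")
    readr::write_csv(
      as_tibble(owsa) %>% mutate(across(c("icer_low", "icer_high", "width"),
                                        ~ round(.x, 2))),
      files$tornado
    )
  }
  files$manifest <- file.path(out_dir, "manifest.json")
  manifest <- run_manifest(model, psa)
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(files)
}

#' Run manifest
#'
#' Provenance record for a run: configuration hash (of the serialised
#' parameters and settings), seed, iteration and rejected-draw counts,
#' package version and timestamp. Identical configurations and seeds give
#' identical manifests up to the timestamp.
#'
#' @param model A [cea_model()].
#' @param psa Optional `psa_results` contributing seed/iteration fields.
#' @return Named list.
#' @export
run_manifest <- function(model, psa = NULL) {
  cfg <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg))
  write_config(model, cfg)
  hash <- unname(tools::md5sum(cfg))
  list(
    config_sha = hash,
    seed = if (!is.null(psa)) psa$seed else NULL,
    iterations = if (!is.null(psa)) psa$n else NULL,
    rejected_draws = if (!is.null(psa)) psa$rejected else NULL,
    package_version = as.character(utils::packageVersion("exercea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
}
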