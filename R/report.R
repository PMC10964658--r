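run_manifest <- function(command, params, seed = NA, scenario = NA_character_) {
  list(
    command = command,
    parameter_hash = rlang::hash(unclass(params)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("tavicea")),
    scenario = scenario
  )
}

write_with_manifest <- function(tables, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write a base-case report to delimited files
#'
#' Emits `categories.csv` (cost per category and arm, with the incremental
#' column), `summary.csv` (one-row headline summary) and `manifest.json`
#' (command, parameter hash, timestamp, package version) into `dir`.
#'
#' @param result A `cea_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cea_report <- function(result, dir) {
  cats <- tidy(result) |>
    select("arm", "category", "discounted") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "discounted") |>
    mutate(incremental = .data$tavi - .data$savr)
  write_with_manifest(
    list(categories = cats, summary = glance(result)),
    run_manifest("base", result$params,
                 scenario = attr(result, "scenario") %||% NA_character_),
    dir
  )
}

#' Write DSA, PSA and scenario reports
#'
#' `write_dsa_report()` emits the swing-ranked tornado table;
#' `write_psa_report()` emits the per-draw cost-effectiveness-plane points,
#' the CEAC table and a one-row summary; `write_scenario_report()` emits
#' one row per catalogued scenario. All carry a `manifest.json`.
#'
#' @param tornado A `cea_tornado`.
#' @param psa A `cea_psa`.
#' @param scenarios A tibble from [run_scenarios()].
#' @param params The parameter set the analysis was run from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @name write_reports
NULL

#' @rdname write_reports
#' @export
write_dsa_report <- function(tornado, params, dir) {
  write_with_manifest(list(tornado = as_tibble(tornado)),
                      run_manifest("dsa", params), dir)
}

#' @rdname write_reports
#' @export
write_psa_report <- function(psa, params, dir) {
  curve <- ceac(psa)
  write_with_manifest(
    list(ce_plane = as_tibble(psa), ceac = as_tibble(curve),
         psa_summary = glance(psa)),
    run_manifest("psa", params, seed = attr(psa, "seed")), dir)
}

#' @rdname write_reports
#' @export
write_scenario_report <- function(scenarios, params, dir) {
  write_with_manifest(list(scenarios = scenarios),
                      run_manifest("scenario", params), dir)
}
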