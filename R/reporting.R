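# Command-layer: thin orchestration over the modelling functions, writing
# CSV/JSON outputs plus a run manifest. Monetary values are rounded to whole
# USD at this layer only; internal arithmetic is full precision.

write_manifest <- function(command, outdir, outputs, config_path, seed = NA,
                           population = NA, engine = NA) {
  m <- list(command = command,
            config = basename(config_path),
            config_md5 = unname(tools::md5sum(config_path)),
            seed = seed, population = population, engine = engine,
            timestamp = format(Sys.time(), tz = "UTC"),
            outputs = basename(outputs))
  path <- file.path(outdir, paste0(command, "_manifest.json"))
  jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(m)
}

#' Base-case command: baseline results table
#'
#' Runs both strategy arms and writes `base_case.csv` (LYs, QALYs, total
#' cost, ICERs, WTP per arm), `base_case.json` (full precision, including
#' the cost breakdowns) and a run manifest.
#'
#' @param config Parameter configuration path (default: bundled).
#' @param outdir Output directory.
#' @param population `"overall"` or `"chinese"`.
#' @param engine `"partitioned_survival"` or `"markov_tp"`.
#' @param repaired Use the repaired survival set (default `TRUE`).
#' @param curve_timescale,half_cycle Passed to [model_settings()].
#' @return The [run_base_case()] result, invisibly.
#' @export
cmd_base_case <- function(config = default_config_path(), outdir = ".",
                          population = "overall",
                          engine = "partitioned_survival",
                          repaired = TRUE, curve_timescale = "stage",
                          half_cycle = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config, population = population)
  settings <- model_settings(wtp_per_qaly = params$settings$wtp_per_qaly,
                             cycle_length_days = params$settings$cycle_length_days,
                             horizon_years = params$settings$horizon_years,
                             annual_discount_rate =
                               params$settings$annual_discount_rate,
                             population = population, engine = engine,
                             curve_timescale = curve_timescale,
                             half_cycle = half_cycle)
  message(sprintf("base-case: population=%s engine=%s curve_timescale=%s %s",
                  population, engine, curve_timescale,
                  if (repaired) "repaired-survival" else "verbatim-survival"))
  bc <- run_base_case(params, settings,
                      survival_set = if (repaired) "repaired" else "verbatim")
  f_csv <- file.path(outdir, "base_case.csv")
  utils::write.csv(bc$table, f_csv, row.names = FALSE)
  f_json <- file.path(outdir, "base_case.json")
  jsonlite::write_json(list(
    settings = unclass(settings),
    intervention = bc$intervention[c("arm", "total_cost", "total_ly",
                                     "total_qaly", "breakdown")],
    comparator = bc$comparator[c("arm", "total_cost", "total_ly",
                                 "total_qaly", "breakdown")],
    comparison = unclass(bc$comparison)),
    f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest("base_case", outdir, c(f_csv, f_json), config,
                 population = population, engine = engine)
  invisible(bc)
}

#' One-way sensitivity command: tornado table
#'
#' Writes `tornado.csv`, sorted by decreasing ICER spread.
#' @inheritParams cmd_base_case
#' @return The [run_owsa()] data frame, invisibly.
#' @export
cmd_owsa <- function(config = default_config_path(), outdir = ".",
                     population = "overall", repaired = TRUE,
                     curve_timescale = "stage") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config, population = population)
  settings <- model_settings(population = population,
                             curve_timescale = curve_timescale)
  tor <- run_owsa(params, settings,
                  survival_set = if (repaired) "repaired" else "verbatim")
  out <- tor
  for (k in c("icer_at_low", "icer_at_high", "base_icer", "spread"))
    out[[k]] <- round(out[[k]])
  f <- file.path(outdir, "tornado.csv")
  utils::write.csv(out, f, row.names = FALSE)
  write_manifest("owsa", outdir, f, config, population = population)
  invisible(tor)
}

#' Probabilistic sensitivity command: PSA draws, summary and CEAC
#'
#' Writes `psa_draws.csv` (the cost-effectiveness-plane scatter),
#' `psa_summary.json` and `ceac.csv`.
#'
#' @inheritParams cmd_base_case
#' @param n Number of draws.
#' @param seed Base seed.
#' @param wtp WTP threshold, USD/QALY.
#' @param wtp_grid CEAC grid.
#' @return The [run_psa()] object, invisibly.
#' @export
cmd_psa <- function(config = default_config_path(), outdir = ".",
                    population = "overall", n = NULL, seed = NULL,
                    wtp = NULL, wtp_grid = seq(0, 80000, by = 1000),
                    repaired = TRUE, curve_timescale = "stage") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config, population = population)
  if (is.null(n)) n <- params$psa$n_draws
  if (is.null(seed)) seed <- params$psa$seed
  if (is.null(wtp)) wtp <- params$settings$wtp_per_qaly
  settings <- model_settings(wtp_per_qaly = wtp, population = population,
                             curve_timescale = curve_timescale)
  psa <- run_psa(params, settings, n_draws = n, seed = seed,
                 survival_set = if (repaired) "repaired" else "verbatim")
  f_draws <- file.path(outdir, "psa_draws.csv")
  utils::write.csv(psa$draws, f_draws, row.names = FALSE)
  f_sum <- file.path(outdir, "psa_summary.json")
  jsonlite::write_json(psa$summary, f_sum, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  f_ceac <- file.path(outdir, "ceac.csv")
  utils::write.csv(ceac(psa, wtp_grid), f_ceac, row.names = FALSE)
  write_manifest("psa", outdir, c(f_draws, f_sum, f_ceac), config,
                 seed = seed, population = population)
  invisible(psa)
}

#' Subgroup command: hazard-ratio table results
#'
#' @inheritParams cmd_psa
#' @param hr_table_csv CSV with columns `name`, `hr` (optionally `hr_low`,
#'   `hr_high`); default: the bundled synthetic example table.
#' @param psa_n PSA draws per subgroup (0 = deterministic only).
#' @return The [run_subgroup_table()] data frame, invisibly.
#' @export
cmd_subgroup <- function(config = default_config_path(),
                         hr_table_csv = system.file("extdata",
                                                    "subgroup_hr_synthetic.csv",
                                                    package = "sclccea"),
                         outdir = ".", population = "overall", psa_n = 0,
                         seed = NULL, curve_timescale = "stage") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config, population = population)
  if (is.null(seed)) seed <- params$psa$seed
  settings <- model_settings(population = population,
                             curve_timescale = curve_timescale)
  res <- run_subgroup_table(params, utils::read.csv(hr_table_csv), settings,
                            psa_n = psa_n, seed = seed)
  f <- file.path(outdir, "subgroup.csv")
  out <- res
  out$icer_per_qaly <- round(out$icer_per_qaly)
  out$delta_cost <- round(out$delta_cost)
  utils::write.csv(out, f, row.names = FALSE)
  write_manifest("subgroup", outdir, f, config, seed = seed,
                 population = population)
  invisible(res)
}

#' Fixture-generation command
#' @param outdir Output directory. @param seed Integer seed.
#' @return Manifest data frame, invisibly.
#' @export
cmd_make_fixtures <- function(outdir = "fixtures", seed = 7L) {
  make_fixture_suite(outdir, seed = seed)
}

#' Parameter-validation command
#'
#' Loads and validates a configuration, prints the survival consistency
#' report and writes a validated JSON provenance dump.
#'
#' @inheritParams cmd_base_case
#' @return The consistency report, invisibly.
#' @export
cmd_validate_params <- function(config = default_config_path(), outdir = ".",
                                population = "overall") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config, population = population)
  rep <- validate_survival_consistency(params)
  print(rep)
  f <- file.path(outdir, "params_validated.json")
  write_parameters(params, f, format = "json")
  write_manifest("validate_params", outdir, f, config,
                 population = population)
  invisible(rep)
}
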