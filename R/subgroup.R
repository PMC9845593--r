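#' Subgroup specification
#'
#' A named overall-survival hazard ratio (intervention vs comparator) with
#' optional confidence bounds. Subgroup OS curves are derived by applying
#' the hazard ratio to the comparator's OS curve under Weibull proportional
#' hazards; PFS handling is unchanged (hazard ratios are published for OS
#' only).
#'
#' @param name Subgroup label.
#' @param hr Overall-survival hazard ratio, > 0.
#' @param hr_low,hr_high Optional CI bounds, `0 < hr_low <= hr <= hr_high`.
#' @return Object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(name, hr, hr_low = NA_real_, hr_high = NA_real_) {
  if (!is.numeric(hr) || hr <= 0) stop("subgroup_spec: hr must be > 0")
  if (!is.na(hr_low) && !is.na(hr_high) &&
      !(0 < hr_low && hr_low <= hr && hr <= hr_high))
    stop("subgroup_spec: need 0 < hr_low <= hr <= hr_high")
  structure(list(name = name, hr = hr, hr_low = hr_low, hr_high = hr_high),
            class = "subgroup_spec")
}

#' Run the pipeline for one subgroup
#'
#' The intervention's OS curve is re-derived from the comparator's OS curve
#' via [apply_hazard_ratio()]; the intervention PFS curve, comparator curves
#' and all cost/utility inputs stay at base case. A deterministic comparison
#' is always produced; setting `psa_n > 0` adds a probabilistic run for the
#' subgroup's probability of cost-effectiveness. A hazard ratio that leaves
#' the derived intervention OS median below its PFS median is flagged
#' infeasible (the deterministic result is still returned, with the PFS
#' curve capped at OS by the trace engine).
#'
#' @param params An `sclc_parameter_set`.
#' @param spec A [subgroup_spec()].
#' @param settings A [model_settings()] object.
#' @param psa_n PSA draws for the subgroup (0 = deterministic only).
#' @param seed PSA seed (default from the config).
#' @param survival_set `"repaired"` or `"verbatim"`.
#' @return List: `name`, `hr`, `comparison` (`sclc_ce_result`), `p_ce`
#'   (`NA` when `psa_n = 0`), `infeasible`.
#' @export
run_subgroup <- function(params, spec, settings = model_settings(),
                         psa_n = 0, seed = params$psa$seed,
                         survival_set = c("repaired", "verbatim")) {
  stopifnot(inherits(spec, "subgroup_spec"))
  survival_set <- match.arg(survival_set)
  sv <- params$survival[[survival_set]]
  int_os <- apply_hazard_ratio(sv$chemo$os, spec$hr)
  int_os$arm <- "serplulimab_chemo"
  int_pfs <- sv$serplulimab_chemo$pfs
  infeasible <- weibull_median(int_os) < weibull_median(int_pfs)
  traces <- list(
    intervention = suppressWarnings(build_trace(int_os, int_pfs, settings,
                                                pd_tol = Inf)),
    comparator = build_trace(sv$chemo$os, sv$chemo$pfs, settings))
  int <- run_arm("serplulimab_chemo", params, settings,
                 trace = traces$intervention)
  comp <- run_arm("chemo", params, settings, trace = traces$comparator)
  ce <- compare(int, comp, wtp = settings$wtp_per_qaly)
  p_ce <- NA_real_
  if (psa_n > 0)
    p_ce <- run_psa(params, settings, n_draws = psa_n, seed = seed,
                    traces = traces)$summary$p_ce
  list(name = spec$name, hr = spec$hr, comparison = ce, p_ce = p_ce,
       infeasible = infeasible)
}

#' Run all subgroups of a hazard-ratio table
#'
#' @param params An `sclc_parameter_set`.
#' @param hr_table Data frame with columns `name`, `hr` and optionally
#'   `hr_low`, `hr_high` (the CSV layout written by [make_fixture_suite()]).
#' @param settings A [model_settings()] object.
#' @param psa_n,seed,survival_set Passed to [run_subgroup()].
#' @return Data frame: `name`, `hr`, `delta_cost`, `delta_qaly`,
#'   `icer_per_qaly`, `p_ce`, `infeasible`.
#' @export
run_subgroup_table <- function(params, hr_table, settings = model_settings(),
                               psa_n = 0, seed = params$psa$seed,
                               survival_set = "repaired") {
  rows <- lapply(seq_len(nrow(hr_table)), function(j) {
    spec <- subgroup_spec(hr_table$name[j], hr_table$hr[j],
                          if ("hr_low" %in% names(hr_table))
                            hr_table$hr_low[j] else NA_real_,
                          if ("hr_high" %in% names(hr_table))
                            hr_table$hr_high[j] else NA_real_)
    res <- run_subgroup(params, spec, settings, psa_n = psa_n, seed = seed,
                        survival_set = survival_set)
    data.frame(name = res$name, hr = res$hr,
               delta_cost = res$comparison$delta_cost,
               delta_qaly = res$comparison$delta_qaly,
               icer_per_qaly = res$comparison$icer_per_qaly,
               p_ce = res$p_ce, infeasible = res$infeasible,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
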