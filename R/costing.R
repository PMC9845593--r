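#' Baseline value list of a parameter set
#'
#' Flattens the distribution specs of an `sclc_parameter_set` into the plain
#' numeric values the accrual functions consume. Sensitivity analyses
#' perturb this list rather than the parameter set itself.
#'
#' @param params An `sclc_parameter_set`.
#' @return Nested list of numerics (utilities, disutilities, AE risks,
#'   topotecan fractions, unit costs, treatment-duration settings).
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "sclc_parameter_set"))
  sp <- function(x) x$mean
  list(
    u_pfs = sp(params$utilities$pfs),
    u_pd = sp(params$utilities$pd),
    disutilities = vapply(params$disutilities, sp, numeric(1)),
    ae_risks = lapply(params$ae_risks, function(a) vapply(a, sp, numeric(1))),
    topo_frac = vapply(params$post_discontinuation_topotecan, sp, numeric(1)),
    drug_costs = vapply(params$drug_costs, sp, numeric(1)),
    ae_cost = vapply(params$ae_management_cost, sp, numeric(1)),
    other_costs = vapply(params$other_costs, sp, numeric(1)),
    weight = sp(params$patient$weight),
    bsa = sp(params$patient$bsa),
    treatment = params$treatment
  )
}

serplulimab_paid_cap <- function(values, settings) {
  tr <- values$treatment
  cap_years <- floor(tr$serplulimab_max_treatment_years * 365.25 /
                       settings$cycle_length_days)
  min(tr$serplulimab_paid_cycles, cap_years)
}

#' Accrue discounted costs over a trace
#'
#' Per-cycle attachment rules: first-line drug costs follow the
#' treatment-duration settings (etoposide/carboplatin for the first
#' `chemo_treatment_cycles` Markov cycles in both arms; serplulimab, in the
#' intervention arm, for the first `serplulimab_paid_cycles` cycles within
#' the overall treatment window — the purchased doses under the
#' patient-assistance scheme); administration, laboratory and imaging costs
#' accrue per progression-free cycle; best supportive care per progressed
#' cycle for the non-topotecan fraction and topotecan for the arm-specific
#' fraction; terminal care is a one-off applied to incident deaths; the
#' arm-level adverse-event management cost is a one-off in cycle 0.
#'
#' @param trace A `markov_trace`.
#' @param arm `"serplulimab_chemo"` or `"chemo"`.
#' @param params An `sclc_parameter_set` (ignored when `values` is given).
#' @param settings The [model_settings()] used to build the trace.
#' @param values Optional [param_values()] list (used by sensitivity
#'   analyses).
#' @param discount Apply discounting (default `TRUE`).
#' @return List with `breakdown` (named vector: drugs, administration,
#'   laboratory, imaging, ae, bsc, topotecan, terminal) and `total`, USD.
#' @export
accrue_costs <- function(trace, arm, params, settings,
                         values = param_values(params), discount = TRUE) {
  stopifnot(inherits(trace, "markov_trace"))
  if (!arm %in% arms()) stop("unknown arm: ", arm)
  n <- settings$n_cycles
  i <- 0:(n - 1)
  d <- if (discount) discount_factors(settings, i) else rep(1, n)
  occ <- accrual_occupancy(trace, settings)
  dc <- values$drug_costs
  oc <- values$other_costs
  tr <- values$treatment

  ec_cost <- (dc[["etoposide"]] + dc[["carboplatin"]]) *
    sum(occ$pfs * d * (i < tr$chemo_treatment_cycles))
  serp_cost <- if (arm == "serplulimab_chemo") {
    dc[["serplulimab"]] * sum(occ$pfs * d * (i < serplulimab_paid_cap(values,
                                                                      settings)))
  } else 0
  topo_occ <- occ$pd
  if (!is.null(tr$topotecan_max_cycles) && is.finite(tr$topotecan_max_cycles)) {
    # progressed patients are charged topotecan for at most this many cycles:
    # approximate by capping the charged PD occupancy at its running maximum
    # over that many cycles of incident progression history
    cap <- tr$topotecan_max_cycles
    inc <- trace$incident_progressions[seq_len(n) + 1]
    charged <- stats::filter(inc, rep(1, cap), sides = 1)
    charged[is.na(charged)] <- cumsum(inc)[is.na(charged)]
    topo_occ <- pmin(occ$pd, as.numeric(charged))
  }
  frac <- values$topo_frac[[arm]]
  inc_death <- trace$incident_deaths[-1]          # deaths during cycle i -> i+1
  d_all <- if (discount) discount_factors(settings, seq_len(n))
           else rep(1, n)
  breakdown <- c(
    drugs = unname(ec_cost + serp_cost),
    administration = oc[["administration"]] * sum(occ$pfs * d),
    laboratory = oc[["laboratory"]] * sum(occ$pfs * d),
    imaging = oc[["imaging"]] * sum(occ$pfs * d),
    ae = unname(values$ae_cost[[arm]]),
    bsc = oc[["bsc"]] * sum(occ$pd * (1 - frac) * d),
    topotecan = dc[["topotecan"]] * sum(topo_occ * frac * d),
    terminal = oc[["terminal"]] * sum(inc_death * d_all)
  )
  list(breakdown = breakdown, total = sum(breakdown))
}

#' One-off adverse-event QALY decrement (undiscounted, cycle 0)
#'
#' `sum(risk * disutility) * cycle length in years` for the arm's grade >= 3
#' adverse events, applied once.
#' @inheritParams accrue_costs
#' @return QALYs lost.
#' @export
ae_qaly_decrement <- function(arm, params, settings,
                              values = param_values(params)) {
  risks <- values$ae_risks[[arm]]
  dis <- values$disutilities[names(risks)]
  sum(risks * dis) * settings$cycle_years
}

#' Accrue discounted quality-adjusted life-years over a trace
#'
#' Progression-free and progressed occupancy are weighted by their state
#' utilities per cycle; the one-off adverse-event decrement
#' ([ae_qaly_decrement()]) is subtracted in cycle 0.
#'
#' @inheritParams accrue_costs
#' @return Total QALYs (scalar).
#' @export
accrue_qalys <- function(trace, arm, params, settings,
                         values = param_values(params), discount = TRUE) {
  stopifnot(inherits(trace, "markov_trace"))
  n <- settings$n_cycles
  d <- if (discount) discount_factors(settings, 0:(n - 1)) else rep(1, n)
  occ <- accrual_occupancy(trace, settings)
  sum((values$u_pfs * occ$pfs + values$u_pd * occ$pd) *
        settings$cycle_years * d) -
    ae_qaly_decrement(arm, params, settings, values = values)
}

#' Run one strategy arm end to end
#'
#' Builds (or reuses) the state trace for the arm's survival curves and
#' accrues discounted life-years, QALYs and the cost breakdown.
#'
#' @param arm `"serplulimab_chemo"` or `"chemo"`.
#' @param params An `sclc_parameter_set`.
#' @param settings A [model_settings()] object.
#' @param values Optional perturbed [param_values()] list.
#' @param survival_set `"repaired"` (default) or `"verbatim"`.
#' @param trace Optional precomputed `markov_trace` (used by the subgroup
#'   pipeline, which substitutes hazard-ratio-adjusted curves).
#' @return Object of class `sclc_arm_result`: totals (`total_cost`,
#'   `total_ly`, `total_qaly`), the per-category cost `breakdown`,
#'   progression-free/progressed life-year split and the trace.
#' @export
run_arm <- function(arm, params, settings, values = param_values(params),
                    survival_set = c("repaired", "verbatim"), trace = NULL) {
  survival_set <- match.arg(survival_set)
  if (is.null(trace)) {
    sv <- params$survival[[survival_set]][[arm]]
    trace <- build_trace(sv$os, sv$pfs, settings)
  }
  ly <- accrue_life_years(trace, settings, discount = TRUE)
  costs <- accrue_costs(trace, arm, params, settings, values = values)
  qaly <- accrue_qalys(trace, arm, params, settings, values = values)
  structure(list(arm = arm,
                 total_cost = costs$total,
                 total_ly = unname(ly[["ly_total"]]),
                 total_qaly = qaly,
                 ly_pfs = unname(ly[["ly_pfs"]]),
                 ly_pd = unname(ly[["ly_pd"]]),
                 breakdown = costs$breakdown,
                 trace = trace),
            class = "sclc_arm_result")
}

#' @export
print.sclc_arm_result <- function(x, ...) {
  cat(sprintf("%s: %.3f LYs, %.3f QALYs, $%s\n", x$arm, x$total_ly,
              x$total_qaly, format(round(x$total_cost), big.mark = ",")))
  invisible(x)
}

#' Pairwise cost-effectiveness comparison
#'
#' Incremental cost, effect, ICERs per QALY and per LY, and net monetary
#' benefit at the willingness-to-pay threshold. Dominance (one strategy
#' cheaper *and* more effective) is reported as an explicit flag rather than
#' a signed ICER; a zero QALY difference leaves the ICER undefined (`NA`)
#' while the NMB is still returned.
#'
#' @param intervention,comparator `sclc_arm_result` objects (or lists with
#'   `total_cost`, `total_qaly`, `total_ly`).
#' @param wtp Willingness-to-pay, USD per QALY.
#' @return Object of class `sclc_ce_result`: `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly`, `nmb`, `wtp`, `dominance`.
#' @examples
#' compare(list(total_cost = 11202, total_qaly = 1.217, total_ly = 2.243),
#'         list(total_cost = 7194, total_qaly = 0.885, total_ly = 1.661),
#'         wtp = 37653)
#' @export
compare <- function(intervention, comparator, wtp = 37653) {
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  dl <- intervention$total_ly - comparator$total_ly
  dominance <- if (dc < 0 && dq > 0) "intervention_dominant"
  else if (dc > 0 && dq < 0) "intervention_dominated"
  else "none"
  structure(list(
    delta_cost = dc, delta_qaly = dq, delta_ly = dl,
    icer_per_qaly = if (dq != 0) dc / dq else NA_real_,
    icer_per_ly = if (dl != 0) dc / dl else NA_real_,
    nmb = wtp * dq - dc, wtp = wtp, dominance = dominance),
    class = "sclc_ce_result")
}

#' @export
print.sclc_ce_result <- function(x, ...) {
  cat(sprintf("dC $%s, dQALY %.3f, dLY %.3f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly,
              x$delta_ly))
  cat(sprintf("ICER $%s/QALY ($%s/LY), NMB $%s at WTP $%s/QALY [%s]\n",
              format(round(x$icer_per_qaly), big.mark = ","),
              format(round(x$icer_per_ly), big.mark = ","),
              format(round(x$nmb), big.mark = ","),
              format(x$wtp, big.mark = ","), x$dominance))
  invisible(x)
}

#' Run the base case: both arms plus the pairwise comparison
#'
#' @inheritParams run_arm
#' @return List with `intervention` and `comparator` (`sclc_arm_result`),
#'   `comparison` (`sclc_ce_result`) and `table` (the baseline-results table:
#'   LYs, QALYs, total cost, ICERs, WTP per arm).
#' @examples
#' \donttest{
#' bc <- run_base_case(load_parameters(), model_settings())
#' bc$table
#' }
#' @export
run_base_case <- function(params, settings = model_settings(),
                          values = param_values(params),
                          survival_set = c("repaired", "verbatim")) {
  survival_set <- match.arg(survival_set)
  int <- run_arm("serplulimab_chemo", params, settings, values = values,
                 survival_set = survival_set)
  comp <- run_arm("chemo", params, settings, values = values,
                  survival_set = survival_set)
  ce <- compare(int, comp, wtp = settings$wtp_per_qaly)
  tab <- data.frame(
    parameter = c("LYs", "QALYs", "Total cost $", "ICER $/LY", "ICER $/QALY",
                  "WTP $/QALY"),
    serplulimab_chemo = c(round(int$total_ly, 3), round(int$total_qaly, 3),
                          round(int$total_cost), round(ce$icer_per_ly),
                          round(ce$icer_per_qaly), settings$wtp_per_qaly),
    chemo = c(round(comp$total_ly, 3), round(comp$total_qaly, 3),
              round(comp$total_cost), NA, NA, settings$wtp_per_qaly))
  list(intervention = int, comparator = comp, comparison = ce, table = tab)
}

#' Carboplatin dose from the Calvert formula
#'
#' Creatinine clearance by Cockcroft-Gault,
#' `((140 - age) * weight) / (72 * serum creatinine)` (x 0.85 for female
#' patients), then `dose = AUC * (CrCl + 25)` mg. Used only by the optional
#' per-dose costing mode; the shipped base case uses per-cycle aggregate drug
#' costs.
#'
#' @param age Years. @param weight Kilograms.
#' @param serum_creatinine mg/dL. @param auc Target AUC, mg/mL/min.
#' @param sex `"male"` or `"female"`.
#' @return Dose in mg.
#' @examples
#' carboplatin_dose(61, 65, 1, 5) # 5 * ((79 * 65) / 72 + 25)
#' @export
carboplatin_dose <- function(age, weight, serum_creatinine = 1, auc = 5,
                             sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (any(c(age, weight, serum_creatinine) <= 0) || auc < 0)
    stop("carboplatin_dose: physiology inputs must be positive")
  crcl <- ((140 - age) * weight) / (72 * serum_creatinine)
  if (sex == "female") crcl <- 0.85 * crcl
  auc * (crcl + 25)
}
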