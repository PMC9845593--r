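#' Registry of uncertain parameters for sensitivity analysis
#'
#' Every scalar input with a distribution specification, in a fixed order
#' (utilities, disutilities, adverse-event risks, subsequent-therapy
#' fractions, drug costs, adverse-event management costs, other unit costs,
#' patient weight and body-surface area). Structural Weibull parameters are
#' not part of the registry: the configuration publishes no ranges or
#' distributions for them, so survival uncertainty is outside the
#' probabilistic analysis. Parameters with `uniform_fixed` family (target
#' AUC, serum creatinine, discount rate) are excluded as well: they are held
#' at baseline. The fixed ordering, combined with one random stream per
#' parameter, means adding a parameter never perturbs earlier draws.
#'
#' @param params An `sclc_parameter_set`.
#' @return Data frame with columns `name` (settable path), `label`, `family`,
#'   `mean`, `low`, `high`.
#' @export
psa_registry <- function(params) {
  rows <- list()
  add <- function(name, label, spec) {
    if (spec$family == "uniform_fixed") return()
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, label = label, family = spec$family, mean = spec$mean,
      low = spec$low, high = spec$high, stringsAsFactors = FALSE)
  }
  add("utility.pfs", "Utility PFS", params$utilities$pfs)
  add("utility.pd", "Utility PD", params$utilities$pd)
  for (k in names(params$disutilities))
    add(paste0("disutility.", k), paste("Disutility", k),
        params$disutilities[[k]])
  for (a in arms())
    for (k in names(params$ae_risks[[a]]))
      add(paste0("ae_risk.", a, ".", k), paste("Risk", k, "-", a),
          params$ae_risks[[a]][[k]])
  for (a in arms())
    add(paste0("topo_frac.", a), paste("Topotecan fraction -", a),
        params$post_discontinuation_topotecan[[a]])
  for (k in names(params$drug_costs))
    add(paste0("drug_cost.", k), paste("Cost of", k), params$drug_costs[[k]])
  for (a in arms())
    add(paste0("ae_cost.", a), paste("Cost of AEs -", a),
        params$ae_management_cost[[a]])
  for (k in names(params$other_costs))
    add(paste0("other_cost.", k), paste("Cost of", k), params$other_costs[[k]])
  add("patient.weight", "Weight", params$patient$weight)
  add("patient.bsa", "Body surface area", params$patient$bsa)
  do.call(rbind, rows)
}

# Set one registry entry inside a param_values() list.
set_value <- function(values, name, x) {
  p <- strsplit(name, ".", fixed = TRUE)[[1]]
  switch(p[1],
    utility = if (p[2] == "pfs") values$u_pfs <- x else values$u_pd <- x,
    disutility = values$disutilities[[p[2]]] <- x,
    ae_risk = values$ae_risks[[p[2]]][[p[3]]] <- x,
    topo_frac = values$topo_frac[[p[2]]] <- x,
    drug_cost = values$drug_costs[[p[2]]] <- x,
    ae_cost = values$ae_cost[[p[2]]] <- x,
    other_cost = values$other_costs[[p[2]]] <- x,
    patient = if (p[2] == "weight") values$weight <- x else values$bsa <- x,
    stop("unknown registry entry: ", name)
  )
  values
}

range_sd <- function(low, high) (high - low) / (2 * stats::qnorm(0.975))

#' Sample one registry parameter
#'
#' Method-of-moments parameterization from baseline and range, with
#' `sd = (high - low) / (2 * 1.96)`: Beta with
#' `alpha = m * (m(1-m)/s^2 - 1)`, Gamma with `shape = m^2/s^2`,
#' `rate = m/s^2`, Normal truncated at zero. A collapsed or missing range
#' yields the baseline in every draw.
#'
#' @param family,mean,low,high Registry fields.
#' @param n Number of draws.
#' @param name Parameter name (for error messages).
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(family, mean, low, high, n, name = "parameter") {
  if (is.na(low) || is.na(high) || high <= low || family == "uniform_fixed")
    return(rep(mean, n))
  s <- range_sd(low, high)
  switch(family,
    beta = {
      v <- s^2
      if (v >= mean * (1 - mean))
        stop(sprintf("PSA setup: beta moments infeasible for '%s'", name))
      k <- mean * (1 - mean) / v - 1
      stats::rbeta(n, mean * k, (1 - mean) * k)
    },
    gamma = {
      if (mean <= 0) return(rep(0, n))
      stats::rgamma(n, shape = mean^2 / s^2, rate = mean / s^2)
    },
    normal = {
      x <- stats::rnorm(n, mean, s)
      while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), mean, s)
      x
    },
    stop(sprintf("PSA setup: unknown distribution family for '%s'", name))
  )
}

#' Draw the joint parameter sample for the probabilistic analysis
#'
#' One independent random stream per registry parameter, seeded
#' `seed + row index` in registry order, so draws for a given parameter are
#' reproducible and unaffected by later additions to the registry.
#'
#' @param params An `sclc_parameter_set`.
#' @param n Number of draws.
#' @param seed Integer base seed.
#' @return Numeric matrix `n x P` with registry names as columns.
#' @export
sample_psa <- function(params, n, seed) {
  reg <- psa_registry(params)
  draws <- matrix(NA_real_, n, nrow(reg),
                  dimnames = list(NULL, reg$name))
  for (k in seq_len(nrow(reg))) {
    set.seed(seed + k)
    draws[, k] <- sample_parameter(reg$family[k], reg$mean[k], reg$low[k],
                                   reg$high[k], n, name = reg$name[k])
  }
  draws
}

# Draw-invariant occupancy aggregates of one arm: with survival fixed in the
# probabilistic analysis, costs and QALYs are linear in the sampled unit
# values, so the whole PSA reduces to vector arithmetic over these sums.
# Agreement with accrue_costs()/accrue_qalys() is enforced by the degenerate
# -distribution test.
arm_aggregates <- function(trace, settings, values) {
  n <- settings$n_cycles
  i <- 0:(n - 1)
  d <- discount_factors(settings, i)
  occ <- accrual_occupancy(trace, settings)
  tr <- values$treatment
  topo_occ <- occ$pd
  if (!is.null(tr$topotecan_max_cycles) && is.finite(tr$topotecan_max_cycles)) {
    cap <- tr$topotecan_max_cycles
    inc <- trace$incident_progressions[seq_len(n) + 1]
    charged <- stats::filter(inc, rep(1, cap), sides = 1)
    charged[is.na(charged)] <- cumsum(inc)[is.na(charged)]
    topo_occ <- pmin(occ$pd, as.numeric(charged))
  }
  list(
    pfs_py = sum(occ$pfs * settings$cycle_years * d),
    pd_py = sum(occ$pd * settings$cycle_years * d),
    pfs_occ = sum(occ$pfs * d),
    pd_occ = sum(occ$pd * d),
    topo_occ = sum(topo_occ * d),
    ec_occ = sum(occ$pfs * d * (i < tr$chemo_treatment_cycles)),
    serp_occ = sum(occ$pfs * d * (i < serplulimab_paid_cap(values, settings))),
    term_w = sum(trace$incident_deaths[-1] * discount_factors(settings,
                                                              seq_len(n)))
  )
}

psa_arm_outcomes <- function(agg, arm, draws, settings, ae_names) {
  col <- function(nm) draws[, nm]
  dec <- 0
  for (k in ae_names)
    dec <- dec + col(paste0("ae_risk.", arm, ".", k)) *
      col(paste0("disutility.", k))
  qaly <- col("utility.pfs") * agg$pfs_py + col("utility.pd") * agg$pd_py -
    dec * settings$cycle_years
  f <- col(paste0("topo_frac.", arm))
  serp <- if (arm == "serplulimab_chemo") col("drug_cost.serplulimab") *
    agg$serp_occ else 0
  cost <- serp +
    (col("drug_cost.etoposide") + col("drug_cost.carboplatin")) * agg$ec_occ +
    (col("other_cost.administration") + col("other_cost.laboratory") +
       col("other_cost.imaging")) * agg$pfs_occ +
    col("other_cost.bsc") * agg$pd_occ * (1 - f) +
    col("drug_cost.topotecan") * agg$topo_occ * f +
    col(paste0("ae_cost.", arm)) +
    col("other_cost.terminal") * agg$term_w
  list(cost = cost, qaly = qaly)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of every registry parameter per its distribution
#' ([sample_psa()]), rebuilding both arms per draw and recording incremental
#' cost and QALYs. Survival curves are not varied (no published
#' distributions), so state occupancy is draw-invariant and the computation
#' is vectorized across draws.
#'
#' @param params An `sclc_parameter_set`.
#' @param settings A [model_settings()] object.
#' @param n_draws Number of Monte-Carlo draws (config default 10,000).
#' @param seed Base seed (config default).
#' @param traces Optional list with precomputed `intervention` and
#'   `comparator` traces (used by the subgroup analysis).
#' @param survival_set `"repaired"` or `"verbatim"`.
#' @return Object of class `sclc_psa`: `draws` (data frame with per-arm cost
#'   and QALYs, `delta_cost`, `delta_qaly`, `nmb`, `ce`), and `summary`
#'   (probability cost-effective at the WTP, incremental means, ICER of
#'   means, cost-effectiveness-plane quadrant counts).
#' @export
run_psa <- function(params, settings = model_settings(),
                    n_draws = params$psa$n_draws, seed = params$psa$seed,
                    traces = NULL,
                    survival_set = c("repaired", "verbatim")) {
  survival_set <- match.arg(survival_set)
  if (n_draws < 1) stop("run_psa: n_draws must be >= 1")
  values <- param_values(params)
  if (is.null(traces)) {
    sv <- params$survival[[survival_set]]
    traces <- list(
      intervention = build_trace(sv$serplulimab_chemo$os,
                                 sv$serplulimab_chemo$pfs, settings),
      comparator = build_trace(sv$chemo$os, sv$chemo$pfs, settings))
  }
  draws <- sample_psa(params, n_draws, seed)
  ae_names <- names(params$ae_risks$serplulimab_chemo)
  agg_i <- arm_aggregates(traces$intervention, settings, values)
  agg_c <- arm_aggregates(traces$comparator, settings, values)
  int <- psa_arm_outcomes(agg_i, "serplulimab_chemo", draws, settings,
                          ae_names)
  comp <- psa_arm_outcomes(agg_c, "chemo", draws, settings, ae_names)
  wtp <- settings$wtp_per_qaly
  d <- data.frame(cost_intervention = int$cost, qaly_intervention = int$qaly,
                  cost_comparator = comp$cost, qaly_comparator = comp$qaly)
  d$delta_cost <- d$cost_intervention - d$cost_comparator
  d$delta_qaly <- d$qaly_intervention - d$qaly_comparator
  d$nmb <- wtp * d$delta_qaly - d$delta_cost
  d$ce <- d$nmb > 0
  quad <- c(ne = sum(d$delta_qaly > 0 & d$delta_cost >= 0),
            se = sum(d$delta_qaly > 0 & d$delta_cost < 0),
            nw = sum(d$delta_qaly <= 0 & d$delta_cost >= 0),
            sw = sum(d$delta_qaly <= 0 & d$delta_cost < 0))
  structure(list(
    draws = d,
    summary = list(n_draws = n_draws, seed = seed, wtp = wtp,
                   p_ce = mean(d$ce),
                   mean_delta_cost = mean(d$delta_cost),
                   mean_delta_qaly = mean(d$delta_qaly),
                   icer_of_means = mean(d$delta_cost) / mean(d$delta_qaly),
                   quadrants = quad)),
    class = "sclc_psa")
}

#' @export
print.sclc_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("PSA: %d draws (seed %d)\n  P(cost-effective at WTP ",
                     "$%s/QALY) = %.1f%%\n  ICER of means = $%s/QALY\n"),
              s$n_draws, s$seed, format(s$wtp, big.mark = ","),
              100 * s$p_ce, format(round(s$icer_of_means), big.mark = ",")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' Fraction of PSA draws in which the intervention's net monetary benefit
#' exceeds the comparator's, over a willingness-to-pay grid.
#'
#' @param psa An `sclc_psa` object.
#' @param wtp_grid WTP values, USD/QALY (default $0-$80,000 by $1,000).
#' @return Data frame with columns `wtp` and `p_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 80000, by = 1000)) {
  stopifnot(inherits(psa, "sclc_psa"))
  if (!length(wtp_grid)) stop("ceac: empty WTP grid")
  d <- psa$draws
  p <- vapply(wtp_grid, function(w) mean(w * d$delta_qaly - d$delta_cost > 0),
              numeric(1))
  data.frame(wtp = wtp_grid, p_ce = p)
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-runs the full deterministic model with each registry parameter at the
#' low and high end of its one-way range ([owsa_range()]; the published range
#' when available, otherwise +/-20% of baseline), all other parameters at
#' baseline, and sorts by the absolute ICER spread for tornado plotting.
#' Parameters whose perturbation makes the model infeasible are flagged, not
#' dropped.
#'
#' @param params An `sclc_parameter_set`.
#' @param settings A [model_settings()] object.
#' @param survival_set `"repaired"` or `"verbatim"`.
#' @return Data frame (one row per parameter, sorted by decreasing `spread`)
#'   with the inputs used, ICERs at both ends, the base-case ICER and an
#'   `infeasible` flag.
#' @export
run_owsa <- function(params, settings = model_settings(),
                     survival_set = c("repaired", "verbatim")) {
  survival_set <- match.arg(survival_set)
  reg <- psa_registry(params)
  base_values <- param_values(params)
  sv <- params$survival[[survival_set]]
  traces <- list(
    serplulimab_chemo = build_trace(sv$serplulimab_chemo$os,
                                    sv$serplulimab_chemo$pfs, settings),
    chemo = build_trace(sv$chemo$os, sv$chemo$pfs, settings))
  icer_at <- function(values) {
    int <- run_arm("serplulimab_chemo", params, settings, values = values,
                   trace = traces$serplulimab_chemo)
    comp <- run_arm("chemo", params, settings, values = values,
                    trace = traces$chemo)
    compare(int, comp, wtp = settings$wtp_per_qaly)$icer_per_qaly
  }
  base_icer <- icer_at(base_values)
  rows <- lapply(seq_len(nrow(reg)), function(k) {
    spec <- dist_spec(reg$family[k], reg$mean[k], reg$low[k], reg$high[k])
    rng <- owsa_range(spec)
    one <- function(x) tryCatch(icer_at(set_value(base_values, reg$name[k], x)),
                                error = function(e) NA_real_)
    lo <- one(rng[1]); hi <- one(rng[2])
    data.frame(parameter = reg$name[k], label = reg$label[k],
               low_input = rng[1], high_input = rng[2],
               icer_at_low = lo, icer_at_high = hi, base_icer = base_icer,
               spread = abs(hi - lo),
               infeasible = is.na(lo) || is.na(hi),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}
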