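#' Distribution specification for one uncertain parameter
#'
#' One row of the parameter registry: baseline value, one-way range and the
#' sampling family used in probabilistic sensitivity analysis. Beta is used
#' for probabilities and utilities, gamma for costs, normal for physiological
#' measures; `uniform_fixed` marks parameters that have no published range
#' and are held at baseline when sampling.
#'
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"uniform_fixed"`.
#' @param mean Baseline value.
#' @param low,high Range minimum/maximum (`NA` when unpublished).
#' @return Object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "normal", "uniform_fixed"),
                      mean, low = NA_real_, high = NA_real_) {
  family <- match.arg(family)
  if (!is.na(low) && !is.na(high)) {
    if (!(low <= mean && mean <= high))
      stop(sprintf("dist_spec: need low <= mean <= high (got %g, %g, %g)",
                   low, mean, high))
  }
  structure(list(family = family, mean = mean, low = low, high = high),
            class = "dist_spec")
}

#' One-way sensitivity range of a parameter
#'
#' Returns the published range when one exists, otherwise plus/minus 20% of
#' the baseline value (the conventional one-way band).
#'
#' @param spec A [dist_spec()].
#' @return Numeric vector `c(low, high)`.
#' @examples
#' owsa_range(dist_spec("beta", 0.673, 0.538, 0.808)) # c(0.538, 0.808)
#' owsa_range(dist_spec("gamma", 605))                # c(484, 726)
#' @export
owsa_range <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.na(spec$low) && !is.na(spec$high)) c(spec$low, spec$high)
  else c(0.8, 1.2) * spec$mean
}

#' Weibull survival parameters for one endpoint of one arm
#'
#' The survival function is `S(t) = exp(-scale * t^shape)` with `t` in months.
#'
#' @param scale Scale \eqn{\lambda > 0} (per month^shape).
#' @param shape Shape \eqn{\gamma > 0}; values above 1 mean increasing hazard.
#' @param endpoint Optional label, `"os"` or `"pfs"`.
#' @param arm Optional label, `"serplulimab_chemo"` or `"chemo"`.
#' @return Object of class `weibull_params`.
#' @export
weibull_params <- function(scale, shape, endpoint = NA_character_,
                           arm = NA_character_) {
  if (!is.numeric(scale) || scale <= 0) stop("weibull scale must be > 0")
  if (!is.numeric(shape) || shape <= 0) stop("weibull shape must be > 0")
  structure(list(scale = scale, shape = shape,
                 endpoint = endpoint, arm = arm),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull (%s/%s): scale = %g, shape = %g, median = %.2f months\n",
              x$arm, x$endpoint, x$scale, x$shape, weibull_median(x)))
  invisible(x)
}

#' Path of the bundled parameter configuration
#' @return File path of the YAML config shipped with the package.
#' @export
default_config_path <- function() {
  system.file("extdata", "params_astrum005.yaml", package = "sclccea",
              mustWork = TRUE)
}

arms <- function() c("serplulimab_chemo", "chemo")

.spec_from_node <- function(node, name) {
  if (is.null(node$value))
    stop(sprintf("parameter '%s': missing 'value'", name))
  dist_spec(family = if (is.null(node$dist)) "uniform_fixed" else node$dist,
            mean = node$value,
            low = if (is.null(node$low)) NA_real_ else node$low,
            high = if (is.null(node$high)) NA_real_ else node$high)
}

.need <- function(cfg, keys) {
  missing <- setdiff(keys, names(cfg))
  if (length(missing))
    stop("config is missing required keys: ", paste(missing, collapse = ", "))
}

#' Load and validate the model parameter set
#'
#' Reads the structured YAML configuration (all drug, cost, utility,
#' adverse-event and survival inputs), validates every invariant, and derives
#' the "repaired" survival set by median matching (see
#' [repair_survival_set()]). Two chemotherapy survival rows of the shipped
#' configuration are internally inconsistent (the implied PFS median exceeds
#' the OS median); base-case runs use the repaired set by default.
#'
#' @param config_path Path to a YAML config; default the bundled file.
#' @param population `"overall"` or `"chinese"`: which fitted survival rows
#'   (and reference medians) to use.
#' @param repair_tol Relative deviation above which a survival row is
#'   considered inconsistent with its reference median during repair.
#' @return Object of class `sclc_parameter_set`.
#' @examples
#' ps <- load_parameters()
#' ps$survival$repaired$serplulimab_chemo$os
#' @export
load_parameters <- function(config_path = default_config_path(),
                            population = c("overall", "chinese"),
                            repair_tol = 0.25) {
  population <- match.arg(population)
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- tryCatch(
    yaml::read_yaml(config_path),
    error = function(e) stop(sprintf("failed to parse '%s': %s",
                                     config_path, conditionMessage(e)),
                             call. = FALSE)
  )
  .need(cfg, c("settings", "survival", "reference_medians", "utilities",
               "disutilities", "ae_risks", "post_discontinuation_topotecan",
               "drug_costs", "ae_management_cost", "other_costs", "patient",
               "treatment", "psa"))

  surv_raw <- cfg$survival[[population]]
  if (is.null(surv_raw)) stop("config has no survival block for population '",
                              population, "'")
  verbatim <- lapply(stats::setNames(arms(), arms()), function(a) {
    lapply(stats::setNames(c("os", "pfs"), c("os", "pfs")), function(ep) {
      w <- surv_raw[[a]][[ep]]
      if (is.null(w)) stop(sprintf("missing survival row %s/%s", a, ep))
      weibull_params(w$scale, w$shape, endpoint = ep, arm = a)
    })
  })
  medians <- cfg$reference_medians[[population]]

  utilities <- list(pfs = .spec_from_node(cfg$utilities$pfs, "utilities.pfs"),
                    pd = .spec_from_node(cfg$utilities$pd, "utilities.pd"))
  if (utilities$pd$mean > utilities$pfs$mean)
    stop("validation error: utilities.pd exceeds utilities.pfs")
  for (u in names(utilities))
    if (utilities[[u]]$mean < 0 || utilities[[u]]$mean > 1)
      stop("validation error: utilities.", u, " outside [0, 1]")

  disutilities <- lapply(stats::setNames(nm = names(cfg$disutilities)),
                         function(k) .spec_from_node(cfg$disutilities[[k]],
                                                     paste0("disutilities.", k)))
  for (k in names(disutilities))
    if (disutilities[[k]]$mean < 0 || disutilities[[k]]$mean > 1)
      stop("validation error: disutilities.", k, " outside [0, 1]")

  ae_risks <- lapply(stats::setNames(nm = arms()), function(a) {
    r <- lapply(stats::setNames(nm = names(cfg$ae_risks[[a]])), function(k)
      .spec_from_node(cfg$ae_risks[[a]][[k]], paste0("ae_risks.", a, ".", k)))
    for (k in names(r))
      if (r[[k]]$mean < 0 || r[[k]]$mean > 1)
        stop("validation error: ae_risks.", a, ".", k, " outside [0, 1]")
    r
  })
  extra <- setdiff(unlist(lapply(ae_risks, names)), names(disutilities))
  if (length(extra))
    stop("adverse events without a disutility entry: ",
         paste(unique(extra), collapse = ", "))

  topo <- lapply(stats::setNames(nm = arms()), function(a)
    .spec_from_node(cfg$post_discontinuation_topotecan[[a]],
                    paste0("post_discontinuation_topotecan.", a)))

  cost_block <- function(block, prefix) {
    out <- lapply(stats::setNames(nm = names(block)), function(k)
      .spec_from_node(block[[k]], paste0(prefix, ".", k)))
    for (k in names(out))
      if (out[[k]]$mean < 0)
        stop("validation error: ", prefix, ".", k, " is negative")
    out
  }
  drug_costs <- cost_block(cfg$drug_costs, "drug_costs")
  .need(drug_costs, c("serplulimab", "etoposide", "carboplatin", "topotecan"))
  ae_cost <- cost_block(cfg$ae_management_cost, "ae_management_cost")
  other_costs <- cost_block(cfg$other_costs, "other_costs")
  .need(other_costs, c("administration", "laboratory", "imaging", "bsc",
                       "terminal"))

  pat <- cfg$patient
  patient <- list(age = pat$age,
                  weight = .spec_from_node(pat$weight, "patient.weight"),
                  bsa = .spec_from_node(pat$bsa, "patient.bsa"),
                  serum_creatinine = .spec_from_node(pat$serum_creatinine,
                                                     "patient.serum_creatinine"),
                  target_auc = .spec_from_node(pat$target_auc,
                                               "patient.target_auc"),
                  sex = if (is.null(pat$sex)) "male" else pat$sex)
  if (patient$age <= 0) stop("validation error: patient.age must be positive")

  treatment <- cfg$treatment
  .need(treatment, c("chemo_treatment_cycles", "serplulimab_paid_cycles",
                     "serplulimab_max_treatment_years"))

  repaired <- repair_survival_set(verbatim, medians, tol = repair_tol)

  ps <- list(
    population = population,
    config_path = config_path,
    raw = cfg,
    settings = cfg$settings,
    survival = list(verbatim = verbatim,
                    repaired = repaired$curves,
                    repair_log = repaired$log),
    reference_medians = medians,
    utilities = utilities,
    disutilities = disutilities,
    ae_risks = ae_risks,
    post_discontinuation_topotecan = topo,
    drug_costs = drug_costs,
    ae_management_cost = ae_cost,
    other_costs = other_costs,
    patient = patient,
    treatment = treatment,
    psa = cfg$psa
  )
  class(ps) <- "sclc_parameter_set"
  ps
}

#' @export
print.sclc_parameter_set <- function(x, ...) {
  cat(sprintf("Parameter set (%s population) from %s\n",
              x$population, basename(x$config_path)))
  cat(sprintf("  %d uncertain parameters registered for sensitivity analysis\n",
              nrow(psa_registry(x))))
  repaired <- x$survival$repair_log
  n_rep <- sum(repaired$action != "verbatim")
  cat(sprintf("  survival repair: %d of %d rows altered\n", n_rep,
              nrow(repaired)))
  invisible(x)
}

#' Write a parameter set back to disk
#'
#' `format = "yaml"` writes a configuration that [load_parameters()] reads
#' back unchanged (round-trip safe); `format = "json"` writes a provenance
#' dump including the derived repaired survival set and repair log.
#'
#' @param params An `sclc_parameter_set`.
#' @param path Output file.
#' @param format `"yaml"` or `"json"`.
#' @param survival_set Which survival set to embed in a YAML dump:
#'   `"verbatim"` (default, the as-loaded configuration) or `"repaired"`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path, format = c("yaml", "json"),
                             survival_set = c("verbatim", "repaired")) {
  stopifnot(inherits(params, "sclc_parameter_set"))
  format <- match.arg(format)
  survival_set <- match.arg(survival_set)
  if (format == "yaml") {
    cfg <- params$raw
    if (survival_set == "repaired") {
      cfg$survival[[params$population]] <-
        lapply(params$survival$repaired, function(eps)
          lapply(eps, function(w) list(scale = w$scale, shape = w$shape)))
    }
    yaml::write_yaml(cfg, path, precision = 15)
  } else {
    dump <- list(population = params$population,
                 settings = params$settings,
                 survival = params$survival[c("verbatim", "repaired")],
                 repair_log = params$survival$repair_log,
                 reference_medians = params$reference_medians,
                 utilities = params$utilities,
                 disutilities = params$disutilities,
                 ae_risks = params$ae_risks,
                 post_discontinuation_topotecan =
                   params$post_discontinuation_topotecan,
                 drug_costs = params$drug_costs,
                 ae_management_cost = params$ae_management_cost,
                 other_costs = params$other_costs,
                 patient = params$patient,
                 treatment = params$treatment)
    jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Repair an internally inconsistent survival parameter block
#'
#' For each arm and endpoint, both published rows of that arm are candidate
#' curves; the row whose implied Weibull median is closest (relative terms)
#' to the reference trial median is assigned. If even the best candidate
#' deviates by more than `tol`, the scale is recalibrated to hit the trial
#' median exactly while holding the endpoint's published shape fixed
#' (`scale = ln 2 / median^shape`). Rows whose own median already matches are
#' kept verbatim.
#'
#' @param curves Nested list `arm -> endpoint -> weibull_params`.
#' @param medians Nested list `arm -> endpoint -> reference median (months)`.
#' @param tol Relative tolerance (default 0.25).
#' @return List with elements `curves` (repaired nested list) and `log`
#'   (data frame describing the action taken per row).
#' @export
repair_survival_set <- function(curves, medians, tol = 0.25) {
  log_rows <- list()
  out <- curves
  for (a in names(curves)) {
    cand <- curves[[a]]
    for (ep in c("os", "pfs")) {
      target <- medians[[a]][[ep]]
      devs <- vapply(cand, function(w)
        abs(weibull_median(w) - target) / target, numeric(1))
      best <- names(which.min(devs))
      if (devs[[best]] <= tol) {
        w <- cand[[best]]
        action <- if (best == ep) "verbatim" else "reassigned"
        out[[a]][[ep]] <- weibull_params(w$scale, w$shape, endpoint = ep,
                                         arm = a)
        src <- best
      } else {
        shape <- cand[[ep]]$shape
        out[[a]][[ep]] <- weibull_params(log(2) / target^shape, shape,
                                         endpoint = ep, arm = a)
        action <- "recalibrated"
        src <- ep
      }
      log_rows[[paste(a, ep)]] <- data.frame(
        arm = a, endpoint = ep, source_row = src, action = action,
        scale = out[[a]][[ep]]$scale, shape = out[[a]][[ep]]$shape,
        implied_median = weibull_median(out[[a]][[ep]]),
        target_median = target, stringsAsFactors = FALSE)
    }
  }
  list(curves = out, log = do.call(rbind, c(log_rows, make.row.names = FALSE)))
}

#' Audit survival curves against reference trial medians
#'
#' Computes the closed-form Weibull median of every curve and flags (a) any
#' curve whose median deviates from its reference median by more than `tol`
#' in relative terms, and (b) any arm whose implied PFS median exceeds its OS
#' median, which is impossible for a coherent pair of endpoints. Report-only:
#' nothing is modified.
#'
#' @param params An `sclc_parameter_set`.
#' @param trial_medians Nested list `arm -> endpoint -> months`; defaults to
#'   the reference medians of the loaded configuration.
#' @param tol Relative deviation triggering a flag (default 0.25).
#' @param survival_set `"verbatim"` (default: audit what was published) or
#'   `"repaired"`.
#' @return Data frame with one row per (arm, endpoint) and logical columns
#'   `flag_median` and `flag_ordering`.
#' @export
validate_survival_consistency <- function(params, trial_medians = NULL,
                                          tol = 0.25,
                                          survival_set = c("verbatim",
                                                           "repaired")) {
  stopifnot(inherits(params, "sclc_parameter_set"))
  survival_set <- match.arg(survival_set)
  curves <- params$survival[[survival_set]]
  if (is.null(trial_medians)) trial_medians <- params$reference_medians
  rows <- list()
  for (a in names(curves)) {
    med <- vapply(curves[[a]], weibull_median, numeric(1))
    ordering_bad <- med[["pfs"]] > med[["os"]]
    for (ep in c("os", "pfs")) {
      target <- trial_medians[[a]][[ep]]
      rel <- abs(med[[ep]] - target) / target
      rows[[paste(a, ep)]] <- data.frame(
        arm = a, endpoint = ep,
        scale = curves[[a]][[ep]]$scale, shape = curves[[a]][[ep]]$shape,
        implied_median = med[[ep]], trial_median = target,
        rel_deviation = rel,
        flag_median = rel > tol,
        flag_ordering = ordering_bad,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
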