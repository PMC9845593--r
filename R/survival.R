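#' Weibull survival function
#'
#' `S(t) = exp(-scale * t^shape)` with time in the unit the parameters were
#' fitted on (months throughout this package).
#'
#' @param t Non-negative time(s).
#' @param params A [weibull_params()] object.
#' @return Survival probabilities in (0, 1]; `S(0) = 1`.
#' @export
weibull_survival <- function(t, params) {
  stopifnot(inherits(params, "weibull_params"))
  if (any(t < 0)) stop("weibull_survival: t must be >= 0")
  exp(-params$scale * t^params$shape)
}

#' Per-cycle transition probability from a Weibull curve
#'
#' The conditional probability of the event during cycle `cycle_index`,
#' `1 - exp(scale * (t - u)^shape - scale * t^shape)` with
#' `t = cycle_index * cycle_length` and `u = cycle_length`, which is
#' algebraically `1 - S(t) / S(t - u)`.
#'
#' @param cycle_index Cycle number(s), >= 1.
#' @param params A [weibull_params()] object.
#' @param cycle_length Cycle length in the curve's time unit.
#' @return Probabilities in `[0, 1)`; constant over cycles when `shape = 1`
#'   (exponential memorylessness), increasing when `shape > 1`.
#' @export
cycle_transition_prob <- function(cycle_index, params, cycle_length) {
  stopifnot(inherits(params, "weibull_params"))
  if (params$scale <= 0 || params$shape <= 0)
    stop("cycle_transition_prob: scale and shape must be > 0")
  if (any(cycle_index < 1)) stop("cycle_transition_prob: cycle_index >= 1")
  if (cycle_length <= 0) stop("cycle_transition_prob: cycle_length > 0")
  t <- cycle_index * cycle_length
  u <- cycle_length
  1 - exp(params$scale * (t - u)^params$shape - params$scale * t^params$shape)
}

#' Closed-form Weibull median
#'
#' @param params A [weibull_params()] object (or anything with `scale` and
#'   `shape` fields).
#' @return `(ln 2 / scale)^(1 / shape)`, in the curve's time unit.
#' @export
weibull_median <- function(params) {
  (log(2) / params$scale)^(1 / params$shape)
}

#' Apply a proportional hazard ratio to a Weibull curve
#'
#' Under Weibull proportional hazards the scale multiplies by the hazard
#' ratio and the shape is unchanged, so `S'(t) = S(t)^hr` pointwise and the
#' median scales by `hr^(-1/shape)`.
#'
#' @param params A [weibull_params()] object.
#' @param hr Hazard ratio, > 0.
#' @return A new `weibull_params` object.
#' @export
apply_hazard_ratio <- function(params, hr) {
  stopifnot(inherits(params, "weibull_params"))
  if (!is.numeric(hr) || hr <= 0) stop("apply_hazard_ratio: hr must be > 0")
  weibull_params(params$scale * hr, params$shape,
                 endpoint = params$endpoint, arm = params$arm)
}

# ---------------------------------------------------------------------------
# Parametric fitting of digitized Kaplan-Meier coordinates

#' Digitized Kaplan-Meier dataset
#'
#' @param time Months, strictly increasing, >= 0.
#' @param survival Survival probabilities in [0, 1], non-increasing (a final
#'   zero is allowed; fitting transforms use the points strictly inside
#'   (0, 1)).
#' @param at_risk Optional numbers at risk per time point (needed for the
#'   maximum-likelihood fitting mode).
#' @return Object of class `km_dataset` (a data frame).
#' @export
km_dataset <- function(time, survival, at_risk = NULL) {
  if (any(diff(time) <= 0)) stop("km_dataset: times must be strictly increasing")
  if (any(survival > 1 + 1e-12) || any(survival < 0))
    stop("km_dataset: survival must lie in [0, 1]")
  if (any(diff(survival) > 1e-12))
    stop("km_dataset: survival must be non-increasing")
  d <- data.frame(time = time, survival = pmin(survival, 1))
  if (!is.null(at_risk)) d$at_risk <- at_risk
  class(d) <- c("km_dataset", "data.frame")
  d
}

#' Read/write a Kaplan-Meier dataset as CSV
#'
#' Two columns `time_months`, `survival`; optional third `at_risk`.
#' @param path CSV file.
#' @return For `read_km_csv`, a [km_dataset()].
#' @export
read_km_csv <- function(path) {
  d <- utils::read.csv(path)
  km_dataset(d$time_months, d$survival, at_risk = d$at_risk)
}

#' @rdname read_km_csv
#' @param km A [km_dataset()].
#' @export
write_km_csv <- function(km, path) {
  d <- data.frame(time_months = km$time, survival = km$survival)
  if (!is.null(km$at_risk)) d$at_risk <- km$at_risk
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# Family registry: survival function, parameter count, linearized starting
# values. Parameterizations: weibull S = exp(-scale t^shape);
# exponential S = exp(-rate t); gompertz S = exp(-(rate/shape)(e^(shape t)-1));
# loglogistic S = 1 / (1 + (t/scale)^shape); lognormal S = 1 - Phi((ln t -
# meanlog)/sdlog).
surv_family <- function(family) {
  switch(family,
    weibull = list(
      npar = 2L, names = c("scale", "shape"),
      S = function(t, p) exp(-p[1] * t^p[2]),
      start = function(t, s) {
        fit <- stats::lm(log(-log(s)) ~ log(t))
        c(exp(stats::coef(fit)[[1]]), stats::coef(fit)[[2]])
      }),
    exponential = list(
      npar = 1L, names = "rate",
      S = function(t, p) exp(-p[1] * t),
      start = function(t, s) mean(-log(s) / t)),
    gompertz = list(
      npar = 2L, names = c("rate", "shape"),
      S = function(t, p) exp(-(p[1] / p[2]) * (exp(p[2] * t) - 1)),
      start = function(t, s) c(mean(-log(s) / t), 0.05)),
    loglogistic = list(
      npar = 2L, names = c("scale", "shape"),
      S = function(t, p) 1 / (1 + (t / p[1])^p[2]),
      start = function(t, s) {
        fit <- stats::lm(log(1 / s - 1) ~ log(t))
        b <- stats::coef(fit)[[2]]
        c(exp(-stats::coef(fit)[[1]] / b), b)
      }),
    lognormal = list(
      npar = 2L, names = c("meanlog", "sdlog"),
      S = function(t, p) 1 - stats::pnorm((log(t) - p[1]) / p[2]),
      start = function(t, s) {
        fit <- stats::lm(stats::qnorm(1 - s) ~ log(t))
        sdlog <- 1 / stats::coef(fit)[[2]]
        c(-stats::coef(fit)[[1]] * sdlog, sdlog)
      }),
    stop("unknown survival family: ", family)
  )
}

surv_families <- function() c("weibull", "exponential", "gompertz",
                              "loglogistic", "lognormal")

#' Evaluate a fitted parametric survival curve
#'
#' @param curve A `survival_curve` (as returned in `fit$curve` by
#'   [fit_parametric()]).
#' @param t Non-negative times (months).
#' @return Survival probabilities.
#' @export
survcurve_prob <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  if (any(t < 0)) stop("survcurve_prob: t must be >= 0")
  surv_family(curve$family)$S(t, curve$params)
}

.check_km <- function(km) {
  if (nrow(km) < 5)
    stop("fit_parametric: need at least 5 Kaplan-Meier points")
  if (min(km$survival) >= 0.8)
    stop("fit_parametric: curve must extend below survival 0.8")
  if (all(km$survival >= 1 - 1e-12))
    stop("fit_parametric: degenerate data (all survival = 1)")
}

#' Fit a parametric survival model to digitized Kaplan-Meier data
#'
#' Default method is deterministic least squares on the survival scale:
#' starting values come from the family's linearized transform (for Weibull,
#' regression of `log(-log S)` on `log t`), then the residual sum of squares
#' `sum((S_fit - S_km)^2)` is minimized. When numbers at risk are supplied,
#' `method = "mle"` reconstructs pseudo individual-patient data from the KM
#' steps and fits by maximum likelihood via \pkg{flexsurv}. Fit statistics
#' carry AIC/BIC for model ranking: from the RSS
#' (`n log(RSS/n) + 2k`) in regression mode, from the likelihood in MLE
#' mode; the two modes are never mixed in one ranking.
#'
#' @param km A [km_dataset()] (or data frame with `time`, `survival`,
#'   optionally `at_risk`).
#' @param family One of `"weibull"`, `"exponential"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param method `"regression"` (default) or `"mle"`.
#' @return Object of class `parametric_fit`: list with `curve` (a
#'   `survival_curve`: family, named parameter vector, `time_unit`) and
#'   `stats` (method, n, k, rss, loglik, aic, bic).
#' @export
fit_parametric <- function(km, family = "weibull",
                           method = c("regression", "mle")) {
  method <- match.arg(method)
  family <- match.arg(family, surv_families())
  .check_km(km)
  fam <- surv_family(family)

  if (method == "regression") {
    use <- km$time > 0 & km$survival < 1 & km$survival > 0
    if (sum(use) < fam$npar + 1)
      stop("fit_parametric: too few informative points after dropping S = 1")
    t0 <- km$time[use]; s0 <- km$survival[use]
    start <- suppressWarnings(fam$start(t0, s0))
    obj <- function(lp) {
      p <- exp(lp)
      v <- sum((fam$S(t0, p) - s0)^2)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- suppressWarnings(
      stats::optim(log(pmax(start, 1e-8)), obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)))
    opt <- suppressWarnings(
      stats::optim(opt$par, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)))
    p <- exp(opt$par)
    rss <- max(opt$value, .Machine$double.xmin)
    n <- length(t0); k <- fam$npar
    stats <- list(method = "regression", n = n, k = k, rss = rss,
                  loglik = NA_real_,
                  aic = n * log(rss / n) + 2 * k,
                  bic = n * log(rss / n) + k * log(n))
  } else {
    if (is.null(km$at_risk))
      stop("fit_parametric: method='mle' needs an at_risk column")
    ipd <- reconstruct_ipd(km)
    dist <- c(weibull = "weibull", exponential = "exp", gompertz = "gompertz",
              loglogistic = "llogis", lognormal = "lnorm")[[family]]
    fs <- flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, data = ipd,
                                dist = dist)
    cf <- stats::setNames(fs$res[, "est"], rownames(fs$res))
    p <- switch(family,
      weibull = c(cf[["scale"]]^(-cf[["shape"]]), cf[["shape"]]),
      exponential = cf[["rate"]],
      gompertz = c(cf[["rate"]], cf[["shape"]]),
      loglogistic = c(cf[["scale"]], cf[["shape"]]),
      lognormal = c(cf[["meanlog"]], cf[["sdlog"]]))
    n <- nrow(ipd); k <- fam$npar
    stats <- list(method = "mle", n = n, k = k, rss = NA_real_,
                  loglik = fs$loglik, aic = -2 * fs$loglik + 2 * k,
                  bic = -2 * fs$loglik + k * log(n))
  }
  curve <- structure(list(family = family,
                          params = stats::setNames(p, fam$names),
                          time_unit = "months"),
                     class = "survival_curve")
  structure(list(curve = curve, stats = stats), class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s): %s | AIC %.2f, BIC %.2f\n",
              x$curve$family, x$stats$method,
              paste(sprintf("%s = %.6g", names(x$curve$params),
                            x$curve$params), collapse = ", "),
              x$stats$aic, x$stats$bic))
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from KM steps
#'
#' Given survival probabilities and numbers at risk at interval boundaries,
#' derives per-interval event counts from the relative drop in survival
#' applied to the risk set at the start of each interval (the initial cohort
#' size is inferred from the first reported risk set and survival level);
#' the balance of the risk set between consecutive boundaries is treated as
#' censored within the interval. Events are placed at interval midpoints,
#' within-interval censorings at the interval end, and patients still at
#' risk at the last boundary are administratively censored there.
#'
#' @param km A [km_dataset()] with an `at_risk` column.
#' @return Data frame with columns `time` and `status` (1 = event).
#' @export
reconstruct_ipd <- function(km) {
  if (is.null(km$at_risk)) stop("reconstruct_ipd: at_risk column required")
  m <- nrow(km)
  tm <- c(0, km$time); sv <- c(1, km$survival)
  # risk set at the start of interval j = (t_{j-1}, t_j]
  n_start <- c(max(km$at_risk[1], round(km$at_risk[1] / max(km$survival[1],
                                                            1e-12))),
               km$at_risk)
  out <- list()
  for (j in seq_len(m)) {
    n_j <- n_start[j]
    drop <- if (sv[j] > 0) 1 - sv[j + 1] / sv[j] else 0
    d_j <- min(max(0, round(n_j * drop)), n_j)
    c_j <- max(0, n_j - d_j - n_start[j + 1])
    mid <- (tm[j] + tm[j + 1]) / 2
    if (d_j > 0) out[[length(out) + 1]] <-
        data.frame(time = rep(mid, d_j), status = 1)
    if (c_j > 0) out[[length(out) + 1]] <-
        data.frame(time = rep(tm[j + 1], c_j), status = 0)
  }
  if (km$at_risk[m] > 0)
    out[[length(out) + 1]] <- data.frame(time = rep(tm[m + 1],
                                                    km$at_risk[m]),
                                         status = 0)
  ipd <- do.call(rbind, out)
  if (sum(ipd$status) == 0) stop("reconstruct_ipd: no events reconstructed")
  ipd
}

#' Select the best-fitting survival family by information criteria
#'
#' Fits every requested family with [fit_parametric()] and returns the
#' minimum-AIC fit; ties are broken by BIC, then by fewer parameters. Families
#' whose fit fails are skipped; if all fail, the per-family errors are
#' reported.
#'
#' @param km A [km_dataset()].
#' @param families Character vector of candidate families.
#' @param method Passed to [fit_parametric()].
#' @return The winning `parametric_fit`, with a `ranking` attribute (data
#'   frame of family, aic, bic, k).
#' @export
select_best_family <- function(km, families = surv_families(),
                               method = "regression") {
  fits <- list(); errs <- character()
  for (f in families) {
    res <- tryCatch(fit_parametric(km, f, method = method), error = identity)
    if (inherits(res, "error")) errs[f] <- conditionMessage(res)
    else fits[[f]] <- res
  }
  if (!length(fits))
    stop("select_best_family: all fits failed:\n",
         paste(sprintf("  %s: %s", names(errs), errs), collapse = "\n"))
  rk <- data.frame(
    family = names(fits),
    aic = vapply(fits, function(x) x$stats$aic, numeric(1)),
    bic = vapply(fits, function(x) x$stats$bic, numeric(1)),
    k = vapply(fits, function(x) x$stats$k, numeric(1)),
    row.names = NULL)
  rk <- rk[order(rk$aic, rk$bic, rk$k), ]
  best <- fits[[rk$family[1]]]
  attr(best, "ranking") <- rk
  best
}
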