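#' Simulate a survival cohort from a Weibull distribution
#'
#' Inverse-transform sampling, `T = (-ln U / scale)^(1/shape)`, with
#' administrative censoring at a fixed cutoff (no dropout process). Emulates
#' the individual-patient data behind a digitized trial curve so the fitting
#' pipeline is testable without trial data.
#'
#' @param params A [weibull_params()] object (months time unit).
#' @param n Number of patients, >= 1.
#' @param cutoff Administrative censoring time in months (`Inf` = none).
#' @param seed Integer seed; the cohort is reproducible under it.
#' @return Object of class `sim_cohort`: data frame with `time` (months) and
#'   `status` (1 = event, 0 = censored at `cutoff`), with the generating
#'   parameters, cutoff and seed as attributes.
#' @export
simulate_cohort <- function(params, n, cutoff = Inf, seed = 1L) {
  stopifnot(inherits(params, "weibull_params"))
  if (n < 1) stop("simulate_cohort: n must be >= 1")
  if (cutoff <= 0) stop("simulate_cohort: cutoff must be > 0")
  set.seed(seed)
  u <- stats::runif(n)
  t_event <- (-log(u) / params$scale)^(1 / params$shape)
  status <- as.integer(t_event <= cutoff)
  d <- data.frame(time = pmin(t_event, cutoff), status = status)
  class(d) <- c("sim_cohort", "data.frame")
  attr(d, "params") <- params
  attr(d, "cutoff") <- cutoff
  attr(d, "seed") <- seed
  d
}

#' Kaplan-Meier estimate of a simulated cohort
#'
#' Product-limit estimator via [survival::survfit()], optionally evaluated on
#' a fixed time grid (with numbers at risk), optionally perturbed by Gaussian
#' jitter to emulate figure-digitization noise (monotonicity is restored with
#' a running minimum).
#'
#' @param cohort A [simulate_cohort()] result (or data frame with `time`,
#'   `status`).
#' @param grid Optional evaluation times in months; default: observed event
#'   times.
#' @param jitter_sd Standard deviation of optional Gaussian jitter on the
#'   survival probabilities (default 0 = none).
#' @param seed Seed for the jitter.
#' @return A [km_dataset()] with an `at_risk` column.
#' @export
km_from_cohort <- function(cohort, grid = NULL, jitter_sd = 0, seed = 1L) {
  if (sum(cohort$status) < 1) stop("km_from_cohort: need at least one event")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = cohort)
  if (is.null(grid)) {
    sm <- summary(fit)
    tm <- sm$time; sv <- sm$surv; nr <- sm$n.risk
  } else {
    sm <- summary(fit, times = grid, extend = TRUE)
    tm <- sm$time; sv <- sm$surv; nr <- sm$n.risk
  }
  keep <- !is.na(sv) & tm > 0
  tm <- tm[keep]; sv <- sv[keep]; nr <- nr[keep]
  if (jitter_sd > 0) {
    set.seed(seed)
    sv <- sv + stats::rnorm(length(sv), 0, jitter_sd)
    sv <- pmin(pmax(sv, 1e-6), 1)
    sv <- cummin(sv)
  }
  km_dataset(tm, sv, at_risk = nr)
}

#' Generate the complete fixture suite
#'
#' Writes, under `outdir`: four digitized-KM CSVs simulated from the
#' overall-population repaired Weibull curves (both arms, OS and PFS), the
#' default parameter configuration, the repaired-survival variant of that
#' configuration, and a synthetic subgroup hazard-ratio table (the trial-wide
#' OS hazard ratios; per-subgroup values were never published, so the table
#' is illustrative). A manifest with MD5 checksums is written alongside and
#' returned.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed controlling the simulated cohorts.
#' @param n Patients per simulated cohort (default 2000).
#' @param config_path Source configuration (default: bundled).
#' @return Data frame manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.csv`.
#' @export
make_fixture_suite <- function(outdir, seed = 7L, n = 2000,
                               config_path = default_config_path()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  params <- load_parameters(config_path, population = "overall")
  files <- character()

  cutoffs <- c(os = 30, pfs = 18)      # months of emulated trial follow-up
  k <- 0L
  for (a in arms()) {
    for (ep in c("os", "pfs")) {
      k <- k + 1L
      w <- params$survival$repaired[[a]][[ep]]
      cohort <- simulate_cohort(w, n = n, cutoff = cutoffs[[ep]],
                                seed = seed + k)
      km <- km_from_cohort(cohort, grid = seq(1, cutoffs[[ep]], by = 1))
      f <- file.path(outdir, sprintf("km_%s_%s.csv", a, ep))
      write_km_csv(km, f)
      files <- c(files, f)
    }
  }

  f_cfg <- file.path(outdir, "params_astrum005.yaml")
  file.copy(config_path, f_cfg, overwrite = TRUE)
  f_rep <- file.path(outdir, "params_astrum005_repaired.yaml")
  write_parameters(params, f_rep, format = "yaml", survival_set = "repaired")
  f_sub <- file.path(outdir, "subgroup_hr_synthetic.csv")
  utils::write.csv(data.frame(
    name = c("overall_population", "asian_population"),
    hr = c(0.63, 0.62), hr_low = c(0.49, 0.46), hr_high = c(0.82, 0.85)),
    f_sub, row.names = FALSE)
  files <- c(files, f_cfg, f_rep, f_sub)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
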