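new_markov_trace <- function(cycle, time_months, pfs, pd, death, settings,
                             engine, clipped = 0L) {
  tr <- data.frame(cycle = cycle, time_months = time_months,
                   pfs = pfs, pd = pd, death = death,
                   incident_deaths = c(0, diff(death)),
                   incident_progressions = c(0, pmax(0, -diff(pfs))))
  class(tr) <- c("markov_trace", "data.frame")
  attr(tr, "settings") <- settings
  attr(tr, "engine") <- engine
  attr(tr, "clipped_cycles") <- clipped
  tr
}

#' Build the three-state trace with the partitioned-survival engine
#'
#' State occupancy at cycle `i` is read directly off the two curves:
#' progression-free = `S_pfs(t_i)`, dead = `1 - S_os(t_i)`, progressed
#' disease = the remainder `S_os(t_i) - S_pfs(t_i)` (clipped at zero when the
#' curves touch). Incident flows are first differences; the gross
#' progression flow is the per-cycle decline of the PFS curve.
#'
#' @param os,pfs [weibull_params()] for overall and progression-free
#'   survival (months time unit).
#' @param settings A [model_settings()] object; its `curve_timescale`
#'   controls how cycle indices map onto curve time.
#' @param pd_tol Largest tolerated PFS-over-OS excursion before the curves
#'   are declared inconsistent (default `1e-6`). Within the tolerance the
#'   progressed-disease row is clipped at zero and the affected cycles are
#'   counted in `attr(trace, "clipped_cycles")`; beyond it the build stops
#'   with a pointer to the repaired parameter set. The subgroup pipeline,
#'   whose hazard-ratio-derived OS curves may legitimately cross a
#'   heavy-tailed PFS curve far out in the extrapolation, clips without
#'   limit (`pd_tol = Inf`).
#' @return A `markov_trace` data frame with columns `cycle`, `time_months`,
#'   `pfs`, `pd`, `death`, `incident_deaths`, `incident_progressions`; every
#'   row sums to 1 and the death column is non-decreasing.
#' @export
build_trace_partitioned <- function(os, pfs, settings, pd_tol = 1e-6) {
  stopifnot(inherits(settings, "sclc_settings"))
  tt <- curve_times(settings)
  s_os <- weibull_survival(tt, os)
  s_pfs <- weibull_survival(tt, pfs)
  pd_raw <- s_os - s_pfs
  if (any(pd_raw < -pd_tol))
    stop("build_trace_partitioned: PFS curve exceeds OS curve (progressed-",
         "disease occupancy would be negative). These survival rows are ",
         "internally inconsistent; use the repaired parameter set ",
         "(survival$repaired, the base-case default).")
  pd <- pmax(pd_raw, 0)
  pfs_m <- pmin(s_pfs, s_os)
  new_markov_trace(0:settings$n_cycles, (0:settings$n_cycles) *
                     settings$cycle_months,
                   pfs_m, pd, 1 - s_os, settings, "partitioned_survival",
                   clipped = sum(pd_raw < 0))
}

#' Build the three-state trace with the transition-probability engine
#'
#' Explicit per-cycle transitions: the progression-free state is left with
#' the PFS curve's transition probability, split between death (the OS
#' curve's transition probability, applied as the all-cause risk) and
#' progression (the remainder); the progressed-to-death probability each
#' cycle is the residual hazard required for cumulative deaths to track
#' `1 - S_os`. Splits that would fall outside `[0, 1]` are clipped and
#' counted (see `attr(trace, "clipped_cycles")`), with a warning.
#'
#' @inheritParams build_trace_partitioned
#' @return A `markov_trace` data frame (see [build_trace_partitioned()]).
#' @export
build_trace_markov <- function(os, pfs, settings) {
  stopifnot(inherits(settings, "sclc_settings"))
  n <- settings$n_cycles
  tt <- curve_times(settings)
  s_os <- weibull_survival(tt, os)
  s_pfs <- weibull_survival(tt, pfs)
  pfs_m <- pd_m <- death <- numeric(n + 1)
  pfs_m[1] <- 1
  clipped <- 0L
  for (i in seq_len(n)) {
    tp_os <- 1 - s_os[i + 1] / s_os[i]
    tp_pfs <- 1 - s_pfs[i + 1] / s_pfs[i]
    p_fd <- tp_os                      # PFS -> death (all-cause)
    p_fp <- tp_pfs - tp_os             # PFS -> PD
    if (p_fp < 0) { clipped <- clipped + 1L; p_fp <- 0 }
    target_d <- s_os[i] - s_os[i + 1]  # required incident deaths
    from_pfs <- pfs_m[i] * p_fd
    p_pd_d <- if (pd_m[i] > 1e-12) (target_d - from_pfs) / pd_m[i] else 0
    if (p_pd_d < 0 || p_pd_d > 1) {
      clipped <- clipped + 1L
      p_pd_d <- min(max(p_pd_d, 0), 1)
    }
    pfs_m[i + 1] <- pfs_m[i] * (1 - p_fd - p_fp)
    pd_m[i + 1] <- pd_m[i] * (1 - p_pd_d) + pfs_m[i] * p_fp
    death[i + 1] <- death[i] + pfs_m[i] * p_fd + pd_m[i] * p_pd_d
  }
  if (clipped > 0)
    warning(sprintf("build_trace_markov: transition split clipped in %d cycle(s)",
                    clipped))
  new_markov_trace(0:n, (0:n) * settings$cycle_months, pfs_m, pd_m, death,
                   settings, "markov_tp", clipped)
}

build_trace <- function(os, pfs, settings, pd_tol = 1e-6) {
  if (settings$engine == "markov_tp") build_trace_markov(os, pfs, settings)
  else build_trace_partitioned(os, pfs, settings, pd_tol = pd_tol)
}

# Occupancy used for accrual during cycles 0 .. n-1: cycle-start occupancy by
# default, interval midpoints under the half-cycle correction.
accrual_occupancy <- function(trace, settings) {
  n <- settings$n_cycles
  i <- seq_len(n)                      # rows 1..n are cycle starts 0..n-1
  if (settings$half_cycle) {
    list(pfs = (trace$pfs[i] + trace$pfs[i + 1]) / 2,
         pd = (trace$pd[i] + trace$pd[i + 1]) / 2)
  } else {
    list(pfs = trace$pfs[i], pd = trace$pd[i])
  }
}

#' Accrue (discounted) life-years over a trace
#'
#' Sums alive-state occupancy across cycles, each cycle contributing its
#' length in years, discounted at the per-cycle factor (cycle 0
#' undiscounted).
#'
#' @param trace A `markov_trace`.
#' @param settings The [model_settings()] the trace was built with.
#' @param discount Apply discounting (default `TRUE`).
#' @return Named numeric vector `c(ly_pfs, ly_pd, ly_total)` in years.
#' @export
accrue_life_years <- function(trace, settings, discount = TRUE) {
  stopifnot(inherits(trace, "markov_trace"))
  occ <- accrual_occupancy(trace, settings)
  d <- if (discount) discount_factors(settings, 0:(settings$n_cycles - 1))
       else rep(1, settings$n_cycles)
  ly_pfs <- sum(occ$pfs * settings$cycle_years * d)
  ly_pd <- sum(occ$pd * settings$cycle_years * d)
  c(ly_pfs = ly_pfs, ly_pd = ly_pd, ly_total = ly_pfs + ly_pd)
}

#' Write a trace to CSV
#' @param trace A `markov_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
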