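#' Model settings for the cohort state-transition model
#'
#' Collects the structural settings of the three-state (progression-free,
#' progressed, dead) cohort model: cycle length, horizon, discounting,
#' willingness-to-pay, trace engine and the curve-time mapping.
#'
#' @param cycle_length_days Markov cycle length in days. Default 42 (6 weeks).
#' @param horizon_years Model horizon in years. Default 10; the cycle count is
#'   `floor(horizon_years * 365.25 / cycle_length_days)` (86 for the defaults).
#' @param annual_discount_rate Annual discount rate applied to costs and
#'   effects; the per-cycle factor is
#'   `(1 + rate)^(-cycle_index * cycle_length_days / 365.25)` with cycle 0
#'   undiscounted. Default 0.03.
#' @param wtp_per_qaly Willingness-to-pay threshold in USD per QALY.
#'   Default 37653 (three times 2021 Chinese per-capita GDP).
#' @param population `"overall"` or `"chinese"`; selects the survival rows
#'   used when the settings are paired with a parameter set.
#' @param engine `"partitioned_survival"` (state occupancy read directly off
#'   the OS and PFS curves, the default) or `"markov_tp"` (explicit per-cycle
#'   transition probabilities).
#' @param curve_timescale How elapsed model time is mapped onto the time axis
#'   of the fitted survival curves. `"stage"` (default) advances the
#'   monthly-fitted curves one fitted time-unit per Markov cycle — the
#'   convention of stage-indexed TreeAge transition formulas, which this
#'   package's reference base case reproduces. `"calendar"` evaluates the
#'   curves at true elapsed months (`cycle_index * cycle_length_days /
#'   30.4375`). See the methods vignette for the trade-off.
#' @param half_cycle Logical; apply a half-cycle (midpoint) correction to
#'   state occupancy when accruing time, costs and QALYs. Default `FALSE`
#'   (cycle-start occupancy).
#'
#' @return An object of class `sclc_settings`: a list with the arguments plus
#'   derived fields `n_cycles`, `cycle_months` and `cycle_years`.
#' @examples
#' s <- model_settings()
#' s$n_cycles # 86
#' @export
model_settings <- function(cycle_length_days = 42,
                           horizon_years = 10,
                           annual_discount_rate = 0.03,
                           wtp_per_qaly = 37653,
                           population = c("overall", "chinese"),
                           engine = c("partitioned_survival", "markov_tp"),
                           curve_timescale = c("stage", "calendar"),
                           half_cycle = FALSE) {
  population <- match.arg(population)
  engine <- match.arg(engine)
  curve_timescale <- match.arg(curve_timescale)
  if (!is.numeric(cycle_length_days) || cycle_length_days <= 0)
    stop("cycle_length_days must be > 0")
  if (annual_discount_rate < 0 || annual_discount_rate >= 1)
    stop("annual_discount_rate must be in [0, 1)")
  if (horizon_years <= 0) stop("horizon_years must be > 0")
  s <- list(
    cycle_length_days = cycle_length_days,
    horizon_years = horizon_years,
    annual_discount_rate = annual_discount_rate,
    wtp_per_qaly = wtp_per_qaly,
    population = population,
    engine = engine,
    curve_timescale = curve_timescale,
    half_cycle = half_cycle,
    n_cycles = floor(horizon_years * 365.25 / cycle_length_days),
    cycle_months = cycle_length_days / 30.4375,
    cycle_years = cycle_length_days / 365.25
  )
  class(s) <- "sclc_settings"
  s
}

#' @export
print.sclc_settings <- function(x, ...) {
  cat("Cohort model settings\n")
  cat(sprintf("  cycle length : %g days (%.4f months)\n",
              x$cycle_length_days, x$cycle_months))
  cat(sprintf("  horizon      : %g years (%d cycles)\n",
              x$horizon_years, x$n_cycles))
  cat(sprintf("  discount     : %.1f%% per year\n",
              100 * x$annual_discount_rate))
  cat(sprintf("  WTP          : $%s per QALY\n",
              format(x$wtp_per_qaly, big.mark = ",")))
  cat(sprintf("  engine       : %s (curve time: %s, half-cycle: %s)\n",
              x$engine, x$curve_timescale, x$half_cycle))
  invisible(x)
}

#' Per-cycle discount factors
#'
#' @param settings An [model_settings()] object.
#' @param cycles Integer vector of cycle indices (default `0:n_cycles`).
#' @return Numeric vector `(1 + r)^(-i * cycle_years)`; cycle 0 is 1.
#' @export
discount_factors <- function(settings, cycles = 0:settings$n_cycles) {
  (1 + settings$annual_discount_rate)^(-cycles * settings$cycle_years)
}

# Time coordinate at which survival curves are evaluated for cycle i.
curve_times <- function(settings, cycles = 0:settings$n_cycles) {
  if (settings$curve_timescale == "stage") cycles
  else cycles * settings$cycle_months
}
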