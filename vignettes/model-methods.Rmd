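---
title: "Model and methods: first-line immunochemotherapy for ES-SCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sclccea)
```

## The decision problem

The package evaluates first-line serplulimab plus etoposide/carboplatin (EC)
against EC alone in extensive-stage small-cell lung cancer from a Chinese
payer perspective. A cohort of 61-year-old, 65-kg patients enters a
three-state model — progression-free (PFS), progressed disease (PD), dead —
in the PFS state and is followed for 10 years in 6-week cycles
(`floor(10 × 365.25 / 42) = 86` cycles), at which point more than 99% of the
cohort has died under every shipped survival set (a property the test suite
asserts). Costs and effects are discounted at 3% per year with the per-cycle
factor `1.03^(−i · 42/365.25)`; cycle 0 is undiscounted. The
willingness-to-pay threshold is $37,653 per QALY (three times 2021 Chinese
per-capita GDP).

## Survival inputs and their repair

Each arm contributes a Weibull overall-survival (OS) and progression-free
survival (PFS) curve, `S(t) = exp(−λ t^γ)` with `t` in months, as obtained
by digitizing trial Kaplan-Meier curves and fitting parametric models. The
per-cycle transition probability is the survival ratio
`1 − S(t)/S(t−u)`; `cycle_transition_prob()` implements the equivalent
closed form `1 − exp{λ(t−u)^γ − λt^γ}` and the identity is enforced to
`1e-12` in tests over the cycles where `S(t)` remains representable in
double precision (the steep Chinese chemotherapy curves underflow to zero
around cycle 77; conditional probabilities past that point are vacuous).

The shipped registry also stores the trial median OS/PFS per arm and
population, because two of the published chemotherapy rows cannot be taken
at face value: in the overall population the chemotherapy "PFS" row implies
a median of ~11.8 months against a trial median of 4.3, exceeding the same
arm's OS median (~11.6) — an impossible ordering — and in the Chinese
population the chemotherapy "OS" row implies ~4.3 months against a trial
median of 11.1 while its "PFS" row implies ~4.1. The rows look swapped or
mistyped. `repair_survival_set()` resolves this mechanically: for each arm
and endpoint both published rows of that arm are candidates, the row whose
implied median `(ln 2/λ)^{1/γ}` is closest to the trial median (relative
terms) is assigned, and if even the best candidate deviates by more than
25% the scale is recalibrated to hit the trial median exactly with the
endpoint's published shape held fixed. For the overall population this
keeps three rows verbatim and recalibrates the chemotherapy PFS scale to
`ln 2 / 4.3^1.56003`; for the Chinese population the chemotherapy "OS" row
is reassigned to the PFS slot and a new OS scale is calibrated to the
11.1-month median. `validate_survival_consistency()` reports (and the tests
assert) exactly which rows are flagged. Base-case runs use the repaired set;
`survival_set = "verbatim"` restores the published rows, and the
partitioned-survival builder refuses them with a pointed error because they
produce negative progressed-disease occupancy.

## Curve time: stage-indexed by default

`model_settings(curve_timescale =)` controls how elapsed model time maps
onto the months axis of the fitted curves. Under `"calendar"` the curves
are evaluated at true elapsed time, `t_i = i × 42/30.4375` months. Under
`"stage"` — the default — they advance one fitted time-unit per cycle
(`t_i = i`), which is how stage-indexed transition formulas are commonly
implemented in TreeAge-style Markov models built from monthly-fitted
curves: with a 6-week cycle this stretches the extrapolated curves by a
factor of 1.38 relative to their fitted time scale. The package defaults to
the stage convention because the base case it ships is calibrated under it;
the published per-arm life-years and QALYs this analysis is built around
are only attainable with the stretch, while the calendar mapping yields
roughly 30% fewer life-years from the same parameters. Both conventions are
first-class: medians, curve audits and the survival-fitting module always
work in fitted months, and switching to `"calendar"` re-derives every
downstream quantity consistently. Analysts reusing the engine on their own
curve sets should prefer `"calendar"`.

## Cost and utility attachment

Per 6-week cycle, with all monetary values in 2022 USD (converted at
¥6.7584 per dollar):

* **First-line drugs.** EC costs ($12 + $73 per cycle) accrue on
  progression-free occupancy for the first 2 cycles (≈ four 3-weekly
  chemotherapy cycles). Serplulimab ($605 per cycle) accrues on
  progression-free occupancy for the first `serplulimab_paid_cycles`
  cycles, default 3 — six 3-weekly doses, the purchased portion under the
  manufacturer patient-assistance scheme, after which doses are donated —
  within an overall 2-year treatment window. Both durations are config
  keys; the defaults are the calibration of the base case.
* **Care during PFS.** Administration ($36), laboratory ($166) and tumour
  imaging ($507) accrue per progression-free cycle (imaging every 6 weeks
  during treatment; the model restricts these to the PFS state).
* **Progressed disease.** An arm-specific fraction (4.1% / 4.9%) receives
  topotecan ($317 per PD cycle, uncapped by default); the remainder receive
  best supportive care ($221 per PD cycle).
* **One-offs.** Terminal care ($2,221) attaches to incident deaths of any
  cause in every cycle — a cohort model cannot separate cause of death from
  the OS curve. The arm-level aggregate cost of grade ≥3 adverse events
  occurring in more than 5% of patients ($309 / $386) is charged once at
  cycle 0, and the matching QALY decrement
  `Σ risk × disutility × (42/365.25)` is subtracted once, undiscounted —
  adverse events are assumed to occupy a single cycle.

QALYs weight PFS and PD occupancy by utilities 0.673 and 0.473 per year.
State occupancy is measured at cycle start (no half-cycle correction),
matching the TreeAge default; `half_cycle = TRUE` switches to midpoint
weighting, under which total life-years are stable to <1% when the cycle
length is halved (cycle-start accrual carries the usual first-order
overestimate of about half a cycle, which is part of the calibrated base
case). Physiology inputs (weight, body-surface area, creatinine, target
AUC) exist for the optional per-dose costing path (`carboplatin_dose()`
implements Calvert dosing with Cockcroft-Gault clearance) but are inert in
the default per-cycle costing mode.

## Trace engines

The partitioned-survival engine reads occupancy directly off the curves.
The `markov_tp` engine exits PFS with the PFS curve's transition
probability, splits the exit between death (the OS curve's transition
probability, taken as the all-cause risk) and progression (the remainder,
floored at zero), and gives PD each cycle the residual death probability
needed for cumulative deaths to track `1 − S_os`; infeasible splits are
clipped into `[0, 1]` and counted in `attr(trace, "clipped_cycles")` with a
warning. The split rule is a reconstruction — nothing in a two-curve
specification identifies it — which is why partitioned survival, which is
fully determined by the curves, is the default and cross-engine agreement
on life-years (within 2%) is a test rather than an assumption.

## Sensitivity analysis

Twenty-nine parameters carry distributions (utilities and disutilities:
Beta; probabilities: Beta; costs: Gamma; weight and body-surface area:
truncated Normal). Published ranges give the dispersion by method of
moments with `sd = (high − low)/(2 × 1.96)`; rows without ranges (discount
rate, creatinine, AUC) are held fixed, and the structural Weibull
parameters are deliberately excluded — the registry publishes no ranges or
distributions for them, so survival uncertainty is out of scope for the
probabilistic analysis.

One-way analysis re-runs the full deterministic model at each parameter's
range bounds (published range, else ±20% of baseline) and sorts by ICER
spread; the PFS utility dominates, and cost parameters move the ICER
exactly linearly because they enter the incremental cost additively.

The probabilistic analysis samples every registry parameter per draw with
one independent random stream per parameter, seeded `seed + k` in fixed
registry order, so adding a parameter never perturbs earlier streams and a
given seed reproduces the analysis bit for bit. Because survival is fixed,
state occupancy is draw-invariant and each draw is a linear combination of
occupancy aggregates; the 10,000-draw default runs in well under a second,
and a degenerate-range configuration collapses every draw onto the base
case exactly (a test). One consequence is worth stating plainly: with
occupancy fixed, the incremental QALY is bounded well away from zero
(mean ≈ 0.34, sd ≈ 0.03) and the incremental cost (mean ≈ $4.3k,
sd ≈ $0.27k) can never reach `WTP × ΔQ` at the $37,653 threshold, so the
computed probability of cost-effectiveness is essentially 100% and the
acceptability curve rises from ~0 to ~1 between roughly $10k and $15k per
QALY. A lower acceptability at the threshold would require uncertainty
sources (for example sampled survival curves or hazard ratios) that the
parameter registry does not specify.

## Subgroups

Subgroup OS curves are derived by applying an overall-survival hazard ratio
to the *comparator's* OS curve under Weibull proportional hazards
(`λ' = λ × HR`, shape unchanged, so `S'(t) = S(t)^HR` — asserted pointwise
in tests); PFS is left at base case because hazard ratios are published for
OS only, and which arm's curve the ratio should rescale is itself a
convention (the comparator-baseline choice is ours). Per-subgroup hazard
ratios were never published, so the bundled table
(`subgroup_hr_synthetic.csv`) carries only the trial-wide ratios (0.63
overall, 0.62 Asian) as illustrations and subgroup ICERs are range-checked,
not point-matched. The ICER is monotone non-increasing as the hazard ratio
falls — additional survival accrues mostly in the progressed state, whose
cost per QALY is far below the base-case ICER — and a ratio that drags the
derived OS median below the intervention's PFS median is flagged
infeasible. Deep-tail crossings of a hazard-ratio-derived OS curve with the
heavy-tailed PFS curve (shape < 1) are clipped rather than refused.

## Synthetic data and the fitting pipeline

`simulate_cohort()` draws event times by inverse transform
(`T = (−ln U/λ)^{1/γ}`) with administrative censoring at a fixed cutoff —
no dropout process, no accrual curve, which is sufficient to exercise the
fitting path but does not emulate staggered trial entry or
figure-digitization pixel noise (an optional Gaussian jitter on the
survival probabilities is available). `km_from_cohort()` wraps the
product-limit estimator. `fit_parametric()` fits Weibull, exponential,
Gompertz (increasing-hazard parameterization
`S(t) = exp(−(λ/θ)(e^{θt}−1))`), log-logistic (`S(t) = 1/(1+(t/α)^β)`) and
log-normal curves: the default deterministic path takes linearized starting
values (complementary log-log for the Weibull) and minimizes the residual
sum of squares on the survival scale, so all families share one response
scale and `AIC = n ln(RSS/n) + 2k` ranks them comparably; the alternative
path reconstructs pseudo individual-patient data from KM steps and
numbers at risk and fits by maximum likelihood (via flexsurv), with
likelihood-based AIC. The two AIC flavours are never mixed in one ranking,
and `select_best_family()` breaks ties by BIC, then by fewer parameters.
Noise-free grids are recovered to 1e-6 relative error; simulated cohorts of
1,000 (2,000-patient fixtures, 20,000 for the tight check) recover the
generating parameters within 10% (3% at the largest size) at fixed seeds —
these sizes are the package's chosen test conditions, balancing statistical
sharpness against suite runtime.

## Numerical and design notes

* Cycle counts use `floor()`; the 10-year horizon is 86 cycles.
* Monetary outputs are rounded to whole dollars only in the reporting
  layer (`cmd_*` functions); internal arithmetic is full precision.
* Beta moment-matching fails loudly (naming the parameter) if the implied
  variance is infeasible for the mean; truncated-Normal sampling resamples
  below-zero draws.
* Degenerate fitting inputs (fewer than 5 points, curves that never fall
  below 0.8, all-ones survival) are rejected with specific errors.
* A terminal KM value of exactly zero is allowed in `km_dataset` (a fully
  observed cohort ends there); transform-based fitting uses the points
  strictly inside (0, 1).
* Re-running any command with the same configuration and seed produces
  byte-identical data files; manifests carry the timestamp instead.

## Limitations

The model inherits every limitation of a two-curve cohort design: no
cause-specific mortality, a reconstructed PFS-exit split in the Markov
engine, and no survival uncertainty in the probabilistic analysis. The
repaired chemotherapy curves are a mechanical fix for inconsistent inputs,
not re-fitted trial data. Treatment-duration rules (chemotherapy cycles,
paid serplulimab cycles) are calibration knobs with defensible but not
uniquely determined defaults. Grade 1-2 and immune-related adverse events,
indirect costs and currency-conversion dynamics are out of scope.
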