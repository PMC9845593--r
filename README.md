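# sclccea

Cost-effectiveness modelling of first-line **serplulimab plus
etoposide/carboplatin (EC)** versus **EC chemotherapy alone** for
extensive-stage small-cell lung cancer (ES-SCLC), from a Chinese payer
perspective. The package is aimed at health-economics analysts who want the
entire analysis — survival extrapolation, cohort trace, costing, sensitivity
and subgroup analyses — as tested, scriptable R functions rather than a
spreadsheet or TreeAge project.

## The model

A three-state cohort model (progression-free survival *PFS*, progressed
disease *PD*, death) runs over a 10-year horizon in 6-week cycles
(86 cycles), discounting costs and effects at 3% per year. Survival for each
arm and endpoint is Weibull,

```
S(t) = exp(-λ t^γ),   λ > 0 (scale), γ > 0 (shape), t in months
```

with per-cycle transition probabilities

```
tp(t, u) = 1 − exp{λ (t−u)^γ − λ t^γ} = 1 − S(t) / S(t−u)
```

for cycle length `u`. The default engine is partitioned survival
(`PFS = S_pfs`, `death = 1 − S_os`, `PD` the remainder); a
transition-probability engine (`markov_tp`) is available and agrees with it
to within 2% on life-years. State occupancy accrues utility-weighted QALYs
(0.673 per PFS-year, 0.473 per PD-year, one-off decrements for grade ≥3
adverse events) and costs (drugs, administration, laboratory, imaging, best
supportive care, topotecan for a small progressed fraction, terminal care).
Strategies are compared by the incremental cost-effectiveness ratio
`ICER = ΔC/ΔE` and net monetary benefit `NMB = WTP·ΔQ − ΔC` at a
willingness-to-pay of $37,653/QALY.

Two of the published chemotherapy Weibull rows are internally inconsistent
(their implied PFS median exceeds the OS median); the loader ships both the
verbatim rows and a *repaired* set chosen by matching implied medians to the
trial medians, and base-case runs use the repaired set. See the methods
vignette (`vignettes/model-methods.Rmd`) for this and every other modelling
convention, including the stage-indexed curve-time mapping the trace engine
uses by default.

## Worked example

```r
library(sclccea)

params <- load_parameters()          # bundled parameter registry
settings <- model_settings()         # 6-week cycles, 10 y, 3%, $37,653/QALY
bc <- run_base_case(params, settings)
bc$table
#>      parameter serplulimab_chemo     chemo
#> 1          LYs             2.080     1.532
#> 2        QALYs             1.187     0.843
#> 3 Total cost $         12584.000  8255.000
#> 4    ICER $/LY          7899.000        NA
#> 5  ICER $/QALY         12588.000        NA
#> 6   WTP $/QALY         37653.000 37653.000
```

The combination arm gains 0.344 QALYs (0.548 LYs) for an extra $4,329,
i.e. about $12,600 per QALY — far below the $37,653/QALY threshold, so the
regimen is cost-effective in the base case. One-way sensitivity shows the
PFS-state utility is the dominant driver:

```r
tor <- run_owsa(params, settings)
head(tor[, c("label", "icer_at_low", "icer_at_high", "spread")], 3)
#>                 label icer_at_low icer_at_high   spread
#> 1         Utility PFS       15114        10786     4327
#> 25    Cost of imaging       11501        13676     2174
#> 3 Cost of serplulimab       11664        13513     1850

psa <- run_psa(params, settings, n_draws = 10000, seed = 1)
psa$summary$p_ce            # probability cost-effective at the threshold
#> [1] 1
```

Commands mirroring these functions (`cmd_base_case()`, `cmd_owsa()`,
`cmd_psa()`, `cmd_subgroup()`, `cmd_make_fixtures()`,
`cmd_validate_params()`) write CSV/JSON outputs with run manifests; a thin
CLI wrapper ships in `inst/cli/sclccea`.

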