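# Model inputs for first-line serplulimab + etoposide/carboplatin (EC) vs EC
# alone in ES-SCLC, Chinese payer perspective. Monetary values in 2022 USD
# (CNY converted at 6.7584); survival times in months.
#
# Each uncertain scalar is given as {value, low, high, dist}; parameters with
# no published range get dist: uniform_fixed and are held at baseline in the
# probabilistic analysis (one-way ranges default to +/-20% of baseline).

settings:
  cycle_length_days: 42        # 6-week Markov cycle
  horizon_years: 10
  annual_discount_rate: 0.03
  wtp_per_qaly: 37653          # 3x 2021 Chinese per-capita GDP, USD/QALY

# Weibull S(t) = exp(-scale * t^shape), t in months since randomization.
survival:
  overall:
    serplulimab_chemo:
      os:  {scale: 0.012874, shape: 1.445565}
      pfs: {scale: 0.14015,  shape: 0.92013}
    chemo:
      os:  {scale: 0.016452, shape: 1.527988}
      pfs: {scale: 0.01472,  shape: 1.56003}
  chinese:
    serplulimab_chemo:
      os:  {scale: 0.009574, shape: 1.535633}
      pfs: {scale: 0.09846,  shape: 1.08898}
    chemo:
      os:  {scale: 0.03359,  shape: 2.07247}
      pfs: {scale: 0.03309,  shape: 2.15174}

# Published median OS/PFS (months) used to audit and, where needed, repair
# the survival rows (two chemotherapy rows are internally inconsistent:
# the repaired set reassigns/recalibrates them by median matching).
reference_medians:
  overall:
    serplulimab_chemo: {os: 15.4, pfs: 5.8}
    chemo:             {os: 10.9, pfs: 4.3}
  chinese:
    serplulimab_chemo: {os: 16.0, pfs: 5.8}
    chemo:             {os: 11.1, pfs: 4.3}

utilities:
  pfs: {value: 0.673, low: 0.538, high: 0.808, dist: beta}   # per year in PFS
  pd:  {value: 0.473, low: 0.378, high: 0.568, dist: beta}   # per year in PD

# One-off decrements for grade >=3 adverse events with incidence > 5%.
disutilities:
  anemia:                    {value: 0.074, low: 0.059, high: 0.089, dist: beta}
  decreased_neutrophil_count: {value: 0.090, low: 0.072, high: 0.108, dist: beta}
  white_blood_cell_decreased: {value: 0.090, low: 0.072, high: 0.108, dist: beta}
  thrombocytopenia:          {value: 0.200, low: 0.160, high: 0.240, dist: beta}

ae_risks:
  chemo:
    anemia:                    {value: 0.054, low: 0.043, high: 0.065, dist: beta}
    thrombocytopenia:          {value: 0.062, low: 0.050, high: 0.074, dist: beta}
    white_blood_cell_decreased: {value: 0.085, low: 0.068, high: 0.102, dist: beta}
    decreased_neutrophil_count: {value: 0.141, low: 0.113, high: 0.169, dist: beta}
  serplulimab_chemo:
    anemia:                    {value: 0.056, low: 0.045, high: 0.067, dist: beta}
    thrombocytopenia:          {value: 0.082, low: 0.066, high: 0.098, dist: beta}
    white_blood_cell_decreased: {value: 0.087, low: 0.070, high: 0.104, dist: beta}
    decreased_neutrophil_count: {value: 0.138, low: 0.110, high: 0.166, dist: beta}

# Fraction of progressed patients receiving topotecan as subsequent therapy;
# the remainder receive best supportive care.
post_discontinuation_topotecan:
  chemo:             {value: 0.049, low: 0.039, high: 0.059, dist: beta}
  serplulimab_chemo: {value: 0.041, low: 0.033, high: 0.049, dist: beta}

drug_costs:            # USD per 6-week Markov cycle
  serplulimab: {value: 605, low: 484, high: 726, dist: gamma}
  etoposide:   {value: 12,  low: 10,  high: 14,  dist: gamma}
  carboplatin: {value: 73,  low: 58,  high: 88,  dist: gamma}
  topotecan:   {value: 317, low: 254, high: 380, dist: gamma}

ae_management_cost:    # one-off, USD, arm-level aggregate
  chemo:             {value: 386, low: 309, high: 463, dist: gamma}
  serplulimab_chemo: {value: 309, low: 247, high: 371, dist: gamma}

other_costs:           # USD; per cycle except terminal (per patient)
  administration: {value: 36,   low: 29,   high: 43,   dist: gamma}
  laboratory:     {value: 166,  low: 133,  high: 199,  dist: gamma}
  imaging:        {value: 507,  low: 406,  high: 608,  dist: gamma}
  bsc:            {value: 221,  low: 177,  high: 265,  dist: gamma}
  terminal:       {value: 2221, low: 1777, high: 2665, dist: gamma}

patient:
  age: 61                                                     # years
  weight: {value: 65,   low: 52,   high: 78,   dist: normal}  # kg
  bsa:    {value: 1.72, low: 1.38, high: 2.06, dist: normal}  # m^2
  serum_creatinine: {value: 1, dist: uniform_fixed}           # mg/dL
  target_auc:       {value: 5, dist: uniform_fixed}           # mg/mL/min
  sex: male

treatment:
  # EC drug cost accrues for the first N Markov cycles (4 q3w chemo cycles).
  chemo_treatment_cycles: 2
  # Serplulimab is charged for the first N Markov cycles (six q3w doses;
  # later doses are covered by the manufacturer patient-assistance scheme),
  # within an overall treatment window of serplulimab_max_treatment_years.
  serplulimab_paid_cycles: 3
  serplulimab_max_treatment_years: 2
  # Cycles of topotecan charged per progressed patient; null = uncapped.
  topotecan_max_cycles: null

psa:
  n_draws: 10000
  seed: 20230104
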