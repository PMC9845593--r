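base_trace <- function(arm = "serplulimab_chemo") {
  sv <- params_overall$survival$repaired[[arm]]
  build_trace_partitioned(sv$os, sv$pfs, settings_default)
}

test_that("QALYs reduce to life-years at unit utility and to zero at zero", {
  tr <- base_trace()
  v <- param_values(params_overall)
  v$u_pfs <- 1; v$u_pd <- 1
  v$ae_risks <- lapply(v$ae_risks, function(a) a * 0)
  q <- accrue_qalys(tr, "serplulimab_chemo", params_overall, settings_default,
                    values = v)
  expect_equal(q, accrue_life_years(tr, settings_default)[["ly_total"]],
               tolerance = 1e-9)
  v$u_pfs <- 0; v$u_pd <- 0
  expect_equal(accrue_qalys(tr, "serplulimab_chemo", params_overall,
                            settings_default, values = v), 0)
})

test_that("QALYs never exceed life-years for utilities in [0, 1]", {
  tr <- base_trace("chemo")
  ly <- accrue_life_years(tr, settings_default)[["ly_total"]]
  set.seed(3)
  for (r in 1:20) {
    v <- param_values(params_overall)
    v$u_pfs <- runif(1)
    v$u_pd <- runif(1, max = v$u_pfs)
    q <- accrue_qalys(tr, "chemo", params_overall, settings_default,
                      values = v)
    expect_lte(q, ly + 1e-12)
  }
})

test_that("the adverse-event decrement is the risk-weighted one-off", {
  v <- param_values(params_overall)
  expected <- sum(c(0.056 * 0.074, 0.082 * 0.200, 0.087 * 0.090,
                    0.138 * 0.090)) * 42 / 365.25
  expect_equal(ae_qaly_decrement("serplulimab_chemo", params_overall,
                                 settings_default), expected)
})

test_that("cost breakdown sums to the total and toggles category-exactly", {
  tr <- base_trace()
  res <- accrue_costs(tr, "serplulimab_chemo", params_overall,
                      settings_default)
  expect_equal(sum(res$breakdown), res$total, tolerance = 1e-6)
  expect_true(all(res$breakdown >= 0))
  expect_equal(unname(res$breakdown[["ae"]]), 309)

  v <- param_values(params_overall)
  v$other_costs[["imaging"]] <- 0
  res0 <- accrue_costs(tr, "serplulimab_chemo", params_overall,
                       settings_default, values = v)
  expect_equal(res$total - res0$total, unname(res$breakdown[["imaging"]]),
               tolerance = 1e-9)

  tr_c <- base_trace("chemo")
  res_c <- accrue_costs(tr_c, "chemo", params_overall, settings_default)
  expect_equal(unname(res_c$breakdown[["ae"]]), 386)   # cycle-0 one-off
  expect_lt(res_c$breakdown[["drugs"]], 200)  # EC only, two charged cycles
  expect_error(accrue_costs(tr, "neither", params_overall, settings_default),
               "arm")
})

test_that("a zero discount rate makes discounting a no-op", {
  s0 <- model_settings(annual_discount_rate = 0)
  sv <- params_overall$survival$repaired$chemo
  tr <- build_trace_partitioned(sv$os, sv$pfs, s0)
  expect_equal(accrue_life_years(tr, s0, TRUE),
               accrue_life_years(tr, s0, FALSE))
  expect_equal(accrue_costs(tr, "chemo", params_overall, s0, discount = TRUE),
               accrue_costs(tr, "chemo", params_overall, s0,
                            discount = FALSE))
})

test_that("pairwise comparison reproduces ICERs by pure division", {
  int <- list(total_cost = 11202, total_qaly = 1.217, total_ly = 2.243)
  comp <- list(total_cost = 7194, total_qaly = 0.885, total_ly = 1.661)
  ce <- compare(int, comp, wtp = 37653)
  expect_equal(ce$delta_cost, 4008)
  expect_equal(ce$delta_qaly, 0.332)
  expect_equal(ce$delta_ly, 0.582)
  expect_equal(ce$icer_per_qaly, 4008 / 0.332)
  expect_equal(ce$icer_per_ly, 4008 / 0.582)
  expect_equal(ce$nmb, 37653 * 0.332 - 4008)
  expect_identical(ce$dominance, "none")
})

test_that("degenerate and dominant comparisons are encoded explicitly", {
  a <- list(total_cost = 1000, total_qaly = 1, total_ly = 1.5)
  same <- compare(a, a)
  expect_equal(same$delta_cost, 0)
  expect_equal(same$nmb, 0)
  expect_true(is.na(same$icer_per_qaly))

  dom <- compare(list(total_cost = 900, total_qaly = 1.2, total_ly = 1.6), a)
  expect_identical(dom$dominance, "intervention_dominant")
  dominated <- compare(list(total_cost = 1100, total_qaly = 0.8,
                            total_ly = 1.4), a)
  expect_identical(dominated$dominance, "intervention_dominated")
})

test_that("Calvert carboplatin dosing matches hand arithmetic", {
  expect_equal(carboplatin_dose(61, 65, 1, 5, "male"),
               5 * ((140 - 61) * 65 / 72 + 25))
  expect_equal(carboplatin_dose(61, 65, 1, 0), 0)
  expect_equal(carboplatin_dose(61, 65, 1, 5, "female"),
               5 * (0.85 * (140 - 61) * 65 / 72 + 25))
  expect_error(carboplatin_dose(-1, 65), "positive")
})
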