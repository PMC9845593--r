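test_that("the sampling registry is complete, ordered and survival-free", {
  reg <- psa_registry(params_overall)
  expect_equal(nrow(reg), 29)
  expect_identical(reg$name[1:2], c("utility.pfs", "utility.pd"))
  expect_false(any(grepl("scale|shape", reg$name)))
  expect_true(all(reg$family %in% c("beta", "gamma", "normal")))
})

test_that("per-parameter streams are reproducible and support-respecting", {
  d1 <- sample_psa(params_overall, 500, seed = 9)
  d2 <- sample_psa(params_overall, 500, seed = 9)
  expect_identical(d1, d2)
  reg <- psa_registry(params_overall)
  for (k in seq_len(nrow(reg))) {
    x <- d1[, reg$name[k]]
    if (reg$family[k] == "beta") expect_true(all(x > 0 & x < 1))
    if (reg$family[k] == "gamma") expect_true(all(x >= 0))
    if (reg$family[k] == "normal") expect_true(all(x >= 0))
    expect_equal(mean(x), reg$mean[k], tolerance = 0.1)
  }
  expect_error(sample_parameter("beta", 0.5, 0, 3, 10, name = "p"),
               "infeasible.*'p'")
})

test_that("degenerate distributions collapse the PSA onto the base case", {
  ps <- load_parameters(collapse_config())
  psa <- run_psa(ps, settings_default, n_draws = 8, seed = 4)
  bc <- run_base_case(ps, settings_default)
  expect_equal(unique(psa$draws$cost_intervention),
               bc$intervention$total_cost, tolerance = 1e-9)
  expect_equal(unique(psa$draws$qaly_intervention),
               bc$intervention$total_qaly, tolerance = 1e-9)
  expect_equal(unique(psa$draws$cost_comparator), bc$comparator$total_cost,
               tolerance = 1e-9)
  expect_equal(unique(psa$draws$qaly_comparator), bc$comparator$total_qaly,
               tolerance = 1e-9)
  expect_identical(psa$summary$p_ce, as.numeric(bc$comparison$nmb > 0))
})

test_that("the same seed reproduces the PSA bit-for-bit", {
  p1 <- run_psa(params_overall, settings_default, n_draws = 300, seed = 21)
  p2 <- run_psa(params_overall, settings_default, n_draws = 300, seed = 21)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
})

test_that("P(cost-effective) is stable across seeds", {
  p1 <- run_psa(params_overall, settings_default, n_draws = 2000, seed = 1)
  p2 <- run_psa(params_overall, settings_default, n_draws = 2000, seed = 2)
  expect_lt(abs(p1$summary$p_ce - p2$summary$p_ce), 0.015)
})

test_that("the acceptability curve is consistent, monotone and limiting", {
  psa <- run_psa(params_overall, settings_default, n_draws = 1000, seed = 5)
  cv <- ceac(psa, wtp_grid = c(seq(0, 80000, 1000),
              settings_default$wtp_per_qaly))
  cv <- cv[order(cv$wtp), ]
  expect_equal(cv$p_ce[cv$wtp == settings_default$wtp_per_qaly],
               psa$summary$p_ce)
  expect_equal(cv$p_ce[cv$wtp == 0], mean(psa$draws$delta_cost < 0))
  if (all(psa$draws$delta_qaly > 0)) expect_true(all(diff(cv$p_ce) >= 0))
  expect_equal(max(cv$p_ce), mean(psa$draws$delta_qaly > 0),
               tolerance = 0.01)
  expect_error(ceac(psa, numeric(0)), "grid")
})

test_that("one-way analysis ranks drivers and moves in the right direction", {
  tor <- run_owsa(params_overall, settings_default)
  expect_identical(tor$parameter[1], "utility.pfs")   # largest spread
  u <- tor[tor$parameter == "utility.pfs", ]
  expect_gt(u$icer_at_low, u$base_icer)
  expect_lt(u$icer_at_high, u$base_icer)
  expect_false(any(tor$infeasible))
  # inert physiology rows perturb nothing in per-cycle costing mode
  expect_equal(tor[tor$parameter == "patient.weight", "spread"], 0)
})

test_that("cost parameters move the ICER linearly", {
  tor <- run_owsa(params_overall, settings_default)
  row <- tor[tor$parameter == "drug_cost.serplulimab", ]
  slope_lo <- (row$base_icer - row$icer_at_low) / (605 - row$low_input)
  slope_hi <- (row$icer_at_high - row$base_icer) / (row$high_input - 605)
  expect_equal(slope_lo, slope_hi, tolerance = 1e-9)

  ps <- load_parameters(collapse_config())
  tor0 <- run_owsa(ps, settings_default)
  expect_equal(tor0[tor0$parameter == "utility.pfs", "spread"], 0)
})
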