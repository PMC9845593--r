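test_that("Weibull survival function behaves as S(t) = exp(-scale t^shape)", {
  w <- weibull_params(0.012874, 1.445565)
  expect_identical(weibull_survival(0, w), 1)
  expect_equal(weibull_survival(1, weibull_params(log(2), 1)), 0.5)
  expect_error(weibull_survival(-1, w), "t must be")

  # cross-check against numerical integration of the hazard
  h <- function(t) w$scale * w$shape * t^(w$shape - 1)
  s12 <- exp(-stats::integrate(h, 0, 12, rel.tol = 1e-12)$value)
  expect_equal(weibull_survival(12, w), s12, tolerance = 1e-10)
  expect_gt(weibull_survival(12, w), 0)
  expect_lt(weibull_survival(12, w), 1)
})

test_that("cycle transition probability is the survival ratio identity", {
  u <- 42 / 30.4375
  for (w in shipped_curves()) {
    i <- 1:86
    # the ratio oracle needs S(t) well inside double range; drop cycles
    # where the Chinese curves have underflowed to ~0
    ok <- weibull_survival(i * u, w) > 1e-280
    tp <- cycle_transition_prob(i[ok], w, u)
    ratio <- 1 - weibull_survival(i[ok] * u, w) /
      weibull_survival((i[ok] - 1) * u, w)
    expect_equal(tp, ratio, tolerance = 1e-12)
    expect_true(all(tp >= 0 & tp < 1))
  }
  expect_error(cycle_transition_prob(0, weibull_params(0.1, 1), 1),
               "cycle_index")
})

test_that("transition probability monotonicity follows the shape parameter", {
  i <- 1:86
  tp_inc <- cycle_transition_prob(i, weibull_params(0.01, 1.5), 1.38)
  expect_true(all(diff(tp_inc) > 0))
  tp_dec <- cycle_transition_prob(i, weibull_params(0.1, 0.8), 1.38)
  expect_true(all(diff(tp_dec) < 0))
  tp_const <- cycle_transition_prob(i, weibull_params(0.05, 1), 1.38)
  expect_equal(diff(tp_const), rep(0, 85), tolerance = 1e-15)
  expect_equal(tp_const[1], 1 - exp(-0.05 * 1.38))
})

test_that("closed-form median agrees with root finding", {
  expect_equal(weibull_median(weibull_params(log(2), 1)), 1)
  for (w in shipped_curves()) {
    med <- weibull_median(w)
    root <- uniroot(function(t) weibull_survival(t, w) - 0.5,
                    c(1e-6, 1e3), tol = 1e-12)$root
    expect_equal(med, root, tolerance = 1e-9)
  }
  # Chinese serplulimab OS median is close to the published 16.0 months
  expect_equal(weibull_median(weibull_params(0.009574, 1.535633)), 16,
               tolerance = 0.03)
})

test_that("hazard ratios rescale the curve as S^hr with shape preserved", {
  w <- weibull_params(0.016452, 1.527988)
  expect_identical(apply_hazard_ratio(w, 1)$scale, w$scale)
  w2 <- apply_hazard_ratio(w, 0.63)
  expect_identical(w2$shape, w$shape)
  tt <- seq(0.5, 60, by = 0.5)
  expect_equal(weibull_survival(tt, w2), weibull_survival(tt, w)^0.63,
               tolerance = 1e-12)
  expect_equal(weibull_median(w2) / weibull_median(w), 0.63^(-1 / w$shape),
               tolerance = 1e-12)
  expect_error(apply_hazard_ratio(w, 0), "hr")
  expect_error(apply_hazard_ratio(w, -1), "hr")
})

test_that("noise-free Kaplan-Meier grids are recovered exactly", {
  km <- exact_km(0.05, 1.3)
  fit <- fit_parametric(km, "weibull")
  expect_equal(unname(fit$curve$params[["scale"]]), 0.05, tolerance = 1e-6)
  expect_equal(unname(fit$curve$params[["shape"]]), 1.3, tolerance = 1e-6)

  best <- select_best_family(km)
  expect_identical(best$curve$family, "weibull")

  km_exp <- km_dataset(seq(1, 30, 1.5), exp(-0.08 * seq(1, 30, 1.5)))
  best_exp <- select_best_family(km_exp)
  if (best_exp$curve$family == "weibull") {
    expect_equal(unname(best_exp$curve$params[["shape"]]), 1,
                 tolerance = 1e-4)
  } else {
    expect_identical(best_exp$curve$family, "exponential")
  }
})

test_that("degenerate or too-sparse curves are rejected", {
  flat <- km_dataset(1:6, rep(1, 6))
  expect_error(fit_parametric(flat, "weibull"), "0.8|degenerate")
  short <- km_dataset(1:3, c(0.9, 0.5, 0.2))
  expect_error(fit_parametric(short, "weibull"), "5")
})

test_that("pseudo-IPD maximum likelihood recovers simulated parameters", {
  w <- weibull_params(0.0165, 1.528)
  cutoff <- 16.6                     # ~30% administratively censored
  cohort <- simulate_cohort(w, n = 400, cutoff = cutoff, seed = 11)
  expect_gt(mean(cohort$status == 0), 0.2)
  km <- km_from_cohort(cohort, grid = seq(1, 16, by = 1))
  fit <- fit_parametric(km, "weibull", method = "mle")
  expect_equal(unname(fit$curve$params[["scale"]]), w$scale, tolerance = 0.1)
  expect_equal(unname(fit$curve$params[["shape"]]), w$shape, tolerance = 0.1)
  fit_exp <- fit_parametric(km, "exponential", method = "mle")
  expect_lte(fit$stats$aic, fit_exp$stats$aic)
})

test_that("information criteria pick the generating family", {
  wins <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    tvals <- exp(stats::rnorm(2000, mean = 2.2, sd = 0.6))
    sf <- survival::survfit(survival::Surv(tvals, rep(1, 2000)) ~ 1)
    grid <- seq(1, 60, by = 2)      # both tails: where the families differ
    sm <- summary(sf, times = grid, extend = TRUE)
    keep <- !is.na(sm$surv)
    km <- km_dataset(sm$time[keep], pmin(sm$surv[keep], 1))
    best <- select_best_family(km)
    if (best$curve$family == "lognormal") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
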