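test_that("bundled config loads with the published survival rows", {
  os <- params_overall$survival$verbatim$serplulimab_chemo$os
  expect_identical(os$scale, 0.012874)
  expect_identical(os$shape, 1.445565)
  os_cn <- params_chinese$survival$verbatim$serplulimab_chemo$os
  expect_identical(os_cn$scale, 0.009574)
  expect_identical(os_cn$shape, 1.535633)
  expect_identical(params_overall$utilities$pfs$mean, 0.673)
  expect_equal(params_overall$other_costs$terminal$mean, 2221)
})

test_that("loader reports malformed files and violated invariants by name", {
  expect_error(load_parameters(tempfile()), "not found")

  bad <- tempfile(fileext = ".yaml")
  writeLines(c("settings:", "  cycle_length_days: [unclosed"), bad)
  expect_error(load_parameters(bad), "parse")

  cfg <- yaml::read_yaml(default_config_path())
  cfg$utilities <- NULL
  incomplete <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, incomplete)
  expect_error(load_parameters(incomplete), "utilities")

  cfg <- yaml::read_yaml(default_config_path())
  cfg$utilities$pd$value <- 0.9           # above the PFS utility
  cfg$utilities$pd$high <- 0.95
  swapped <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, swapped)
  expect_error(load_parameters(swapped), "utilities.pd")
})

test_that("one-way ranges come from the table, else +/-20% of baseline", {
  expect_equal(owsa_range(params_overall$utilities$pfs), c(0.538, 0.808))
  expect_equal(owsa_range(params_overall$drug_costs$serplulimab), c(484, 726))
  expect_equal(owsa_range(dist_spec("gamma", 100)), c(80, 120))
  expect_equal(owsa_range(dist_spec("gamma", 0)), c(0, 0))
})

test_that("write-then-load round-trips every value bit-exactly", {
  f <- tempfile(fileext = ".yaml")
  write_parameters(params_overall, f)
  back <- load_parameters(f, population = "overall")
  expect_identical(param_values(back), param_values(params_overall))
  expect_identical(back$survival$verbatim, params_overall$survival$verbatim)
  expect_identical(back$survival$repaired, params_overall$survival$repaired)

  fj <- tempfile(fileext = ".json")
  write_parameters(params_overall, fj, format = "json")
  expect_true(file.exists(fj))
})

test_that("consistency audit flags the impossible chemotherapy rows", {
  rep_overall <- validate_survival_consistency(params_overall)
  chemo <- rep_overall[rep_overall$arm == "chemo", ]
  expect_true(any(chemo$flag_median))          # PFS median ~11.8 vs 4.3
  expect_true(all(chemo$flag_ordering))        # PFS median > OS median
  serp <- rep_overall[rep_overall$arm == "serplulimab_chemo", ]
  expect_false(any(serp$flag_median))

  rep_cn <- validate_survival_consistency(params_chinese)
  expect_true(rep_cn[rep_cn$arm == "chemo" & rep_cn$endpoint == "os",
                     "flag_median"])           # OS median ~4.3 vs 11.1

  # medians set to exactly the implied values -> nothing flagged
  curves <- params_overall$survival$verbatim
  self <- lapply(curves, function(a) lapply(a, weibull_median))
  rep_self <- validate_survival_consistency(params_overall,
                                            trial_medians = self)
  expect_false(any(rep_self$flag_median))
})

test_that("repair reassigns or recalibrates only the inconsistent rows", {
  log_ov <- params_overall$survival$repair_log
  expect_identical(log_ov$action[log_ov$arm == "serplulimab_chemo"],
                   c("verbatim", "verbatim"))
  pfs_row <- log_ov[log_ov$arm == "chemo" & log_ov$endpoint == "pfs", ]
  expect_identical(pfs_row$action, "recalibrated")
  expect_equal(pfs_row$scale, log(2) / 4.3^1.56003)
  expect_equal(weibull_median(params_overall$survival$repaired$chemo$pfs),
               4.3, tolerance = 1e-12)

  log_cn <- params_chinese$survival$repair_log
  # the published Chinese chemo OS row is a PFS-like curve: it is assigned
  # to the PFS slot and the OS scale is recalibrated to the trial median
  expect_identical(log_cn[log_cn$arm == "chemo" & log_cn$endpoint == "pfs",
                          "action"], "reassigned")
  expect_equal(params_chinese$survival$repaired$chemo$pfs$scale, 0.03359)
  expect_identical(log_cn[log_cn$arm == "chemo" & log_cn$endpoint == "os",
                          "action"], "recalibrated")
  expect_equal(weibull_median(params_chinese$survival$repaired$chemo$os),
               11.1, tolerance = 1e-12)
})
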