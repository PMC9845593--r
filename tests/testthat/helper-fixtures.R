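# Shared fixtures: parameter sets are loaded once per test run.
params_overall <- load_parameters(population = "overall")
params_chinese <- load_parameters(population = "chinese")
settings_default <- model_settings()

shipped_curves <- function() {
  out <- list()
  for (ps in list(params_overall, params_chinese))
    for (set in c("verbatim", "repaired"))
      for (a in names(ps$survival[[set]]))
        for (ep in c("os", "pfs"))
          out[[paste(ps$population, set, a, ep)]] <-
            ps$survival[[set]][[a]][[ep]]
  out
}

# Rewrite the bundled config with every published range collapsed onto the
# baseline value, so all sampling distributions are degenerate.
collapse_config <- function(path = tempfile(fileext = ".yaml")) {
  cfg <- yaml::read_yaml(default_config_path())
  collapse <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$value) && !is.null(x$dist)) {
        x$low <- x$value; x$high <- x$value
        x
      } else lapply(x, collapse)
    } else x
  }
  cfg <- collapse(cfg)
  yaml::write_yaml(cfg, path, precision = 15)
  path
}

# Noise-free Kaplan-Meier grid evaluated exactly from a Weibull curve.
exact_km <- function(scale, shape, times = seq(1, 30, by = 1.5)) {
  km_dataset(times, exp(-scale * times^shape))
}
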