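# Shared fixtures, all generated in code.

# Standard confounder set used in the synthetic study.
conf_vars <- c("sex", "married", "education", "smoking",
               "passive_smoking", "life_events", "vitamin_d")

study_model_spec <- function(age_powers = 1) {
  pbam_model_spec("alcohol", conf_vars, age_var = "age",
                  age_powers = age_powers)
}

# Small but well-behaved synthetic case-control study (~350 cases,
# ~1050 controls): outcome made less rare than the default so that a
# modest base population suffices.
quick_config <- function(n_population = 5e4) {
  sim_config(n_population = n_population,
             outcome_model = c(intercept = -6.0, alcohol = log(2),
                               sex = 0.95, passive_smoking = 0.60,
                               vitamin_d = -1.12, education = 0.035,
                               age = -0.010),
             sf_control = 1057 / n_population)
}

quick_study <- function(seed = 42, n_population = 5e4) {
  simulate_study(quick_config(n_population), seed = seed)
}

# Case-control rows generated directly from a simple logistic model;
# handy for conventional-analysis and outcome-model checks.
logistic_toy_data <- function(n = 5000, beta_x = log(2), beta_z = 0.5,
                              intercept = -1, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  x <- stats::rbinom(n, 1, 0.3)
  y <- stats::rbinom(n, 1, stats::plogis(intercept + beta_x * x +
                                           beta_z * z))
  data.frame(case = y, exposure = x, z = z)
}

# The parameter-recovery experiment shared by several acceptance checks:
# default study conditions (5e5 base, true marginal RR ~2, reporting
# accuracy Se 0.79 / Sp 0.84), triangular priors centered at the truth,
# 20 bootstrap x 100 iterations, ten seeds. Computed once per test run.
recovery_cache <- new.env(parent = emptyenv())

recovery_experiment <- function() {
  if (!is.null(recovery_cache$res)) {
    return(recovery_cache$res)
  }
  pr <- alcohol_accuracy_priors("triangular")
  spec <- study_model_spec()
  res <- t(vapply(1:10, function(s) {
    study <- simulate_study(sim_config(), seed = 1000 + s)
    draws <- bootstrap_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                            n_boot = 20, n_iter = 100, seed = s)
    conv <- conventional_analysis(study$data, spec, study$sf, n_boot = 0)
    rr <- summarize_draws(draws, "rr")
    pafs <- summarize_draws(draws, "paf")
    oracle <- attr(study, "oracle")
    c(rr_med = rr$point, rr_lo = rr$lower, rr_hi = rr$upper,
      paf_med = pafs$point, conv_rr = conv$risks$rr,
      rr_true = oracle$rr_true, paf_true = oracle$paf_true)
  }, numeric(7)))
  recovery_cache$res <- res
  res
}
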