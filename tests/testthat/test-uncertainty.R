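test_that("the Monte Carlo loop returns exactly the requested draws", {
  study <- quick_study(seed = 51)
  pr <- alcohol_accuracy_priors("triangular")
  spec <- study_model_spec()
  d <- run_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                n_iter = 25, seed = 3)
  expect_identical(nrow(d), 25L)
  expect_true(all(is.finite(d$rr) & d$rr > 0))
  expect_true(all(d$risk_unexposed > 0 & d$risk_unexposed < 1))
  expect_true(all(d$bootstrap_index == 0))
  expect_equal(d$paf, (d$observed_risk - d$risk_unexposed) /
                 d$observed_risk, tolerance = 1e-12)
})

test_that("bootstrap pooling yields n_boot x n_iter reproducible draws", {
  study <- quick_study(seed = 52)
  pr <- alcohol_accuracy_priors("beta")
  spec <- study_model_spec()
  d1 <- bootstrap_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                       n_boot = 4, n_iter = 10, seed = 9)
  expect_identical(nrow(d1), 40L)
  expect_identical(sort(unique(d1$bootstrap_index)), as.numeric(1:4))
  d2 <- bootstrap_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                       n_boot = 4, n_iter = 10, seed = 9)
  expect_identical(d1, d2)
})

test_that("draw summaries are empirical percentiles", {
  d <- structure(data.frame(rr = rep(2.5, 10)), class = c("pbam_draws",
                                                          "data.frame"))
  s <- summarize_draws(d, "rr")
  expect_equal(c(s$point, s$lower, s$upper), rep(2.5, 3))

  d <- structure(data.frame(rr = c(1, 2, 3)), class = c("pbam_draws",
                                                        "data.frame"))
  expect_equal(summarize_draws(d, "rr")$point, 2)

  set.seed(33)
  d <- structure(data.frame(rr = rnorm(1e5)), class = c("pbam_draws",
                                                        "data.frame"))
  s <- summarize_draws(d, "rr")
  expect_lt(abs(s$lower - qnorm(0.025)), 0.02)
  expect_lt(abs(s$upper - qnorm(0.975)), 0.02)

  expect_error(summarize_draws(structure(data.frame(rr = numeric(0)),
                                         class = c("pbam_draws",
                                                   "data.frame")), "rr"),
               "no draws")

  # per-bootstrap summarization reduces replicates to their medians first
  d <- structure(data.frame(rr = c(1, 1, 5, 5),
                            bootstrap_index = c(1, 1, 2, 2)),
                 class = c("pbam_draws", "data.frame"))
  s <- summarize_draws(d, "rr", method = "per_bootstrap")
  expect_equal(s$point, 3)
  expect_identical(s$n_draws, 2L)
})

test_that("point-mass priors at the truth give narrower intervals than wide priors", {
  study <- quick_study(seed = 53)
  spec <- study_model_spec()
  pm_se <- bias_prior("triangular", list(min = 0.79, max = 0.79, mode = 0.79))
  pm_sp <- bias_prior("triangular", list(min = 0.84, max = 0.84, mode = 0.84))
  wide <- alcohol_accuracy_priors("triangular")
  d_pm <- run_pbam(study$data, pm_se, pm_sp, study$sf, spec,
                   n_iter = 80, seed = 21)
  d_wide <- run_pbam(study$data, wide$sens, wide$spec, study$sf, spec,
                     n_iter = 80, seed = 21)
  w <- function(d) {
    s <- summarize_draws(d, "rr")
    log(s$upper) - log(s$lower)
  }
  expect_lt(w(d_pm), w(d_wide))
})

test_that("bootstrap widens the simulation interval", {
  spec <- study_model_spec()
  pr <- alcohol_accuracy_priors("triangular")
  wider <- vapply(1:6, function(s) {
    study <- quick_study(seed = 600 + s)
    mc <- run_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                   n_iter = 40, seed = s)
    bt <- bootstrap_pbam(study$data, pr$sens, pr$spec, study$sf, spec,
                         n_boot = 5, n_iter = 40, seed = s)
    w <- function(d) {
      x <- summarize_draws(d, "rr")
      log(x$upper) - log(x$lower)
    }
    w(bt) - w(mc)
  }, numeric(1))
  expect_gt(mean(wider), 0)
})

test_that("conventional analysis recovers a known conditional odds ratio", {
  d <- logistic_toy_data(n = 1e4, beta_x = log(2), seed = 61)
  spec <- pbam_model_spec("exposure", "z")
  conv <- conventional_analysis(d, spec, sampling_fractions(1, 1),
                                n_boot = 50, seed = 1)
  expect_lt(abs(log(conv$or) - log(2)), 3 * conv$log_or_se)
  expect_true(conv$rr_ci[1] <= conv$risks$rr &&
                conv$risks$rr <= conv$rr_ci[2])
  expect_true(is.finite(conv$paf$paf))
})

test_that("conventional Wald interval covers a null effect at its nominal rate", {
  covered <- vapply(1:100, function(s) {
    d <- logistic_toy_data(n = 1500, beta_x = 0, seed = 700 + s)
    spec <- pbam_model_spec("exposure", "z")
    conv <- conventional_analysis(d, spec, sampling_fractions(1, 1),
                                  n_boot = 0)
    conv$or_ci[1] <= 1 && 1 <= conv$or_ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / 100))
})

test_that("a constant exposure stops the conventional analysis", {
  d <- logistic_toy_data(n = 100, seed = 62)
  d$exposure <- 1
  expect_error(conventional_analysis(d, pbam_model_spec("exposure", "z"),
                                     sampling_fractions(1, 1), n_boot = 0),
               "constant")
})
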