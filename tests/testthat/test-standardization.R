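# Manually assembled fitted-model objects let the standardization
# arithmetic be checked against hand computation.
manual_model <- function(intercept, coefs, spec) {
  structure(list(intercept = intercept, coefficients = coefs,
                 converged = TRUE, deviance = NA_real_, spec = spec,
                 outcome = "case", n = NA_integer_),
            class = "pbam_logit")
}

test_that("intercept offset is the log sampling-fraction ratio", {
  expect_equal(round(intercept_offset(
    sampling_fractions(0.96, 1057 / 5115679)), 2), 8.44)
  expect_equal(intercept_offset(sampling_fractions(0.3, 0.3)), 0)
  expect_equal(intercept_offset(sampling_fractions(1, exp(-3))), 3,
               tolerance = 1e-12)
  expect_error(sampling_fractions(0, 0.5))
  expect_error(sampling_fractions(0.5, 1.2))
})

test_that("standardized risks match hand-computed expit averages", {
  spec <- pbam_model_spec("exposure", "z")
  m <- manual_model(-2, c(exposure = log(2), z = 1), spec)
  d <- data.frame(case = c(0, 1), exposure = c(0, 1), z = c(0, 1))
  sf <- sampling_fractions(0.5, 0.5)  # equal weights, zero offset
  sr <- standardized_risks(m, d, sf)
  expect_equal(sr$risk_exposed, mean(plogis(c(-2 + log(2),
                                              -2 + log(2) + 1))),
               tolerance = 1e-12)
  expect_equal(sr$risk_unexposed, mean(plogis(c(-2, -1))),
               tolerance = 1e-12)
  expect_equal(c(sr$risk_exposed, sr$risk_unexposed, sr$rr),
               c(0.3185, 0.1941, 1.6409), tolerance = 2e-4)
  expect_equal(sr$rd, sr$risk_exposed - sr$risk_unexposed)
})

test_that("a zero exposure coefficient gives RR 1 and RD 0", {
  spec <- pbam_model_spec("exposure", "z")
  m <- manual_model(-1.2, c(exposure = 0, z = 0.7), spec)
  d <- data.frame(case = rep(c(0, 1), 5), exposure = rbinom(10, 1, 0.5),
                  z = rnorm(10))
  sr <- standardized_risks(m, d, sampling_fractions(0.2, 0.1))
  expect_equal(sr$rr, 1, tolerance = 1e-12)
  expect_equal(sr$rd, 0, tolerance = 1e-12)
})

test_that("a confounder-free model collapses to the closed form", {
  spec <- pbam_model_spec("exposure", character(0))
  m <- manual_model(-1.5, c(exposure = 0.8), spec)
  d <- data.frame(case = rep(c(0, 1), 10), exposure = rep(c(0, 1), 10))
  sr <- standardized_risks(m, d, sampling_fractions(0.4, 0.4))
  expect_equal(sr$rr, plogis(-1.5 + 0.8) / plogis(-1.5),
               tolerance = 1e-12)
})

test_that("record averaging equals direct standardization over strata", {
  set.seed(31)
  n <- 200
  d <- data.frame(case = rbinom(n, 1, 0.4),
                  exposure = rbinom(n, 1, 0.3),
                  z1 = rbinom(n, 1, 0.5),
                  z2 = rbinom(n, 1, 0.2))
  sf <- sampling_fractions(0.8, 0.05)
  spec <- pbam_model_spec("exposure", c("z1", "z2"))
  fit <- fit_outcome_model(d, spec)
  sr <- standardized_risks(fit, d, sf)

  # independent route: aggregate the weighted confounder distribution
  # over discrete strata and average stratum-specific model risks
  w <- ifelse(d$case == 1, 1 / sf$sf_case, 1 / sf$sf_control)
  strata <- aggregate(w, by = list(z1 = d$z1, z2 = d$z2), FUN = sum)
  strata$p <- strata$x / sum(strata$x)
  b0 <- fit$intercept - log(sf$sf_case / sf$sf_control)
  bx <- fit$coefficients[["exposure"]]
  bz <- fit$coefficients[c("z1", "z2")]
  risk_a <- function(a) {
    sum(strata$p * plogis(b0 + bx * a +
                            as.matrix(strata[, c("z1", "z2")]) %*% bz))
  }
  expect_equal(sr$risk_exposed, risk_a(1), tolerance = 1e-10)
  expect_equal(sr$risk_unexposed, risk_a(0), tolerance = 1e-10)
  expect_equal(sr$rr, risk_a(1) / risk_a(0), tolerance = 1e-10)
})

test_that("jointly rescaling both sampling fractions leaves the estimate invariant", {
  set.seed(32)
  n <- 150
  d <- data.frame(case = rbinom(n, 1, 0.4), exposure = rbinom(n, 1, 0.3),
                  z1 = rnorm(n))
  spec <- pbam_model_spec("exposure", "z1")
  fit <- fit_outcome_model(d, spec)
  sr1 <- standardized_risks(fit, d, sampling_fractions(0.9, 0.02))
  sr2 <- standardized_risks(fit, d, sampling_fractions(0.45, 0.01))
  expect_equal(sr1$rr, sr2$rr, tolerance = 1e-12)
  expect_equal(sr1$risk_exposed, sr2$risk_exposed, tolerance = 1e-12)
})

test_that("non-converged models and degenerate risks are refused", {
  spec <- pbam_model_spec("exposure", character(0))
  m <- manual_model(-1, c(exposure = 1), spec)
  m$converged <- FALSE
  d <- data.frame(case = c(0, 1), exposure = c(0, 1))
  expect_error(standardized_risks(m, d, sampling_fractions(1, 1)),
               "converged")
})

test_that("standardization recovers oracle effects at large n", {
  cfg <- quick_config(n_population = 1e5)
  set.seed(77)
  pop <- generate_population(cfg)
  oracle <- oracle_effects(pop)
  cc <- sample_case_control(pop, sampling_fractions(0.96, 0.25))
  spec <- pbam_model_spec("alcohol_true",
                          c(conf_vars, "age"))
  fit <- fit_outcome_model(cc$data, spec)
  sr <- standardized_risks(fit, cc$data, cc$sf)
  # sampling error of the log RR dominates; 3 x ~0.12 is a generous bound
  expect_lt(abs(log(sr$rr) - log(oracle$rr_true)), 0.4)
  expect_lt(abs(sr$rd - oracle$rd_true), 0.5 * oracle$rd_true + 5e-4)
})
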