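test_that("count correction inverts the misclassification matrix", {
  cc <- correct_counts(group_counts(30, 70), sens_spec(0.8, 0.9))
  expect_equal(cc$A, (30 - 0.1 * 100) / 0.7, tolerance = 1e-12)
  expect_equal(cc$B, 100 - cc$A, tolerance = 1e-12)
  expect_true(cc$valid)
  # forward identity: Se*A + (1-Sp)*B reproduces the reported exposed
  expect_equal(0.8 * cc$A + 0.1 * cc$B, 30, tolerance = 1e-10)

  # perfect classification is the identity
  cc <- correct_counts(group_counts(12, 88), sens_spec(1, 1))
  expect_equal(c(cc$A, cc$B), c(12, 88))

  # inadmissible cell flagged, not an error
  cc <- correct_counts(group_counts(5, 95), sens_spec(0.8, 0.9))
  expect_lt(cc$A, 0)
  expect_false(cc$valid)

  expect_error(correct_counts(group_counts(10, 10), sens_spec(0.4, 0.5)),
               "non-identifiable")
  expect_error(group_counts(0, 0))
})

test_that("count conservation holds exactly over random draws", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(0:500, 1)
    b <- sample(1:500, 1)
    ss <- sens_spec(runif(1, 0.55, 1), runif(1, 0.6, 1))
    cc <- correct_counts(group_counts(a, b), ss)
    expect_equal(cc$A + cc$B, a + b, tolerance = 1e-12)
  }
})

test_that("correction recovers the true exposed count from simulated reporting", {
  set.seed(21)
  n <- 5e4
  true <- rbinom(n, 1, 0.3)
  se <- 0.8; sp <- 0.9
  reported <- ifelse(true == 1, rbinom(n, 1, se), rbinom(n, 1, 1 - sp))
  cc <- correct_counts(group_counts(sum(reported), n - sum(reported)),
                       sens_spec(se, sp))
  # reported-count noise is inflated by 1/(Se+Sp-1) on the corrected scale
  sd_rep <- sqrt(n * mean(reported) * (1 - mean(reported)))
  expect_lt(abs(cc$A - sum(true)), 3 * sd_rep / (se + sp - 1))
})

test_that("predictive values follow Bayes' rule on the corrected table", {
  ss <- sens_spec(0.8, 0.9)
  cc <- correct_counts(group_counts(30, 70), ss)
  pv <- predictive_values(cc, ss)
  expect_equal(pv$ppv, 0.8 * cc$A / (0.8 * cc$A + 0.1 * cc$B),
               tolerance = 1e-12)
  expect_equal(pv$npv, 0.9 * cc$B / (0.9 * cc$B + 0.2 * cc$A),
               tolerance = 1e-12)
  expect_equal(round(c(pv$ppv, pv$npv), 3), c(0.762, 0.918))

  # perfect classification
  pv <- predictive_values(correct_counts(group_counts(40, 60),
                                         sens_spec(1, 1)), sens_spec(1, 1))
  expect_equal(c(pv$ppv, pv$npv), c(1, 1))

  # symmetric table with Se = Sp
  ss <- sens_spec(0.8, 0.8)
  cc <- structure(list(A = 50, B = 50, valid = TRUE),
                  class = "corrected_counts")
  pv <- predictive_values(cc, ss)
  expect_equal(c(pv$ppv, pv$npv), c(0.8, 0.8), tolerance = 1e-12)

  bad <- structure(list(A = -2, B = 102, valid = FALSE),
                   class = "corrected_counts")
  expect_error(predictive_values(bad, ss), "valid")
})

test_that("record-level imputation honors the predictive values", {
  pv1 <- structure(list(ppv = 1, npv = 1), class = "predictive_values")
  d <- data.frame(case = rep(c(1, 0), each = 50),
                  exposure = rep(c(1, 0), 50))
  out <- impute_exposure(d, pv1, pv1)
  expect_identical(out$exposure_imputed, as.integer(d$exposure))

  # ppv = 0 flips every reported-exposed record
  pv0 <- structure(list(ppv = 0, npv = 1), class = "predictive_values")
  out <- impute_exposure(d, pv0, pv0)
  expect_true(all(out$exposure_imputed[d$exposure == 1] == 0L))
  expect_true(all(out$exposure_imputed[d$exposure == 0] == 0L))

  # flipped fraction matches its binomial expectation
  set.seed(3)
  pv <- structure(list(ppv = 0.7, npv = 1), class = "predictive_values")
  d <- data.frame(case = rep(1, 1e4), exposure = rep(1, 1e4))
  out <- impute_exposure(d, pv, pv)
  flipped <- mean(out$exposure_imputed == 0)
  expect_lt(abs(flipped - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))

  d$exposure[1] <- NA
  expect_error(impute_exposure(d, pv, pv), "missing")
})

test_that("imputed table matches the corrected table in expectation", {
  set.seed(9)
  ss <- sens_spec(0.82, 0.88)
  n_case <- 4000; n_ctrl <- 8000
  d <- data.frame(case = rep(c(1, 0), c(n_case, n_ctrl)),
                  exposure = c(rbinom(n_case, 1, 0.35),
                               rbinom(n_ctrl, 1, 0.22)))
  cc_case <- correct_counts(group_counts(sum(d$exposure[d$case == 1]),
                                         n_case - sum(d$exposure[d$case == 1])), ss)
  cc_ctrl <- correct_counts(group_counts(sum(d$exposure[d$case == 0]),
                                         n_ctrl - sum(d$exposure[d$case == 0])), ss)
  out <- impute_exposure(d, predictive_values(cc_case, ss),
                         predictive_values(cc_ctrl, ss))
  imp_case <- sum(out$exposure_imputed[d$case == 1])
  imp_ctrl <- sum(out$exposure_imputed[d$case == 0])
  expect_lt(abs(imp_case - cc_case$A), 3 * sqrt(n_case * 0.35 * 0.65))
  expect_lt(abs(imp_ctrl - cc_ctrl$A), 3 * sqrt(n_ctrl * 0.22 * 0.78))
})
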