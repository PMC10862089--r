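test_that("DerSimonian-Laird pooling matches hand computation", {
  # identical inputs: pooled estimate is the common value, tau^2 = 0
  s <- pool_accuracy(list(accuracy_study(1.0, 0.3),
                          accuracy_study(1.0, 0.02)))
  expect_equal(s$median, plogis(1.0), tolerance = 1e-12)
  expect_equal(attr(s, "tau2"), 0)

  # hand-computed DL: w = 4, 4; Q = 8; C = 4; tau2 = 1.75; pooled = 1
  s <- pool_accuracy(list(accuracy_study(0, 0.25),
                          accuracy_study(2, 0.25)))
  expect_equal(attr(s, "tau2"), 1.75, tolerance = 1e-12)
  expect_equal(attr(s, "logit_pooled"), 1.0, tolerance = 1e-12)
  expect_equal(s$median, plogis(1.0), tolerance = 1e-6)

  # single study: back-transformed estimate and normal-theory limits
  s <- pool_accuracy(list(accuracy_study(1.386, 0.04)))
  expect_equal(s$median, plogis(1.386), tolerance = 1e-12)
  expect_equal(s$q025, plogis(1.386 - qnorm(0.975) * 0.2), tolerance = 1e-12)
  expect_equal(s$q975, plogis(1.386 + qnorm(0.975) * 0.2), tolerance = 1e-12)

  expect_error(pool_accuracy(list()), "at least one")
  expect_error(accuracy_study(1.0, -0.1), "positive")
})

test_that("pooling agrees with an independent meta-analysis routine", {
  skip_if_not_installed("metafor")
  yi <- c(0.2, 0.9, 1.4, 0.6)
  vi <- c(0.05, 0.12, 0.30, 0.08)
  fit <- metafor::rma(yi = yi, vi = vi, method = "DL")
  mine <- pool_accuracy(mapply(accuracy_study, yi, vi, SIMPLIFY = FALSE))
  expect_equal(attr(mine, "logit_pooled"), as.numeric(fit$beta),
               tolerance = 1e-10)
  expect_equal(attr(mine, "tau2"), fit$tau2, tolerance = 1e-10)
  expect_equal(mine$q025, plogis(fit$ci.lb), tolerance = 1e-10)
})

test_that("pooling with tau2 = 0 reduces to the fixed-effect mean", {
  yi <- c(1.00, 1.05)
  vi <- c(0.25, 0.50)  # Q < k - 1, so tau2 truncates to 0
  s <- pool_accuracy(mapply(accuracy_study, yi, vi, SIMPLIFY = FALSE))
  expect_equal(attr(s, "tau2"), 0)
  expect_equal(attr(s, "logit_pooled"),
               sum(yi / vi) / sum(1 / vi), tolerance = 1e-12)
})

test_that("triangular fitting maps the interval onto the support", {
  p <- fit_prior("triangular", quantile_spec(0.79, 0.72, 0.86))
  expect_equal(p$params, list(min = 0.72, max = 0.86, mode = 0.79))
})

test_that("beta fitting reproduces the target quantiles", {
  for (qs in list(quantile_spec(0.79, 0.72, 0.86),
                  quantile_spec(0.84, 0.80, 0.89))) {
    p <- fit_prior("beta", qs)
    q <- prior_quantiles(p)
    expect_lt(max(abs(q - c(qs$q025, qs$median, qs$q975))), 0.015)
  }
  # published reference pair for the sensitivity prior passes the same check
  ref <- bias_prior("beta", list(alpha = 79.79, beta = 20.32))
  expect_lt(max(abs(prior_quantiles(ref) - c(0.72, 0.79, 0.86))), 0.015)
  # symmetric spec gives a symmetric fit
  p <- fit_prior("beta", quantile_spec(0.5, 0.3, 0.7))
  expect_equal(p$params$alpha, p$params$beta, tolerance = 1e-3)
  expect_equal(prior_quantiles(p, 0.5), 0.5, tolerance = 1e-3)
})

test_that("logit-logistic fitting reproduces the target quantiles", {
  for (qs in list(quantile_spec(0.79, 0.72, 0.86),
                  quantile_spec(0.84, 0.80, 0.89))) {
    p <- fit_prior("logit_logistic", qs)
    expect_equal(p$params$location, qlogis(qs$median), tolerance = 1e-12)
    q <- prior_quantiles(p)
    expect_equal(q[2], qs$median, tolerance = 1e-12)
    expect_lt(max(abs(q - c(qs$q025, qs$median, qs$q975))), 0.015)
  }
})

test_that("degenerate quantile specifications are rejected", {
  expect_error(quantile_spec(0.8, 0.8, 0.8))
  expect_error(quantile_spec(0.5, 0.7, 0.9))
  expect_error(quantile_spec(0.5, 0.3, 1.2))
})

test_that("refitting beta and logit-logistic priors to their own implied quantiles is a near-identity", {
  for (kind in c("beta", "logit_logistic")) {
    p1 <- fit_prior(kind, quantile_spec(0.79, 0.72, 0.86))
    p2 <- fit_prior(kind, implied_spec(p1))
    expect_lt(max(abs(prior_quantiles(p2) - prior_quantiles(p1))), 1e-3)
  }
})

test_that("prior draws follow the fitted distribution", {
  # point mass
  pm <- bias_prior("triangular", list(min = 0.8, max = 0.8, mode = 0.8))
  expect_true(all(sample_prior(pm, 100) == 0.8))
  expect_equal(sample_sens_spec(pm, pm), sens_spec(0.8, 0.8))

  # empirical quantiles of 1e5 triangular draws vs the closed form
  tri <- bias_prior("triangular", list(min = 0.72, max = 0.86, mode = 0.79))
  set.seed(11)
  draws <- sample_prior(tri, 1e5)
  emp <- unname(quantile(draws, c(0.025, 0.5, 0.975)))
  expect_lt(max(abs(emp - prior_quantiles(tri))), 0.01)

  # support and determinism across all kinds
  for (kind in c("triangular", "beta", "logit_logistic")) {
    p <- fit_prior(kind, quantile_spec(0.84, 0.80, 0.89))
    set.seed(5)
    d1 <- sample_prior(p, 2000)
    set.seed(5)
    d2 <- sample_prior(p, 2000)
    expect_identical(d1, d2)
    expect_true(all(d1 > 0 & d1 < 1))
  }
})
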