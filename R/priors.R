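#' Quantile specification for a bias parameter
#'
#' Bundles the median and central 95% limits of an exposure-classification
#' accuracy parameter (sensitivity or specificity), typically the pooled
#' estimate and confidence limits from a meta-analysis of validation
#' studies. Prior distributions are fitted to this specification with
#' [fit_prior()].
#'
#' @param median Median (pooled point estimate), strictly between `q025`
#'   and `q975`.
#' @param q025,q975 2.5th and 97.5th percentiles, each in (0, 1).
#' @return An object of class `"quantile_spec"`: a list with elements
#'   `median`, `q025`, `q975`.
#' @examples
#' quantile_spec(0.79, 0.72, 0.86)
#' @export
quantile_spec <- function(median, q025, q975) {
  stopifnot(is.numeric(median), is.numeric(q025), is.numeric(q975),
            length(median) == 1L, length(q025) == 1L, length(q975) == 1L)
  if (!(0 < q025 && q025 < median && median < q975 && q975 < 1)) {
    stop("quantile_spec requires 0 < q025 < median < q975 < 1", call. = FALSE)
  }
  structure(list(median = median, q025 = q025, q975 = q975),
            class = "quantile_spec")
}

#' @export
print.quantile_spec <- function(x, ...) {
  cat(sprintf("quantile spec: %.4g (95%% limits %.4g, %.4g)\n",
              x$median, x$q025, x$q975))
  invisible(x)
}

#' One validation study's accuracy estimate on the logit scale
#'
#' Represents a single study's sensitivity or specificity for the
#' random-effects pooling in [pool_accuracy()]. Supply either the logit
#' estimate and its variance directly, or a probability-scale estimate
#' with 95% confidence limits (converted via the logit transform, the
#' variance taken from the interval width).
#'
#' @param logit_estimate Estimate on the logit scale.
#' @param variance Variance of the logit estimate (> 0).
#' @param estimate,lower,upper Alternative probability-scale input.
#' @return An object of class `"accuracy_study"`.
#' @examples
#' accuracy_study(logit_estimate = 1.386, variance = 0.04)
#' accuracy_study(estimate = 0.8, lower = 0.69, upper = 0.88)
#' @export
accuracy_study <- function(logit_estimate = NULL, variance = NULL,
                           estimate = NULL, lower = NULL, upper = NULL) {
  if (is.null(logit_estimate)) {
    stopifnot(!is.null(estimate), !is.null(lower), !is.null(upper),
              0 < lower, lower < estimate, estimate < upper, upper < 1)
    logit_estimate <- stats::qlogis(estimate)
    variance <- ((stats::qlogis(upper) - stats::qlogis(lower)) /
                   (2 * stats::qnorm(0.975)))^2
  }
  stopifnot(is.numeric(logit_estimate), is.numeric(variance),
            length(logit_estimate) == 1L, length(variance) == 1L)
  if (!is.finite(variance) || variance <= 0) {
    stop("accuracy_study variance must be a positive number", call. = FALSE)
  }
  structure(list(logit_estimate = logit_estimate, variance = variance),
            class = "accuracy_study")
}

#' Pool accuracy estimates across validation studies
#'
#' DerSimonian-Laird random-effects pooling of logit sensitivities (or
#' specificities) from external validation studies. The method-of-moments
#' between-study variance is
#' \eqn{\tau^2 = \max\{0, (Q - (k-1))/C\}} with Cochran's \eqn{Q} and
#' \eqn{C = \sum w_i - \sum w_i^2 / \sum w_i}, inverse-variance weights
#' \eqn{w_i = 1/v_i}. The pooled logit estimate and its normal-theory 95%
#' limits are back-transformed to the probability scale, giving the
#' quantile specification that prior distributions are fitted to. A single
#' study is returned as its own estimate and confidence interval
#' (\eqn{\tau^2 = 0}).
#'
#' @param studies A non-empty list of [accuracy_study()] objects (a single
#'   object is accepted).
#' @return A [quantile_spec()] with attributes `tau2` (between-study
#'   variance on the logit scale) and `logit_pooled`.
#' @examples
#' pool_accuracy(list(
#'   accuracy_study(logit_estimate = 0, variance = 0.25),
#'   accuracy_study(logit_estimate = 2, variance = 0.25)
#' ))
#' @export
pool_accuracy <- function(studies) {
  if (inherits(studies, "accuracy_study")) studies <- list(studies)
  if (!is.list(studies) || length(studies) == 0L) {
    stop("pool_accuracy needs at least one accuracy_study", call. = FALSE)
  }
  studies <- lapply(studies, function(s) {
    if (!inherits(s, "accuracy_study")) {
      s <- accuracy_study(logit_estimate = s[["logit_estimate"]],
                          variance = s[["variance"]])
    }
    s
  })
  yi <- vapply(studies, `[[`, numeric(1), "logit_estimate")
  vi <- vapply(studies, `[[`, numeric(1), "variance")
  if (any(vi <= 0)) stop("study variances must be positive", call. = FALSE)
  k <- length(yi)
  if (k == 1L) {
    tau2 <- 0
    mu <- yi
    se <- sqrt(vi)
  } else {
    wi <- 1 / vi
    ybar <- sum(wi * yi) / sum(wi)
    Q <- sum(wi * (yi - ybar)^2)
    C <- sum(wi) - sum(wi^2) / sum(wi)
    tau2 <- max(0, (Q - (k - 1)) / C)
    ws <- 1 / (vi + tau2)
    mu <- sum(ws * yi) / sum(ws)
    se <- sqrt(1 / sum(ws))
  }
  z <- stats::qnorm(0.975)
  out <- quantile_spec(stats::plogis(mu),
                       stats::plogis(mu - z * se),
                       stats::plogis(mu + z * se))
  attr(out, "tau2") <- tau2
  attr(out, "logit_pooled") <- mu
  out
}

#' Prior distribution for a classification accuracy parameter
#'
#' Constructs a prior for sensitivity or specificity directly from its
#' parameters. Use [fit_prior()] to derive parameters from a quantile
#' specification; the direct constructor exists for externally supplied
#' (e.g. published) parameter values.
#'
#' Supported kinds:
#' \describe{
#'   \item{`triangular`}{`min`, `max`, `mode` with
#'     `min <= mode <= max`; `min == max` gives a point mass.}
#'   \item{`beta`}{shape parameters `alpha`, `beta`, both > 0.}
#'   \item{`logit_logistic`}{`location` and `scale` (> 0) of a logistic
#'     distribution on the logit scale; draws are expit-transformed.}
#' }
#'
#' @param kind One of `"triangular"`, `"beta"`, `"logit_logistic"`.
#' @param params Named list of kind-specific parameters (above).
#' @return An object of class `"bias_prior"`.
#' @examples
#' bias_prior("triangular", list(min = 0.72, max = 0.86, mode = 0.79))
#' bias_prior("beta", list(alpha = 79.79, beta = 20.32))
#' @export
bias_prior <- function(kind = c("triangular", "beta", "logit_logistic"),
                       params) {
  kind <- match.arg(kind)
  params <- as.list(params)
  switch(kind,
    triangular = {
      stopifnot(all(c("min", "max", "mode") %in% names(params)))
      with(params, {
        if (!(min <= mode && mode <= max)) {
          stop("triangular prior requires min <= mode <= max", call. = FALSE)
        }
        if (min < 0 || max > 1) {
          stop("triangular support must lie within [0, 1]", call. = FALSE)
        }
      })
    },
    beta = {
      stopifnot(all(c("alpha", "beta") %in% names(params)))
      if (params$alpha <= 0 || params$beta <= 0) {
        stop("beta prior requires alpha > 0 and beta > 0", call. = FALSE)
      }
    },
    logit_logistic = {
      stopifnot(all(c("location", "scale") %in% names(params)))
      if (params$scale <= 0) {
        stop("logit-logistic prior requires scale > 0", call. = FALSE)
      }
    })
  structure(list(kind = kind, params = params), class = "bias_prior")
}

#' @export
print.bias_prior <- function(x, ...) {
  cat(sprintf("bias prior [%s]: %s\n", x$kind,
              paste(sprintf("%s = %.4g", names(x$params),
                            unlist(x$params)), collapse = ", ")))
  invisible(x)
}

#' Fit a prior distribution to a quantile specification
#'
#' Derives distribution parameters so that the prior reproduces the
#' median and 95% central interval of `spec`:
#' \describe{
#'   \item{triangular}{direct mapping `min = q025`, `max = q975`,
#'     `mode = median` (the conventional parameterization for bias
#'     priors; the interval endpoints become the support, so the
#'     implied 2.5/97.5 percentiles sit slightly inside them).}
#'   \item{beta}{`(alpha, beta)` minimizing the summed squared deviation
#'     of the implied (2.5, 50, 97.5) percentiles from `spec`
#'     (Nelder-Mead on the log-parameter scale, started from moment
#'     matching).}
#'   \item{logit_logistic}{`location = logit(median)`; `scale` is the
#'     average of the two one-sided solutions mapping the 95% logistic
#'     interval on the logit scale onto `(logit(q025), logit(q975))`.}
#' }
#'
#' @param kind One of `"triangular"`, `"beta"`, `"logit_logistic"`.
#' @param spec A [quantile_spec()].
#' @return A [bias_prior()].
#' @examples
#' fit_prior("triangular", quantile_spec(0.79, 0.72, 0.86))
#' fit_prior("beta", quantile_spec(0.84, 0.80, 0.89))
#' @export
fit_prior <- function(kind = c("triangular", "beta", "logit_logistic"),
                      spec) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "quantile_spec"))
  if (spec$q975 - spec$q025 <= .Machine$double.eps) {
    stop("degenerate quantile spec: q025 and q975 coincide", call. = FALSE)
  }
  params <- switch(kind,
    triangular = list(min = spec$q025, max = spec$q975, mode = spec$median),
    beta = .fit_beta_quantiles(spec),
    logit_logistic = .fit_logit_logistic(spec))
  bias_prior(kind, params)
}

.fit_beta_quantiles <- function(spec) {
  target <- c(spec$q025, spec$median, spec$q975)
  m <- spec$median
  v <- ((spec$q975 - spec$q025) / (2 * stats::qnorm(0.975)))^2
  s <- max(m * (1 - m) / v - 1, 2)  # moment-matching start
  obj <- function(lp) {
    q <- stats::qbeta(c(0.025, 0.5, 0.975), exp(lp[1]), exp(lp[2]))
    sum((q - target)^2)
  }
  opt <- stats::optim(log(c(m * s, (1 - m) * s)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(alpha = exp(opt$par[1]), beta = exp(opt$par[2]))
}

.fit_logit_logistic <- function(spec) {
  loc <- stats::qlogis(spec$median)
  # qlogis(0.975) = log(39): half-width of the central 95% logistic interval
  hw <- stats::qlogis(0.975)
  s_lo <- (loc - stats::qlogis(spec$q025)) / hw
  s_hi <- (stats::qlogis(spec$q975) - loc) / hw
  list(location = loc, scale = (s_lo + s_hi) / 2)
}

#' Quantiles implied by a bias prior
#'
#' @param prior A [bias_prior()].
#' @param p Vector of probabilities.
#' @return Numeric vector of quantiles on the probability scale.
#' @export
prior_quantiles <- function(prior, p = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(prior, "bias_prior"), all(p >= 0 & p <= 1))
  with(prior$params, switch(prior$kind,
    triangular = .qtriangular(p, min, max, mode),
    beta = stats::qbeta(p, alpha, beta),
    logit_logistic = stats::plogis(location + scale * stats::qlogis(p))))
}

#' Quantile specification implied by a fitted prior
#'
#' The (2.5, 50, 97.5) percentiles of `prior` repackaged as a
#' [quantile_spec()]; refitting a prior to its own implied specification
#' should be a near-identity.
#'
#' @param prior A [bias_prior()].
#' @return A [quantile_spec()].
#' @export
implied_spec <- function(prior) {
  q <- prior_quantiles(prior, c(0.025, 0.5, 0.975))
  quantile_spec(q[2], q[1], q[3])
}

.qtriangular <- function(p, min, max, mode) {
  if (max == min) return(rep(mode, length(p)))
  fc <- (mode - min) / (max - min)
  ifelse(p < fc,
         min + sqrt(p * (max - min) * (mode - min)),
         max - sqrt((1 - p) * (max - min) * (max - mode)))
}

#' Draw values from a bias prior
#'
#' Inverse-CDF sampling for the triangular and logit-logistic kinds,
#' `rbeta` for the beta kind. Draws consume the current R random stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param prior A [bias_prior()].
#' @param n Number of draws.
#' @return Numeric vector in (0, 1) (boundary values of a degenerate
#'   triangular prior are returned as-is).
#' @export
sample_prior <- function(prior, n = 1L) {
  stopifnot(inherits(prior, "bias_prior"), n >= 1)
  with(prior$params, switch(prior$kind,
    triangular = .qtriangular(stats::runif(n), min, max, mode),
    beta = stats::rbeta(n, alpha, beta),
    logit_logistic = stats::plogis(location + scale *
                                     stats::qlogis(stats::runif(n)))))
}

#' Sensitivity/specificity pair
#'
#' One draw (or fixed value) of the exposure-classification accuracy
#' applied non-differentially to cases and controls.
#'
#' @param sensitivity,specificity Probabilities in (0, 1].
#' @return An object of class `"sens_spec"`.
#' @examples
#' sens_spec(0.79, 0.84)
#' @export
sens_spec <- function(sensitivity, specificity) {
  stopifnot(is.numeric(sensitivity), is.numeric(specificity),
            length(sensitivity) == 1L, length(specificity) == 1L)
  if (sensitivity < 0 || sensitivity > 1 ||
      specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  structure(list(sensitivity = sensitivity, specificity = specificity),
            class = "sens_spec")
}

#' @export
print.sens_spec <- function(x, ...) {
  cat(sprintf("Se = %.4g, Sp = %.4g\n", x$sensitivity, x$specificity))
  invisible(x)
}

#' Draw one sensitivity/specificity pair from its priors
#'
#' One independent draw from each prior. The same pair is applied to the
#' case and the control group within a bias-analysis iteration
#' (non-differential misclassification); redrawing when the implied
#' corrected counts are inadmissible is the caller's responsibility.
#'
#' @param sens_prior,spec_prior [bias_prior()] objects for sensitivity
#'   and specificity.
#' @return A [sens_spec()].
#' @export
sample_sens_spec <- function(sens_prior, spec_prior) {
  sens_spec(sample_prior(sens_prior, 1L), sample_prior(spec_prior, 1L))
}

#' Pooled accuracy priors for self-reported alcohol consumption
#'
#' Convenience constructor for the sensitivity and specificity priors
#' used throughout the worked examples: pooled validation-study accuracy
#' of self-reported alcohol consumption against biomarker gold standards,
#' Se 0.79 (0.72, 0.86) and Sp 0.84 (0.80, 0.89), fitted as the requested
#' distribution kind.
#'
#' @param kind Prior kind passed to [fit_prior()].
#' @return List with elements `sens` and `spec`, each a [bias_prior()],
#'   plus the underlying `sens_spec_q`/`spec_spec_q` quantile specs.
#' @examples
#' alcohol_accuracy_priors("triangular")
#' @export
alcohol_accuracy_priors <- function(kind = c("triangular", "beta",
                                             "logit_logistic")) {
  kind <- match.arg(kind)
  qs_se <- quantile_spec(0.79, 0.72, 0.86)
  qs_sp <- quantile_spec(0.84, 0.80, 0.89)
  list(sens = fit_prior(kind, qs_se),
       spec = fit_prior(kind, qs_sp),
       sens_spec_q = qs_se,
       spec_spec_q = qs_sp)
}
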