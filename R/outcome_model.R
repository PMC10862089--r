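#' Outcome model specification
#'
#' Describes the multivariable logistic model for case/control status:
#' the (imputed) binary exposure, the confounder set, and optional
#' fractional-polynomial (FP) terms for age. FP powers are drawn from the
#' conventional set \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\} with 0 denoting the
#' log transform; a repeated power \eqn{p} is encoded as
#' \eqn{\{x^p, x^p \log x\}}. Age is divided by `age_scale` (default 10)
#' before transformation to keep the powers numerically stable.
#'
#' @param exposure Name of the binary exposure column.
#' @param confounders Character vector of confounder columns
#'   (`age_var` may be included; it is handled through its FP terms).
#' @param age_var Optional column receiving FP treatment.
#' @param age_powers Numeric vector of 0-2 FP powers (default `1`,
#'   i.e. linear age).
#' @param age_scale Positive divisor applied to `age_var`.
#' @return An object of class `"pbam_model_spec"`.
#' @examples
#' pbam_model_spec("alcohol", c("age", "sex", "smoking"), age_var = "age")
#' @export
pbam_model_spec <- function(exposure, confounders, age_var = NULL,
                            age_powers = 1, age_scale = 10) {
  stopifnot(is.character(exposure), length(exposure) == 1L,
            is.character(confounders))
  if (!is.null(age_var)) {
    stopifnot(length(age_var) == 1L, is.numeric(age_powers),
              length(age_powers) >= 1L, length(age_powers) <= 2L,
              age_scale > 0)
    if (!all(age_powers %in% c(-2, -1, -0.5, 0, 0.5, 1, 2, 3))) {
      stop("age powers must come from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}",
           call. = FALSE)
    }
  }
  structure(list(exposure = exposure,
                 confounders = setdiff(confounders, age_var),
                 age_var = age_var,
                 age_powers = if (is.null(age_var)) NULL else sort(age_powers),
                 age_scale = age_scale),
            class = "pbam_model_spec")
}

# FP basis for one positive variable; repeated power p gives x^p and
# x^p * log(x); power 0 is log(x).
.fp_term_matrix <- function(x, powers, var = "age") {
  if (any(x <= 0)) {
    stop("fractional-polynomial variable must be positive after scaling",
         call. = FALSE)
  }
  one <- function(p) if (p == 0) log(x) else x^p
  if (length(powers) == 2L && powers[1] == powers[2]) {
    m <- cbind(one(powers[1]), one(powers[1]) * log(x))
    colnames(m) <- paste0("fp(", var, ",", powers[1], c(")", ").log"))
  } else {
    m <- vapply(powers, one, numeric(length(x)))
    dim(m) <- c(length(x), length(powers))
    colnames(m) <- paste0("fp(", var, ",", powers, ")")
  }
  m
}

# Design matrix: intercept | exposure | confounders | FP(age) terms.
# exposure_values overrides the exposure column (scalar or vector), used
# for imputed draws and for forcing exposure to 0/1 in standardization.
.build_design <- function(data, spec, exposure_values = NULL,
                          exposure_col = NULL) {
  n <- nrow(data)
  if (is.null(exposure_values)) {
    col <- if (is.null(exposure_col)) spec$exposure else exposure_col
    if (!col %in% names(data)) {
      stop(sprintf("exposure column '%s' not found", col), call. = FALSE)
    }
    exposure_values <- data[[col]]
  }
  exposure_values <- rep_len(as.numeric(exposure_values), n)
  parts <- list(`(Intercept)` = rep(1, n), exposure = exposure_values)
  X <- do.call(cbind, parts)
  colnames(X) <- c("(Intercept)", spec$exposure)
  if (length(spec$confounders)) {
    cf <- stats::model.matrix(stats::reformulate(spec$confounders),
                              data)[, -1, drop = FALSE]
    X <- cbind(X, cf)
  }
  if (!is.null(spec$age_var)) {
    xa <- data[[spec$age_var]] / spec$age_scale
    X <- cbind(X, .fp_term_matrix(xa, spec$age_powers, spec$age_var))
  }
  X
}

# Logistic ML fit on a prebuilt design matrix, with separation and
# convergence diagnostics. Rank deficiency is an error. Separation is
# flagged as non-convergence only when it involves the exposure column
# (column 2): an iteration redraw can cure an imputed-exposure
# pathology, but not quasi-separation in a rare confounder of a
# bootstrap resample, whose fit remains usable for standardization.
.fit_logistic <- function(X, y, exposure_col = 2L) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg, fixed = TRUE) ||
          grepl("did not converge", msg, fixed = TRUE)) {
        warned <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (fit$rank < ncol(X) || anyNA(fit$coefficients)) {
    stop("rank-deficient outcome model design matrix", call. = FALSE)
  }
  boundary <- any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8)
  exposure_diverged <- (warned || boundary) &&
    abs(fit$coefficients[exposure_col]) > 10
  list(coefficients = fit$coefficients,
       converged = fit$converged && !exposure_diverged,
       deviance = fit$deviance,
       qr = fit$qr, rank = fit$rank)
}

#' Fit the multivariable logistic outcome model
#'
#' Maximum-likelihood logistic regression of case/control status on the
#' exposure (reported or imputed), the confounders, and the FP age terms
#' of `spec`. The intercept returned is the apparent case-control
#' intercept; [standardized_risks()] corrects it to the population risk
#' scale using the sampling fractions.
#'
#' @param data Data frame without missing values in the model columns.
#' @param spec A [pbam_model_spec()].
#' @param outcome Name of the 0/1 outcome column (1 = case).
#' @param exposure_col Optional name of the column holding the exposure
#'   values to use (defaults to `spec$exposure`; the Monte Carlo loop
#'   passes the imputed column here).
#' @return Object of class `"pbam_logit"`: `intercept`, `coefficients`
#'   (named, intercept excluded), `converged`, `deviance`, `vcov`, `spec`,
#'   `n`.
#' @export
fit_outcome_model <- function(data, spec, outcome = "case",
                              exposure_col = NULL) {
  stopifnot(is.data.frame(data), inherits(spec, "pbam_model_spec"),
            outcome %in% names(data))
  used <- c(outcome, spec$confounders, spec$age_var,
            if (is.null(exposure_col)) spec$exposure else exposure_col)
  if (anyNA(data[used])) {
    stop("missing values in model columns", call. = FALSE)
  }
  X <- .build_design(data, spec, exposure_col = exposure_col)
  y <- as.numeric(data[[outcome]])
  fit <- .fit_logistic(X, y)
  p1 <- seq_len(fit$rank)
  vcov <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(intercept = unname(fit$coefficients[1]),
                 coefficients = fit$coefficients[-1],
                 converged = fit$converged,
                 deviance = fit$deviance,
                 vcov = vcov,
                 spec = spec,
                 outcome = outcome,
                 n = nrow(data)),
            class = "pbam_logit")
}

#' @export
print.pbam_logit <- function(x, ...) {
  cat(sprintf("logistic outcome model (n = %d, deviance = %.2f%s)\n",
              x$n, x$deviance,
              if (x$converged) "" else ", NOT converged"))
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  invisible(x)
}

#' @export
coef.pbam_logit <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Select fractional-polynomial powers for age
#'
#' Royston-Altman closed testing of the age function at level `alpha`,
#' with the exposure and remaining confounders always in the model:
#' the best-fitting FP2 model is compared against the age-free model
#' (chi-square, 4 df), then against linear age (3 df), then against the
#' best FP1 (2 df), using deviance differences. Selection stops at the
#' first non-significant comparison; linear age (`powers = 1`) is
#' returned whenever linearity is not rejected. Age stays in the model
#' regardless, being a confounder of the minimally sufficient adjustment
#' set.
#'
#' Selection is intended to be run once on the observed (pre-imputation)
#' data; the chosen powers are then held fixed across all Monte Carlo
#' iterations so that model-selection noise does not enter the bias
#' distribution.
#'
#' @param data Data frame.
#' @param outcome,exposure Column names.
#' @param confounders Confounders other than age.
#' @param age_var Age column (positive after scaling).
#' @param alpha Significance level of the closed test.
#' @param age_scale Divisor applied to age before the power transforms.
#' @return Object of class `"fp_selection"`: `powers`, the comparison
#'   `table` (deviances, df, p-values), and the candidate model
#'   deviances.
#' @export
select_fp_powers <- function(data, outcome, exposure, confounders,
                             age_var = "age", alpha = 0.05,
                             age_scale = 10) {
  stopifnot(is.data.frame(data), age_var %in% names(data))
  x <- data[[age_var]]
  if (length(unique(x)) <= 1L) {
    stop("age is constant; fractional-polynomial selection undefined",
         call. = FALSE)
  }
  confounders <- setdiff(confounders, age_var)
  y <- as.numeric(data[[outcome]])
  pset <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

  dev_for <- function(powers) {
    spec <- pbam_model_spec(exposure, confounders, age_var = age_var,
                            age_powers = powers, age_scale = age_scale)
    .fit_logistic(.build_design(data, spec), y)$deviance
  }
  spec0 <- pbam_model_spec(exposure, confounders)
  dev_null <- .fit_logistic(.build_design(data, spec0), y)$deviance
  dev_lin <- dev_for(1)

  dev_fp1 <- vapply(pset, dev_for, numeric(1))
  best1 <- pset[which.min(dev_fp1)]

  pairs <- as.matrix(expand.grid(p1 = pset, p2 = pset))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  dev_fp2 <- apply(pairs, 1, dev_for)
  best2 <- pairs[which.min(dev_fp2), ]

  d2 <- min(dev_fp2)
  p_any <- stats::pchisq(dev_null - d2, df = 4, lower.tail = FALSE)
  p_lin <- stats::pchisq(dev_lin - d2, df = 3, lower.tail = FALSE)
  p_fp1 <- stats::pchisq(min(dev_fp1) - d2, df = 2, lower.tail = FALSE)

  powers <- if (p_any >= alpha || p_lin >= alpha) {
    1
  } else if (p_fp1 >= alpha) {
    best1
  } else {
    best2
  }
  structure(list(
    powers = powers,
    table = data.frame(
      comparison = c("FP2 vs no age", "FP2 vs linear", "FP2 vs FP1"),
      deviance_diff = c(dev_null - d2, dev_lin - d2, min(dev_fp1) - d2),
      df = c(4, 3, 2),
      p_value = c(p_any, p_lin, p_fp1)),
    best_fp1 = best1, best_fp2 = best2,
    deviances = c(null = dev_null, linear = dev_lin,
                  fp1 = min(dev_fp1), fp2 = d2),
    alpha = alpha),
    class = "fp_selection")
}

#' @export
print.fp_selection <- function(x, ...) {
  cat("fractional-polynomial closed test (alpha =", x$alpha, ")\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("selected powers:", paste(x$powers, collapse = ", "), "\n")
  invisible(x)
}
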