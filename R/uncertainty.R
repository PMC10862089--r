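#' Monte Carlo probabilistic bias analysis with standardization
#'
#' Runs the bias-analysis loop on one dataset: per iteration a
#' sensitivity/specificity pair is drawn from its priors, reported
#' exposure counts are corrected within cases and within controls
#' (draws implying non-positive corrected cells are discarded and
#' redrawn), group-specific predictive values are derived, record-level
#' exposure is re-imputed, the logistic outcome model is refitted with
#' the imputed exposure (fixed fractional-polynomial powers), and the
#' model is standardized to the study base to give that iteration's
#' marginal RR, RD, and PAF. Non-converged fits are likewise discarded
#' and the iteration redrawn.
#'
#' @param data Case-control records: 0/1 outcome and reported exposure
#'   plus the confounders of `spec`.
#' @param sens_prior,spec_prior [bias_prior()] objects.
#' @param sf A [sampling_fractions()].
#' @param spec A [pbam_model_spec()].
#' @param n_iter Number of valid iterations to return (>= 1).
#' @param seed Optional seed; `NULL` continues the current random stream.
#' @param outcome Outcome column name.
#' @param observed_risk_method `"counts"` (default) computes the
#'   observed risk from reconstructed base counts; `"model"` uses the
#'   weighted mean predicted risk at the imputed exposure.
#' @param max_redraw Cap on discarded draws per iteration before failing.
#' @param bootstrap_index Index recorded in the draws (0 = original
#'   data; set by [bootstrap_pbam()]).
#' @return Data frame of class `"pbam_draws"` with one row per
#'   iteration: `iteration`, `bootstrap_index`, `sensitivity`,
#'   `specificity`, `risk_exposed`, `risk_unexposed`, `rr`, `rd`,
#'   `observed_risk`, `paf`; discard counts in attributes
#'   `"n_discarded_cells"` and `"n_discarded_fits"`.
#' @export
run_pbam <- function(data, sens_prior, spec_prior, sf, spec,
                     n_iter = 1000, seed = NULL, outcome = "case",
                     observed_risk_method = c("counts", "model"),
                     max_redraw = 10000, bootstrap_index = 0L) {
  stopifnot(is.data.frame(data), inherits(sens_prior, "bias_prior"),
            inherits(spec_prior, "bias_prior"),
            inherits(sf, "sampling_fractions"),
            inherits(spec, "pbam_model_spec"), n_iter >= 1)
  observed_risk_method <- match.arg(observed_risk_method)
  if (!is.null(seed)) set.seed(seed)

  y <- as.numeric(data[[outcome]])
  reported <- as.integer(data[[spec$exposure]])
  if (anyNA(reported) || !all(reported %in% c(0L, 1L))) {
    stop("reported exposure must be complete and coded 0/1", call. = FALSE)
  }
  is_case <- y == 1
  n_case <- sum(is_case)
  n_control <- sum(!is_case)
  counts_case <- group_counts(sum(reported[is_case]),
                              n_case - sum(reported[is_case]))
  counts_ctrl <- group_counts(sum(reported[!is_case]),
                              n_control - sum(reported[!is_case]))

  X <- .build_design(data, spec)           # reported exposure in column 2
  exp_col <- spec$exposure
  offset <- intercept_offset(sf)
  w <- ifelse(is_case, 1 / sf$sf_case, 1 / sf$sf_control)
  w <- w / sum(w)
  obs_risk_counts <- observed_risk(n_case, n_control, sf)

  draws <- vector("list", n_iter)
  n_disc_cells <- 0L
  n_disc_fits <- 0L
  for (i in seq_len(n_iter)) {
    attempts <- 0L
    repeat {
      # (Se, Sp) draws are redrawn until both groups' corrected counts
      # are admissible and the resulting fit converges
      ss <- NULL
      repeat {
        cand <- sample_sens_spec(sens_prior, spec_prior)
        if (cand$sensitivity + cand$specificity <= 1) {
          n_disc_cells <- n_disc_cells + 1L
          attempts <- attempts + 1L
        } else {
          cc_case <- correct_counts(counts_case, cand)
          cc_ctrl <- correct_counts(counts_ctrl, cand)
          if (cc_case$valid && cc_ctrl$valid) {
            ss <- cand
            break
          }
          n_disc_cells <- n_disc_cells + 1L
          attempts <- attempts + 1L
        }
        if (attempts >= max_redraw) {
          stop(sprintf(paste0(
            "redraw cap (%d) exceeded: priors repeatedly imply ",
            "non-positive corrected counts near Se = %.3f, Sp = %.3f"),
            max_redraw, cand$sensitivity, cand$specificity), call. = FALSE)
        }
      }
      pv_case <- predictive_values(cc_case, ss)
      pv_ctrl <- predictive_values(cc_ctrl, ss)
      u <- stats::runif(nrow(data))
      imputed <- .impute_vec(reported,
                             ifelse(is_case, pv_case$ppv, pv_ctrl$ppv),
                             ifelse(is_case, pv_case$npv, pv_ctrl$npv), u)
      X[, exp_col] <- imputed
      fit <- .fit_logistic(X, y)
      if (fit$converged) break
      n_disc_fits <- n_disc_fits + 1L
      attempts <- attempts + 1L
      if (attempts >= max_redraw) {
        stop(sprintf("redraw cap (%d) exceeded: outcome model repeatedly fails to converge",
                     max_redraw), call. = FALSE)
      }
    }
    beta <- fit$coefficients
    beta[1] <- beta[1] - offset
    lp_imputed <- drop(X %*% beta)
    X[, exp_col] <- 1
    risk1 <- sum(w * stats::plogis(drop(X %*% beta)))
    X[, exp_col] <- 0
    risk0 <- sum(w * stats::plogis(drop(X %*% beta)))
    X[, exp_col] <- reported
    obs_risk <- if (observed_risk_method == "counts") obs_risk_counts
                else sum(w * stats::plogis(lp_imputed))
    draws[[i]] <- c(iteration = i, bootstrap_index = bootstrap_index,
                    sensitivity = ss$sensitivity,
                    specificity = ss$specificity,
                    risk_exposed = risk1, risk_unexposed = risk0,
                    rr = risk1 / risk0, rd = risk1 - risk0,
                    observed_risk = obs_risk,
                    paf = (obs_risk - risk0) / obs_risk)
  }
  out <- as.data.frame(do.call(rbind, draws))
  attr(out, "n_discarded_cells") <- n_disc_cells
  attr(out, "n_discarded_fits") <- n_disc_fits
  class(out) <- c("pbam_draws", "data.frame")
  out
}

#' Bootstrap the probabilistic bias analysis
#'
#' Nests [run_pbam()] inside a stratified nonparametric bootstrap:
#' cases and controls are resampled with replacement independently,
#' preserving the original group sizes, and the full bias-analysis loop
#' is run on every resample. The pooled `n_boot * n_iter` draws carry
#' both the misclassification/confounding correction and random error.
#'
#' Reproducibility: the master `seed` generates one sub-seed per
#' bootstrap replicate, so the pooled draws are identical on repeat
#' regardless of how replicates are executed.
#'
#' @inheritParams run_pbam
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @return A `"pbam_draws"` data frame of `n_boot * n_iter` rows with
#'   `bootstrap_index` in `1:n_boot`; discard counts summed over
#'   replicates.
#' @export
bootstrap_pbam <- function(data, sens_prior, spec_prior, sf, spec,
                           n_boot = 500, n_iter = 1000, seed = NULL,
                           outcome = "case",
                           observed_risk_method = c("counts", "model"),
                           max_redraw = 10000) {
  stopifnot(n_boot >= 1)
  observed_risk_method <- match.arg(observed_risk_method)
  if (!is.null(seed)) set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  idx_case <- which(data[[outcome]] == 1)
  idx_ctrl <- which(data[[outcome]] == 0)
  if (!length(idx_case) || !length(idx_ctrl)) {
    stop("both cases and controls are required for the stratified bootstrap",
         call. = FALSE)
  }
  pieces <- vector("list", n_boot)
  disc_cells <- 0L
  disc_fits <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    idx <- c(sample(idx_case, length(idx_case), replace = TRUE),
             sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    d <- run_pbam(data[idx, , drop = FALSE], sens_prior, spec_prior, sf,
                  spec, n_iter = n_iter, seed = NULL, outcome = outcome,
                  observed_risk_method = observed_risk_method,
                  max_redraw = max_redraw, bootstrap_index = b)
    disc_cells <- disc_cells + attr(d, "n_discarded_cells")
    disc_fits <- disc_fits + attr(d, "n_discarded_fits")
    pieces[[b]] <- d
  }
  out <- do.call(rbind, lapply(pieces, as.data.frame))
  rownames(out) <- NULL
  attr(out, "n_discarded_cells") <- disc_cells
  attr(out, "n_discarded_fits") <- disc_fits
  class(out) <- c("pbam_draws", "data.frame")
  out
}

#' Summarize Monte Carlo draws into a point estimate and interval
#'
#' Median and central 95% limits (2.5th/97.5th empirical percentiles,
#' linear-interpolation order statistics, `stats::quantile` type 7) of
#' one field of the draws. With `method = "pooled"` (default) all draws
#' enter one distribution - the simulation interval then reflects both
#' bias-parameter uncertainty and, if the draws come from
#' [bootstrap_pbam()], random error. `method = "per_bootstrap"` first
#' reduces each bootstrap replicate to its median and summarizes those.
#'
#' @param draws A `"pbam_draws"` data frame.
#' @param field Column to summarize (e.g. `"rr"`, `"rd"`, `"paf"`).
#' @param method Summary method, see above.
#' @return Object of class `"effect_summary"`: `point`, `lower`,
#'   `upper`, `n_draws`, `n_discarded`.
#' @export
summarize_draws <- function(draws, field = "rr",
                            method = c("pooled", "per_bootstrap")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(draws), field %in% names(draws))
  v <- draws[[field]]
  if (!length(v)) stop("no draws to summarize", call. = FALSE)
  if (method == "per_bootstrap" && "bootstrap_index" %in% names(draws)) {
    v <- tapply(v, draws$bootstrap_index, stats::median)
  }
  q <- unname(stats::quantile(v, c(0.025, 0.5, 0.975), type = 7))
  n_disc <- sum(attr(draws, "n_discarded_cells"),
                attr(draws, "n_discarded_fits"))
  structure(list(point = q[2], lower = q[1], upper = q[3],
                 n_draws = length(v),
                 n_discarded = if (length(n_disc)) n_disc else 0L,
                 field = field, method = method),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %.*g (95%% limits %.*g to %.*g) [%d draws]\n",
              x$field, digits, x$point, digits, x$lower, digits, x$upper,
              x$n_draws))
  invisible(x)
}

#' Conventional (uncorrected) analysis
#'
#' The comparison analysis without misclassification correction: one
#' logistic fit on the reported exposure giving the confounder-adjusted
#' odds ratio with a Wald 95% CI, plus model-based standardization of
#' the same fit (marginal RR, RD) and the conventional PAF. Random-error
#' intervals for RR, RD, and PAF come from a stratified bootstrap
#' (resampling cases and controls separately with the original sizes)
#' using percentile limits.
#'
#' @inheritParams run_pbam
#' @param n_boot Bootstrap resamples for the RR/RD/PAF intervals.
#' @return Object of class `"pbam_conventional"`: `or`, `or_ci`,
#'   `fit`, `risks` (point [standardized_risks()]), `paf` (point
#'   [paf()]), and `boot` (data frame of bootstrap estimates) with
#'   percentile CIs in `rr_ci`, `rd_ci`, `paf_ci`.
#' @export
conventional_analysis <- function(data, spec, sf, n_boot = 500,
                                  seed = NULL, outcome = "case",
                                  observed_risk_method = c("counts",
                                                           "model")) {
  stopifnot(is.data.frame(data), inherits(spec, "pbam_model_spec"),
            inherits(sf, "sampling_fractions"))
  observed_risk_method <- match.arg(observed_risk_method)
  if (!is.null(seed)) set.seed(seed)
  if (length(unique(data[[spec$exposure]])) < 2L) {
    stop("reported exposure is constant; conventional analysis undefined",
         call. = FALSE)
  }
  est <- .conventional_point(data, spec, sf, outcome, observed_risk_method)
  fit <- est$fit
  se <- sqrt(fit$vcov[spec$exposure, spec$exposure])
  z <- stats::qnorm(0.975)
  logor <- fit$coefficients[[spec$exposure]]

  boot <- NULL
  if (n_boot >= 1) {
    idx_case <- which(data[[outcome]] == 1)
    idx_ctrl <- which(data[[outcome]] == 0)
    boot <- matrix(NA_real_, n_boot, 3,
                   dimnames = list(NULL, c("rr", "rd", "paf")))
    b <- 1L
    tries <- 0L
    while (b <= n_boot) {
      idx <- c(sample(idx_case, length(idx_case), replace = TRUE),
               sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
      res <- tryCatch(
        .conventional_point(data[idx, , drop = FALSE], spec, sf, outcome,
                            observed_risk_method),
        error = function(e) NULL)
      tries <- tries + 1L
      if (tries > 20L * n_boot) {
        stop("conventional bootstrap failed to produce enough valid resamples",
             call. = FALSE)
      }
      if (is.null(res) || !res$fit$converged) next
      boot[b, ] <- c(res$risks$rr, res$risks$rd, res$paf$paf)
      b <- b + 1L
    }
    boot <- as.data.frame(boot)
  }
  ci <- function(v) if (is.null(boot)) c(NA_real_, NA_real_) else
    unname(stats::quantile(v, c(0.025, 0.975), type = 7))
  structure(list(or = exp(logor),
                 or_ci = exp(logor + c(-1, 1) * z * se),
                 log_or_se = se,
                 fit = fit, risks = est$risks, paf = est$paf,
                 boot = boot,
                 rr_ci = ci(boot$rr), rd_ci = ci(boot$rd),
                 paf_ci = ci(boot$paf)),
            class = "pbam_conventional")
}

.conventional_point <- function(data, spec, sf, outcome,
                                observed_risk_method) {
  fit <- fit_outcome_model(data, spec, outcome = outcome)
  if (!fit$converged) stop("conventional fit did not converge", call. = FALSE)
  risks <- standardized_risks(fit, data, sf, outcome = outcome)
  n_case <- sum(data[[outcome]] == 1)
  n_control <- sum(data[[outcome]] == 0)
  obs <- if (observed_risk_method == "counts") {
    observed_risk(n_case, n_control, sf)
  } else {
    w <- ifelse(data[[outcome]] == 1, 1 / sf$sf_case, 1 / sf$sf_control)
    w <- w / sum(w)
    beta <- c(fit$intercept - intercept_offset(sf), fit$coefficients)
    X <- .build_design(data, fit$spec)
    sum(w * stats::plogis(drop(X %*% beta)))
  }
  list(fit = fit, risks = risks, paf = paf(obs, risks$risk_unexposed))
}

#' @export
print.pbam_conventional <- function(x, ...) {
  cat(sprintf("conventional adjusted OR: %.3f (95%% CI %.3f to %.3f)\n",
              x$or, x$or_ci[1], x$or_ci[2]))
  cat(sprintf("standardized RR: %.3f (95%% CI %.3f to %.3f)\n",
              x$risks$rr, x$rr_ci[1], x$rr_ci[2]))
  cat(sprintf("standardized RD: %.3g (95%% CI %.3g to %.3g)\n",
              x$risks$rd, x$rd_ci[1], x$rd_ci[2]))
  cat(sprintf("conventional PAF: %.3f (95%% CI %.3f to %.3f)\n",
              x$paf$paf, x$paf_ci[1], x$paf_ci[2]))
  invisible(x)
}
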