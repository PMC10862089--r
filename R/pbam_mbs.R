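#' Bias-corrected causal effect of a misclassified exposure
#'
#' Fits the combined probabilistic bias analysis / model-based
#' standardization estimator to case-control data with known sampling
#' fractions. The procedure: (1) optionally select fractional-polynomial
#' age powers once on the observed data; (2) run the conventional
#' analysis on the reported exposure (adjusted OR, standardized RR/RD,
#' PAF with stratified-bootstrap CIs); (3) nest the Monte Carlo bias
#' analysis - sensitivity/specificity drawn from `sens_prior` and
#' `spec_prior`, record-level exposure re-imputation via group-specific
#' predictive values, refit, intercept correction, standardization -
#' inside a stratified bootstrap; (4) summarize the pooled draws by
#' median and 2.5/97.5 percentiles (the Monte Carlo sensitivity-analysis
#' interval).
#'
#' @param formula `outcome ~ exposure + confounders`; the outcome must
#'   be 0/1 (1 = case) and the exposure binary 0/1.
#' @param data Data frame.
#' @param exposure Name of the exposure term on the right-hand side.
#' @param sf A [sampling_fractions()].
#' @param sens_prior,spec_prior [bias_prior()] objects (see
#'   [fit_prior()], [alcohol_accuracy_priors()]).
#' @param n_iter Bias-analysis iterations per dataset.
#' @param n_boot Bootstrap resamples; `0` runs the bias analysis on the
#'   original data only (no random-error component).
#' @param seed Integer seed controlling all randomness of the fit.
#' @param age_var Optional column receiving fractional-polynomial
#'   treatment.
#' @param age_powers Fix the FP powers; `NULL` selects them by the
#'   closed test of [select_fp_powers()].
#' @param fp_alpha Level of the FP closed test.
#' @param summary_method `"pooled"` (default) or `"per_bootstrap"`, see
#'   [summarize_draws()].
#' @param observed_risk_method How the observed risk entering the PAF is
#'   computed, see [run_pbam()].
#' @param conventional_boot Bootstrap resamples for the conventional
#'   CIs (defaults to `max(n_boot, 1)`).
#' @return Object of class `"pbam_mbs"` with components `rr`, `rd`,
#'   `paf` ([summarize_draws()] summaries), `conventional`, `draws`,
#'   `fp`, `spec`, `sf`, `priors`, `seed`, and the matched `call`.
#'   Methods: `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' study <- simulate_study(sim_config(n_population = 2e5), seed = 7)
#' priors <- alcohol_accuracy_priors("triangular")
#' fit <- pbam_mbs(case ~ alcohol + age + sex + married + education +
#'                   smoking + passive_smoking + life_events + vitamin_d,
#'                 data = study$data, exposure = "alcohol", sf = study$sf,
#'                 sens_prior = priors$sens, spec_prior = priors$spec,
#'                 n_iter = 50, n_boot = 10, seed = 1, age_var = "age")
#' fit
#' }
#' @export
pbam_mbs <- function(formula, data, exposure, sf, sens_prior, spec_prior,
                     n_iter = 1000, n_boot = 500, seed = NULL,
                     age_var = NULL, age_powers = NULL, fp_alpha = 0.05,
                     summary_method = c("pooled", "per_bootstrap"),
                     observed_risk_method = c("counts", "model"),
                     conventional_boot = NULL) {
  cl <- match.call()
  summary_method <- match.arg(summary_method)
  observed_risk_method <- match.arg(observed_risk_method)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  vars <- all.vars(formula)
  outcome <- vars[1]
  rhs <- vars[-1]
  if (!exposure %in% rhs) {
    stop("'exposure' must appear on the right-hand side of the formula",
         call. = FALSE)
  }
  confounders <- setdiff(rhs, exposure)
  if (!is.null(seed)) set.seed(seed)

  fp <- NULL
  if (!is.null(age_var) && is.null(age_powers)) {
    fp <- select_fp_powers(data, outcome, exposure,
                           setdiff(confounders, age_var),
                           age_var = age_var, alpha = fp_alpha)
    age_powers <- fp$powers
  }
  spec <- pbam_model_spec(exposure, confounders, age_var = age_var,
                          age_powers = if (is.null(age_var)) 1
                                       else age_powers)

  if (is.null(conventional_boot)) conventional_boot <- max(n_boot, 1L)
  conv <- conventional_analysis(data, spec, sf,
                                n_boot = conventional_boot, seed = NULL,
                                outcome = outcome,
                                observed_risk_method = observed_risk_method)

  draws <- if (n_boot >= 1) {
    bootstrap_pbam(data, sens_prior, spec_prior, sf, spec,
                   n_boot = n_boot, n_iter = n_iter, seed = NULL,
                   outcome = outcome,
                   observed_risk_method = observed_risk_method)
  } else {
    run_pbam(data, sens_prior, spec_prior, sf, spec, n_iter = n_iter,
             seed = NULL, outcome = outcome,
             observed_risk_method = observed_risk_method)
  }

  structure(list(
    rr = summarize_draws(draws, "rr", summary_method),
    rd = summarize_draws(draws, "rd", summary_method),
    paf = summarize_draws(draws, "paf", summary_method),
    conventional = conv,
    draws = draws,
    fp = fp,
    spec = spec,
    sf = sf,
    priors = list(sens = sens_prior, spec = spec_prior),
    outcome = outcome,
    n_iter = n_iter, n_boot = n_boot, seed = seed,
    summary_method = summary_method,
    n_case = sum(data[[outcome]] == 1),
    n_control = sum(data[[outcome]] == 0),
    call = cl), class = "pbam_mbs")
}

#' @export
print.pbam_mbs <- function(x, ...) {
  cat("Probabilistic bias analysis with model-based standardization\n")
  cat(sprintf("  %d cases / %d controls; priors: %s (Se), %s (Sp)\n",
              x$n_case, x$n_control, x$priors$sens$kind,
              x$priors$spec$kind))
  cat(sprintf("  %d bootstrap x %d iterations (%d pooled draws)\n",
              x$n_boot, x$n_iter, nrow(x$draws)))
  cat(sprintf("conventional adjusted OR: %.2f (95%% CI %.2f to %.2f)\n",
              x$conventional$or, x$conventional$or_ci[1],
              x$conventional$or_ci[2]))
  cat(sprintf("bias-adjusted RR:  %.2f (95%% MCSA %.2f to %.2f)\n",
              x$rr$point, x$rr$lower, x$rr$upper))
  cat(sprintf("bias-adjusted RD:  %.4f (95%% MCSA %.4f to %.4f)\n",
              x$rd$point, x$rd$lower, x$rd$upper))
  cat(sprintf("bias-adjusted PAF: %.2f (95%% MCSA %.3f to %.2f)\n",
              x$paf$point, x$paf$lower, x$paf$upper))
  invisible(x)
}

#' @export
coef.pbam_mbs <- function(object, ...) {
  c(rr = object$rr$point, rd = object$rd$point, paf = object$paf$point)
}

#' @export
summary.pbam_mbs <- function(object, ...) {
  est <- rbind(
    rr = unlist(object$rr[c("point", "lower", "upper")]),
    rd = unlist(object$rd[c("point", "lower", "upper")]),
    paf = unlist(object$paf[c("point", "lower", "upper")]))
  structure(list(estimates = as.data.frame(est),
                 conventional = object$conventional,
                 fp = object$fp,
                 n_draws = nrow(object$draws),
                 n_discarded_cells = attr(object$draws,
                                          "n_discarded_cells"),
                 n_discarded_fits = attr(object$draws, "n_discarded_fits"),
                 object = object),
            class = "summary.pbam_mbs")
}

#' @export
print.summary.pbam_mbs <- function(x, ...) {
  print(x$object)
  cat(sprintf("\ndiscarded draws: %d inadmissible cells, %d non-converged fits\n",
              x$n_discarded_cells, x$n_discarded_fits))
  if (!is.null(x$fp)) {
    cat("fractional-polynomial age powers:",
        paste(x$fp$powers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Histogram of bias-corrected risk-ratio draws
#'
#' Distribution of the pooled Monte Carlo RR draws with the median and
#' the 2.5/97.5 percentile limits marked.
#'
#' @param x A [pbam_mbs()] fit.
#' @param field Draw column to plot.
#' @param breaks Passed to [graphics::hist()].
#' @param ... Further arguments to [graphics::hist()].
#' @return Invisibly, the histogram object.
#' @export
plot.pbam_mbs <- function(x, field = "rr", breaks = 50, ...) {
  v <- x$draws[[field]]
  s <- summarize_draws(x$draws, field, x$summary_method)
  h <- graphics::hist(v, breaks = breaks, main = sprintf(
    "bias-corrected %s draws (%s priors)", toupper(field),
    x$priors$sens$kind),
    xlab = sprintf("%s (%d draws)", toupper(field), length(v)), ...)
  graphics::abline(v = c(s$lower, s$point, s$upper),
                   lty = c(3, 2, 3), lwd = c(1, 2, 1))
  invisible(h)
}
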