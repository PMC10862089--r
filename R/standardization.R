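#' Case and control sampling fractions
#'
#' The case sampling fraction is the ratio of sampled cases to all
#' incident cases arising in the study base; the control fraction is the
#' ratio of sampled controls to the eligible base population. Both are
#' needed to (i) correct the case-control logistic intercept to the
#' population risk scale and (ii) weight records back to the study base
#' during standardization.
#'
#' @param sf_case,sf_control Fractions in (0, 1]. Alternatively supply
#'   `(n, N)` pairs through `case` / `control`.
#' @param case,control Optional numeric length-2 vectors
#'   `c(n_sampled, n_base)`.
#' @return Object of class `"sampling_fractions"`.
#' @examples
#' sampling_fractions(0.96, 1057 / 5115679)
#' sampling_fractions(case = c(547, 570), control = c(1057, 5115679))
#' @export
sampling_fractions <- function(sf_case = NULL, sf_control = NULL,
                               case = NULL, control = NULL) {
  if (!is.null(case)) sf_case <- case[1] / case[2]
  if (!is.null(control)) sf_control <- control[1] / control[2]
  stopifnot(is.numeric(sf_case), is.numeric(sf_control),
            length(sf_case) == 1L, length(sf_control) == 1L)
  if (sf_case <= 0 || sf_case > 1 || sf_control <= 0 || sf_control > 1) {
    stop("sampling fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(sf_case = sf_case, sf_control = sf_control),
            class = "sampling_fractions")
}

#' @export
print.sampling_fractions <- function(x, ...) {
  cat(sprintf("sampling fractions: cases %.4g, controls %.4g (offset %.4g)\n",
              x$sf_case, x$sf_control, intercept_offset(x)))
  invisible(x)
}

#' Intercept offset induced by case-control sampling
#'
#' Case-control sampling inflates the logistic intercept by
#' \eqn{\log(sf_{case}/sf_{control})}; subtracting this offset from the
#' apparent intercept recovers the intercept of the study-base risk
#' model, which standardization requires.
#'
#' @param sf A [sampling_fractions()].
#' @return The scalar \eqn{\log(sf_{case}/sf_{control})}.
#' @examples
#' intercept_offset(sampling_fractions(0.96, 1057 / 5115679))  # 8.44
#' @export
intercept_offset <- function(sf) {
  stopifnot(inherits(sf, "sampling_fractions"))
  log(sf$sf_case / sf$sf_control)
}

#' Model-based standardized risks, marginal RR and RD
#'
#' The g-formula at a single time point: each record's outcome risk is
#' predicted from the fitted logistic model with the exposure forced to
#' 1 and then to 0, keeping its observed confounders, and with the
#' intercept corrected by [intercept_offset()]. Risks are averaged over
#' the reconstructed study base, i.e. with normalized weights
#' \eqn{1/sf_{case}} for cases and \eqn{1/sf_{control}} for controls.
#' The marginal risk ratio and risk difference are the ratio and
#' difference of the two standardized risks.
#'
#' @param model A converged [fit_outcome_model()] result.
#' @param data Data frame the model applies to (confounders and outcome
#'   columns present).
#' @param sf A [sampling_fractions()].
#' @param outcome Name of the 0/1 outcome column used for weighting.
#' @return Object of class `"standardized_risks"`: `risk_exposed`,
#'   `risk_unexposed`, `rr`, `rd`.
#' @export
standardized_risks <- function(model, data, sf, outcome = "case") {
  stopifnot(inherits(model, "pbam_logit"), inherits(sf, "sampling_fractions"),
            is.data.frame(data), outcome %in% names(data))
  if (!isTRUE(model$converged)) {
    stop("standardization requires a converged outcome model", call. = FALSE)
  }
  w <- ifelse(data[[outcome]] == 1, 1 / sf$sf_case, 1 / sf$sf_control)
  w <- w / sum(w)
  beta <- c(model$intercept - intercept_offset(sf), model$coefficients)
  X <- .build_design(data, model$spec, exposure_values = 1)
  risk1 <- sum(w * stats::plogis(drop(X %*% beta)))
  X[, model$spec$exposure] <- 0
  risk0 <- sum(w * stats::plogis(drop(X %*% beta)))
  if (risk0 <= 0) {
    stop("standardized risk under no exposure is zero; RR undefined",
         call. = FALSE)
  }
  structure(list(risk_exposed = risk1, risk_unexposed = risk0,
                 rr = risk1 / risk0, rd = risk1 - risk0),
            class = "standardized_risks")
}

#' @export
print.standardized_risks <- function(x, ...) {
  cat(sprintf("standardized risks: exposed %.4g, unexposed %.4g\n",
              x$risk_exposed, x$risk_unexposed))
  cat(sprintf("marginal RR %.4g, RD %.4g\n", x$rr, x$rd))
  invisible(x)
}
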