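#' Observed outcome risk of the reconstructed study base
#'
#' Weighted outcome prevalence obtained by scaling the sampled cases and
#' controls back to the study base by their inverse sampling fractions:
#' \deqn{\Pr[Y = 1] =
#'   \frac{n_{case}/sf_{case}}
#'        {n_{case}/sf_{case} + n_{control}/sf_{control}}.}
#'
#' @param n_case,n_control Sampled case and control counts.
#' @param sf A [sampling_fractions()].
#' @return The observed risk (probability).
#' @examples
#' observed_risk(547, 1057, sampling_fractions(0.96, 1057 / 5115679))
#' @export
observed_risk <- function(n_case, n_control, sf) {
  stopifnot(inherits(sf, "sampling_fractions"),
            n_case >= 0, n_control >= 0)
  if (n_case + n_control == 0) {
    stop("empty study: no cases or controls", call. = FALSE)
  }
  cases_base <- n_case / sf$sf_case
  base_total <- cases_base + n_control / sf$sf_control
  cases_base / base_total
}

#' Population attributable fraction
#'
#' The proportion of observed cases that would not have occurred had the
#' whole study base been unexposed:
#' \deqn{PAF = \frac{\Pr[Y = 1] - \Pr[Y^{a=0} = 1]}{\Pr[Y = 1]},}
#' with \eqn{\Pr[Y^{a=0} = 1]} the standardized risk under no exposure
#' from [standardized_risks()] and \eqn{\Pr[Y=1]} the observed risk
#' (count-based by default, see [observed_risk()]). Negative values are
#' permitted (protective exposure). For the bias-adjusted PAF the
#' Monte Carlo loop evaluates this per draw and summarizes the draws.
#'
#' @param observed_risk Observed risk, > 0.
#' @param risk_no_exposure Counterfactual risk under no exposure.
#' @return Object of class `"paf_result"`: `paf`, `observed_risk`,
#'   `risk_no_exposure`.
#' @examples
#' paf(0.0002, 0.0001)
#' @export
paf <- function(observed_risk, risk_no_exposure) {
  stopifnot(is.numeric(observed_risk), is.numeric(risk_no_exposure))
  if (observed_risk <= 0) {
    stop("observed risk must be positive to define the PAF", call. = FALSE)
  }
  structure(list(paf = (observed_risk - risk_no_exposure) / observed_risk,
                 observed_risk = observed_risk,
                 risk_no_exposure = risk_no_exposure),
            class = "paf_result")
}

#' @export
print.paf_result <- function(x, ...) {
  cat(sprintf("PAF = %.4g (observed risk %.4g, risk under no exposure %.4g)\n",
              x$paf, x$observed_risk, x$risk_no_exposure))
  invisible(x)
}
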