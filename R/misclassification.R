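#' Reported exposure counts within one group
#'
#' @param n_exposed,n_unexposed Non-negative counts of reported-exposed
#'   and reported-unexposed records; their sum must be positive.
#' @return An object of class `"group_counts"`.
#' @export
group_counts <- function(n_exposed, n_unexposed) {
  stopifnot(is.numeric(n_exposed), is.numeric(n_unexposed),
            n_exposed >= 0, n_unexposed >= 0)
  if (n_exposed + n_unexposed <= 0) {
    stop("group must contain at least one record", call. = FALSE)
  }
  structure(list(n_exposed = n_exposed, n_unexposed = n_unexposed),
            class = "group_counts")
}

#' Correct reported exposure counts for misclassification
#'
#' Inverts the 2x2 misclassification matrix: with reported counts
#' \eqn{a^*} (exposed) and \eqn{b^*} (unexposed), the expected true
#' exposed count is
#' \deqn{A = \frac{a^* - (1 - Sp)(a^* + b^*)}{Se + Sp - 1},}
#' and \eqn{B = (a^* + b^*) - A}. The forward identity
#' \eqn{Se \cdot A + (1 - Sp) \cdot B = a^*} holds by construction.
#' Cells with \eqn{A \le 0} or \eqn{B \le 0} are flagged `valid = FALSE`
#' rather than raising an error: in the Monte Carlo loop the
#' sensitivity/specificity draw is discarded and redrawn.
#'
#' @param counts A [group_counts()] (or numeric vector
#'   `c(n_exposed, n_unexposed)`).
#' @param ss A [sens_spec()]; requires `Se + Sp > 1` for identifiability.
#' @return Object of class `"corrected_counts"`: list with `A`, `B`
#'   (expected true exposed/unexposed, real-valued), and `valid`.
#' @examples
#' correct_counts(group_counts(30, 70), sens_spec(0.8, 0.9))
#' @export
correct_counts <- function(counts, ss) {
  if (!inherits(counts, "group_counts")) {
    counts <- group_counts(counts[[1]], counts[[2]])
  }
  stopifnot(inherits(ss, "sens_spec"))
  se <- ss$sensitivity
  sp <- ss$specificity
  if (se + sp <= 1) {
    stop("non-identifiable correction: sensitivity + specificity must exceed 1",
         call. = FALSE)
  }
  n <- counts$n_exposed + counts$n_unexposed
  A <- (counts$n_exposed - (1 - sp) * n) / (se + sp - 1)
  B <- n - A
  structure(list(A = A, B = B, valid = (A > 0 && B > 0)),
            class = "corrected_counts")
}

#' Predictive values from corrected counts
#'
#' Positive and negative predictive values implied by the corrected true
#' counts and the accuracy pair that produced them:
#' \deqn{PPV = \frac{Se\,A}{Se\,A + (1 - Sp)\,B}, \qquad
#'       NPV = \frac{Sp\,B}{Sp\,B + (1 - Se)\,A}.}
#' Because the true exposure prevalence differs between cases and
#' controls, predictive values are computed separately within each group
#' even though the accuracy pair is shared (non-differential).
#'
#' @param cc A valid [correct_counts()] result.
#' @param ss The [sens_spec()] used to produce `cc`.
#' @return Object of class `"predictive_values"`: list with `ppv`, `npv`.
#' @export
predictive_values <- function(cc, ss) {
  stopifnot(inherits(cc, "corrected_counts"), inherits(ss, "sens_spec"))
  if (!isTRUE(cc$valid)) {
    stop("predictive values require a valid corrected-count cell", call. = FALSE)
  }
  se <- ss$sensitivity
  sp <- ss$specificity
  ppv <- se * cc$A / (se * cc$A + (1 - sp) * cc$B)
  npv <- sp * cc$B / (sp * cc$B + (1 - se) * cc$A)
  structure(list(ppv = ppv, npv = npv), class = "predictive_values")
}

# Vectorized record-level imputation given per-record ppv/npv and uniforms.
# reported-exposed: keep 1 unless u > ppv; reported-unexposed: keep 0
# unless u > npv.
.impute_vec <- function(reported, ppv, npv, u) {
  imputed <- reported
  imputed[reported == 1L & u > ppv] <- 0L
  imputed[reported == 0L & u > npv] <- 1L
  imputed
}

#' Impute record-level exposure from predictive values
#'
#' Replaces each record's reported binary exposure with a Bernoulli
#' re-draw governed by its group's predictive values: for a
#' reported-exposed record a uniform \eqn{U_i} exceeding the PPV sets the
#' exposure to 0; for a reported-unexposed record \eqn{U_i} exceeding the
#' NPV sets it to 1; otherwise the reported value is kept. The expected
#' 2x2 table of the imputed exposure equals the corrected-count table.
#'
#' @param records Data frame with an outcome column (1 = case) and a 0/1
#'   reported exposure column, no missing values in either.
#' @param pv_cases,pv_controls [predictive_values()] computed within
#'   cases and controls from the same sensitivity/specificity draw.
#' @param outcome,exposure Column names.
#' @return `records` with an added integer column
#'   `paste0(exposure, "_imputed")`.
#' @export
impute_exposure <- function(records, pv_cases, pv_controls,
                            outcome = "case", exposure = "exposure") {
  stopifnot(is.data.frame(records),
            inherits(pv_cases, "predictive_values"),
            inherits(pv_controls, "predictive_values"),
            outcome %in% names(records), exposure %in% names(records))
  y <- records[[outcome]]
  x <- records[[exposure]]
  if (anyNA(x) || anyNA(y)) {
    stop("missing exposure or outcome values", call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop("reported exposure must be coded 0/1", call. = FALSE)
  }
  is_case <- y == 1
  ppv <- ifelse(is_case, pv_cases$ppv, pv_controls$ppv)
  npv <- ifelse(is_case, pv_cases$npv, pv_controls$npv)
  u <- stats::runif(nrow(records))
  records[[paste0(exposure, "_imputed")]] <-
    .impute_vec(as.integer(x), ppv, npv, u)
  records
}
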