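#' Descriptive characteristics table by case status
#'
#' The familiar "Table 1" of case-control reports: for each variable,
#' n (%) of the positive level for binaries and mean (SD) for continuous
#' variables, split into cases and controls, percentages to one decimal
#' place.
#'
#' @param data Non-empty data frame with a 0/1 outcome column.
#' @param outcome Outcome column name (1 = case).
#' @param variables Columns to describe; defaults to all others.
#' @return Data frame with columns `variable`, `statistic`, `cases`,
#'   `controls` (formatted strings).
#' @examples
#' d <- data.frame(case = rep(1:0, c(547, 1057)),
#'                 sex = rep(c(1, 0, 1, 0), c(401, 146, 544, 513)))
#' describe_dataset(d)
#' @export
describe_dataset <- function(data, outcome = "case", variables = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(variables)) variables <- setdiff(names(data), outcome)
  is_case <- data[[outcome]] == 1
  if (sum(is_case) == 0L || sum(!is_case) == 0L) {
    stop("both cases and controls must be present", call. = FALSE)
  }
  cell <- function(x, grp) {
    x <- x[grp]
    if (all(x %in% c(0, 1, NA))) {
      n <- sum(x == 1, na.rm = TRUE)
      sprintf("%d (%.1f)", n, 100 * n / sum(!is.na(x)))
    } else {
      sprintf("%.1f (%.1f)", mean(x, na.rm = TRUE),
              stats::sd(x, na.rm = TRUE))
    }
  }
  stat <- vapply(variables, function(v) {
    if (all(data[[v]] %in% c(0, 1, NA))) "n (%)" else "mean (SD)"
  }, character(1))
  data.frame(
    variable = variables,
    statistic = unname(stat),
    cases = vapply(variables, function(v) cell(data[[v]], is_case),
                   character(1)),
    controls = vapply(variables, function(v) cell(data[[v]], !is_case),
                      character(1)),
    row.names = NULL)
}

.as_sampling_fractions <- function(x) {
  if (inherits(x, "sampling_fractions")) return(x)
  x <- as.list(x)
  if (!is.null(x$sf_case)) {
    sampling_fractions(x$sf_case, x$sf_control)
  } else {
    sampling_fractions(case = unlist(x$case), control = unlist(x$control))
  }
}

.prior_from_block <- function(block, kind) {
  block <- as.list(block)
  if (!is.null(block$params)) {
    p <- unlist(block$params)
    params <- switch(kind,
      triangular = list(min = p[1], max = p[2], mode = p[3]),
      beta = list(alpha = p[1], beta = p[2]),
      logit_logistic = list(location = p[1], scale = p[2]))
    bias_prior(kind, params)
  } else {
    fit_prior(kind, quantile_spec(block$median, block$lower, block$upper))
  }
}

#' Run the full reporting pipeline
#'
#' Orchestrates a complete analysis from a configuration list (or YAML
#' file): reads the dataset, writes a descriptive table, runs the
#' conventional analysis, then the bias analysis under each configured
#' prior kind, and writes the effect table (RR/RD rows per prior kind
#' with MCSA limits), the PAF table, the pooled draws, a histogram of
#' the RR draws, and a run log recording seeds and discard counts.
#'
#' Configuration fields: `dataset` (CSV path) or `data` (data frame);
#' `outcome`, `exposure`, `confounders`, optional `age_var`;
#' `sampling_fractions` (either `sf_case`/`sf_control` or
#' `case: [n, N]` / `control: [n, N]` pairs); `priors` with `kinds`
#' (default all three) and `sensitivity`/`specificity` blocks, each
#' `{median, lower, upper}` or `{params: [...]}`; `n_iter`, `n_boot`,
#' `seed`, `outdir`; optional `summary_method` and
#' `observed_risk_method`.
#'
#' @param config Named list or path to a YAML file.
#' @return Invisibly, a list with the `"pbam_mbs"` fits per prior kind,
#'   the conventional analysis, and the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  data <- if (!is.null(config[["data"]])) config[["data"]] else {
    if (is.null(config[["dataset"]]) || !file.exists(config[["dataset"]])) {
      stop("config$dataset does not exist", call. = FALSE)
    }
    utils::read.csv(config[["dataset"]])
  }
  outcome <- config$outcome %||% "case"
  exposure <- config$exposure %||% "alcohol"
  confounders <- unlist(config$confounders)
  if (is.null(confounders)) {
    stop("config$confounders is required", call. = FALSE)
  }
  age_var <- config$age_var
  sf <- .as_sampling_fractions(config$sampling_fractions)
  n_iter <- config$n_iter %||% 1000
  n_boot <- config$n_boot %||% 500
  seed <- config$seed %||% 1L
  outdir <- config$outdir %||% "."
  kinds <- unlist(config$priors$kinds) %||%
    c("triangular", "beta", "logit_logistic")
  summary_method <- config$summary_method %||% "pooled"
  orm <- config$observed_risk_method %||% "counts"
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  fmla <- stats::reformulate(c(exposure, confounders), response = outcome)
  set.seed(seed)
  kind_seeds <- sample.int(.Machine$integer.max - 1L, length(kinds) + 1L)

  log_lines <- c(sprintf("pbamstd %s pipeline run, %s",
                         as.character(utils::packageVersion("pbamstd")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("seed = %d; n_iter = %d; n_boot = %d",
                         seed, n_iter, n_boot),
                 sprintf("dataset: %d cases, %d controls",
                         sum(data[[outcome]] == 1),
                         sum(data[[outcome]] == 0)))

  desc <- describe_dataset(data, outcome = outcome,
                           variables = c(confounders, age_var, exposure))
  paths <- list(describe = file.path(outdir, "describe.csv"))
  utils::write.csv(desc, paths$describe, row.names = FALSE)

  fits <- list()
  eff_rows <- list()
  paf_rows <- list()
  all_draws <- list()
  for (i in seq_along(kinds)) {
    kind <- kinds[i]
    sens_prior <- .prior_from_block(config$priors$sensitivity %||%
                                      list(median = 0.79, lower = 0.72,
                                           upper = 0.86), kind)
    spec_prior <- .prior_from_block(config$priors$specificity %||%
                                      list(median = 0.84, lower = 0.80,
                                           upper = 0.89), kind)
    fit <- pbam_mbs(fmla, data, exposure = exposure, sf = sf,
                    sens_prior = sens_prior, spec_prior = spec_prior,
                    n_iter = n_iter, n_boot = n_boot,
                    seed = kind_seeds[i], age_var = age_var,
                    summary_method = summary_method,
                    observed_risk_method = orm)
    fits[[kind]] <- fit
    eff_rows[[kind]] <- data.frame(
      prior = kind,
      rr = fit$rr$point, rr_lower = fit$rr$lower, rr_upper = fit$rr$upper,
      rd = fit$rd$point, rd_lower = fit$rd$lower, rd_upper = fit$rd$upper)
    paf_rows[[kind]] <- data.frame(
      prior = kind, paf = fit$paf$point,
      paf_lower = fit$paf$lower, paf_upper = fit$paf$upper)
    d <- as.data.frame(fit$draws)
    d$prior <- kind
    all_draws[[kind]] <- d
    log_lines <- c(log_lines, sprintf(
      "%s: seed %d, %d draws, discarded cells %d, discarded fits %d",
      kind, kind_seeds[i], nrow(fit$draws),
      attr(fit$draws, "n_discarded_cells"),
      attr(fit$draws, "n_discarded_fits")))
  }

  conv <- fits[[1]]$conventional
  paths$effects <- file.path(outdir, "effects.csv")
  utils::write.csv(do.call(rbind, eff_rows), paths$effects,
                   row.names = FALSE)
  paths$paf <- file.path(outdir, "paf.csv")
  utils::write.csv(do.call(rbind, paf_rows), paths$paf, row.names = FALSE)
  paths$conventional <- file.path(outdir, "conventional.csv")
  utils::write.csv(data.frame(
    or = conv$or, or_lower = conv$or_ci[1], or_upper = conv$or_ci[2],
    rr = conv$risks$rr, rr_lower = conv$rr_ci[1],
    rr_upper = conv$rr_ci[2],
    rd = conv$risks$rd, rd_lower = conv$rd_ci[1],
    rd_upper = conv$rd_ci[2],
    paf = conv$paf$paf, paf_lower = conv$paf_ci[1],
    paf_upper = conv$paf_ci[2]),
    paths$conventional, row.names = FALSE)
  paths$draws <- file.path(outdir, "draws.csv")
  utils::write.csv(do.call(rbind, all_draws), paths$draws,
                   row.names = FALSE)

  paths$plot <- file.path(outdir, "rr_histogram.pdf")
  grDevices::pdf(paths$plot, width = 7, height = 5)
  for (kind in kinds) plot(fits[[kind]])
  grDevices::dev.off()

  paths$log <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, paths$log)

  invisible(list(fits = fits, conventional = conv, describe = desc,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
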