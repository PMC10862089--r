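---
title: "Misclassification bias analysis with model-based standardization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Misclassification bias analysis with model-based standardization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbamstd)
```

## The estimand and the procedure

`pbamstd` estimates the marginal causal risk ratio (RR), risk
difference (RD), and population attributable fraction (PAF) of a binary
exposure on a binary outcome from a case-control study in which

* the exposure is a self-report with imperfect sensitivity (Se) and
  specificity (Sp), assumed **non-differential** (identical in cases
  and controls), and
* the **sampling fractions** are known: the fraction of the study
  base's incident cases that were recruited, and the fraction of the
  eligible base population recruited as controls.

One Monte Carlo iteration of the bias analysis proceeds as follows.

1. Draw one (Se, Sp) pair from the prior distributions. The same pair
   applies to both groups.
2. Within cases and within controls separately, invert the 2×2
   misclassification matrix: with $a^*$ reported exposed of $n$
   records, $A = \frac{a^* - (1-Sp)\,n}{Se + Sp - 1}$ and
   $B = n - A$. The inversion requires $Se + Sp > 1$; draws implying
   $A \le 0$ or $B \le 0$ are discarded and redrawn (with a cap of
   10,000 discards per iteration, after which the run stops with a
   diagnostic — such priors are incompatible with the data).
3. Convert the corrected counts into group-specific predictive values,
   $PPV = \frac{Se\,A}{Se\,A + (1-Sp)\,B}$ and
   $NPV = \frac{Sp\,B}{Sp\,B + (1-Se)\,A}$. Predictive values must be
   group-specific because true exposure prevalence differs between
   cases and controls even though (Se, Sp) does not.
4. Re-impute each record's exposure: a reported-exposed record is kept
   exposed unless a uniform draw exceeds its group's PPV; a
   reported-unexposed record is kept unexposed unless the draw exceeds
   its group's NPV. In expectation the imputed 2×2 table equals the
   corrected table.
5. Refit the multivariable logistic outcome model on the imputed
   exposure and the confounders.
6. Standardize: subtract $\log(sf_{case}/sf_{control})$ from the
   apparent intercept (case-control sampling inflates the intercept by
   exactly this amount), predict every record's risk with exposure
   forced to 1 and to 0, and average with weights proportional to
   $1/sf$ within each group — the g-formula over the reconstructed
   study base. RR and RD are the ratio and difference of the two
   standardized risks; the PAF compares the observed risk with the
   standardized risk under no exposure.

The loop is nested inside a stratified nonparametric bootstrap (cases
and controls resampled with replacement, separately, preserving group
sizes). The pooled `n_boot × n_iter` draws are summarized by their
median and 2.5th/97.5th percentiles — the Monte Carlo sensitivity
analysis (MCSA) interval, which reflects classification uncertainty and
random error jointly.

## Prior distributions

`fit_prior()` accepts a quantile specification — median and 95% central
limits, typically a pooled estimate with its confidence interval from
`pool_accuracy()` (DerSimonian–Laird random effects on the logit
scale) — and returns one of three distribution kinds:

* **triangular**: the conventional bias-analysis mapping
  (min, max, mode) = (q025, q975, median). The interval endpoints
  become the *support*, so the distribution's own 2.5th/97.5th
  percentiles sit slightly inside the specified limits (by
  $\sqrt{0.025\,(max-min)(mode-min)}$, about 0.016 for a width-0.14
  prior). This is a property of the parameterization, not a fitting
  error; we keep the standard mapping because it is what published bias
  analyses report. It also means that refitting a triangular prior to
  its own implied percentiles contracts the support — the
  fit/implied-quantile round trip is a near-identity for the beta and
  logit-logistic kinds only.
* **beta**: (α, β) minimizing the summed squared deviation of the
  implied (2.5, 50, 97.5) percentiles from the specification
  (Nelder–Mead on log-parameters, moment-matching start, relative
  tolerance 1e-14). Fitted deviations are below 0.006 for the default
  accuracy specifications.
* **logit-logistic**: a logistic distribution on the logit scale,
  expit-transformed. Location is the logit of the median; because a
  quantile triple is generally asymmetric on the logit scale while the
  logistic is symmetric, the scale is the average of the two one-sided
  solutions mapping the central 95% interval onto the specified limits.
  Published location/scale pairs for this kind are frequently
  inconsistent with the limits they accompany, so the fitter always
  derives its own scale; externally specified parameters can still be
  imposed verbatim through `bias_prior()`.

Se and Sp are drawn **independently**. Validation studies report the
two jointly and a negative correlation is plausible, but the published
bias-analysis practice this package follows specifies the two margins
separately and gives no correlation; a joint prior is out of scope.

## Outcome model and age

Age enters through fractional polynomials: powers from
$\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 = log; a repeated power $p$
contributes $x^p$ and $x^p\log x$), with age divided by 10 beforehand
so that the extreme powers stay numerically tame. The Royston–Altman
closed test (best FP2 vs. no age on 4 df, vs. linear on 3 df, vs. best
FP1 on 2 df, deviance differences against χ²) selects the powers at
`fp_alpha = 0.05`. Two deliberate choices:

* Selection runs **once, on the observed pre-imputation data**, and the
  powers are held fixed across all Monte Carlo iterations. Re-selecting
  per iteration would mix model-selection noise into the bias
  distribution and make draws incomparable.
* Age is never dropped: it belongs to the minimally sufficient
  adjustment set, so when nonlinearity is not demonstrated the model
  keeps linear age.

Iterations whose refit shows separation *in the exposure column*
(|coefficient| > 10 with boundary fitted values or a convergence
warning) are discarded and redrawn, mirroring the inadmissible-cell
convention; quasi-separation in a rare confounder of a bootstrap
resample is tolerated, because no (Se, Sp) redraw can cure it and the
fit remains usable for standardization. Discard counts of both kinds
are reported in `summary()` and the pipeline run log.

## Numerical conventions

* Percentiles use empirical order statistics with linear interpolation
  (`stats::quantile`, type 7), stated because quantile conventions
  differ across software.
* The point estimate is the median of the **pooled** draws. The
  alternative — summarizing per-bootstrap medians — is available as
  `summary_method = "per_bootstrap"`; pooling is the default because it
  is the only reading that produces a single final interval carrying
  both uncertainty sources.
* The observed risk in the PAF uses reconstructed base counts,
  $\frac{n_{case}/sf_{case}}{n_{case}/sf_{case} + n_{control}/sf_{control}}$;
  a model-standardized alternative is exposed as
  `observed_risk_method = "model"`.
* Standardization weights are normalized to sum to one, so jointly
  rescaling both sampling fractions leaves every estimate unchanged.
* One master seed drives everything; the bootstrap derives one sub-seed
  per replicate, so results are bit-for-bit reproducible and
  independent of how replicates might be scheduled.

## The synthetic generator

`sim_config()` describes a study base of adults aged 15–50 emulating a
population-based incident case-control study of alcohol consumption and
multiple sclerosis: age ~ truncated Normal(31.3, 9.3²) on [15, 50],
education ~ Normal(13.4, 3.2²) truncated at zero, and Bernoulli
confounders at the control-arm prevalences (female 0.515, married
0.538, smoking 0.199, passive smoking 0.375, life events 0.819, vitamin
D supplement 0.076). True exposure follows a logistic model with
intercept −2.370 (10% base prevalence) and modest confounder
dependence (smoking +0.9, female −0.7, life events +0.3 on the log-odds
scale — directions a survey scientist would expect for alcohol use in
this setting). The outcome model's conditional exposure log-odds ratio
is log 2 with confounder effects (female +0.95, passive smoking +0.60,
vitamin D −1.12, education +0.035/yr, age −0.010/yr) chosen so the
simulated case arm reproduces the characteristic case-control contrasts
(≈73% female cases vs. ≈52% female controls, and so on); the intercept
−7.825 targets a base risk of about 1.16 × 10⁻³, so the default
5 × 10⁵ base yields roughly 570 cases,
and the default control fraction 1057/5 × 10⁵ roughly 1057 controls,
preserving the sample sizes of the motivating study design at a
simulable base size. The implied oracle marginal RR is 1.997 and oracle
PAF about 0.079, both computed by exact counterfactual enumeration in
`oracle_effects()`, never by model fitting.

What the generator does **not** emulate: correlation between
confounders (only marginals are targeted; a hook exists but defaults to
independence), telephone-sampling mechanics, differential reporting, or
measurement error in the confounders. Passing tests therefore
demonstrate the estimator's internal correctness and its behavior under
non-differential misclassification with independent confounders — not
robustness to violations the model itself does not contemplate.

## Validation problem sizes

The test suite checks exact algebra (count correction, predictive
values, standardization vs. direct standardization over discrete
strata) at tolerance 1e-10, distributional properties at 10⁵ draws, and
end-to-end behavior on ten replicate synthetic studies of the default
5 × 10⁵ base with 20 bootstrap × 100 Monte Carlo draws each — enough
replication to separate method bias from the (large) per-study sampling
error while keeping a complete run in minutes on one core. The
reported-headline script uses 50 × 200 draws per prior kind.

## Known limitations

* **Record-level imputation conditions only on reported exposure and
  case status.** When true exposure is correlated with confounders, the
  imputed exposure carries that correlation only as far as the report
  does, so the refitted conditional coefficient — and with it the
  standardized RR — remains somewhat attenuated. Under the default
  generator (modest exposure–confounder dependence) the residual
  attenuation of the corrected estimate is on the order of 15% on the
  log scale, well inside the method's Monte Carlo spread; with exposure
  independent of confounders the correction is exactly calibrated (the
  reduction to the conventional analysis under perfect-accuracy priors
  is draw-for-draw, and the point-mass-prior pipeline is unbiased).
  This is a property of the published procedure itself, faithfully
  implemented; covariate-conditional predictive values would be the
  remedy and are out of scope.
* **Noise amplification is intrinsic.** The corrected prevalence
  inherits reported-prevalence sampling noise inflated by
  $1/(Se+Sp-1)$ — about 1.6 at the default accuracy. MCSA intervals
  spanning a factor of 4 on the RR at ~550 cases are the honest output,
  not a convergence failure.
* Only non-differential misclassification of the exposure is modeled;
  outcome misclassification and confounder measurement error are not.
* The PAF interval is a percentile summary of the draw distribution; no
  delta-method or subgroup decomposition is provided.
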