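# Credibility assessment of significant pooled associations:
# statistical power, false-positive report probability (FPRP),
# Bayesian false discovery probability (BFDP), composite verdict.

#' Power to detect a given odds ratio
#'
#' Probability that a two-sided level-`alpha` Wald test on the log odds
#' ratio, with standard error `se`, rejects when the true odds ratio is
#' `or_alt`:
#' `power = 1 - pnorm(z_a - |log(or_alt)|/se) + pnorm(-z_a - |log(or_alt)|/se)`.
#'
#' @param se standard error of the pooled log odds ratio.
#' @param or_alt alternative odds ratio to detect (use `1/or_alt` and
#'   `or_alt` interchangeably: only `|log(or_alt)|` enters).
#' @param alpha two-sided test level.
#' @return Power in `[0, 1]`; equals `alpha` when `or_alt = 1`.
#' @export
detectable_power <- function(se, or_alt = 1.5, alpha = 0.05) {
  stopifnot(all(se > 0), all(or_alt > 0))
  za <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(log(or_alt)) / se
  1 - stats::pnorm(za - ncp) + stats::pnorm(-za - ncp)
}

#' False-positive report probability
#'
#' `FPRP = p*(1-pi) / (p*(1-pi) + power*pi)` for an observed (two-sided)
#' p-value `p`, the power to detect the alternative at the test level, and
#' a prior probability `pi` that the association is real.  By convention
#' `FPRP = 1` when the power is zero.
#'
#' @param p_obs observed p-value of the pooled association.
#' @param power power at the alternative odds ratio (see
#'   [detectable_power()]).
#' @param prior prior probability (or vector of priors) in `(0, 1)`.
#' @return FPRP value(s) in `[0, 1]`, named by prior.
#' @export
fprp <- function(p_obs, power, prior) {
  stopifnot(all(prior > 0), all(prior < 1),
            p_obs >= 0, p_obs <= 1, power >= 0, power <= 1)
  if (power == 0) return(stats::setNames(rep(1, length(prior)),
                                         format(prior)))
  out <- p_obs * (1 - prior) / (p_obs * (1 - prior) + power * prior)
  stats::setNames(out, format(prior))
}

#' Bayesian false discovery probability
#'
#' Wakefield's approximate-Bayes-factor measure.  With estimate `theta`
#' (log OR), sampling variance `V`, and a normal prior on the log OR whose
#' 97.5th percentile is `log(or_alt_upper)` (prior variance
#' `W = (log(or_alt_upper)/1.96)^2`):
#' `r = W/(V+W)`, `Z = theta/sqrt(V)`,
#' `ABF = exp(-Z^2 r / 2) / sqrt(1-r)`, and
#' `BFDP = ABF*PO / (ABF*PO + 1)` with prior odds `PO = (1-pi)/pi`.
#'
#' @param log_or_hat pooled log odds ratio.
#' @param variance its squared standard error.
#' @param prior prior probability (or vector) of a true association.
#' @param or_alt_upper odds ratio at the upper 97.5th prior percentile.
#' @return BFDP value(s) in `[0, 1]`, named by prior.
#' @export
bfdp <- function(log_or_hat, variance, prior, or_alt_upper = 1.5) {
  stopifnot(variance > 0, all(prior > 0), all(prior < 1), or_alt_upper > 0)
  W <- (log(or_alt_upper) / stats::qnorm(0.975))^2
  r <- W / (variance + W)
  z <- log_or_hat / sqrt(variance)
  log_abf <- -z^2 * r / 2 - 0.5 * log1p(-r)
  po <- (1 - prior) / prior
  # BFDP = ABF*PO/(ABF*PO+1) computed stably in logs
  log_num <- log_abf + log(po)
  out <- 1 / (1 + exp(-log_num))
  stats::setNames(out, format(prior))
}

#' Composite credibility verdict for a significant association
#'
#' An association is judged `high_credibility` only if all four conditions
#' hold: significant in at least two genetic models; FPRP below 0.2 *and*
#' BFDP below 0.8 at the reference prior; I-squared below 50 percent; and
#' power above 80 percent at the alternative odds ratio.  Everything else
#' is `less_credible`.  All inequalities are strict.
#'
#' @param fit a [meta_or()] fit (supplies estimate, variance, p-value and
#'   I-squared), or `NULL` if the raw inputs are given.
#' @param n_significant_models in how many of the five genetic models the
#'   association is significant.
#' @param log_or_hat,variance,p_value,i_squared raw inputs, used when
#'   `fit` is `NULL`.
#' @param priors grid of prior probabilities reported.
#' @param reference_prior prior at which the verdict conditions are
#'   evaluated.
#' @param or_alt alternative odds ratio for power and FPRP: used as given
#'   for risk estimates and reciprocally for protective ones (only its
#'   magnitude on the log scale matters).
#' @param alpha test level for the power computation.
#' @param fprp_cut,bfdp_cut,i2_cut,power_cut verdict thresholds.
#' @return An object of class `"credibility"`: `power`, named vectors
#'   `fprp` and `bfdp` over the prior grid, the inputs, and `verdict`.
#' @export
assess_credibility <- function(fit = NULL, n_significant_models,
                               log_or_hat = NULL, variance = NULL,
                               p_value = NULL, i_squared = NULL,
                               priors = c(0.25, 0.1, 0.01, 0.001, 1e-4),
                               reference_prior = 0.001,
                               or_alt = 1.5, alpha = 0.05,
                               fprp_cut = 0.2, bfdp_cut = 0.8,
                               i2_cut = 50, power_cut = 0.8) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "meta_or"))
    log_or_hat <- fit$pooled$log_or
    variance <- fit$pooled$se^2
    p_value <- fit$pooled$p_value
    i_squared <- fit$het$i_squared
  }
  se <- sqrt(variance)
  pw <- detectable_power(se, or_alt = or_alt, alpha = alpha)
  fp <- fprp(p_value, pw, priors)
  bf <- bfdp(log_or_hat, variance, priors, or_alt_upper = or_alt)
  fp_ref <- fprp(p_value, pw, reference_prior)
  bf_ref <- bfdp(log_or_hat, variance, reference_prior,
                 or_alt_upper = or_alt)
  high <- (n_significant_models >= 2) &&
    (fp_ref < fprp_cut) && (bf_ref < bfdp_cut) &&
    (is.finite(i_squared) && i_squared < i2_cut) &&
    (pw > power_cut)
  structure(list(power = pw, fprp = fp, bfdp = bf,
                 fprp_reference = unname(fp_ref),
                 bfdp_reference = unname(bf_ref),
                 reference_prior = reference_prior,
                 n_significant_models = n_significant_models,
                 i_squared = i_squared, p_value = p_value,
                 log_or_hat = log_or_hat, variance = variance,
                 verdict = if (high) "high_credibility" else
                   "less_credible"),
            class = "credibility")
}

#' @export
print.credibility <- function(x, ...) {
  cat("Credibility assessment\n")
  cat(sprintf("  power at alternative: %.3f | I2 = %.1f%% | significant in %d model(s)\n",
              x$power, x$i_squared, x$n_significant_models))
  cat("  FPRP by prior: ",
      paste(sprintf("%s=%.3f", names(x$fprp), x$fprp), collapse = "  "),
      "\n")
  cat("  BFDP by prior: ",
      paste(sprintf("%s=%.3f", names(x$bfdp), x$bfdp), collapse = "  "),
      "\n")
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}

#' Simplified Venice-style descriptive grading
#'
#' Optional three-letter descriptive grade: amount of evidence by the
#' pooled minor-allele count among cases and controls (A > 1000,
#' B 100-1000, C < 100); consistency by I-squared (A < 25, B 25-50,
#' C > 50); protection from bias by Egger's test and Hardy-Weinberg status
#' (A: Egger p > 0.05 and all controls in equilibrium; B: Egger p > 0.05;
#' C otherwise).  Descriptive only — the composite verdict of
#' [assess_credibility()] is the package's credibility rule.
#'
#' @param fit a [meta_or()] fit.
#' @param egger_p p-value of Egger's test for the contrast.
#' @param all_hwe logical: are all pooled studies' controls in equilibrium?
#' @return Character scalar like `"ABC"`.
#' @export
venice_grade <- function(fit, egger_p, all_hwe) {
  stopifnot(inherits(fit, "meta_or"))
  s <- fit$dataset$studies
  minor <- sum(2 * s$case_eff_hom + s$case_het +
                 2 * s$control_eff_hom + s$control_het)
  amount <- if (minor > 1000) "A" else if (minor >= 100) "B" else "C"
  i2 <- fit$het$i_squared
  consistency <- if (!is.finite(i2)) "C"
    else if (i2 < 25) "A" else if (i2 <= 50) "B" else "C"
  bias <- if (egger_p > 0.05 && all_hwe) "A"
    else if (egger_p > 0.05) "B" else "C"
  paste0(amount, consistency, bias)
}
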