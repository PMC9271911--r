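#' Cochran's Q, I-squared and the DerSimonian-Laird tau-squared
#'
#' Inverse-variance heterogeneity statistics for a set of per-study effects:
#' `Q = sum(w_i * (y_i - ybar)^2)` with `w_i = 1/se_i^2`, `df = k - 1`,
#' `I2 = max(0, 100 * (Q - df) / Q)` and the DerSimonian-Laird moment
#' estimator `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`.
#'
#' @param yi per-study effects (log odds ratios).
#' @param sei per-study standard errors.
#' @return List with `q_stat`, `df`, `p_heterogeneity`, `i_squared`,
#'   `tau_squared`.
#' @export
heterogeneity_stats <- function(yi, sei) {
  k <- length(yi)
  if (k < 2L)
    stop("heterogeneity requires at least two studies", call. = FALSE)
  stopifnot(length(sei) == k, all(sei > 0))
  w <- 1 / sei^2
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  df <- k - 1L
  list(q_stat = q, df = df,
       p_heterogeneity = stats::pchisq(q, df, lower.tail = FALSE),
       i_squared = max(0, 100 * (q - df) / q),
       tau_squared = max(0, (q - df) / (sum(w) - sum(w^2) / sum(w))))
}

#' Heterogeneity-driven choice between fixed and random effects
#'
#' The selection rule: the random-effects model when the Q-test p-value is
#' below 0.10 *or* I-squared exceeds 50 percent (strict inequalities);
#' otherwise the fixed-effect (Mantel-Haenszel) model.
#'
#' @param p_heterogeneity Q-test p-value.
#' @param i_squared I-squared, in percent.
#' @param p_cut,i2_cut rule thresholds.
#' @return `"random_dl"` or `"fixed_mh"`.
#' @export
select_model <- function(p_heterogeneity, i_squared,
                         p_cut = 0.10, i2_cut = 50) {
  if (p_heterogeneity < p_cut || i_squared > i2_cut) "random_dl"
  else "fixed_mh"
}

# internal: Mantel-Haenszel pooled log OR with the
# Robins-Breslow-Greenland variance, on a data.frame of 2x2 cells
mh_log_or <- function(a, b, c, d) {
  n <- a + b + c + d
  R <- sum(a * d / n)
  S <- sum(b * c / n)
  if (R == 0 || S == 0)
    stop("Mantel-Haenszel estimate undefined (no discordant information)",
         call. = FALSE)
  p <- (a + d) / n
  q <- (b + c) / n
  v <- sum(p * a * d / n) / (2 * R^2) +
    sum(p * b * c / n + q * a * d / n) / (2 * R * S) +
    sum(q * b * c / n) / (2 * S^2)
  list(log_or = log(R / S), se = sqrt(v))
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' Pools contrast tables with the Mantel-Haenszel weighting
#' `OR = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`; the confidence interval
#' uses the Robins-Breslow-Greenland variance of the log pooled OR.  Cells
#' are used as supplied: pass continuity-corrected cells only for studies
#' that contain zeros.
#'
#' @param tables a list of [build_contrast()] tables (inestimable ones are
#'   dropped), or a data.frame with columns `exposed_cases`,
#'   `unexposed_cases`, `exposed_controls`, `unexposed_controls`.
#' @param conf_level confidence level.
#' @return List with `log_or`, `se`, `or`, `ci_low`, `ci_high`, `z`,
#'   `p_value`, `k`.
#' @export
pool_fixed_mh <- function(tables, conf_level = 0.95) {
  if (is.data.frame(tables)) {
    cells <- tables
  } else {
    tables <- Filter(function(t) t$estimable, tables)
    if (length(tables) == 0L)
      stop("no estimable tables to pool", call. = FALSE)
    cells <- do.call(rbind, lapply(tables, function(t)
      data.frame(exposed_cases = t$exposed_cases,
                 unexposed_cases = t$unexposed_cases,
                 exposed_controls = t$exposed_controls,
                 unexposed_controls = t$unexposed_controls)))
  }
  if (nrow(cells) == 0L) stop("no estimable tables to pool", call. = FALSE)
  mh <- mh_log_or(cells$exposed_cases, cells$unexposed_cases,
                  cells$exposed_controls, cells$unexposed_controls)
  finish_pool(mh$log_or, mh$se, k = nrow(cells), conf_level = conf_level,
              effects_model = "fixed_mh")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance pooling with weights `1/(se_i^2 + tau2)`, `tau2` the
#' DerSimonian-Laird moment estimate from [heterogeneity_stats()].
#'
#' @inheritParams heterogeneity_stats
#' @param conf_level confidence level.
#' @return List as in [pool_fixed_mh()] plus `tau_squared`.
#' @export
pool_random_dl <- function(yi, sei, conf_level = 0.95) {
  k <- length(yi)
  if (k < 2L)
    stop("random-effects pooling requires at least two studies",
         call. = FALSE)
  het <- heterogeneity_stats(yi, sei)
  w <- 1 / (sei^2 + het$tau_squared)
  theta <- sum(w * yi) / sum(w)
  se <- 1 / sqrt(sum(w))
  out <- finish_pool(theta, se, k = k, conf_level = conf_level,
                     effects_model = "random_dl")
  out$tau_squared <- het$tau_squared
  out
}

# internal: wrap a pooled log OR + se into the common result fields
finish_pool <- function(log_or, se, k, conf_level, effects_model) {
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- log_or / se
  list(log_or = log_or, se = se,
       or = exp(log_or),
       ci_low = exp(log_or - zc * se), ci_high = exp(log_or + zc * se),
       z = z, p_value = 2 * stats::pnorm(-abs(z)),
       k = k, effects_model = effects_model, conf_level = conf_level)
}

#' Pool a genetic-model contrast over a study collection
#'
#' The central fitting function.  For every study the genotype counts are
#' collapsed into the 2x2 table of the chosen genetic model; studies whose
#' contrast column is empty in both arms are excluded (they carry no
#' information about the contrast); tables with a remaining zero cell
#' receive a continuity correction of `correction` added to all four cells.
#' Inverse-variance heterogeneity statistics are computed on the per-study
#' log odds ratios, the pooling model is chosen by [select_model()] (random
#' effects when `P_h < 0.10` or `I2 > 50` percent), and the pooled odds
#' ratio, confidence interval and two-sided p-value are returned.
#'
#' Under the fixed-effect model the pooled estimate is Mantel-Haenszel with
#' the Robins-Breslow-Greenland variance (corrected cells only in studies
#' with zeros); under random effects it is DerSimonian-Laird on the
#' corrected per-study effects.
#'
#' @param dataset a [study_dataset()].
#' @param model one of [genetic_models()].
#' @param subset optional predicate over the study columns (as in
#'   [subset_studies()]) restricting the analysis stratum.
#' @param method `"auto"` applies the heterogeneity rule; `"fixed"` or
#'   `"random"` force a model.
#' @param correction continuity-correction increment.
#' @param conf_level confidence level of the interval.
#' @return An object of class `"meta_or"`; see Details.  Key components:
#'   `pooled` (or/ci/z/p), `het` (Q, df, p, I2, tau2), `effects_model`,
#'   `k`, `excluded_ids`, and a per-study data.frame `studies` with the
#'   corrected cells, `log_or` and `se`.
#' @examples
#' ds <- load_bundled_dataset("4b/a")
#' fit <- meta_or(ds, model = "recessive")
#' fit
#' coef(fit)
#' @export
meta_or <- function(dataset, model = "allele", subset = NULL,
                    method = c("auto", "fixed", "random"),
                    correction = 0.5, conf_level = 0.95) {
  stopifnot(inherits(dataset, "study_dataset"))
  method <- match.arg(method)
  model <- match.arg(model, genetic_models())
  e <- substitute(subset)
  if (!is.null(e)) {
    keep <- eval(e, dataset$studies, parent.frame())
    if (is.null(keep)) keep <- rep(TRUE, nrow(dataset$studies))
    keep[is.na(keep)] <- FALSE
    dataset <- subset_studies_lgl(dataset, keep)
  }
  if (nrow(dataset$studies) == 0L)
    stop("no studies in the requested stratum", call. = FALSE)

  ce <- contrast_effects(dataset$studies, model, correction = correction)
  excluded <- ce$study_id[!ce$estimable]
  use <- ce$estimable
  k <- sum(use)
  if (k < 1L)
    stop("no estimable studies for the ", model, " contrast", call. = FALSE)

  yi <- ce$yi[use]; sei <- ce$sei[use]
  cc <- ce$cc[use, , drop = FALSE]
  single <- k == 1L

  if (single) {
    het <- list(q_stat = NA_real_, df = 0L, p_heterogeneity = NA_real_,
                i_squared = NA_real_, tau_squared = 0)
    pooled <- finish_pool(yi, sei, k = 1L, conf_level = conf_level,
                          effects_model = "fixed_mh")
  } else {
    het <- heterogeneity_stats(yi, sei)
    chosen <- switch(method,
      auto = select_model(het$p_heterogeneity, het$i_squared),
      fixed = "fixed_mh",
      random = "random_dl")
    pooled <- if (chosen == "random_dl") {
      pool_random_dl(yi, sei, conf_level = conf_level)
    } else {
      pool_fixed_mh(cc, conf_level = conf_level)
    }
  }

  per_study <- data.frame(study_id = ce$study_id[use], cc,
                          corrected = ce$corrected[use],
                          log_or = yi, se = sei,
                          or = exp(yi),
                          ci_low = exp(yi - stats::qnorm(0.975) * sei),
                          ci_high = exp(yi + stats::qnorm(0.975) * sei))
  structure(list(call = match.call(),
                 polymorphism = dataset$polymorphism,
                 model = model, method = method,
                 effects_model = pooled$effects_model,
                 k = k, excluded_ids = excluded,
                 single_study = single,
                 pooled = pooled, het = het,
                 studies = per_study,
                 dataset = dataset,
                 correction = correction, conf_level = conf_level),
            class = "meta_or")
}

contrast_label <- function(x) {
  p <- x$polymorphism
  r <- p$ref_allele; e <- p$eff_allele
  switch(x$model,
    hybrid = sprintf("%s%s vs %s%s", r, e, r, r),
    homozygous = sprintf("%s%s vs %s%s", e, e, r, r),
    dominant = sprintf("%s%s+%s%s vs %s%s", r, e, e, e, r, r),
    recessive = sprintf("%s%s vs %s%s+%s%s", e, e, r, r, r, e),
    allele = sprintf("%s vs %s", e, r))
}

#' @export
print.meta_or <- function(x, digits = 3, ...) {
  cat(sprintf("Genetic-association meta-analysis: %s, %s model (%s)\n",
              x$polymorphism$name, x$model, contrast_label(x)))
  cat(sprintf("  k = %d studies pooled%s\n", x$k,
              if (length(x$excluded_ids))
                sprintf(" (%d excluded: %s)", length(x$excluded_ids),
                        paste(x$excluded_ids, collapse = ", "))
              else ""))
  if (x$single_study) {
    cat("  single study: pooled values are that study's own estimate\n")
  } else {
    cat(sprintf("  heterogeneity: Q = %.*f (df = %d, P = %.3g), I2 = %.1f%%, tau2 = %.4f\n",
                digits, x$het$q_stat, x$het$df, x$het$p_heterogeneity,
                x$het$i_squared, x$het$tau_squared))
  }
  cat(sprintf("  model: %s\n",
              c(fixed_mh = "fixed effect (Mantel-Haenszel)",
                random_dl = "random effects (DerSimonian-Laird)")[x$effects_model]))
  p <- x$pooled
  cat(sprintf("  OR = %.2f (%d%% CI %.2f-%.2f), Z = %.2f, P = %.3g\n",
              p$or, round(100 * x$conf_level), p$ci_low, p$ci_high,
              p$z, p$p_value))
  invisible(x)
}

#' @export
summary.meta_or <- function(object, ...) {
  structure(list(fit = object), class = "summary.meta_or")
}

#' @export
print.summary.meta_or <- function(x, ...) {
  print(x$fit)
  cat("\nPer-study estimates:\n")
  s <- x$fit$studies
  out <- data.frame(study = s$study_id,
                    OR = round(s$or, 3),
                    ci_low = round(s$ci_low, 3),
                    ci_high = round(s$ci_high, 3),
                    corrected = s$corrected)
  print(out, row.names = FALSE)
  invisible(x)
}

#' @export
coef.meta_or <- function(object, ...) {
  c(log_or = object$pooled$log_or)
}

#' @export
confint.meta_or <- function(object, parm, level = NULL, ...) {
  zc <- stats::qnorm(1 - (1 - (level %||% object$conf_level)) / 2)
  p <- object$pooled
  m <- matrix(exp(p$log_or + c(-1, 1) * zc * p$se), 1, 2,
              dimnames = list("OR", c("lower", "upper")))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forest plot of a fitted contrast
#'
#' @param x a [meta_or()] fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.meta_or <- function(x, ...) {
  s <- x$studies
  k <- nrow(s)
  ylim <- c(0, k + 2)
  xr <- range(c(s$ci_low, s$ci_high, x$pooled$ci_low, x$pooled$ci_high, 1))
  graphics::plot(NA, xlim = log(xr), ylim = ylim, yaxt = "n",
                 xlab = "odds ratio (log scale)", ylab = "",
                 main = sprintf("%s: %s", x$polymorphism$name,
                                contrast_label(x)), xaxt = "n", ...)
  at <- pretty(xr, n = 6); at <- at[at > 0]
  graphics::axis(1, at = log(at), labels = at)
  graphics::abline(v = 0, lty = 3)
  ys <- rev(seq_len(k)) + 1
  graphics::segments(log(s$ci_low), ys, log(s$ci_high), ys)
  graphics::points(log(s$or), ys, pch = 15,
                   cex = 0.6 + 0.8 * (1 / s$se) / max(1 / s$se))
  graphics::axis(2, at = ys, labels = s$study_id, las = 1, cex.axis = 0.6)
  p <- x$pooled
  graphics::polygon(log(c(p$ci_low, p$or, p$ci_high, p$or)),
                    c(0.5, 0.8, 0.5, 0.2), col = "grey40")
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the pooled contrast omitting one study at a time and flags
#' omissions that flip statistical significance at the 0.05 level relative
#' to the full fit.
#'
#' @param fit a [meta_or()] fit with at least three pooled studies.
#' @return A data.frame with one row per omitted study: pooled `or`,
#'   `ci_low`, `ci_high`, `p_value`, `effects_model`, `significant`, and
#'   `flips_significance`.
#' @export
leave_one_out <- function(fit) {
  stopifnot(inherits(fit, "meta_or"))
  if (fit$k < 3L)
    stop("leave-one-out requires at least three pooled studies",
         call. = FALSE)
  full_sig <- fit$pooled$p_value < 0.05
  ids <- fit$studies$study_id
  rows <- lapply(ids, function(id) {
    ds <- subset_studies_lgl(fit$dataset, fit$dataset$studies$study_id != id)
    f <- meta_or(ds, model = fit$model, method = fit$method,
                 correction = fit$correction, conf_level = fit$conf_level)
    data.frame(omitted = id, or = f$pooled$or, ci_low = f$pooled$ci_low,
               ci_high = f$pooled$ci_high, p_value = f$pooled$p_value,
               effects_model = f$effects_model,
               significant = f$pooled$p_value < 0.05)
  })
  out <- do.call(rbind, rows)
  out$flips_significance <- out$significant != full_sig
  out
}

#' Random-effects meta-regression on a study-level covariate
#'
#' Univariate mixed-effects meta-regression of the per-study log odds
#' ratios on a study covariate, with residual between-study variance
#' estimated by REML and normal (Wald) tests of the slope.  The model
#' fitting is delegated to [metafor::rma()].
#'
#' @param dataset a [study_dataset()].
#' @param model one of [genetic_models()].
#' @param covariate name of a study column (`"ethnicity"`,
#'   `"control_type"`, `"matching"`, `"nos_score"`, `"year"`), or the
#'   derived flags `"hwe"` (controls in Hardy-Weinberg equilibrium) and
#'   `"quality"` (high-quality study).
#' @param correction continuity-correction increment.
#' @param hwe_alpha,quality_threshold passed to [assign_quality()] for the
#'   derived covariates.
#' @return An object of class `"meta_regress"`: data.frame of coefficients
#'   (`estimate`, `se`, `z`, `p_value`) with `tau2_residual` and the
#'   underlying metafor fit as attributes.
#' @export
meta_regress <- function(dataset, model, covariate, correction = 0.5,
                         hwe_alpha = 0.05, quality_threshold = 8) {
  stopifnot(inherits(dataset, "study_dataset"))
  model <- match.arg(model, genetic_models())
  ce <- contrast_effects(dataset$studies, model, correction = correction)
  use <- ce$estimable
  s <- dataset$studies[use, , drop = FALSE]
  x <- if (covariate %in% c("hwe", "quality")) {
    flags <- assign_quality(dataset, hwe_alpha = hwe_alpha,
                            quality_threshold = quality_threshold)[use, ]
    if (covariate == "hwe") flags$in_hwe else flags$high_quality
  } else if (covariate %in% names(s)) {
    s[[covariate]]
  } else stop("unknown covariate: ", covariate, call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("covariate '", covariate, "' is constant across studies ",
         "(singular design)", call. = FALSE)
  if (is.character(x)) x <- factor(x)
  fit <- metafor::rma(yi = ce$yi[use], sei = ce$sei[use], mods = ~x,
                      method = "REML", test = "z")
  coefs <- data.frame(term = rownames(fit$beta),
                      estimate = as.numeric(fit$beta),
                      se = fit$se, z = fit$zval, p_value = fit$pval)
  coefs$term <- sub("^x", covariate, coefs$term)
  structure(coefs, tau2_residual = fit$tau2, covariate = covariate,
            rma = fit, class = c("meta_regress", "data.frame"))
}

#' @export
print.meta_regress <- function(x, ...) {
  cat("Random-effects meta-regression on", attr(x, "covariate"), "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("Residual tau2 (REML): %.4f\n", attr(x, "tau2_residual")))
  invisible(x)
}
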