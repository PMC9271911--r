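# Publication-bias diagnostics: Egger regression, Begg rank correlation,
# Duval-Tweedie trim-and-fill.

# internal: accept a meta_or fit or raw yi/sei
effects_from <- function(object, sei = NULL) {
  if (inherits(object, "meta_or")) {
    list(yi = object$studies$log_or, sei = object$studies$se)
  } else {
    stopifnot(is.numeric(object), is.numeric(sei),
              length(object) == length(sei), all(sei > 0))
    list(yi = as.numeric(object), sei = as.numeric(sei))
  }
}

#' Egger's regression test for funnel-plot asymmetry
#'
#' Regresses the standardized effect `y_i / se_i` on the precision
#' `1 / se_i` by ordinary least squares; the intercept measures small-study
#' asymmetry and is tested against zero with a Student-t reference on
#' `k - 2` degrees of freedom (two-sided).
#'
#' @param object a [meta_or()] fit, or a numeric vector of per-study log
#'   odds ratios.
#' @param sei per-study standard errors (when `object` is numeric).
#' @return An object of class `"htest"` with the intercept (`estimate`),
#'   its standard error, `statistic` (t) and `p.value`.
#' @export
egger_test <- function(object, sei = NULL) {
  e <- effects_from(object, sei)
  k <- length(e$yi)
  if (k < 3L) stop("Egger's test requires at least three studies",
                   call. = FALSE)
  fit <- stats::lm(I(e$yi / e$sei) ~ I(1 / e$sei))
  sm <- summary(fit)$coefficients
  t_stat <- sm[1L, 3L]
  structure(list(statistic = c(t = t_stat),
                 parameter = c(df = k - 2L),
                 p.value = 2 * stats::pt(-abs(t_stat), df = k - 2L),
                 estimate = c(intercept = sm[1L, 1L]),
                 stderr = sm[1L, 2L],
                 method = "Egger's regression test for funnel-plot asymmetry",
                 data.name = sprintf("%d study effects", k),
                 alternative = "two.sided"),
            class = "htest")
}

#' Begg's rank correlation test for publication bias
#'
#' Kendall rank correlation between the standardized deviates
#' `(y_i - ybar_fixed) / sqrt(v_i - v_bar)` and the sampling variances,
#' where `ybar_fixed` is the inverse-variance fixed-effect estimate and
#' `v_bar` its variance.  The tie-corrected normal approximation with
#' continuity correction gives the p-value.
#'
#' @inheritParams egger_test
#' @return An `"htest"` with Kendall's tau (`estimate`), `statistic` (z)
#'   and `p.value`.
#' @export
begg_test <- function(object, sei = NULL) {
  e <- effects_from(object, sei)
  k <- length(e$yi)
  if (k < 3L) stop("Begg's test requires at least three studies",
                   call. = FALSE)
  vi <- e$sei^2
  w <- 1 / vi
  ybar <- sum(w * e$yi) / sum(w)
  vstar <- pmax(vi - 1 / sum(w), .Machine$double.eps)
  u <- (e$yi - ybar) / sqrt(vstar)
  # concordant/discordant pairs against vi
  conc <- 0L; disc <- 0L
  for (i in seq_len(k - 1L)) {
    du <- u[(i + 1L):k] - u[i]
    dv <- vi[(i + 1L):k] - vi[i]
    s <- sign(du) * sign(dv)
    conc <- conc + sum(s > 0)
    disc <- disc + sum(s < 0)
  }
  npairs <- k * (k - 1) / 2
  tau <- (conc - disc) / npairs
  v_s <- k * (k - 1) * (2 * k + 5) / 18  # null variance of Kendall's S
  s_stat <- conc - disc
  z <- if (s_stat == 0) 0 else (s_stat - sign(s_stat)) / sqrt(v_s)
  structure(list(statistic = c(z = z),
                 p.value = 2 * stats::pnorm(-abs(z)),
                 estimate = c(tau = tau),
                 method = "Begg's rank correlation test for publication bias",
                 data.name = sprintf("%d study effects", k),
                 alternative = "two.sided"),
            class = "htest")
}

#' Duval-Tweedie trim-and-fill
#'
#' Estimates the number of studies suppressed from one side of the funnel
#' with the iterative L0 ("linear") estimator: center the effects at the
#' inverse-variance fixed-effect estimate, rank the absolute deviations,
#' estimate the number of asymmetric extreme studies `k0`, trim them,
#' re-center and repeat until `k0` stabilizes.  The trimmed-away studies
#' are then mirrored across the final center ("filled"), and the filled set
#' is re-pooled under the heterogeneity-selected model.
#'
#' @inheritParams egger_test
#' @param side funnel side on which studies are presumed missing:
#'   `"auto"` (chosen by the sign of Egger's intercept — a positive
#'   intercept means small studies push estimates up, so studies are
#'   missing on the `"left"`), `"left"` or `"right"`.
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param maxiter iteration cap.
#' @return An object of class `"trimfill"`: `k0`, `side`, `filled_yi`,
#'   `filled_sei` (the imputed studies only), `adjusted` (pooled result on
#'   observed + filled effects, as in [pool_random_dl()]), and the
#'   unadjusted pooled result.
#' @export
trim_and_fill <- function(object, sei = NULL, side = c("auto", "left",
                                                       "right"),
                          estimator = c("L0", "R0"), maxiter = 50L) {
  e <- effects_from(object, sei)
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  yi <- e$yi; sei <- e$sei
  k <- length(yi)
  if (k < 3L) stop("trim-and-fill requires at least three studies",
                   call. = FALSE)
  if (side == "auto") {
    side <- if (egger_test(yi, sei)$estimate >= 0) "left" else "right"
  }
  # work on the scale where missing studies are on the LEFT: flip for right
  flip <- if (side == "right") -1 else 1
  y <- flip * yi
  vi <- sei^2
  w <- 1 / vi

  k0 <- 0L
  for (it in seq_len(maxiter + 1L)) {
    if (it > maxiter)
      stop("trim-and-fill failed to converge after ", maxiter,
           " iterations (last k0 = ", k0, ")", call. = FALSE)
    use <- order(y)[seq_len(k - k0)]   # trim the k0 largest values
    mu <- sum(w[use] * y[use]) / sum(w[use])
    dev <- y - mu
    r <- rank(abs(dev), ties.method = "average")
    if (estimator == "L0") {
      s_pos <- sum(r[dev > 0])
      k0_new <- max(0, round((4 * s_pos - k * (k + 1)) / (2 * k - 1)))
    } else {  # R0: rightmost run of positive deviations
      ord <- order(abs(dev), decreasing = TRUE)
      run <- 0L
      for (j in ord) { if (dev[j] > 0) run <- run + 1L else break }
      k0_new <- max(0L, run - 1L)
    }
    k0_new <- min(k0_new, k - 2L)
    if (k0_new == k0) break
    k0 <- k0_new
  }

  if (k0 > 0L) {
    idx <- order(y, decreasing = TRUE)[seq_len(k0)]
    fill_y <- flip * (2 * mu - y[idx])
    fill_se <- sei[idx]
  } else {
    fill_y <- numeric(0)
    fill_se <- numeric(0)
  }
  all_y <- c(yi, fill_y)
  all_se <- c(sei, fill_se)
  het <- heterogeneity_stats(all_y, all_se)
  adj <- if (select_model(het$p_heterogeneity, het$i_squared) ==
             "random_dl") {
    pool_random_dl(all_y, all_se)
  } else {
    w2 <- 1 / all_se^2
    finish_pool(sum(w2 * all_y) / sum(w2), 1 / sqrt(sum(w2)),
                k = length(all_y), conf_level = 0.95,
                effects_model = "fixed_iv")
  }
  unadj_het <- heterogeneity_stats(yi, sei)
  unadj <- if (select_model(unadj_het$p_heterogeneity,
                            unadj_het$i_squared) == "random_dl") {
    pool_random_dl(yi, sei)
  } else {
    w2 <- 1 / sei^2
    finish_pool(sum(w2 * yi) / sum(w2), 1 / sqrt(sum(w2)),
                k = k, conf_level = 0.95, effects_model = "fixed_iv")
  }
  structure(list(k0 = as.integer(k0), side = side, estimator = estimator,
                 filled_yi = fill_y, filled_sei = fill_se,
                 yi = yi, sei = sei,
                 adjusted = adj, unadjusted = unadj),
            class = "trimfill")
}

#' @export
print.trimfill <- function(x, ...) {
  cat(sprintf("Trim-and-fill (%s estimator): %d imputed studies on the %s side\n",
              x$estimator, x$k0, x$side))
  cat(sprintf("  unadjusted OR = %.2f (%.2f-%.2f)\n",
              x$unadjusted$or, x$unadjusted$ci_low, x$unadjusted$ci_high))
  cat(sprintf("  adjusted   OR = %.2f (%.2f-%.2f), k = %d\n",
              x$adjusted$or, x$adjusted$ci_low, x$adjusted$ci_high,
              x$adjusted$k))
  invisible(x)
}

#' Funnel-plot data for a fitted contrast
#'
#' Per-study log odds ratios and standard errors plus the pseudo 95 percent
#' confidence guide lines around the fixed-effect center, suitable for a
#' funnel plot; filled (imputed) studies from [trim_and_fill()] can be
#' appended by the caller.
#'
#' @param fit a [meta_or()] fit.
#' @return A list with `points` (data.frame `study_id`, `log_or`, `se`)
#'   and `center` (fixed-effect log OR).
#' @export
funnel_data <- function(fit) {
  stopifnot(inherits(fit, "meta_or"))
  w <- 1 / fit$studies$se^2
  list(points = data.frame(study_id = fit$studies$study_id,
                           log_or = fit$studies$log_or,
                           se = fit$studies$se),
       center = sum(w * fit$studies$log_or) / sum(w))
}
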