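# Trial sequential analysis: diversity-adjusted required information size,
# O'Brien-Fleming alpha-spending monitoring boundaries (group-sequential
# recursion), cumulative Z-curve.

#' O'Brien-Fleming-type alpha-spending function
#'
#' Cumulative two-sided type-I error spent by information fraction `t`:
#' `alpha*(t) = 2 * (1 - pnorm(qnorm(1 - alpha/2) / sqrt(t)))`.
#' Spends almost nothing early and exactly `alpha` at `t = 1`.
#'
#' @param t information fraction(s) in `(0, 1]`.
#' @param alpha total two-sided level.
#' @return Cumulative alpha spent at each `t`.
#' @export
of_spending <- function(t, alpha = 0.05) {
  if (any(t <= 0)) stop("information fraction must be positive",
                        call. = FALSE)
  t <- pmin(t, 1)
  2 * (1 - stats::pnorm(stats::qnorm(1 - alpha / 2) / sqrt(t)))
}

#' Group-sequential monitoring boundaries for an alpha-spending function
#'
#' Solves the symmetric two-sided monitoring boundary at each interim look
#' so that the cumulative boundary-crossing probability under the null
#' equals the spending function at that look's information fraction.  The
#' joint law of the sequential Z statistics (Brownian motion observed at
#' the look fractions) is propagated by numerical integration: the score
#' process density, restricted to the continuation region, is advanced one
#' Gaussian increment per look on a trapezoid grid, and each boundary is
#' found by bisection.
#'
#' @param fractions strictly increasing information fractions in `(0, 1]`.
#' @param alpha total two-sided level.
#' @param spending spending function `f(t, alpha)`; defaults to
#'   [of_spending()].
#' @param grid_points grid resolution for the density recursion.
#' @param tol bisection tolerance on the boundary (z scale).
#' @return Numeric vector of boundary z values, one per look.
#' @examples
#' monitoring_boundaries(1)           # single look: 1.959964
#' monitoring_boundaries(c(0.5, 1))   # O'Brien-Fleming-like pair
#' @export
monitoring_boundaries <- function(fractions, alpha = 0.05,
                                  spending = of_spending,
                                  grid_points = 4001L, tol = 1e-8) {
  m <- length(fractions)
  if (m == 0L) return(numeric(0))
  if (any(diff(fractions) <= 0))
    stop("information fractions must be strictly increasing", call. = FALSE)
  if (any(fractions <= 0) || any(fractions > 1 + 1e-12))
    stop("information fractions must lie in (0, 1]", call. = FALSE)
  spend <- spending(fractions, alpha)
  zmax <- 8  # standard units; crossing beyond is negligible

  bounds <- numeric(m)
  grid_x <- NULL   # score-scale grid of the continuation density
  dens <- NULL

  for (k in seq_len(m)) {
    t_k <- fractions[k]
    incr <- spend[k] - if (k == 1L) 0 else spend[k - 1L]
    sd_inc <- sqrt(t_k - if (k == 1L) 0 else fractions[k - 1L])

    # exit probability at this look for a candidate score bound c
    exit_prob <- function(c_score) {
      if (k == 1L) {
        2 * stats::pnorm(-c_score / sd_inc)
      } else {
        tails <- stats::pnorm((-c_score - grid_x) / sd_inc) +
          stats::pnorm((grid_x - c_score) / sd_inc)
        trap_int(grid_x, dens * tails)
      }
    }

    if (incr <= 1e-14) {
      bounds[k] <- zmax
    } else {
      lo <- 0; hi <- zmax * sqrt(t_k)
      while (hi - lo > tol * sqrt(t_k)) {
        mid <- (lo + hi) / 2
        if (exit_prob(mid) > incr) lo <- mid else hi <- mid
      }
      bounds[k] <- (lo + hi) / 2 / sqrt(t_k)
    }
    c_k <- min(bounds[k], zmax) * sqrt(t_k)

    # advance the continuation density to this look's grid
    new_x <- seq(-c_k, c_k, length.out = grid_points)
    if (k == 1L) {
      new_d <- stats::dnorm(new_x / sd_inc) / sd_inc
    } else {
      ker <- stats::dnorm(outer(new_x, grid_x, "-") / sd_inc) / sd_inc
      w <- trap_weights(grid_x)
      new_d <- as.numeric(ker %*% (w * dens))
    }
    grid_x <- new_x
    dens <- new_d
  }
  bounds
}

# trapezoid helpers on a (possibly non-uniform) grid
trap_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}
trap_int <- function(x, y) sum(trap_weights(x) * y)

#' Diversity (D-squared) of a meta-analysis
#'
#' `D2 = (vR - vF) / vR`, where `vF` and `vR` are the variances of the
#' fixed-effect (inverse-variance) and DerSimonian-Laird random-effects
#' pooled estimates.  Zero when `tau2 = 0`; approaches 1 as between-study
#' variance dominates.  Used to inflate the required information size.
#'
#' @inheritParams heterogeneity_stats
#' @return D-squared in `[0, 1)`.
#' @export
diversity_d2 <- function(yi, sei) {
  if (length(yi) < 2L)
    stop("diversity requires at least two studies", call. = FALSE)
  het <- heterogeneity_stats(yi, sei)
  v_f <- 1 / sum(1 / sei^2)
  v_r <- 1 / sum(1 / (sei^2 + het$tau_squared))
  max(0, (v_r - v_f) / v_r)
}

#' Diversity-adjusted required information size
#'
#' Sample size (cases + controls) needed by a two-sided level-`alpha` test
#' with power `1 - beta` to detect a relative risk reduction `rrr` of the
#' control event proportion, inflated by `1/(1 - d_squared)` for
#' between-study diversity:
#' `RIS = ceil( 4 * (z_{1-a/2} + z_{1-b})^2 * pbar*(1-pbar) / delta^2
#'              / (1 - D2) )`
#' with `p_exp = p_control*(1-rrr)`, `delta = p_control - p_exp` and
#' `pbar` their mean.
#'
#' @param p_control event proportion in the control group.
#' @param rrr relative risk reduction the analysis should detect.
#' @param alpha,beta type-I and type-II error rates.
#' @param d_squared diversity from [diversity_d2()].
#' @return Required information size (integer).
#' @export
required_information_size <- function(p_control, rrr = 0.15, alpha = 0.05,
                                      beta = 0.2, d_squared = 0) {
  stopifnot(p_control > 0, p_control < 1, d_squared >= 0, d_squared < 1)
  p_exp <- p_control * (1 - rrr)
  delta <- p_control - p_exp
  if (delta == 0) stop("null alternative: delta = 0", call. = FALSE)
  pbar <- (p_control + p_exp) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(1 - beta)
  as.integer(ceiling(4 * (za + zb)^2 * pbar * (1 - pbar) / delta^2 /
                       (1 - d_squared)))
}

#' Trial sequential analysis of a genetic-model contrast
#'
#' Orders the studies chronologically (publication year when available,
#' ties and missing years by table order), pools the accumulating set at
#' each step under the heterogeneity-selected model, and compares the
#' cumulative Z-curve with O'Brien-Fleming alpha-spending monitoring
#' boundaries evaluated at the accrued fraction of the diversity-adjusted
#' required information size.  Information is counted as cumulative
#' participants (cases + controls); the event proportion for the sizing is
#' the pooled control-arm exposure fraction of the analyzed contrast (for
#' the dominant model, the effect-allele carrier fraction among controls).
#'
#' An approximate futility (beta-spending) bound of O'Brien-Fleming type is
#' reported alongside: `max(0, drift*sqrt(t) - z_{1-beta*(t)})` with drift
#' `z_{1-alpha/2} + z_{1-beta}` at full information.
#'
#' @param dataset a [study_dataset()].
#' @param model one of [genetic_models()]; the dominant contrast is the
#'   conventional choice for a trial sequential analysis of carriers.
#' @param alpha,beta,rrr design parameters (two-sided alpha; power
#'   `1 - beta`; relative risk reduction).
#' @param correction continuity-correction increment.
#' @param grid_points resolution passed to [monitoring_boundaries()].
#' @return An object of class `"tsa"`: `d_squared`, `ris`, `p_control`,
#'   and a per-look data.frame `looks` with `study_id`, `accrued`,
#'   `fraction`, `z`, `boundary`, `futility`; plus the flags
#'   `crossed_boundary` and `reached_ris`.
#' @examples
#' \donttest{
#' tsa_fit <- tsa(load_bundled_dataset("4b/a"), model = "dominant")
#' tsa_fit
#' }
#' @export
tsa <- function(dataset, model = "dominant", alpha = 0.05, beta = 0.2,
                rrr = 0.15, correction = 0.5, grid_points = 4001L) {
  stopifnot(inherits(dataset, "study_dataset"))
  model <- match.arg(model, genetic_models())
  s <- dataset$studies
  if (!all(is.na(s$year))) {
    s <- s[order(s$year, s$study_id, na.last = TRUE), , drop = FALSE]
  }
  ce <- contrast_effects(s, model, correction = correction)
  use <- ce$estimable
  s <- s[use, , drop = FALSE]
  yi <- ce$yi[use]; sei <- ce$sei[use]
  cells <- ce$cells[use, , drop = FALSE]
  k <- length(yi)
  if (k < 2L) stop("trial sequential analysis needs at least two ",
                   "estimable studies", call. = FALSE)

  d2 <- diversity_d2(yi, sei)
  p_control <- sum(cells$exposed_controls) /
    sum(cells$exposed_controls + cells$unexposed_controls)
  ris <- required_information_size(p_control, rrr = rrr, alpha = alpha,
                                   beta = beta, d_squared = d2)
  accrued <- cumsum(s$n_cases + s$n_controls)

  look_idx <- 2:k
  z <- vapply(look_idx, function(i) {
    het <- heterogeneity_stats(yi[1:i], sei[1:i])
    if (select_model(het$p_heterogeneity, het$i_squared) == "random_dl") {
      pool_random_dl(yi[1:i], sei[1:i])$z
    } else {
      w <- 1 / sei[1:i]^2
      (sum(w * yi[1:i]) / sum(w)) * sqrt(sum(w))
    }
  }, numeric(1))

  frac <- pmin(accrued[look_idx] / ris, 1)
  # boundaries are computed on the strictly increasing prefix of fractions
  # (once full information is reached the boundary stays at its final value)
  inc <- frac
  first_full <- match(TRUE, inc >= 1)
  if (!is.na(first_full) && first_full < length(inc)) {
    keep <- seq_len(first_full)
  } else keep <- seq_along(inc)
  b_inc <- monitoring_boundaries(inc[keep], alpha = alpha,
                                 grid_points = grid_points)
  boundary <- c(b_inc, rep(b_inc[length(b_inc)],
                           length(inc) - length(keep)))

  drift <- stats::qnorm(1 - alpha / 2) + stats::qnorm(1 - beta)
  beta_spent <- pmin(2 - 2 * stats::pnorm(stats::qnorm(1 - beta / 2) /
                                            sqrt(frac)), beta)
  futility <- pmax(0, drift * sqrt(frac) -
                     stats::qnorm(1 - pmax(beta_spent, 1e-12)))
  futility <- pmin(futility, boundary)

  looks <- data.frame(study_id = s$study_id[look_idx],
                      accrued = accrued[look_idx],
                      fraction = frac, z = z,
                      boundary = boundary, futility = futility)
  structure(list(polymorphism = dataset$polymorphism, model = model,
                 alpha = alpha, beta = beta, rrr = rrr,
                 d_squared = d2, p_control = p_control, ris = ris,
                 looks = looks,
                 crossed_boundary = any(abs(z) >= boundary),
                 reached_ris = max(accrued) >= ris,
                 final_z = z[length(z)]),
            class = "tsa")
}

#' @export
print.tsa <- function(x, ...) {
  cat(sprintf("Trial sequential analysis: %s, %s model\n",
              x$polymorphism$name, x$model))
  cat(sprintf("  D2 = %.3f, control event proportion = %.3f\n",
              x$d_squared, x$p_control))
  cat(sprintf("  required information size = %s; accrued = %s (%s)\n",
              format(x$ris, big.mark = ","),
              format(max(x$looks$accrued), big.mark = ","),
              if (x$reached_ris) "RIS reached" else "RIS not reached"))
  cat(sprintf("  final Z = %.2f; monitoring boundary %s\n", x$final_z,
              if (x$crossed_boundary) "crossed" else "not crossed"))
  invisible(x)
}

#' Z-curve plot of a trial sequential analysis
#'
#' @param x a [tsa()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tsa <- function(x, ...) {
  l <- x$looks
  ylim <- range(c(-l$boundary, l$boundary, l$z, -8, 8))
  graphics::plot(l$accrued, l$z, type = "b", pch = 16, ylim = ylim,
                 xlab = "accrued participants", ylab = "cumulative Z",
                 main = sprintf("TSA: %s (%s)", x$polymorphism$name,
                                x$model), ...)
  graphics::lines(l$accrued, l$boundary, lty = 2)
  graphics::lines(l$accrued, -l$boundary, lty = 2)
  graphics::lines(l$accrued, l$futility, lty = 3)
  graphics::lines(l$accrued, -l$futility, lty = 3)
  graphics::abline(h = c(-1, 1) * stats::qnorm(1 - x$alpha / 2),
                   col = "grey60")
  graphics::abline(v = x$ris, col = "grey30", lwd = 2)
  invisible(x)
}
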