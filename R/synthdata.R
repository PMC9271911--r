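# Synthetic case-control study collections with known truth, for
# statistical validation of the analysis chain.

# internal: genotype probabilities with inbreeding coefficient F
genotype_probs <- function(q, f) {
  p <- c((1 - q)^2 + f * q * (1 - q),
         2 * q * (1 - q) * (1 - f),
         q^2 + f * q * (1 - q))
  p <- pmax(p, 0)
  if (sum(p) <= 0) stop("degenerate genotype probabilities", call. = FALSE)
  p / sum(p)
}

# internal: simulate one study (assumes the per-study RNG state is set)
simulate_genotype_study_ <- function(study_index, q_control, true_or, model,
                                     tau_squared, inbreeding_f,
                                     n_case_range, n_control_range) {
  n_case <- if (n_case_range[1] == n_case_range[2]) n_case_range[1] else
    sample(n_case_range[1]:n_case_range[2], 1L)
  n_ctrl <- if (n_control_range[1] == n_control_range[2])
    n_control_range[1] else sample(n_control_range[1]:n_control_range[2], 1L)
  theta <- stats::rnorm(1L, log(true_or), sqrt(tau_squared))
  g0 <- genotype_probs(q_control, inbreeding_f)

  if (model == "allele") {
    # shift the allele odds; case genotypes keep the same inbreeding level
    odds1 <- exp(theta) * q_control / (1 - q_control)
    q1 <- odds1 / (1 + odds1)
    g1 <- genotype_probs(q1, inbreeding_f)
  } else {
    # collapse controls into exposed/unexposed classes, shift the exposure
    # odds by the study OR, and keep the control-arm genotype composition
    # within each class
    sel <- switch(model,
      hybrid = c(FALSE, TRUE, FALSE),
      homozygous = c(FALSE, FALSE, TRUE),
      dominant = c(FALSE, TRUE, TRUE),
      recessive = c(FALSE, FALSE, TRUE))
    base <- switch(model,
      hybrid = c(TRUE, FALSE, FALSE),
      homozygous = c(TRUE, FALSE, FALSE),
      dominant = c(TRUE, FALSE, FALSE),
      recessive = c(TRUE, TRUE, FALSE))
    p_exp0 <- sum(g0[sel])
    p_base0 <- sum(g0[base])
    # for hybrid/homozygous the third category is outside the contrast;
    # keep its mass fixed and shift odds within the contrast categories
    p_other <- 1 - p_exp0 - p_base0
    odds1 <- exp(theta) * p_exp0 / p_base0
    p_exp1 <- odds1 / (1 + odds1) * (1 - p_other)
    p_base1 <- (1 - p_other) - p_exp1
    g1 <- numeric(3L)
    g1[sel] <- g0[sel] / p_exp0 * p_exp1
    g1[base] <- g0[base] / p_base0 * p_base1
    g1[!(sel | base)] <- g0[!(sel | base)]
  }
  case <- as.integer(stats::rmultinom(1L, n_case, g1))
  ctrl <- as.integer(stats::rmultinom(1L, n_ctrl, g0))
  data.frame(study_id = sprintf("sim%03d", study_index),
             year = 2000L + study_index,
             ethnicity = "mixed", control_type = "healthy",
             matching = "age_and_sex",
             n_cases = n_case, n_controls = n_ctrl,
             case_ref_hom = case[1], case_het = case[2],
             case_eff_hom = case[3],
             control_ref_hom = ctrl[1], control_het = ctrl[2],
             control_eff_hom = ctrl[3],
             nos_score = 8L)
}

#' Simulate a collection of case-control genotype studies
#'
#' Generates `k` studies of a biallelic polymorphism with known truth.
#' Control genotypes follow Hardy-Weinberg proportions at effect-allele
#' frequency `q_control`, optionally distorted by an inbreeding coefficient
#' `inbreeding_f` (positive values deplete heterozygotes).  Each study
#' draws its own log odds ratio from
#' `Normal(log(true_or), tau_squared)` and applies it as an exposure-odds
#' shift on the 2-category collapse defined by the genetic model, keeping
#' the within-class genotype composition of the controls — so the target
#' contrast's odds ratio equals the study's drawn value exactly in
#' expectation.  Counts are multinomial.
#'
#' One-sided publication suppression can be emulated with the graded
#' selection rule of the publication-bias simulation literature: a study
#' significant in the positive direction (one-sided z above the upper
#' 0.025 critical value on the analyzed contrast) is always retained; a
#' positive but nonsignificant study is retained with probability
#' `1 - suppress_fraction`; a negative-direction study with probability
#' `(1 - suppress_fraction)^2`.  Suppressed studies are dropped (the
#' collection shrinks; nothing is regenerated), producing genuine funnel
#' asymmetry.
#'
#' Each study uses an RNG substream derived from `seed` and the study
#' index, so a study's counts do not depend on how many studies precede it.
#'
#' @param k number of studies to generate.
#' @param q_control effect-allele frequency in controls, in `(0, 1)`.
#' @param true_or odds ratio of the chosen contrast.
#' @param model one of [genetic_models()].
#' @param tau_squared between-study variance of the true log odds ratio.
#' @param inbreeding_f inbreeding coefficient in `[-1, 1]`.
#' @param n_case_range,n_control_range inclusive ranges for per-arm sizes.
#' @param suppress_fraction probability that a nonsignificant study is
#'   suppressed, in `[0, 1)`.
#' @param seed integer seed; the simulation is bit-reproducible given the
#'   seed.
#' @param name polymorphism label of the simulated dataset.
#' @return A [study_dataset()].
#' @examples
#' ds <- simulate_meta_dataset(k = 10, q_control = 0.3, true_or = 1.4,
#'                             model = "allele", seed = 1)
#' n_studies(ds)
#' @export
simulate_meta_dataset <- function(k, q_control, true_or = 1,
                                  model = "allele", tau_squared = 0,
                                  inbreeding_f = 0,
                                  n_case_range = c(50L, 1000L),
                                  n_control_range = c(50L, 1000L),
                                  suppress_fraction = 0, seed = NULL,
                                  name = "synthetic biallelic marker") {
  stopifnot(k >= 1, q_control > 0, q_control < 1, true_or > 0,
            tau_squared >= 0, inbreeding_f >= -1, inbreeding_f <= 1,
            suppress_fraction >= 0, suppress_fraction < 1)
  model <- match.arg(model, genetic_models())
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)

  rows <- lapply(seq_len(k), function(i) {
    set.seed((seed %% 1000003L) * 1009L + i)
    simulate_genotype_study_(i, q_control, true_or, model, tau_squared,
                             inbreeding_f, n_case_range, n_control_range)
  })
  studies <- do.call(rbind, rows)

  if (suppress_fraction > 0) {
    ce <- contrast_effects(studies, model)
    z <- ce$yi / ce$sei
    p_keep <- ifelse(z >= stats::qnorm(0.975), 1,
                     ifelse(z >= 0, 1 - suppress_fraction,
                            (1 - suppress_fraction)^2))
    set.seed((seed %% 1000003L) * 1013L + 7L)
    drop <- stats::runif(k) >= p_keep
    studies <- studies[!drop, , drop = FALSE]
    if (nrow(studies) == 0L)
      stop("all simulated studies were suppressed", call. = FALSE)
  }
  study_dataset(studies,
                polymorphism(name, "A", "B"),
                strict = TRUE)
}

#' Simulate a single genotype study
#'
#' Convenience wrapper generating one study from the same machinery as
#' [simulate_meta_dataset()]; identical parameters and the same
#' `(seed, study_index)` pair reproduce the same study regardless of
#' collection size.
#'
#' @inheritParams simulate_meta_dataset
#' @param study_index index of the study's RNG substream.
#' @return A single-row study data.frame.
#' @export
simulate_genotype_study <- function(study_index, q_control, true_or = 1,
                                    model = "allele", tau_squared = 0,
                                    inbreeding_f = 0,
                                    n_case_range = c(50L, 1000L),
                                    n_control_range = c(50L, 1000L),
                                    seed = 1L) {
  model <- match.arg(model, genetic_models())
  set.seed((as.integer(seed) %% 1000003L) * 1009L + study_index)
  simulate_genotype_study_(study_index, q_control, true_or, model,
                           tau_squared, inbreeding_f, n_case_range,
                           n_control_range)
}
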