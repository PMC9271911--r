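#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit test of genotype counts against Hardy-Weinberg
#' proportions.  The effect-allele frequency is estimated as
#' `q = (2*eff_hom + het) / (2*n)`; expected counts are `n*(1-q)^2`,
#' `2*n*q*(1-q)` and `n*q^2`; the statistic is referred to a chi-square
#' distribution with one degree of freedom (two genotype classes are free,
#' one allele frequency is estimated).
#'
#' Monomorphic samples (`q` equal to 0 or 1) fit Hardy-Weinberg proportions
#' trivially and are returned with `chi2 = 0`, `p_value = 1` and the
#' `monomorphic` flag set.
#'
#' @param ref_hom,het,eff_hom genotype counts (vectors are recycled to a
#'   common length, so a whole column of studies can be tested at once).
#' @param alpha significance level used for the `in_hwe` flag (conventionally
#'   0.05: `p > alpha` means equilibrium).
#' @return A data.frame with columns `chi2`, `p_value`, `in_hwe`,
#'   `monomorphic`.
#' @examples
#' hwe_test(0, 47, 201)    # p ~ 0.099
#' hwe_test(25, 50, 25)    # exact HW proportions: chi2 = 0, p = 1
#' @export
hwe_test <- function(ref_hom, het, eff_hom, alpha = 0.05) {
  n <- ref_hom + het + eff_hom
  if (any(is.na(n)) || any(n <= 0))
    stop("genotype counts must be present with total > 0", call. = FALSE)
  q <- (2 * eff_hom + het) / (2 * n)
  mono <- q == 0 | q == 1
  chi2 <- numeric(length(n))
  qv <- ifelse(mono, 0.5, q)  # placeholder to avoid 0/0; overwritten below
  e_rr <- n * (1 - qv)^2
  e_rh <- 2 * n * qv * (1 - qv)
  e_hh <- n * qv^2
  chi2 <- (ref_hom - e_rr)^2 / e_rr + (het - e_rh)^2 / e_rh +
    (eff_hom - e_hh)^2 / e_hh
  chi2[mono] <- 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p[mono] <- 1
  data.frame(chi2 = chi2, p_value = p, in_hwe = p > alpha,
             monomorphic = mono)
}

#' Exact Hardy-Weinberg test
#'
#' Conditional exact test (sum of probabilities of heterozygote counts no
#' more probable than the observed one, given the allele counts).  Offered
#' as an alternative to [hwe_test()]; the chi-square test is the package
#' default throughout.
#'
#' @inheritParams hwe_test
#' @return p-value.
#' @export
hwe_exact_test <- function(ref_hom, het, eff_hom) {
  stopifnot(length(ref_hom) == 1L, length(het) == 1L, length(eff_hom) == 1L)
  n <- ref_hom + het + eff_hom
  if (n <= 0) stop("total must be > 0", call. = FALSE)
  n_eff <- 2 * eff_hom + het  # minor-side allele count
  n_a <- min(n_eff, 2L * n - n_eff)
  hets <- seq(n_a %% 2L, n_a, by = 2L)
  # log probability of each heterozygote count given allele counts
  lp <- vapply(hets, function(h) {
    hom_rare <- (n_a - h) / 2
    hom_common <- n - hom_rare - h
    lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
      lgamma(hom_common + 1) + h * log(2) +
      lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1L))
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- min(het, n_a)  # het count expressed on the rare-allele side
  sum(p[p <= p[match(obs, hets)] + 1e-12])
}

#' Quality and Hardy-Weinberg flags for each study
#'
#' Computes, per study, the control-arm Hardy-Weinberg test and the quality
#' classification used by the sensitivity analyses: `high_quality` when the
#' Newcastle-Ottawa score meets `quality_threshold`, and `eligible_strict`
#' when a study is both high quality and has controls in equilibrium (the
#' "high-quality and HWE" stratum).
#'
#' The default threshold is a score of 8 or more.  (Quality-stratified
#' tables in this literature are commonly headed "quality score > 7".)
#'
#' @param dataset a [study_dataset()].
#' @param hwe_alpha significance level of the Hardy-Weinberg screen.
#' @param quality_threshold minimum Newcastle-Ottawa score counted as high
#'   quality.
#' @return A data.frame with one row per study: `study_id`, `chi2`,
#'   `hwe_p`, `in_hwe`, `monomorphic`, `high_quality`, `eligible_strict`.
#' @examples
#' flags <- assign_quality(load_bundled_dataset("4b/a"))
#' sum(flags$eligible_strict)   # 19 studies in the strict stratum
#' @export
assign_quality <- function(dataset, hwe_alpha = 0.05, quality_threshold = 8) {
  stopifnot(inherits(dataset, "study_dataset"))
  s <- dataset$studies
  hw <- hwe_test(s$control_ref_hom, s$control_het, s$control_eff_hom,
                 alpha = hwe_alpha)
  data.frame(study_id = s$study_id,
             chi2 = hw$chi2,
             hwe_p = hw$p_value,
             in_hwe = hw$in_hwe,
             monomorphic = hw$monomorphic,
             high_quality = s$nos_score >= quality_threshold,
             eligible_strict = s$nos_score >= quality_threshold & hw$in_hwe)
}
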