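# Independent brute-force oracles used across the test files.

# Pearson chi-square Hardy-Weinberg test, written out from first
# principles (expected counts from the estimated allele frequency).
oracle_hwe_p <- function(rr, rh, hh) {
  n <- rr + rh + hh
  q <- (2 * hh + rh) / (2 * n)
  if (q == 0 || q == 1) return(1)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((c(rr, rh, hh) - expected)^2 / expected)
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# DerSimonian-Laird pooling evaluated step by step.
oracle_dl <- function(yi, sei) {
  w <- 1 / sei^2
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  tau2 <- max(0, (q - (length(yi) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (sei^2 + tau2)
  list(theta = sum(ws * yi) / sum(ws), se = 1 / sqrt(sum(ws)), tau2 = tau2)
}

# Mantel-Haenszel log OR with the Robins-Breslow-Greenland variance,
# written directly from the published formula.
oracle_mh <- function(a, b, c, d) {
  n <- a + b + c + d
  R <- sum(a * d / n); S <- sum(b * c / n)
  P <- (a + d) / n; Q <- (b + c) / n
  v <- sum(P * a * d / n) / (2 * R^2) +
    sum(P * b * c / n + Q * a * d / n) / (2 * R * S) +
    sum(Q * b * c / n) / (2 * S^2)
  list(log_or = log(R / S), se = sqrt(v))
}

# Kendall concordant/discordant pair count, O(k^2).
oracle_kendall_s <- function(x, y) {
  k <- length(x); s <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
  }
  s
}

# random small meta-analysis instance on the effect scale
random_effects_instance <- function(k = NULL) {
  if (is.null(k)) k <- sample(3:10, 1)
  list(yi = rnorm(k, 0.2, 0.5), sei = runif(k, 0.1, 0.6))
}

# a small internally consistent study table for round-trip/validation tests
toy_studies <- function(k = 4) {
  set.seed(99)
  counts <- function() {
    m <- t(rmultinom(k, 200, c(0.45, 0.4, 0.15)))
    m
  }
  ca <- counts(); co <- counts()
  data.frame(study_id = paste0("s", seq_len(k)),
             year = 2000L + seq_len(k),
             ethnicity = rep(c("asian", "caucasian"), length.out = k),
             control_type = rep(c("healthy", "non_diabetic"),
                                length.out = k),
             matching = "age_and_sex",
             n_cases = rowSums(ca), n_controls = rowSums(co),
             case_ref_hom = ca[, 1], case_het = ca[, 2],
             case_eff_hom = ca[, 3],
             control_ref_hom = co[, 1], control_het = co[, 2],
             control_eff_hom = co[, 3],
             nos_score = 8L)
}

toy_dataset <- function(k = 4) {
  study_dataset(toy_studies(k), polymorphism("toy marker", "A", "B"))
}
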