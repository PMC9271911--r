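test_that("power formula matches direct normal-CDF evaluation", {
  # se from a 95% CI of 1.15-2.01: se = log(2.01/1.15)/3.92 = 0.14242
  p <- detectable_power(0.14242, or_alt = 1.5, alpha = 0.05)
  ncp <- log(1.5) / 0.14242
  expect_equal(p, 1 - pnorm(qnorm(0.975) - ncp) +
                 pnorm(-qnorm(0.975) - ncp), tolerance = 1e-12)
  expect_equal(p, 0.813, tolerance = 1e-3)

  expect_equal(detectable_power(0.2, or_alt = 1, alpha = 0.05), 0.05,
               tolerance = 1e-12)              # null alternative
  expect_gt(detectable_power(1e-6, or_alt = 1.5), 1 - 1e-12)  # se -> 0
  # protective and risk alternatives are equivalent
  expect_equal(detectable_power(0.2, or_alt = 1.5),
               detectable_power(0.2, or_alt = 1 / 1.5), tolerance = 1e-12)
})

test_that("FPRP follows its defining formula and limits", {
  expect_equal(unname(fprp(0.00328, 0.813, 0.001)),
               0.00328 * 0.999 / (0.00328 * 0.999 + 0.813 * 0.001),
               tolerance = 1e-12)
  expect_equal(round(unname(fprp(0.00328, 0.813, 0.001)), 3), 0.801)
  expect_equal(unname(fprp(0.3, 0.3, 0.5)), 0.5, tolerance = 1e-12)
  expect_lt(unname(fprp(1e-12, 0.8, 0.001)), 1e-6)
  expect_equal(unname(fprp(0.01, 0, 0.001)), 1)  # zero power convention
})

test_that("BFDP matches the approximate-Bayes-factor formula", {
  got <- unname(bfdp(log(1.52), 0.14242^2, 0.001, or_alt_upper = 1.5))
  W <- (log(1.5) / qnorm(0.975))^2
  V <- 0.14242^2
  r <- W / (V + W)
  abf <- exp(-(log(1.52) / sqrt(V))^2 * r / 2) / sqrt(1 - r)
  po <- 0.999 / 0.001
  expect_equal(got, abf * po / (abf * po + 1), tolerance = 1e-12)
  expect_equal(round(got, 3), 0.989)
  # infinite evidence: BFDP -> 0
  expect_lt(unname(bfdp(0.4, 1e-8, 0.001)), 1e-6)
})

test_that("FPRP and BFDP are monotone in prior, p-value and power", {
  priors <- c(0.25, 0.1, 0.01, 0.001, 1e-4)
  f <- fprp(0.01, 0.8, priors)
  b <- bfdp(0.3, 0.04, priors)
  expect_true(all(diff(unname(f)) > 0))  # decreasing prior -> larger FPRP
  expect_true(all(diff(unname(b)) > 0))
  expect_lt(unname(fprp(0.001, 0.8, 0.01)), unname(fprp(0.01, 0.8, 0.01)))
  expect_gt(unname(fprp(0.01, 0.4, 0.01)), unname(fprp(0.01, 0.9, 0.01)))
})

test_that("composite verdict requires all four conditions strictly", {
  good <- list(n_significant_models = 3, log_or_hat = log(1.6),
               variance = 0.01, p_value = 1e-6, i_squared = 10)
  expect_equal(do.call(assess_credibility, good)$verdict,
               "high_credibility")

  # high heterogeneity alone forces less_credible
  bad_i2 <- good; bad_i2$i_squared <- 70.2
  expect_equal(do.call(assess_credibility, bad_i2)$verdict,
               "less_credible")

  # a single significant model is not enough
  one_model <- good; one_model$n_significant_models <- 1
  expect_equal(do.call(assess_credibility, one_model)$verdict,
               "less_credible")

  # the power condition is a strict inequality: just below the threshold
  # fails, just above passes (all other conditions held favourable)
  se_below <- uniroot(function(s) detectable_power(s) - 0.799,
                      c(0.05, 0.5), tol = 1e-12)$root
  below <- good; below$variance <- se_below^2
  expect_equal(do.call(assess_credibility, below)$verdict,
               "less_credible")
  se_above <- uniroot(function(s) detectable_power(s) - 0.801,
                      c(0.05, 0.5), tol = 1e-12)$root
  above <- good
  above$variance <- se_above^2
  above$log_or_hat <- log(2.5)  # strong evidence keeps BFDP low
  expect_equal(do.call(assess_credibility, above)$verdict,
               "high_credibility")

  # i_squared exactly 50 fails
  at_i2 <- good; at_i2$i_squared <- 50
  expect_equal(do.call(assess_credibility, at_i2)$verdict,
               "less_credible")
})

test_that("assess_credibility reads its inputs from a meta_or fit", {
  fit <- meta_or(load_bundled_dataset("4b/a"), model = "recessive")
  cr <- assess_credibility(fit, n_significant_models = 4)
  expect_equal(cr$i_squared, fit$het$i_squared)
  expect_equal(cr$p_value, fit$pooled$p_value)
  expect_equal(cr$verdict, "less_credible")  # I2 = 66.4 > 50
})

test_that("venice grading reflects evidence, consistency and bias", {
  fit <- meta_or(load_bundled_dataset("4b/a"), model = "recessive")
  g <- venice_grade(fit, egger_p = 0.87, all_hwe = FALSE)
  expect_match(g, "^A")   # far more than 1000 minor alleles
  expect_match(g, "C$|B$")
  expect_equal(substr(venice_grade(fit, 0.01, FALSE), 3, 3), "C")
})
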