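test_that("Egger regression matches an explicit least-squares oracle", {
  set.seed(41)
  for (i in 1:10) {
    inst <- random_effects_instance()
    got <- egger_test(inst$yi, inst$sei)
    fit <- lm(I(inst$yi / inst$sei) ~ I(1 / inst$sei))
    sm <- summary(fit)$coefficients
    expect_equal(unname(got$estimate), sm[1, 1], tolerance = 1e-10)
    expect_equal(unname(got$statistic), sm[1, 3], tolerance = 1e-10)
    expect_equal(got$p.value, sm[1, 4], tolerance = 1e-10)
  }
  expect_error(egger_test(c(1, 2), c(1, 1)), "three")
})

test_that("Egger intercept: zero on mirrored funnels, scale-invariant,
           sign-flipping", {
  sei <- c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3)
  yi <- c(0.5, 0.8, 1.1, -0.5, -0.8, -1.1)  # mirrored pairs per precision
  expect_equal(unname(egger_test(yi, sei)$estimate), 0, tolerance = 1e-10)

  set.seed(42)
  inst <- random_effects_instance(8)
  e1 <- egger_test(inst$yi, inst$sei)
  e2 <- egger_test(inst$yi * 3, inst$sei * 3)   # common rescaling
  expect_equal(unname(e1$estimate), unname(e2$estimate), tolerance = 1e-10)
  e3 <- egger_test(-inst$yi, inst$sei)
  expect_equal(unname(e3$estimate), -unname(e1$estimate),
               tolerance = 1e-10)
})

test_that("Begg rank correlation matches brute-force pair counting", {
  set.seed(43)
  for (i in 1:10) {
    inst <- random_effects_instance()
    got <- begg_test(inst$yi, inst$sei)
    vi <- inst$sei^2
    w <- 1 / vi
    u <- (inst$yi - sum(w * inst$yi) / sum(w)) / sqrt(vi - 1 / sum(w))
    s <- oracle_kendall_s(u, vi)
    k <- length(vi)
    expect_equal(unname(got$estimate), s / (k * (k - 1) / 2),
                 tolerance = 1e-10)
  }
})

test_that("Begg extremes: perfect inverse ranking and total ties", {
  # effects in perfect inverse rank order of the variances
  sei <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  yi <- c(5, 4, 3, 2, 1) * 0.2
  # with these numbers the deviates decrease while variance decreases
  got <- begg_test(yi, sei)
  expect_equal(abs(unname(got$estimate)), 1)

  tied <- begg_test(c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2))
  expect_equal(unname(tied$statistic), 0)
  expect_equal(tied$p.value, 1)
})

test_that("trim-and-fill is exact on symmetric funnels and idempotent", {
  sei <- rep(c(0.1, 0.25, 0.4), 2)
  yi <- c(0.3, 0.6, 0.9, -0.3, -0.6, -0.9)
  tf <- trim_and_fill(yi, sei, side = "left")
  expect_equal(tf$k0, 0L)
  expect_equal(tf$adjusted$or, tf$unadjusted$or, tolerance = 1e-12)

  # second application to a filled set is a fixed point
  set.seed(44)
  inst <- random_effects_instance(9)
  inst$yi <- inst$yi + 2 / (1 / inst$sei)  # induce asymmetry
  tf1 <- trim_and_fill(inst$yi, inst$sei, side = "left")
  filled <- c(inst$yi, tf1$filled_yi)
  filled_se <- c(inst$sei, tf1$filled_sei)
  tf2 <- trim_and_fill(filled, filled_se, side = "left")
  expect_equal(tf2$k0, 0L)
})

test_that("trim-and-fill k0 equals metafor's L0 implementation", {
  skip_if_not_installed("metafor")
  set.seed(45)
  for (i in 1:10) {
    inst <- random_effects_instance()
    got <- trim_and_fill(inst$yi, inst$sei, side = "left")
    ref <- suppressWarnings(
      metafor::trimfill(metafor::rma(yi = inst$yi, sei = inst$sei,
                                     method = "FE"),
                        side = "left", estimator = "L0"))
    expect_equal(got$k0, ref$k0)
  }
})

test_that("deterministic one-sided censoring is recovered by trim-and-fill", {
  # delete the five most negative effects of an unbiased collection
  set.seed(46)
  d <- simulate_meta_dataset(k = 40, q_control = 0.3, true_or = 1,
                             tau_squared = 0, seed = 12)
  f <- meta_or(d, method = "random")
  yi <- f$studies$log_or; sei <- f$studies$se
  keep <- rank(yi) > 5
  tf <- trim_and_fill(yi[keep], sei[keep], side = "left")
  expect_lte(abs(tf$k0 - 5L), 3L)
})

test_that("stochastic suppression biases the Egger intercept upward", {
  set.seed(47)
  res <- t(replicate(40, {
    d <- simulate_meta_dataset(k = 60, q_control = 0.3, true_or = 1,
                               suppress_fraction = 0.8,
                               seed = sample.int(1e6, 1))
    if (n_studies(d) < 3) return(c(NA, NA))
    e <- egger_test(meta_or(d, method = "random"))
    c(unname(e$estimate), e$p.value < 0.05)
  }))
  ints <- res[, 1][!is.na(res[, 1])]
  expect_gt(mean(ints), 0)
  expect_gt(mean(ints > 0), 0.6)

  # with a larger surviving collection the test gains real power
  rej <- replicate(25, {
    d <- simulate_meta_dataset(k = 600, q_control = 0.3, true_or = 1,
                               suppress_fraction = 0.8,
                               seed = sample.int(1e6, 1))
    egger_test(meta_or(d, method = "random"))$p.value < 0.05
  })
  expect_gt(mean(rej), 0.3)
})

test_that("published asymmetry pattern: only one polymorphism is affected", {
  pvals <- function(which) {
    vapply(genetic_models(), function(m)
      egger_test(meta_or(load_bundled_dataset(which), model = m,
                         method = "random"))$p.value, numeric(1))
  }
  pg <- pvals("G894T")
  expect_lt(pg[["hybrid"]], 0.05)
  expect_lt(pg[["dominant"]], 0.05)
  expect_lt(pg[["allele"]], 0.05)
  expect_true(all(pvals("4b/a") > 0.05))
  expect_true(all(pvals("T786C") > 0.05))
})
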