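test_that("heterogeneity statistics match hand computation", {
  # identical effects: no heterogeneity at all
  h0 <- heterogeneity_stats(c(0.4, 0.4), c(0.1, 0.1))
  expect_equal(h0$q_stat, 0)
  expect_equal(h0$i_squared, 0)
  expect_equal(h0$tau_squared, 0)

  # w = 100 each, mean 0.5: Q = 100*0.25 + 100*0.25 = 50, I2 = 98
  h <- heterogeneity_stats(c(0, 1), c(0.1, 0.1))
  expect_equal(h$q_stat, 50, tolerance = 1e-12)
  expect_equal(h$df, 1)
  expect_equal(h$i_squared, 98, tolerance = 1e-12)

  expect_error(heterogeneity_stats(0.2, 0.1), "at least two")
})

test_that("DL pooling matches metafor and the step-by-step oracle", {
  skip_if_not_installed("metafor")
  set.seed(31)
  for (i in 1:10) {
    inst <- random_effects_instance()
    got <- pool_random_dl(inst$yi, inst$sei)
    ora <- oracle_dl(inst$yi, inst$sei)
    expect_equal(got$log_or, ora$theta, tolerance = 1e-10)
    expect_equal(got$se, ora$se, tolerance = 1e-10)
    m <- metafor::rma(yi = inst$yi, sei = inst$sei, method = "DL")
    expect_equal(got$log_or, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(got$se, m$se, tolerance = 1e-10)
    expect_equal(got$tau_squared, m$tau2, tolerance = 1e-10)
  }
})

test_that("MH pooling matches the RBG oracle and metafor::rma.mh", {
  skip_if_not_installed("metafor")
  set.seed(32)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    a <- sample(5:60, k, TRUE); b <- sample(5:60, k, TRUE)
    cc <- sample(5:60, k, TRUE); d <- sample(5:60, k, TRUE)
    got <- pool_fixed_mh(data.frame(exposed_cases = a, unexposed_cases = b,
                                    exposed_controls = cc,
                                    unexposed_controls = d))
    ora <- oracle_mh(a, b, cc, d)
    expect_equal(got$log_or, ora$log_or, tolerance = 1e-10)
    expect_equal(got$se, ora$se, tolerance = 1e-10)
    m <- metafor::rma.mh(ai = a, bi = b, ci = cc, di = d, measure = "OR",
                         correct = FALSE)
    expect_equal(got$log_or, as.numeric(m$beta), tolerance = 1e-10)
    expect_equal(got$se, m$se, tolerance = 1e-10)
  }
})

test_that("a single study pools to itself; balanced tables give OR 1", {
  one <- pool_fixed_mh(data.frame(exposed_cases = 20, unexposed_cases = 10,
                                  exposed_controls = 15,
                                  unexposed_controls = 30))
  expect_equal(one$or, (20 * 30) / (10 * 15), tolerance = 1e-12)
  bal <- pool_fixed_mh(data.frame(exposed_cases = c(10, 30),
                                  unexposed_cases = c(10, 30),
                                  exposed_controls = c(10, 5),
                                  unexposed_controls = c(10, 5)))
  expect_equal(bal$or, 1, tolerance = 1e-12)
})

test_that("DL degenerates to inverse-variance pooling when tau2 = 0", {
  yi <- c(0.2, 0.21, 0.19); sei <- c(0.3, 0.35, 0.32)  # Q < df
  got <- pool_random_dl(yi, sei)
  expect_equal(got$tau_squared, 0)
  w <- 1 / sei^2
  expect_equal(got$log_or, sum(w * yi) / sum(w), tolerance = 1e-12)
  expect_equal(got$se, 1 / sqrt(sum(w)), tolerance = 1e-12)
})

test_that("model selection follows the P<0.10 / I2>50 rule strictly", {
  expect_equal(select_model(0.265, 12.8), "fixed_mh")
  expect_equal(select_model(0.079, 34.8), "random_dl")
  expect_equal(select_model(0.5, 70), "random_dl")
  expect_equal(select_model(0.10, 50), "fixed_mh")  # boundary: strict
})

test_that("pooled estimate is a convex combination; random CI is wider", {
  set.seed(33)
  for (i in 1:10) {
    inst <- random_effects_instance()
    dl <- pool_random_dl(inst$yi, inst$sei)
    expect_gte(dl$log_or, min(inst$yi) - 1e-12)
    expect_lte(dl$log_or, max(inst$yi) + 1e-12)
    w <- 1 / inst$sei^2
    se_iv <- 1 / sqrt(sum(w))
    expect_gte(dl$se, se_iv - 1e-12)
  }
})

test_that("meta_or reproduces published stratum results end-to-end", {
  ds <- load_bundled_dataset("4b/a")
  rec <- meta_or(ds, model = "recessive")
  expect_equal(rec$effects_model, "random_dl")
  expect_equal(round(rec$pooled$or, 2), 0.77)
  expect_equal(round(rec$pooled$ci_low, 2), 0.66)
  expect_equal(round(rec$pooled$ci_high, 2), 0.89)
  expect_equal(round(rec$het$i_squared, 1), 66.4)

  hom_asian <- meta_or(ds, model = "homozygous",
                       subset = ethnicity == "asian")
  expect_equal(hom_asian$k, 17)  # 5 of 22 have no aa in either arm
  expect_length(hom_asian$excluded_ids, 5)
  expect_equal(round(hom_asian$pooled$or, 2), 0.44)

  # forcing the model overrides the heterogeneity rule
  hy <- meta_or(ds, model = "hybrid")
  expect_equal(hy$effects_model, "fixed_mh")
  hy_r <- meta_or(ds, model = "hybrid", method = "random")
  expect_equal(hy_r$effects_model, "random_dl")
  expect_equal(round(hy_r$pooled$or, 2), 0.71)
})

test_that("single-study strata are reported with a flag", {
  ds <- load_bundled_dataset("4b/a")
  fit <- meta_or(ds, model = "allele", subset = ethnicity == "african")
  expect_true(fit$single_study)
  expect_equal(fit$k, 1)
  tab <- snpmeta:::contrast_effects(
    ds$studies[ds$studies$ethnicity == "african", ], "allele")
  expect_equal(fit$pooled$log_or, tab$yi[1], tolerance = 1e-12)
})

test_that("leave-one-out returns k results and flags flips", {
  ds <- toy_dataset(3)
  fit <- meta_or(ds, model = "allele")
  loo <- leave_one_out(fit)
  expect_equal(nrow(loo), 3)

  # the published allele-model association survives every omission
  fit4 <- meta_or(load_bundled_dataset("4b/a"), model = "allele")
  loo4 <- leave_one_out(fit4)
  expect_equal(nrow(loo4), 36)
  expect_false(any(loo4$flips_significance))

  expect_error(leave_one_out(meta_or(toy_dataset(2), model = "allele")),
               "at least three")
})

test_that("identical simulated studies give identical leave-one-out fits", {
  one <- simulate_meta_dataset(k = 1, q_control = 0.3, true_or = 1.5,
                               n_case_range = c(300L, 300L),
                               n_control_range = c(300L, 300L), seed = 5)
  s <- one$studies[rep(1, 4), ]
  s$study_id <- paste0("s", 1:4)
  ds <- study_dataset(s, one$polymorphism)
  loo <- leave_one_out(meta_or(ds, model = "allele"))
  expect_equal(length(unique(round(loo$or, 12))), 1L)
})

test_that("meta-regression recovers a known subgroup shift", {
  skip_if_not_installed("metafor")
  # two halves of the collection differ by 0.5 on the log OR scale
  d1 <- simulate_meta_dataset(k = 20, q_control = 0.3, true_or = 1,
                              tau_squared = 0.02, seed = 71)
  d2 <- simulate_meta_dataset(k = 20, q_control = 0.3, true_or = exp(0.5),
                              tau_squared = 0.02, seed = 72)
  s1 <- d1$studies
  s1$ethnicity <- "asian"       # baseline level (null subgroup)
  s2 <- d2$studies
  s2$study_id <- paste0(s2$study_id, "b")
  s2$ethnicity <- "caucasian"   # shifted subgroup
  ds <- study_dataset(rbind(s1, s2), d1$polymorphism)
  mr <- meta_regress(ds, "allele", "ethnicity")
  slope <- mr$estimate[2]; se <- mr$se[2]
  expect_lt(abs(slope - 0.5), 2 * se)

  expect_error(meta_regress(d1, "allele", "control_type"), "constant")
})

test_that("Hardy-Weinberg status explains 4b/a hybrid heterogeneity", {
  skip_if_not_installed("metafor")
  mr <- meta_regress(load_bundled_dataset("4b/a"), "hybrid", "hwe")
  expect_lt(mr$p_value[2], 0.05)
})
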