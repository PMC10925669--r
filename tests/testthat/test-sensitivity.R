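test_that("Cochran's Q matches hand summation and flags heterogeneity", {
  # two identical ratio estimates
  set0 <- toy_set(gamma = c(0.1, 0.1), Gamma = c(0.05, 0.05))
  expect_equal(cochran_q(set0)$q, 0)
  # hand case: ratios 0.5 and 0.7 with ratio-SE 0.1 about theta = 0.6
  set <- toy_set(gamma = c(0.1, 0.1), Gamma = c(0.05, 0.07),
                 se_Gamma = 0.01)  # ratio SE = 0.01/0.1 = 0.1
  qv <- cochran_q(set, theta = 0.6)
  expect_equal(qv$q, 2)
  expect_equal(qv$df, 1L)
  expect_equal(qv$pval, pchisq(2, 1, lower.tail = FALSE))
  # heterogeneity flag at p < 0.05
  g <- rep(0.1, 8)
  het <- toy_set(gamma = g, Gamma = g * c(1, 1, 1, 1, -1, -1, -1, -1) * 0.5,
                 se_Gamma = 0.005)
  expect_lt(cochran_q(het)$pval, 0.05)
})

test_that("Rucker's Q' never exceeds Cochran's Q on the same set", {
  for (s in 1:15) {
    set <- sim_set(simulation_config(n_variants = 20, seed = 200 + s,
                                     pleiotropy_mode = "directional",
                                     prop_invalid = 0.3,
                                     pleiotropy_scale = 0.05))
    expect_lte(rucker_q(set)$q, cochran_q(set)$q + 1e-9)
  }
})

test_that("I2_GX separates precise from noisy instrument estimates", {
  # identical instrument effects, equal SEs: Q_GX = 0, flag raised
  set0 <- toy_set(gamma = rep(0.1, 5), Gamma = rep(0.02, 5), se_gamma = 0.02)
  ig0 <- i2_gx(set0)
  expect_equal(ig0$q_gx, 0)
  expect_equal(ig0$i2, 0)
  expect_true(ig0$nome_flag)
  # widely separated effects with tiny SEs: I2 near 1, no flag
  set1 <- toy_set(gamma = seq(0.1, 0.5, length.out = 5),
                  Gamma = rep(0.02, 5), se_gamma = 0.001)
  ig1 <- i2_gx(set1)
  expect_gt(ig1$i2, 0.99)
  expect_false(ig1$nome_flag)
})

test_that("leave-one-out is stable on homogeneous sets and catches outliers", {
  expect_error(leave_one_out(toy_set(gamma = 0.1, Gamma = 0.02)), "at least 2")
  g <- rep(0.1, 6)
  hom <- toy_set(gamma = g, Gamma = 0.3 * g)
  loo <- leave_one_out(hom)
  expect_true(loo$stable)
  expect_equal(loo$estimates$beta, rep(0.3, 6))

  # one gross outlier strong enough to flip the pooled sign: dropping it
  # flips the estimate back, so the set is judged unstable and the outlier
  # is identified as the influential variant
  out <- toy_set(gamma = g, Gamma = c(rep(0.01, 5), -0.3))
  loo2 <- leave_one_out(out)
  expect_false(loo2$stable)
  expect_identical(loo2$influential, "v6")
})

test_that("MR-PRESSO flags a planted outlier and passes smaller checks", {
  expect_error(mr_presso(toy_set(gamma = rep(0.1, 3), Gamma = rep(0.02, 3))),
               "at least 4")
  cfg <- simulation_config(n_variants = 30, theta = 0.2, seed = 31)
  set <- sim_set(cfg)
  j <- 7
  set$Gamma[j] <- set$Gamma[j] + 10 * set$se_Gamma[j]
  pr <- mr_presso(set, n_sim = 500, seed = 2)
  expect_true(set$variant_id[j] %in% pr$outliers)
  expect_lt(pr$global_pval, 0.05)
  expect_false(is.na(pr$distortion_pval))
  # deterministic given seed
  pr2 <- mr_presso(set, n_sim = 500, seed = 2)
  expect_identical(pr, pr2)
})

test_that("Steiger compares explained variance and is antisymmetric", {
  cfg <- simulation_config(n_variants = 20, theta = 0.2, seed = 41)
  set <- sim_set(cfg)
  st <- steiger(set)
  expect_true(st$direction)
  expect_lt(st$pval, 0.05)
  expect_gt(st$r2_exposure, st$r2_outcome)
  # swapping exposure and outcome flips the verdict
  swapped <- harmonized_set(gamma = set$Gamma, se_gamma = set$se_Gamma,
                            Gamma = set$gamma, se_Gamma = set$se_gamma,
                            eaf = set$eaf,
                            exposure_type = "binary", outcome_type = "continuous",
                            n_exposure = attr(set, "n_outcome"),
                            n_outcome = attr(set, "n_exposure"),
                            case_fraction = attr(set, "case_fraction"))
  expect_false(steiger(swapped)$direction)
  # per-variant form covers every instrument
  pv <- steiger(set, per_variant = TRUE)
  expect_identical(nrow(pv), 20L)
  expect_true(all(pv$r2_exposure > pv$r2_outcome))
})

test_that("Steiger verdict is invariant to allele re-orientation", {
  set <- sim_set(simulation_config(n_variants = 15, theta = 0.2, seed = 43))
  flip <- rep(c(-1, 1), length.out = 15)
  re <- harmonized_set(gamma = flip * set$gamma, se_gamma = set$se_gamma,
                       Gamma = flip * set$Gamma, se_Gamma = set$se_Gamma,
                       eaf = set$eaf,
                       n_exposure = attr(set, "n_exposure"),
                       n_outcome = attr(set, "n_outcome"),
                       case_fraction = attr(set, "case_fraction"))
  expect_identical(steiger(re)$direction, steiger(set)$direction)
  expect_equal(steiger(re)$pval, steiger(set)$pval)
})

test_that("analytic power is alpha at the null and monotone in its drivers", {
  expect_equal(power_binary(20000, 0.25, 0.02, or_alt = 1), 0.05)
  p_base <- power_binary(20000, 0.25, 0.02, 1.2)
  expect_gt(power_binary(60000, 0.25, 0.02, 1.2), p_base)
  expect_gt(power_binary(20000, 0.25, 0.06, 1.2), p_base)
  expect_gt(power_binary(20000, 0.25, 0.02, 1.4), p_base)
  # symmetric in the direction of effect
  expect_equal(power_binary(20000, 0.25, 0.02, 1 / 1.2), p_base)
  expect_equal(power_continuous(20000, 0.02, beta_alt = 0), 0.05)
})

test_that("funnel data are symmetric for valid sets", {
  set <- sim_set(simulation_config(n_variants = 200, theta = 0.2, seed = 51))
  fd <- funnel_data(set)
  expect_identical(names(fd), c("variant_id", "ratio", "precision"))
  # no small-study-style asymmetry: ratio does not trend with precision
  fit <- stats::lm(ratio ~ precision, data = fd)
  expect_gt(summary(fit)$coefficients["precision", "Pr(>|t|)"], 0.01)
  one <- funnel_data(set[1, ])
  expect_identical(nrow(one), 1L)
  expect_error(funnel_data(set[integer(0), ]), "empty")
})

test_that("the sensitivity report gates small sets and fills large ones", {
  small <- sim_set(simulation_config(n_variants = 2, seed = 61))
  rep_s <- sensitivity_report(small, n_presso = 100)
  expect_true(is.na(rep_s$egger_intercept_pval))
  expect_true(is.na(rep_s$presso_global_pval))
  big <- sim_set(simulation_config(n_variants = 25, theta = 0.2, seed = 62))
  rep_b <- sensitivity_report(big, n_presso = 100, seed = 3)
  expect_false(is.na(rep_b$egger_intercept_pval))
  expect_false(is.na(rep_b$presso_global_pval))
  expect_true(rep_b$steiger_direction)
  expect_gte(rep_b$power, 0); expect_lte(rep_b$power, 1)
  df <- as.data.frame(rep_b)
  expect_identical(nrow(df), 1L)
})
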