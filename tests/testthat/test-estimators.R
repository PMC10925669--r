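test_that("Wald ratio follows the delta-method formulas", {
  fit <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(fit$beta, 0.5)
  expect_equal(fit$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  # second-order: se^2 = se_G^2/g^2 + G^2 sg^2/g^4 = 0.01 + 0.0025
  fit2 <- wald_ratio(0.1, 0.01, 0.05, 0.01, second_order = TRUE)
  expect_equal(fit2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "gamma = 0")
})

test_that("IVW matches its closed form and degenerates to the Wald ratio", {
  set2 <- toy_set(gamma = c(0.1, 0.2), Gamma = c(0.05, 0.12))
  fit <- ivw_mre(set2)
  expect_equal(fit$beta, 0.029 / 0.05)  # hand evaluation: 0.58
  set1 <- toy_set(gamma = 0.1, Gamma = 0.05)
  expect_equal(ivw_mre(set1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.01)$beta)
  expect_equal(ivw_mre(set1)$se, wald_ratio(0.1, 0.01, 0.05, 0.01)$se)
  expect_error(ivw_mre(toy_set(gamma = c(0, 0), Gamma = c(0.1, 0.1))), "zero")
})

test_that("consensus ratios give Q = 0 and no random-effects inflation", {
  g <- c(0.05, 0.1, 0.2, 0.4)
  set <- toy_set(gamma = g, Gamma = 0.3 * g, se_Gamma = c(0.01, 0.02, 0.01, 0.03))
  fit <- ivw_mre(set)
  expect_equal(fit$beta, 0.3)
  expect_equal(fit$q, 0)
  expect_equal(fit$phi, 1)
  expect_equal(fit$se, fit$se_fixed)
})

test_that("random-effects SE never falls below the fixed-effect SE", {
  for (s in 1:20) {
    set <- sim_set(simulation_config(n_variants = 15, seed = s,
                                     pleiotropy_mode = "balanced",
                                     prop_invalid = 0.4,
                                     pleiotropy_scale = 0.05))
    fit <- ivw_mre(set)
    expect_gte(fit$se, fit$se_fixed)
    expect_identical(fit$se > fit$se_fixed, fit$q > fit$n_snp - 1)
  }
})

test_that("Egger recovers slope and constant pleiotropy exactly without noise", {
  g <- seq(0.05, 0.3, length.out = 6)
  set <- toy_set(gamma = g, Gamma = 0.3 * g + 0.02)
  fit <- egger(set)
  expect_equal(fit$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)
  set0 <- toy_set(gamma = g, Gamma = 0.3 * g)
  expect_equal(egger(set0)$intercept, 0, tolerance = 1e-12)
  expect_error(egger(toy_set(gamma = c(0.1, 0.2), Gamma = c(0.03, 0.06))),
               "at least 3")
})

test_that("Egger orientation makes the fit invariant to allele flips", {
  set <- sim_set(simulation_config(n_variants = 20, seed = 3))
  flip <- rep(c(1, -1), 10)
  flipped <- harmonized_set(gamma = flip * set$gamma, se_gamma = set$se_gamma,
                            Gamma = flip * set$Gamma, se_Gamma = set$se_Gamma)
  expect_equal(egger(flipped)$beta, egger(set)$beta)
  expect_equal(egger(flipped)$intercept, egger(set)$intercept)
})

test_that("weighted median interpolates the weighted ratio quantile", {
  set <- toy_set(gamma = rep(0.1, 3), Gamma = 0.1 * c(0.2, 0.4, 0.6))
  expect_equal(weighted_median(set, n_boot = 50)$beta, 0.4)

  # breakdown robustness: a <25%-weight outlier cannot drag the estimate out
  g <- c(0.1, 0.1, 0.1, 0.05)
  set_out <- toy_set(gamma = g, Gamma = g * c(0.2, 0.4, 0.6, 100))
  est <- weighted_median(set_out, n_boot = 50)$beta
  expect_gte(est, 0.2); expect_lte(est, 0.6)

  # oracle: brute-force evaluation of the interpolated weighted-quantile
  # definition on unequal weights
  for (s in 1:10) {
    set.seed(s)
    b <- rnorm(5); w <- runif(5, 0.5, 2)
    ord <- order(b); bs <- b[ord]; ws <- w[ord] / sum(w)
    sj <- cumsum(ws) - ws / 2
    oracle <- if (0.5 <= sj[1]) bs[1] else if (0.5 >= sj[5]) bs[5] else
      stats::approx(sj, bs, xout = 0.5)$y
    g <- sqrt(w) * 0.01  # weights g^2/se_G^2 = w with se_G = 0.01
    set_r <- toy_set(gamma = g, Gamma = g * b)
    expect_equal(weighted_median(set_r, n_boot = 10)$beta, oracle)
  }
})

test_that("weighted mode finds the plurality cluster", {
  g <- rep(0.1, 4)
  set <- toy_set(gamma = g, Gamma = g * c(0.3, 0.3, 0.3, 0.9))
  expect_equal(weighted_mode(set, n_boot = 50)$beta, 0.3, tolerance = 1e-6)

  # dense grid-search oracle over the same kernel density
  set.seed(42)
  b <- c(rnorm(6, 0.25, 0.02), 0.8, 1.1)
  g <- runif(8, 0.05, 0.2)
  set_r <- toy_set(gamma = g, Gamma = g * b)
  w <- g^2 / 0.01^2; w <- w / sum(w)
  h <- 0.9 * min(sd(b), mad(b)) / 8^(1 / 5)
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 20000L)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, b, h)), numeric(1))
  oracle <- grid[which.max(dens)]
  est <- weighted_mode(set_r, n_boot = 10)$beta
  expect_equal(est, oracle, tolerance = h / 10)

  # single tight cluster: estimate equals the cluster centre
  b2 <- rep(0.5, 5) + c(-2, -1, 0, 1, 2) * 1e-4
  set_c <- toy_set(gamma = rep(0.1, 5), Gamma = 0.1 * b2)
  expect_equal(weighted_mode(set_c, n_boot = 10)$beta, 0.5, tolerance = 1e-3)
})

test_that("an infinite bandwidth drives the mode to the weighted mean", {
  set.seed(7)
  b <- rnorm(6, 0.3, 0.3); g <- runif(6, 0.05, 0.2)
  set <- toy_set(gamma = g, Gamma = g * b)
  w <- g^2 / 0.01^2; w <- w / sum(w)
  est <- weighted_mode(set, bandwidth_factor = 1e4, n_boot = 10)$beta
  expect_equal(est, sum(w * b), tolerance = 1e-3)
})

test_that("RAPS matches a grid-search oracle for the plain profile likelihood", {
  set <- toy_set(gamma = c(0.1, 0.15, 0.2), Gamma = c(0.04, 0.05, 0.03),
                 se_gamma = 0.02, se_Gamma = 0.015)
  fit <- raps(set, overdispersion = FALSE, loss = "l2")
  grid <- seq(-1, 1, length.out = 80001L)
  obj <- vapply(grid, function(th) {
    t <- (set$Gamma - th * set$gamma) /
      sqrt(set$se_Gamma^2 + th^2 * set$se_gamma^2)
    sum(t^2) / 2
  }, numeric(1))
  expect_equal(fit$beta, grid[which.min(obj)], tolerance = 5e-5)
})

test_that("RAPS is approximately unbiased under balanced pleiotropy", {
  ests <- vapply(1:60, function(s) {
    set <- sim_set(simulation_config(n_variants = 100, theta = 0.2,
                                     pleiotropy_mode = "balanced",
                                     prop_invalid = 1, pleiotropy_scale = 0.05,
                                     seed = 4000 + s))
    suppressWarnings(raps(set)$beta)
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.2), 3 * mc_se)
})

test_that("all five estimators recover theta exactly on noiseless data", {
  cfg <- simulation_config(n_variants = 30, theta = 0.17, prop_invalid = 0,
                           noise_scale = 0, seed = 6)
  set <- sim_set(cfg)
  expect_equal(ivw_mre(set)$beta, 0.17, tolerance = 1e-8)
  expect_equal(egger(set)$beta, 0.17, tolerance = 1e-8)
  expect_equal(weighted_median(set, n_boot = 10)$beta, 0.17, tolerance = 1e-8)
  expect_equal(weighted_mode(set, n_boot = 10)$beta, 0.17, tolerance = 1e-8)
  expect_equal(suppressWarnings(raps(set)$beta), 0.17, tolerance = 1e-8)
})

test_that("median and mode estimates stay inside the ratio range", {
  for (s in 1:10) {
    set <- sim_set(simulation_config(n_variants = 12, seed = 100 + s,
                                     pleiotropy_mode = "directional",
                                     prop_invalid = 0.3, pleiotropy_scale = 0.1))
    r <- set$Gamma / set$gamma
    wm <- weighted_median(set, n_boot = 10)$beta
    md <- weighted_mode(set, n_boot = 10)$beta
    expect_gte(wm, min(r)); expect_lte(wm, max(r))
    expect_gte(md, min(r)); expect_lte(md, max(r))
  }
})

test_that("OR transforms are order-preserving, invertible and round to percent", {
  est <- mr_estimate("ivw_mre", beta = log(0.315), se = 0.05, n_snp = 5)
  expect_equal(or_and_percent(est)$percent_change, -68L)
  est2 <- mr_estimate("ivw_mre", beta = log(2.285), se = 0.05, n_snp = 5)
  expect_equal(or_and_percent(est2)$percent_change, 129L)
  est3 <- mr_estimate("ivw_mre", beta = 0, se = 0.05, n_snp = 5)
  expect_equal(or_and_percent(est3)$percent_change, 0L)
  expect_lt(est$ci_low, est$or_value); expect_gt(est$ci_high, est$or_value)
  # invertibility: printed OR + CI reproduce beta and se
  back <- mr_estimate_from_or(est$or_value, est$ci_low, est$ci_high)
  expect_equal(back$beta, est$beta)
  expect_equal(back$se, est$se)
})
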