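test_that("significance screen keeps exactly the sub-threshold variants", {
  tab <- summary_stats(toy_stats_df(3, pval = c(1e-9, 1e-7, 0.5)), "t")
  expect_identical(nrow(select_significant(tab, 5e-8)), 1L)
  expect_identical(nrow(select_significant(tab, 1e-6)), 2L)
  expect_identical(nrow(select_significant(tab, 0.9999)), 3L)
  expect_warning(select_significant(tab, 1e-20), "no variants")
})

test_that("clumping keeps the smallest p-value among correlated variants", {
  tab <- summary_stats(toy_stats_df(2, pval = c(1e-10, 1e-8)), "t")
  ld <- data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.5)
  expect_identical(clump(tab, ld, r2_max = 0.01)$variant_id, "rs1")
  ld0 <- data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.0)
  expect_identical(nrow(clump(tab, ld0, r2_max = 0.01)), 2L)
  expect_error(clump(tab, ld, window_kb = -5), "negative")
})

test_that("one fully-correlated LD block collapses to its top variant", {
  pv <- c(3e-9, 1e-11, 5e-8, 2e-10, 4e-9)
  df <- toy_stats_df(5, pval = pv)
  df$pos <- 1e6 + seq_len(5) * 1e4
  tab <- summary_stats(df, "t")
  pairs <- t(combn(paste0("rs", 1:5), 2))
  ld <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2], r2 = 0.9)
  kept <- clump(tab, ld, r2_max = 0.01, window_kb = 10000)
  # oracle: greedy selection by p-order on an all-correlated block must
  # retain exactly the global minimum p
  expect_identical(kept$variant_id, paste0("rs", which.min(pv)))
})

test_that("clumping respects the physical window", {
  df <- toy_stats_df(2, pval = c(1e-10, 1e-8))
  df$pos <- c(1e6, 5e8)  # 499 Mb apart
  tab <- summary_stats(df, "t")
  ld <- data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.99)
  expect_identical(nrow(clump(tab, ld, r2_max = 0.01, window_kb = 10000)), 2L)
  expect_identical(nrow(clump(tab, ld, r2_max = 0.01, window_kb = 1e6)), 1L)
})

test_that("F statistic and the weak-instrument filter follow the formula", {
  expect_equal(f_statistic(0.1, 0.02), 25)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_error(f_statistic(0.1, 0), "positive")

  df <- toy_stats_df(3)
  df$beta <- c(0.05, 0.03, 0.11); df$se <- c(0.01, 0.01, 0.0331662)
  tab <- summary_stats(df, "t")   # F = 25, 9, ~11.0
  expect_identical(filter_weak(tab, 10)$variant_id, c("rs1", "rs3"))
  # boundary is a strict inequality: F at (or numerically just below) the
  # bound is removed
  df$beta <- rep(10, 3); df$se <- rep(sqrt(10), 3)
  expect_false(any(f_statistic(df$beta, df$se) > 10))
  expect_identical(nrow(filter_weak(summary_stats(df, "t"), 10)), 0L)
  expect_identical(nrow(filter_weak(tab[0, ], 10)), 0L)
})

test_that("harmonization aligns swapped and strand-flipped records", {
  exp_df <- toy_stats_df(4)
  exp_df$effect_allele <- c("A", "A", "A", "C")
  exp_df$other_allele <- c("G", "G", "G", "T")
  out_df <- exp_df
  out_df$n <- 20000
  # rs1 aligned; rs2 swapped; rs3 strand-complemented; rs4 complement+swap
  out_df$effect_allele <- c("A", "G", "T", "A")
  out_df$other_allele <- c("G", "A", "C", "G")
  out_df$beta <- c(0.05, 0.05, 0.05, 0.05)
  exp_tab <- summary_stats(exp_df, "x")
  out_tab <- summary_stats(out_df, "y", "binary")
  set <- harmonize(exp_tab, out_tab)
  expect_identical(nrow(set), 4L)
  expect_equal(set$Gamma, c(0.05, -0.05, 0.05, -0.05))
  expect_identical(attr(set, "n_outcome"), 20000)
})

test_that("palindromic variants are removed in strict mode and counted", {
  exp_df <- toy_stats_df(3)
  exp_df$effect_allele <- c("A", "C", "A")
  exp_df$other_allele <- c("T", "G", "G")
  exp_tab <- summary_stats(exp_df, "x")
  out_tab <- summary_stats(exp_df, "y")
  set <- harmonize(exp_tab, out_tab, strict_palindrome = TRUE)
  expect_identical(set$variant_id, "rs3")
  expect_identical(attr(set, "removals")$ambiguous_palindromic, c("rs1", "rs2"))
  set2 <- harmonize(exp_tab, out_tab, strict_palindrome = FALSE)
  expect_identical(nrow(set2), 3L)
})

test_that("variants missing from the outcome are removed and counted", {
  exp_tab <- summary_stats(toy_stats_df(3), "x")
  out_tab <- summary_stats(toy_stats_df(2), "y")
  set <- harmonize(exp_tab, out_tab)
  expect_identical(nrow(set), 2L)
  expect_identical(attr(set, "removals")$missing_in_outcome, "rs3")
})

test_that("harmonization is involution-safe on an aligned pair", {
  cfg <- simulation_config(n_variants = 20, prop_flipped = 0.3, seed = 5)
  pair <- generate_pair(cfg)
  once <- harmonize(pair$exposure, pair$outcome)
  # rebuild the outcome in already-aligned orientation and harmonize again
  aligned <- as.data.frame(pair$exposure)
  aligned$beta <- once$Gamma
  aligned$se <- once$se_Gamma
  aligned$pval <- once$pval_outcome
  out2 <- summary_stats(aligned, "outcome", "binary")
  twice <- harmonize(pair$exposure, out2)
  expect_equal(twice$Gamma, once$Gamma)
  expect_equal(twice$gamma, once$gamma)
})

test_that("confounder screen removes only listed-trait associations", {
  set <- toy_set(gamma = c(0.1, 0.1, 0.1), Gamma = c(0.02, 0.02, 0.02))
  ann <- data.frame(variant_id = c("v1", "v2"),
                    trait = c("serum vitamin D", "height"),
                    p = c(1e-9, 1e-9), stringsAsFactors = FALSE)
  out <- screen_confounders(set, ann, confounder_traits = "serum vitamin D")
  expect_identical(out$variant_id, c("v2", "v3"))
  # empty annotation is the identity
  expect_identical(nrow(screen_confounders(set, NULL)), 3L)
  # boundary: association above the threshold is kept
  ann2 <- data.frame(variant_id = "v1", trait = "serum vitamin D", p = 1e-7)
  expect_identical(nrow(screen_confounders(set, ann2,
                                           confounder_traits = "serum vitamin D")), 3L)
})

test_that("Bonferroni outcome filter uses alpha over the current set size", {
  set <- toy_set(gamma = rep(0.1, 10), Gamma = rep(0.001, 10))
  set$pval_outcome <- rep(0.5, 10)
  expect_identical(nrow(bonferroni_outcome_filter(set)), 10L)  # identity
  set$pval_outcome[4] <- 1e-4  # below 0.05/10 = 0.005
  out <- bonferroni_outcome_filter(set)
  expect_identical(nrow(out), 9L)
  expect_identical(attr(out, "removals")$bonferroni_outcome, "v4")
  # threshold arithmetic: 0.05/25 = 0.002
  set25 <- toy_set(gamma = rep(0.1, 25), Gamma = rep(0.001, 25))
  set25$pval_outcome <- rep(0.0021, 25)
  expect_identical(nrow(bonferroni_outcome_filter(set25)), 25L)
  set25$pval_outcome <- rep(0.0019, 25)
  expect_identical(nrow(bonferroni_outcome_filter(set25)), 0L)
})

test_that("ledger conservation holds and violations are rejected", {
  led <- ledger_new(916)
  for (st in list(c("missing_in_outcome", 8), c("ambiguous_palindromic", 115),
                  c("confounders", 7), c("presso_outliers", 8),
                  c("steiger_direction", 0), c("bonferroni_outcome", 26)))
    led <- ledger_add(led, st[1], as.integer(st[2]))
  expect_identical(ledger_final(led), 752L)
  df <- as.data.frame(led)
  expect_identical(df$remaining[nrow(df)], 752L)
  expect_identical(916L - sum(df$removed), ledger_final(led))
  expect_error(ledger_add(led, "x", -1), "non-negative")
  expect_error(ledger_add(led, "x", 753), "only")
  expect_identical(as.data.frame(as_ledger(df)), df)
})

test_that("a permissive cascade removes nothing", {
  cfg <- simulation_config(n_variants = 30, theta = 0.15, seed = 9,
                           instrument_strength = c(0.15, 0.02))
  pair <- generate_pair(cfg)
  cc <- cascade_config(p_threshold = 0.999, f_min = 0, presso = FALSE,
                       bonferroni_alpha = 1e-300)
  res <- run_cascade(pair$exposure, pair$outcome, cc)
  expect_identical(res$ledger$initial_count, 30L)
  expect_identical(ledger_final(res$ledger), 30L)
  expect_true(all(res$ledger$stages$removed == 0L))
})

test_that("the cascade is deterministic and conserves counts", {
  cfg <- simulation_config(n_variants = 60, theta = 0.2, seed = 13,
                           prop_palindromic = 0.15, prop_flipped = 0.1,
                           prop_invalid = 0.1, pleiotropy_mode = "directional",
                           pleiotropy_scale = 0.2)
  pair <- generate_pair(cfg)
  cc <- cascade_config(p_threshold = 1e-6, presso_nsim = 200, seed = 4)
  r1 <- run_cascade(pair$exposure, pair$outcome, cc)
  r2 <- run_cascade(pair$exposure, pair$outcome, cc)
  expect_identical(r1$ledger, r2$ledger)
  expect_equal(as.data.frame(r1$set), as.data.frame(r2$set))
  expect_identical(ledger_final(r1$ledger), nrow(r1$set))
  expect_gt(r1$ledger$stages$removed[
    r1$ledger$stages$stage == "ambiguous_palindromic"], 0L)
})
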