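# shared fixtures, built in code

# harmonized set straight from a simulated pair (no cascade filtering),
# carrying the case fraction the generator used
sim_set <- function(config) {
  pair <- generate_pair(config)
  set <- harmonize(pair$exposure, pair$outcome)
  attr(set, "case_fraction") <- config$case_fraction
  set
}

# hand-built set from explicit vectors (no simulation)
toy_set <- function(gamma, Gamma, se_gamma = 0.01, se_Gamma = 0.01, ...) {
  J <- length(gamma)
  harmonized_set(gamma = gamma, se_gamma = rep_len(se_gamma, J),
                 Gamma = Gamma, se_Gamma = rep_len(se_Gamma, J), ...)
}

# minimal sensitivity report for decision-rule tests
fake_report <- function(egger_intercept_pval = NA, q_ivw_pval = NA,
                        i2_gx = 0.95, power = 1) {
  structure(list(exposure_id = "x", outcome_id = "y", n_snp = 10L,
                 q_ivw = NA_real_, q_ivw_pval = q_ivw_pval,
                 q_egger = NA_real_, q_egger_pval = NA_real_,
                 egger_intercept = NA_real_,
                 egger_intercept_pval = egger_intercept_pval,
                 i2_gx = i2_gx, nome_flag = i2_gx < 0.9,
                 steiger_direction = TRUE, steiger_pval = 1e-10,
                 loo_stable = TRUE, loo = NULL,
                 presso_global_pval = NA_real_, presso_outliers = character(),
                 presso_distortion_pval = NA_real_, power = power),
            class = "sensitivity_report")
}

# a summary-stats data frame with canonical columns
toy_stats_df <- function(n = 3, pval = NULL) {
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = "1",
             pos = seq_len(n) * 1e6,
             effect_allele = rep_len(c("A", "C", "G"), n),
             other_allele = rep_len(c("G", "T", "A"), n),
             eaf = 0.3, beta = 0.1, se = 0.01,
             pval = pval %||% rep(1e-9, n), n = 10000,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
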