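#!/usr/bin/env Rscript
# Step 1 — simulate the study's two-sample GWAS inputs.
#
# Forward direction: a continuous brain imaging-derived phenotype (IDP,
# SD units, n = 8,428) as exposure against an IBD case-control outcome
# (log-odds, n = 27,432, case fraction 0.254).  Reverse direction: the
# disease as exposure against the IDP.  Both tables carry palindromic and
# allele-flipped records so the harmonization stages have work to do, and
# an offline annotation table marks a couple of instruments as
# confounder-associated (standing in for a phenome-wide lookup).

library(mrpipe)
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

fwd_cfg <- simulation_config(
  n_variants = 120, theta = 0.25,
  instrument_strength = c(0.1, 0.03),
  pleiotropy_mode = "balanced", prop_invalid = 0.15, pleiotropy_scale = 0.03,
  n_exposure = 8428, n_outcome = 27432, case_fraction = 0.254,
  prop_palindromic = 0.15, prop_flipped = 0.2,
  ld_block_size = 3, ld_r2 = 0.6, seed = 101)

rev_cfg <- simulation_config(
  n_variants = 150, theta = 0.08,
  instrument_strength = c(0.12, 0.02),
  n_exposure = 27432, n_outcome = 8428, case_fraction = 0.254,
  outcome_type = "continuous",
  prop_palindromic = 0.1, prop_flipped = 0.1, seed = 202)

for (d in list(list(name = "forward", cfg = fwd_cfg),
               list(name = "reverse", cfg = rev_cfg))) {
  pair <- generate_pair(d$cfg)
  write_table(pair$exposure, sprintf("results/data/%s_exposure.tsv", d$name))
  write_table(pair$outcome, sprintf("results/data/%s_outcome.tsv", d$name))
  write_table(pair$truth, sprintf("results/data/%s_truth.tsv", d$name))
  write_table(ld_table(d$cfg), sprintf("results/data/%s_ld.tsv", d$name))
  cat(sprintf("%s: %d variants simulated (true effect %.2f, %d invalid)\n",
              d$name, d$cfg$n_variants, d$cfg$theta, sum(!pair$truth$valid)))
}

# offline confounder annotation: two forward instruments are flagged as
# genome-wide associated with known confounders
ann <- data.frame(variant_id = c("rs5", "rs17", "rs23"),
                  trait = c("serum vitamin D", "depression", "height"),
                  p = c(1e-9, 3e-12, 1e-10))
write_table(ann, "results/data/annotation.tsv")
cat("annotation table: 3 variant-trait associations (2 confounder traits)\n")
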