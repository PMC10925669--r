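#' Configuration for the synthetic two-sample GWAS generator
#'
#' Bundles every knob of the summary-statistics generator together with
#' the true causal effect, so that a config plus its seed fully determines
#' the simulated tables (bit-identical reproduction).
#'
#' Defaults emulate the statistical shape of a brain-imaging-phenotype
#' exposure GWAS (continuous trait, SD units, n = 8,428) against an
#' inflammatory-bowel-disease case-control outcome GWAS (log-odds,
#' n = 27,432 with case fraction 0.254), with genome-wide-significant
#' instruments of moderate strength (median F around 30).
#'
#' @param n_variants number of variants.
#' @param theta true causal effect (log-odds per SD exposure for a binary
#'   outcome; SD per SD for a continuous outcome).
#' @param instrument_strength length-2 numeric `c(mean, sd)` of the normal
#'   distribution the true per-variant exposure effects are drawn from.
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct effects centred
#'   at zero), `"directional"` (centred at `pleiotropy_scale`) or
#'   `"correlated"` (InSIDE violation: direct effect = `pleiotropy_cor`
#'   times the instrument effect plus noise).
#' @param pleiotropy_scale SD (and, for directional mode, mean) of the
#'   direct effects of invalid instruments.
#' @param pleiotropy_cor slope linking direct effects to instrument
#'   strength in correlated mode.
#' @param prop_invalid fraction of variants given a direct effect.
#' @param n_exposure,n_outcome the two (non-overlapping) GWAS sample sizes.
#' @param case_fraction case proportion of a binary outcome, in (0, 1).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param maf_range minor-allele-frequency interval within (0, 0.5].
#' @param prop_palindromic fraction of variants assigned A/T or C/G
#'   allele pairs.
#' @param prop_flipped fraction of variants whose outcome record has
#'   effect/other alleles swapped (with beta negated), exercising
#'   harmonization.
#' @param noise_scale multiplier on the sampling noise added to the true
#'   effects; 0 gives noiseless observed effects (the reported standard
#'   errors stay at their sample-size-consistent values).
#' @param ld_block_size variants per LD block (1 = all independent).
#' @param ld_r2 within-block squared correlation reported by [ld_table()].
#' @param seed integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_variants = 50L,
                              theta = 0.2,
                              instrument_strength = c(mean = 0.1, sd = 0.03),
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional", "correlated"),
                              pleiotropy_scale = 0.05,
                              pleiotropy_cor = 0.5,
                              prop_invalid = 0,
                              n_exposure = 8428L,
                              n_outcome = 27432L,
                              case_fraction = 0.254,
                              outcome_type = c("binary", "continuous"),
                              maf_range = c(0.05, 0.5),
                              prop_palindromic = 0,
                              prop_flipped = 0,
                              noise_scale = 1,
                              ld_block_size = 1L,
                              ld_r2 = 0.8,
                              seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  outcome_type <- match.arg(outcome_type)
  stopifnot(n_variants >= 1, length(instrument_strength) == 2,
            n_exposure >= 2, n_outcome >= 2, ld_block_size >= 1)
  if (instrument_strength[2] < 0) stop("instrument_strength sd must be >= 0")
  if (pleiotropy_scale < 0) stop("pleiotropy_scale must be >= 0")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  for (p in c(prop_invalid, prop_palindromic, prop_flipped))
    if (p < 0 || p > 1) stop("fractions must lie in [0, 1]")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must lie in (0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  structure(list(
    n_variants = as.integer(n_variants), theta = theta,
    instrument_strength = unname(instrument_strength),
    pleiotropy_mode = pleiotropy_mode, pleiotropy_scale = pleiotropy_scale,
    pleiotropy_cor = pleiotropy_cor, prop_invalid = prop_invalid,
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    case_fraction = case_fraction, outcome_type = outcome_type,
    maf_range = maf_range, prop_palindromic = prop_palindromic,
    prop_flipped = prop_flipped, noise_scale = noise_scale,
    ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# standard error of a per-allele effect estimate given allele frequency and
# sample size; binary traits use the log-odds-scale approximation
# 1/sqrt(n K (1-K) 2f(1-f)), continuous traits 1/sqrt(n 2f(1-f)) (trait
# variance 1).
se_from_n <- function(maf, n, trait_type, case_fraction = NA) {
  v <- 2 * maf * (1 - maf)
  if (trait_type == "binary")
    1 / sqrt(n * case_fraction * (1 - case_fraction) * v)
  else
    1 / sqrt(n * v)
}

#' Generate a synthetic two-sample GWAS pair with known causal structure
#'
#' Draws per-variant true exposure effects gamma_j from the instrument
#' strength distribution, direct (pleiotropic) outcome effects alpha_j for
#' the invalid fraction, sets the true outcome effect to
#' `Gamma_j = theta * gamma_j + alpha_j`, and observes both with
#' independent noise whose standard errors are consistent with the two
#' sample sizes and the allele frequency — the two-sample (no overlap)
#' noise structure.  Palindromic variants get A/T or C/G allele pairs;
#' flipped variants have their alleles swapped (beta negated, eaf
#' mirrored) in the outcome table only.
#'
#' @param config a [simulation_config()].
#' @return list with elements `exposure` and `outcome` ([summary_stats]
#'   tables) and `truth`, a data frame of per-variant true effects
#'   (`gamma`, `alpha`, `Gamma`), the validity flag and the
#'   palindromic/flipped assignments.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    J <- config$n_variants
    maf <- runif(J, config$maf_range[1], config$maf_range[2])
    gamma <- rnorm(J, config$instrument_strength[1], config$instrument_strength[2])

    alpha <- numeric(J)
    valid <- rep(TRUE, J)
    n_invalid <- round_half_up(config$prop_invalid * J)
    if (config$pleiotropy_mode != "none" && n_invalid > 0) {
      idx <- sample.int(J, n_invalid)
      valid[idx] <- FALSE
      sc <- config$pleiotropy_scale
      alpha[idx] <- switch(config$pleiotropy_mode,
        balanced    = rnorm(n_invalid, 0, sc),
        directional = rnorm(n_invalid, sc, sc / 2),
        correlated  = config$pleiotropy_cor * gamma[idx] + rnorm(n_invalid, 0, sc))
    }
    Gamma <- config$theta * gamma + alpha

    se_g <- se_from_n(maf, config$n_exposure, "continuous")
    se_G <- se_from_n(maf, config$n_outcome, config$outcome_type,
                      config$case_fraction)
    beta_exp <- gamma + config$noise_scale * rnorm(J) * se_g
    beta_out <- Gamma + config$noise_scale * rnorm(J) * se_G

    # allele pairs: palindromic variants are A/T or C/G; the rest get a
    # non-ambiguous transition pair
    n_pal <- round_half_up(config$prop_palindromic * J)
    palindromic <- rep(FALSE, J)
    if (n_pal > 0) palindromic[sample.int(J, n_pal)] <- TRUE
    ea <- oa <- character(J)
    pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                        ncol = 2, byrow = TRUE)
    std_pairs <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                        ncol = 2, byrow = TRUE)
    pick_pal <- sample.int(4, J, replace = TRUE)
    pick_std <- sample.int(4, J, replace = TRUE)
    ea <- ifelse(palindromic, pal_pairs[pick_pal, 1], std_pairs[pick_std, 1])
    oa <- ifelse(palindromic, pal_pairs[pick_pal, 2], std_pairs[pick_std, 2])

    n_flip <- round_half_up(config$prop_flipped * J)
    flipped <- rep(FALSE, J)
    if (n_flip > 0) flipped[sample.int(J, n_flip)] <- TRUE

    block <- ceiling(seq_len(J) / config$ld_block_size)
    within <- seq_len(J) - (block - 1L) * config$ld_block_size
    pos <- block * 1e6 + within * 1e4
    ids <- paste0("rs", seq_len(J))

    exposure <- summary_stats(data.frame(
      variant_id = ids, chrom = "1", pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta_exp, se = se_g,
      pval = 2 * pnorm(-abs(beta_exp / se_g)),
      n = config$n_exposure, stringsAsFactors = FALSE
    ), trait_id = "exposure", trait_type = "continuous")

    out_ea <- ifelse(flipped, oa, ea)
    out_oa <- ifelse(flipped, ea, oa)
    out_beta <- ifelse(flipped, -beta_out, beta_out)
    out_eaf <- ifelse(flipped, 1 - maf, maf)
    outcome <- summary_stats(data.frame(
      variant_id = ids, chrom = "1", pos = pos,
      effect_allele = out_ea, other_allele = out_oa, eaf = out_eaf,
      beta = out_beta, se = se_G,
      pval = 2 * pnorm(-abs(out_beta / se_G)),
      n = config$n_outcome, stringsAsFactors = FALSE
    ), trait_id = "outcome", trait_type = config$outcome_type)

    truth <- data.frame(variant_id = ids, gamma = gamma, alpha = alpha,
                        Gamma = Gamma, valid = valid,
                        palindromic = palindromic, flipped = flipped,
                        stringsAsFactors = FALSE)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Pairwise LD table for a simulated variant set
#'
#' Emits the block-diagonal LD structure implied by a
#' [simulation_config()]: every pair of variants in the same block is
#' reported at `ld_r2`; cross-block pairs are absent (r-squared 0 by
#' convention of the clumping lookup).
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `id_a`, `id_b`, `r2`.
#' @export
ld_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  J <- config$n_variants
  block <- ceiling(seq_len(J) / config$ld_block_size)
  ids <- paste0("rs", seq_len(J))
  rows <- list()
  for (b in unique(block)) {
    members <- ids[block == b]
    if (length(members) < 2) next
    pr <- t(utils::combn(members, 2))
    rows[[length(rows) + 1L]] <- data.frame(id_a = pr[, 1], id_b = pr[, 2],
                                            r2 = config$ld_r2,
                                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(data.frame(id_a = character(), id_b = character(),
                                       r2 = numeric()))
  do.call(rbind, rows)
}
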