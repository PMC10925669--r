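#' Construct a harmonized exposure/outcome variant set
#'
#' The unit every estimator consumes: per-variant exposure effects
#' (`gamma`, `se_gamma`) and outcome effects (`Gamma`, `se_Gamma`)
#' expressed per the *same* effect allele.  Usually produced by
#' [harmonize()]; the constructor is exported so simulations and tests can
#' build sets directly.
#'
#' @param gamma,se_gamma exposure effects and standard errors.
#' @param Gamma,se_Gamma outcome effects and standard errors.
#' @param variant_id,effect_allele,other_allele,eaf optional per-variant
#'   annotation.
#' @param pval_exposure,pval_outcome optional marginal p-values (computed
#'   from the z ratio when omitted).
#' @param exposure_id,outcome_id,exposure_type,outcome_type,n_exposure,n_outcome,case_fraction
#'   trait metadata carried as attributes.
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(gamma, se_gamma, Gamma, se_Gamma,
                           variant_id = NULL, effect_allele = NULL,
                           other_allele = NULL, eaf = NULL,
                           pval_exposure = NULL, pval_outcome = NULL,
                           exposure_id = "exposure", outcome_id = "outcome",
                           exposure_type = "continuous",
                           outcome_type = "binary",
                           n_exposure = NA_real_, n_outcome = NA_real_,
                           case_fraction = NA_real_) {
  J <- length(gamma)
  stopifnot(J >= 1, length(se_gamma) == J, length(Gamma) == J,
            length(se_Gamma) == J)
  if (any(se_gamma <= 0) || any(se_Gamma <= 0))
    stop("standard errors must be positive")
  df <- data.frame(
    variant_id = variant_id %||% paste0("v", seq_len(J)),
    effect_allele = effect_allele %||% rep(NA_character_, J),
    other_allele = other_allele %||% rep(NA_character_, J),
    eaf = eaf %||% rep(NA_real_, J),
    gamma = gamma, se_gamma = se_gamma, Gamma = Gamma, se_Gamma = se_Gamma,
    pval_exposure = pval_exposure %||% 2 * pnorm(-abs(gamma / se_gamma)),
    pval_outcome = pval_outcome %||% 2 * pnorm(-abs(Gamma / se_Gamma)),
    stringsAsFactors = FALSE
  )
  structure(df, exposure_id = exposure_id, outcome_id = outcome_id,
            exposure_type = exposure_type, outcome_type = outcome_type,
            n_exposure = n_exposure, n_outcome = n_outcome,
            case_fraction = case_fraction,
            class = c("harmonized_set", "data.frame"))
}

hs_meta <- function(set) {
  attributes(set)[c("exposure_id", "outcome_id", "exposure_type",
                    "outcome_type", "n_exposure", "n_outcome",
                    "case_fraction")]
}

hs_subset <- function(set, keep) {
  out <- as.data.frame(set)[keep, , drop = FALSE]
  rownames(out) <- NULL
  meta <- hs_meta(set)
  attributes(out) <- c(attributes(out), meta)
  class(out) <- c("harmonized_set", "data.frame")
  out
}

# keep class + trait metadata through row subsetting
#' @export
`[.harmonized_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    meta <- hs_meta(x)
    for (nm in names(meta)) attr(out, nm) <- meta[[nm]]
    class(out) <- class(x)
  }
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("harmonized_set: %s -> %s, %d variants\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Genome-wide significance screen
#'
#' Keeps variants associated with the trait at `pval < p_threshold`
#' (5e-8 is the conventional genome-wide level; a relaxed 1e-6 is common
#' when an exposure yields too few instruments).
#'
#' @param table a [summary_stats] table.
#' @param p_threshold significance level in (0, 1).
#' @return The subset table; an empty result is allowed but flagged with a
#'   warning.
#' @export
select_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_stats"),
            p_threshold > 0, p_threshold < 1)
  out <- table[table$pval < p_threshold, ]
  if (nrow(out) == 0L) warning("no variants pass the significance threshold")
  out
}

#' Greedy LD clumping by p-value
#'
#' Orders variants by ascending p-value and keeps each in turn, removing
#' any not-yet-kept variant on the same chromosome within `window_kb` of a
#' kept variant whose pairwise r-squared with it is at least `r2_max`.
#' Pairs absent from `ld` are treated as uncorrelated.
#'
#' @param table a [summary_stats] table (needs `chrom`/`pos` when a window
#'   is enforced).
#' @param ld pairwise LD as a data frame `id_a`, `id_b`, `r2`, or `NULL`
#'   (all pairs uncorrelated).
#' @param r2_max clumping r-squared threshold (default 0.01).
#' @param window_kb clumping window in kilobases (default 10,000 kb).
#' @return The clumped subset, in the original table order.
#' @export
clump <- function(table, ld = NULL, r2_max = 0.01, window_kb = 10000) {
  stopifnot(inherits(table, "summary_stats"))
  if (window_kb < 0) stop("negative clumping window")
  if (nrow(table) <= 1L || is.null(ld) || nrow(ld) == 0L) return(table)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  r2 <- setNames(ld$r2, key(ld$id_a, ld$id_b))
  ord <- order(table$pval)
  ids <- table$variant_id
  pos <- table$pos
  chrom <- table$chrom
  state <- setNames(rep("open", nrow(table)), ids)  # open / kept / removed
  for (i in ord) {
    if (state[ids[i]] != "open") next
    state[ids[i]] <- "kept"
    near <- which(state == "open" &
                    (is.na(chrom) | is.na(chrom[i]) | chrom == chrom[i]) &
                    (is.na(pos) | is.na(pos[i]) |
                       abs(pos - pos[i]) <= window_kb * 1000))
    if (length(near)) {
      r <- r2[key(ids[near], ids[i])]
      r[is.na(r)] <- 0
      state[ids[near][r >= r2_max]] <- "removed"
    }
  }
  table[state[ids] == "kept", ]
}

#' Instrument-strength F statistic
#'
#' `F = beta^2 / se^2`, the square of the marginal z statistic; F > 10 is
#' the conventional bar for a non-weak instrument.
#'
#' @param beta,se per-variant effect and standard error (vectorized).
#' @return F statistic(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  beta^2 / se^2
}

#' Drop weak instruments
#'
#' Retains variants with `F > f_min` (strict inequality).
#'
#' @param table a [summary_stats] table.
#' @param f_min weak-instrument bound, default 10.
#' @return The filtered table.
#' @export
filter_weak <- function(table, f_min = 10) {
  stopifnot(inherits(table, "summary_stats"))
  if (nrow(table) == 0L) return(table)
  table[f_statistic(table$beta, table$se) > f_min, ]
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize outcome effects onto the exposure effect alleles
#'
#' Matches variants by id, then aligns each outcome record to the
#' exposure's effect allele: records already aligned (directly or after
#' strand complementation) are kept as is; records with swapped alleles
#' have their beta negated and eaf mirrored.  Variants missing from the
#' outcome are removed and counted; palindromic (A/T, C/G) variants —
#' whose strand cannot be resolved from alleles alone — and records whose
#' alleles cannot be reconciled at all are removed when `strict_palindrome`
#' is on (there is no allele-frequency rescue).
#'
#' @param exposure a [summary_stats] table of selected instruments.
#' @param outcome a [summary_stats] table for the outcome trait.
#' @param strict_palindrome drop palindromic variants (default `TRUE`).
#' @return A [harmonized_set]; removal counts are attached as
#'   `attr(, "removals")` (ids per stage: `missing_in_outcome`,
#'   `ambiguous_palindromic`).
#' @export
harmonize <- function(exposure, outcome, strict_palindrome = TRUE) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  m <- match(exposure$variant_id, outcome$variant_id)
  missing_ids <- exposure$variant_id[is.na(m)]
  exp_df <- as.data.frame(exposure)[!is.na(m), , drop = FALSE]
  out_df <- as.data.frame(outcome)[m[!is.na(m)], , drop = FALSE]

  ea <- exp_df$effect_allele; oa <- exp_df$other_allele
  o_ea <- out_df$effect_allele; o_oa <- out_df$other_allele
  pal <- is_palindromic(ea, oa)

  direct <- o_ea == ea & o_oa == oa
  swapped <- o_ea == oa & o_oa == ea
  comp_direct <- COMPLEMENT[o_ea] == ea & COMPLEMENT[o_oa] == oa
  comp_swapped <- COMPLEMENT[o_ea] == oa & COMPLEMENT[o_oa] == ea
  resolvable <- direct | swapped | comp_direct | comp_swapped
  # for palindromic variants direct and comp_swapped coincide: orientation
  # is genuinely ambiguous
  ambiguous <- !resolvable | (pal & strict_palindrome)

  flip <- (swapped | comp_swapped) & !ambiguous
  Gamma <- ifelse(flip, -out_df$beta, out_df$beta)

  keep <- !ambiguous
  removed_amb <- exp_df$variant_id[ambiguous]
  exp_k <- exp_df[keep, , drop = FALSE]
  out_k <- out_df[keep, , drop = FALSE]
  if (nrow(exp_k) == 0L) warning("no variants remain after harmonization")

  set <- harmonized_set(
    gamma = exp_k$beta, se_gamma = exp_k$se,
    Gamma = Gamma[keep], se_Gamma = out_k$se,
    variant_id = exp_k$variant_id, effect_allele = exp_k$effect_allele,
    other_allele = exp_k$other_allele, eaf = exp_k$eaf,
    pval_exposure = exp_k$pval, pval_outcome = out_k$pval,
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"),
    exposure_type = attr(exposure, "trait_type"),
    outcome_type = attr(outcome, "trait_type"),
    n_exposure = if (all(is.na(exp_k$n))) NA_real_ else max(exp_k$n, na.rm = TRUE),
    n_outcome = if (all(is.na(out_k$n))) NA_real_ else max(out_k$n, na.rm = TRUE)
  )
  attr(set, "removals") <- list(missing_in_outcome = missing_ids,
                                ambiguous_palindromic = removed_amb)
  set
}

#' Screen instruments against known confounder associations
#'
#' Removes variants that an offline annotation table (variant, associated
#' trait, association p-value) links to any listed confounder trait at
#' `p < p_threshold`.  The annotation table stands in for an online
#' phenome-wide lookup, keeping the screen reproducible.
#'
#' @param set a [harmonized_set].
#' @param annotation data frame with columns `variant_id`, `trait`, `p`.
#' @param p_threshold association significance level (default 5e-8).
#' @param confounder_traits traits considered confounders; `NULL` means
#'   every trait present in the annotation.
#' @return The filtered set; removed ids in `attr(, "removals")`.
#' @export
screen_confounders <- function(set, annotation, p_threshold = 5e-8,
                               confounder_traits = NULL) {
  stopifnot(inherits(set, "harmonized_set"))
  if (is.null(annotation) || nrow(annotation) == 0L) {
    attr(set, "removals") <- list(confounders = character())
    return(set)
  }
  stopifnot(all(c("variant_id", "trait", "p") %in% names(annotation)))
  if (is.null(confounder_traits)) confounder_traits <- unique(annotation$trait)
  hits <- annotation[annotation$trait %in% confounder_traits &
                       annotation$p < p_threshold, , drop = FALSE]
  bad <- set$variant_id %in% hits$variant_id
  out <- hs_subset(set, !bad)
  attr(out, "removals") <- list(confounders = set$variant_id[bad])
  out
}

#' Bonferroni filter on direct outcome association
#'
#' Removes variants whose outcome p-value falls below `alpha / n`, where
#' `n` is the set size entering this stage — instruments this strongly
#' associated with the outcome are suspected of acting on it directly.
#'
#' @param set a [harmonized_set].
#' @param alpha family-wise level (default 0.05).
#' @return The filtered set; removed ids in `attr(, "removals")`.
#' @export
bonferroni_outcome_filter <- function(set, alpha = 0.05) {
  stopifnot(inherits(set, "harmonized_set"))
  thr <- alpha / nrow(set)
  bad <- set$pval_outcome < thr
  out <- hs_subset(set, !bad)
  attr(out, "removals") <- list(bonferroni_outcome = set$variant_id[bad])
  out
}

#' Remove variants whose per-variant direction test fails
#'
#' Applies the per-variant Steiger test ([steiger()]) and drops variants
#' for which the outcome explains significantly more variance than the
#' exposure (wrong direction at `p < alpha`).
#'
#' @param set a [harmonized_set].
#' @param alpha per-variant significance level (default 0.05).
#' @param ... forwarded to [steiger()].
#' @return The filtered set; removed ids in `attr(, "removals")`.
#' @export
steiger_filter <- function(set, alpha = 0.05, ...) {
  stopifnot(inherits(set, "harmonized_set"))
  st <- steiger(set, per_variant = TRUE, ...)
  bad <- !st$direction & st$pval < alpha
  out <- hs_subset(set, !bad)
  attr(out, "removals") <- list(steiger_direction = set$variant_id[bad])
  out
}

#' Cascade configuration
#'
#' @param p_threshold instrument significance level (1e-6 is the relaxed
#'   forward default; 5e-8 the genome-wide reverse default).
#' @param clump_r2,clump_kb LD clumping parameters (r2 < 0.01 within a
#'   10,000 kb window by default; set `clump_kb = 10` for a literal 10 kb
#'   reading).
#' @param ld pairwise LD table for [clump()], or `NULL`.
#' @param f_min weak-instrument F bound.
#' @param strict_palindrome drop palindromic variants during harmonization.
#' @param annotation,confounder_traits,confounder_p confounder screen
#'   inputs (see [screen_confounders()]).
#' @param presso run the MR-PRESSO outlier stage (needs >= 4 variants).
#' @param presso_nsim,presso_alpha MR-PRESSO simulation count and outlier
#'   level.
#' @param steiger_alpha per-variant direction-test level.
#' @param bonferroni_alpha level for the direct-outcome filter.
#' @param seed seed for the PRESSO simulations.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(p_threshold = 1e-6, clump_r2 = 0.01,
                           clump_kb = 10000, ld = NULL, f_min = 10,
                           strict_palindrome = TRUE, annotation = NULL,
                           confounder_traits = NULL, confounder_p = 5e-8,
                           presso = TRUE, presso_nsim = 1000,
                           presso_alpha = 0.05, steiger_alpha = 0.05,
                           bonferroni_alpha = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "cascade_config")
}

#' Run the full instrument-selection cascade
#'
#' Significance screen, LD clumping, weak-instrument filter, allele
#' harmonization (missing-in-outcome and ambiguous/palindromic removals),
#' confounder screen, MR-PRESSO outlier removal, per-variant Steiger
#' direction filter, and the Bonferroni direct-outcome filter — in that
#' order, with every removal logged in an [ledger_new()] ledger whose
#' conservation invariant is checked at the end.
#'
#' @param exposure,outcome [summary_stats] tables.
#' @param config a [cascade_config()].
#' @return list with elements `set` (the final [harmonized_set]) and
#'   `ledger` (the [ledger_new()] accounting).
#' @export
run_cascade <- function(exposure, outcome, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"))
  sig <- suppressWarnings(select_significant(exposure, config$p_threshold))
  led <- ledger_new(nrow(sig))
  if (nrow(sig) == 0L) stop("no significant instruments; cascade cannot run")

  cl <- clump(sig, ld = config$ld, r2_max = config$clump_r2,
              window_kb = config$clump_kb)
  led <- ledger_add(led, "ld_clump", nrow(sig) - nrow(cl))

  st <- filter_weak(cl, config$f_min)
  led <- ledger_add(led, "weak_instruments", nrow(cl) - nrow(st))

  set <- harmonize(st, outcome, strict_palindrome = config$strict_palindrome)
  rem <- attr(set, "removals")
  led <- ledger_add(led, "missing_in_outcome", length(rem$missing_in_outcome))
  led <- ledger_add(led, "ambiguous_palindromic",
                    length(rem$ambiguous_palindromic))

  set2 <- screen_confounders(set, config$annotation,
                             p_threshold = config$confounder_p,
                             confounder_traits = config$confounder_traits)
  led <- ledger_add(led, "confounders", nrow(set) - nrow(set2))

  if (isTRUE(config$presso) && nrow(set2) >= 4L) {
    pr <- mr_presso(set2, n_sim = config$presso_nsim, seed = config$seed,
                    outlier_alpha = config$presso_alpha)
    set3 <- hs_subset(set2, !(set2$variant_id %in% pr$outliers))
  } else {
    set3 <- set2
  }
  led <- ledger_add(led, "presso_outliers", nrow(set2) - nrow(set3))

  set4 <- steiger_filter(set3, alpha = config$steiger_alpha)
  led <- ledger_add(led, "steiger_direction", nrow(set3) - nrow(set4))

  set5 <- bonferroni_outcome_filter(set4, alpha = config$bonferroni_alpha)
  led <- ledger_add(led, "bonferroni_outcome", nrow(set4) - nrow(set5))

  stopifnot(ledger_final(led) == nrow(set5))
  list(set = set5, ledger = led)
}
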