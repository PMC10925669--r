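#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared differences between each variant's Wald ratio
#' and the overall estimate, `Q = sum w_j (b_j - theta)^2` with
#' `w_j = gamma_j^2 / se_Gamma_j^2` (the inverse variance of the
#' first-order ratio).  Referred to the chi-square with J - 1 degrees of
#' freedom; p < 0.05 is the conventional heterogeneity flag.
#'
#' @param set a [harmonized_set].
#' @param theta the pooled estimate the deviations are taken from; the
#'   fixed-effect IVW solution when omitted.
#' @return list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(set, theta = NULL) {
  stopifnot(inherits(set, "harmonized_set"))
  w <- set$gamma^2 / set$se_Gamma^2
  b <- set$Gamma / set$gamma
  if (is.null(theta)) theta <- sum(w * b) / sum(w)
  q <- sum(w * (b - theta)^2)
  df <- nrow(set) - 1L
  list(q = q, df = df,
       pval = if (df >= 1) pchisq(q, df, lower.tail = FALSE) else NA_real_)
}

#' Rucker's Q' (residual heterogeneity after the Egger intercept)
#'
#' @param set a [harmonized_set] with at least 3 variants.
#' @return list with `q`, `df`, `pval`.
#' @export
rucker_q <- function(set) {
  fit <- egger(set)
  df <- nrow(set) - 2L
  list(q = fit$q, df = df, pval = pchisq(fit$q, df, lower.tail = FALSE))
}

#' I-squared of the instrument-strength estimates (NOME diagnostic)
#'
#' `I2_GX = max(0, (Q_GX - (J-1)) / Q_GX)`, with `Q_GX` the heterogeneity
#' of the sign-oriented exposure effects about their inverse-variance
#' weighted mean.  Values below 0.9 indicate that measurement error in the
#' instrument effects will attenuate the Egger slope (NOME violation), and
#' raise a flag.
#'
#' @param set a [harmonized_set].
#' @return list with `i2`, `q_gx` and `nome_flag` (`TRUE` when I2 < 0.9).
#' @export
i2_gx <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  o <- orient_positive(set)
  w <- 1 / o$sg^2
  gbar <- sum(w * o$g) / sum(w)
  q_gx <- sum(w * (o$g - gbar)^2)
  i2 <- if (q_gx > 0) max(0, (q_gx - (nrow(set) - 1)) / q_gx) else 0
  list(i2 = i2, q_gx = q_gx, nome_flag = i2 < 0.9)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the causal effect J times, each time dropping one
#' variant.  The set is judged stable when every leave-one-out estimate
#' keeps the sign of the full estimate and its 95% CI overlaps the full
#' CI; variants violating either condition are reported as influential.
#'
#' @param set a [harmonized_set] with at least 2 variants.
#' @param estimator estimator function applied to each subset (default
#'   [ivw_mre()]).
#' @return list with `estimates` (per-dropped-variant data frame),
#'   `stable`, and `influential` (variant ids).
#' @export
leave_one_out <- function(set, estimator = ivw_mre) {
  stopifnot(inherits(set, "harmonized_set"))
  J <- nrow(set)
  if (J < 2) stop("leave-one-out needs at least 2 variants")
  full <- estimator(set)
  rows <- lapply(seq_len(J), function(j) {
    fit <- estimator(hs_subset(set, -j))
    data.frame(variant_dropped = set$variant_id[j], beta = fit$beta,
               se = fit$se, ci_low_log = fit$beta - qnorm(0.975) * fit$se,
               ci_high_log = fit$beta + qnorm(0.975) * fit$se,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  full_lo <- full$beta - qnorm(0.975) * full$se
  full_hi <- full$beta + qnorm(0.975) * full$se
  ok <- sign(est$beta) == sign(full$beta) &
    est$ci_low_log <= full_hi & est$ci_high_log >= full_lo
  list(estimates = est, stable = all(ok), influential = est$variant_dropped[!ok])
}

# leave-one-out fixed-effect IVW estimates for each column of the
# (n_rep x J) matrices G and g, with per-variant weights w (length J):
# returns an n_rep x J matrix of theta_{-j}
loo_theta_matrix <- function(Gm, gm, w) {
  wg2 <- sweep(gm^2, 2, w, `*`)
  wgG <- sweep(gm * Gm, 2, w, `*`)
  S1 <- rowSums(wgG); S2 <- rowSums(wg2)
  (S1 - wgG) / (S2 - wg2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed weighted residual sum of squares of each
#' variant about its leave-one-out IVW prediction is compared with its
#' parametric null distribution, simulated by resampling exposure and
#' outcome effects from the fitted model.  Outlier test: each variant's
#' observed residual is referred to its own simulated distribution, with
#' Bonferroni adjustment across variants.  Distortion test: the shift in
#' the IVW estimate caused by removing the flagged outliers is compared
#' with shifts from removing random subsets of the same size.
#'
#' @param set a [harmonized_set] with at least 4 variants.
#' @param n_sim simulated null datasets (default 1000).
#' @param seed RNG seed.
#' @param outlier_alpha level for the Bonferroni-adjusted per-variant
#'   outlier test (default 0.05).
#' @return list with `global_pval`, `outliers` (variant ids),
#'   `distortion_pval` (`NA` when no outliers) and `rss_obs`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed = 1L, outlier_alpha = 0.05) {
  stopifnot(inherits(set, "harmonized_set"))
  J <- nrow(set)
  if (J < 4) stop("MR-PRESSO needs at least 4 variants")
  g <- set$gamma; G <- set$Gamma; sg <- set$se_gamma; sG <- set$se_Gamma
  w <- 1 / sG^2

  th_loo <- drop(loo_theta_matrix(matrix(G, 1), matrix(g, 1), w))
  res_obs <- w * (G - th_loo * g)^2
  rss_obs <- sum(res_obs)

  with_seed(seed, {
    gm <- matrix(rnorm(n_sim * J, mean = rep(g, each = n_sim),
                       sd = rep(sg, each = n_sim)), n_sim, J)
    Gm <- matrix(rnorm(n_sim * J, mean = rep(th_loo * g, each = n_sim),
                       sd = rep(sG, each = n_sim)), n_sim, J)
    th_sim <- loo_theta_matrix(Gm, gm, w)
    res_sim <- sweep((Gm - th_sim * gm)^2, 2, w, `*`)
    rss_sim <- rowSums(res_sim)
    global_pval <- (1 + sum(rss_sim >= rss_obs)) / (1 + n_sim)

    # plain proportion (no +1 floor): the Bonferroni-adjusted outlier test
    # must be able to fall below alpha at moderate simulation counts
    p_var <- colSums(sweep(res_sim, 2, res_obs, `>=`)) / n_sim
    p_adj <- pmin(1, p_var * J)
    outliers <- set$variant_id[p_adj < outlier_alpha]

    distortion_pval <- NA_real_
    if (length(outliers) > 0 && length(outliers) < J - 1) {
      keep <- !(set$variant_id %in% outliers)
      ivw_theta <- function(idx) sum(w[idx] * g[idx] * G[idx]) / sum(w[idx] * g[idx]^2)
      d_obs <- ivw_theta(keep) - ivw_theta(seq_len(J))
      n_out <- sum(!keep)
      d_rand <- vapply(seq_len(min(n_sim, 500L)), function(i) {
        drop_idx <- sample.int(J, n_out)
        ivw_theta(setdiff(seq_len(J), drop_idx)) - ivw_theta(seq_len(J))
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (1 + length(d_rand))
    }
    list(global_pval = global_pval, outliers = outliers,
         distortion_pval = distortion_pval, rss_obs = rss_obs)
  })
}

# per-variant variance explained in a trait; continuous traits use
# r2 = t^2/(t^2 + n - 2); binary traits a pseudo-r2 on the latent scale
variant_r2 <- function(beta, se, n, eaf, trait_type, case_fraction = NA,
                       r2_method = "logodds") {
  if (trait_type == "continuous") {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  } else if (r2_method == "logodds") {
    v <- 2 * eaf * (1 - eaf)
    beta^2 * v / (beta^2 * v + pi^2 / 3)
  } else { # liability-scale approximation
    z <- dnorm(qnorm(case_fraction))
    b_liab <- beta * case_fraction * (1 - case_fraction) / z
    pmin(b_liab^2 * 2 * eaf * (1 - eaf), 0.999)
  }
}

#' Steiger directionality test
#'
#' Compares the variance each instrument explains in the exposure with
#' the variance it explains in the outcome; under a true
#' exposure-to-outcome effect the exposure r-squared must dominate.
#' Binary traits use a pseudo-r-squared (`"logodds"` latent-logistic
#' default, `"liability"` optional).  The pooled test converts the two
#' multiple correlations to Fisher z and refers their difference to the
#' two-sample normal reference
#' `z = (atanh r_exp - atanh r_out) / sqrt(1/(n_exp-3) + 1/(n_out-3))`.
#'
#' @param set a [harmonized_set].
#' @param per_variant return per-variant verdicts instead of the pooled
#'   one.
#' @param r2_method `"logodds"` or `"liability"` for binary traits.
#' @param n_exposure,n_outcome,case_fraction override set metadata.
#' @return Pooled: list with `direction` (`TRUE` when exposure variance
#'   dominates), `pval`, `r2_exposure`, `r2_outcome`.  Per-variant: data
#'   frame with one row per instrument.
#' @export
steiger <- function(set, per_variant = FALSE, r2_method = c("logodds", "liability"),
                    n_exposure = NULL, n_outcome = NULL, case_fraction = NULL) {
  stopifnot(inherits(set, "harmonized_set"))
  r2_method <- match.arg(r2_method)
  n_exp <- n_exposure %||% attr(set, "n_exposure")
  n_out <- n_outcome %||% attr(set, "n_outcome")
  K <- case_fraction %||% attr(set, "case_fraction")
  if (is.na(K) || is.null(K)) K <- 0.5
  if (is.null(n_exp) || is.na(n_exp)) n_exp <- 1e5
  if (is.null(n_out) || is.na(n_out)) n_out <- 1e5
  eaf <- ifelse(is.na(set$eaf), 0.25, set$eaf)

  r2e <- variant_r2(set$gamma, set$se_gamma, n_exp, eaf,
                    attr(set, "exposure_type") %||% "continuous", K, r2_method)
  r2o <- variant_r2(set$Gamma, set$se_Gamma, n_out, eaf,
                    attr(set, "outcome_type") %||% "binary", K, r2_method)

  steiger_z <- function(r2_exp, r2_out) {
    r_e <- sqrt(pmin(r2_exp, 0.999)); r_o <- sqrt(pmin(r2_out, 0.999))
    (atanh(r_e) - atanh(r_o)) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  }
  if (per_variant) {
    z <- steiger_z(r2e, r2o)
    return(data.frame(variant_id = set$variant_id, r2_exposure = r2e,
                      r2_outcome = r2o, direction = r2e > r2o,
                      pval = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE))
  }
  R2e <- min(sum(r2e), 0.999); R2o <- min(sum(r2o), 0.999)
  z <- steiger_z(R2e, R2o)
  list(direction = R2e > R2o, pval = 2 * pnorm(-abs(z)),
       r2_exposure = R2e, r2_outcome = R2o)
}

#' Analytic power for MR with a binary outcome
#'
#' Asymptotic two-sided power of the (fixed-effect) IVW Wald test for
#' detecting `log(or_alt)`, given the outcome sample size, its case
#' fraction and the variance in the exposure explained by the
#' instruments: the estimator's standard error is
#' `1 / sqrt(n K (1-K) r2)` and
#' `power = Phi(-z_{1-a/2} + |b|/se) + Phi(-z_{1-a/2} - |b|/se)`,
#' which equals `alpha` exactly at `or_alt = 1`.
#'
#' @param n_outcome outcome GWAS sample size.
#' @param case_fraction case proportion K in (0, 1).
#' @param r2_exposure variance in the exposure explained by the
#'   instruments, in (0, 1).
#' @param or_alt odds ratio under the alternative.
#' @param alpha two-sided level (default 0.05).
#' @return Power as a fraction in \[0, 1\] (vectorized over arguments).
#' @export
power_binary <- function(n_outcome, case_fraction, r2_exposure, or_alt,
                         alpha = 0.05) {
  stopifnot(all(case_fraction > 0 & case_fraction < 1),
            all(r2_exposure > 0 & r2_exposure < 1))
  se <- 1 / sqrt(n_outcome * case_fraction * (1 - case_fraction) * r2_exposure)
  b <- abs(log(or_alt))
  zq <- qnorm(1 - alpha / 2)
  pnorm(-zq + b / se) + pnorm(-zq - b / se)
}

#' Analytic power for MR with a continuous outcome
#'
#' As [power_binary()] but for an outcome in SD units:
#' `se = 1/sqrt(n r2)`.
#'
#' @param n_outcome outcome sample size.
#' @param r2_exposure instrument r-squared on the exposure.
#' @param beta_alt effect (SD per SD) under the alternative.
#' @param alpha two-sided level.
#' @return Power fraction (vectorized).
#' @export
power_continuous <- function(n_outcome, r2_exposure, beta_alt, alpha = 0.05) {
  se <- 1 / sqrt(n_outcome * r2_exposure)
  b <- abs(beta_alt)
  zq <- qnorm(1 - alpha / 2)
  pnorm(-zq + b / se) + pnorm(-zq - b / se)
}

#' Funnel-plot data
#'
#' Per-variant Wald ratio against its precision (inverse first-order
#' ratio SE); a valid instrument set scatters symmetrically about the IVW
#' estimate.
#'
#' @param set a non-empty [harmonized_set].
#' @return data frame `variant_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) == 0L) stop("empty set")
  data.frame(variant_id = set$variant_id, ratio = set$Gamma / set$gamma,
             precision = abs(set$gamma) / set$se_Gamma, stringsAsFactors = FALSE)
}

#' Full sensitivity report for one harmonized set
#'
#' Computes the diagnostics that drive the primary-method decision:
#' Cochran's Q (IVW) and Rucker's Q' (Egger) with p-values, the Egger
#' intercept test, I2_GX with its NOME flag, the pooled Steiger direction,
#' leave-one-out stability, the MR-PRESSO global/outlier/distortion
#' results, and analytic power at the observed IVW effect.  Diagnostics
#' needing at least 3 (or 4, for PRESSO) instruments are `NA` for smaller
#' sets.
#'
#' @param set a [harmonized_set].
#' @param seed seed for the PRESSO simulations.
#' @param n_presso PRESSO simulation count (default 1000).
#' @param or_alt odds ratio at which power is evaluated; the observed IVW
#'   odds ratio when omitted (power at the estimated effect).
#' @param alpha level used by the heterogeneity/pleiotropy flags.
#' @return A `sensitivity_report` list.
#' @export
sensitivity_report <- function(set, seed = 1L, n_presso = 1000,
                               or_alt = NULL, alpha = 0.05) {
  stopifnot(inherits(set, "harmonized_set"))
  J <- nrow(set)
  ivw <- ivw_mre(set)
  qv <- cochran_q(set)

  rep <- list(
    exposure_id = attr(set, "exposure_id"), outcome_id = attr(set, "outcome_id"),
    n_snp = J,
    q_ivw = qv$q, q_ivw_pval = qv$pval,
    q_egger = NA_real_, q_egger_pval = NA_real_,
    egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
    i2_gx = NA_real_, nome_flag = NA,
    steiger_direction = NA, steiger_pval = NA_real_,
    loo_stable = NA, loo = NULL,
    presso_global_pval = NA_real_, presso_outliers = character(),
    presso_distortion_pval = NA_real_,
    power = NA_real_
  )
  if (J >= 3) {
    eg <- egger(set)
    rq <- rucker_q(set)
    ig <- i2_gx(set)
    rep$q_egger <- rq$q; rep$q_egger_pval <- rq$pval
    rep$egger_intercept <- eg$intercept
    rep$egger_intercept_pval <- eg$intercept_pval
    rep$i2_gx <- ig$i2; rep$nome_flag <- ig$nome_flag
  }
  st <- steiger(set)
  rep$steiger_direction <- st$direction; rep$steiger_pval <- st$pval
  if (J >= 2) {
    loo <- leave_one_out(set)
    rep$loo_stable <- loo$stable; rep$loo <- loo$estimates
  }
  if (J >= 4) {
    pr <- mr_presso(set, n_sim = n_presso, seed = seed)
    rep$presso_global_pval <- pr$global_pval
    rep$presso_outliers <- pr$outliers
    rep$presso_distortion_pval <- pr$distortion_pval
  }
  eaf <- ifelse(is.na(set$eaf), 0.25, set$eaf)
  n_exp <- attr(set, "n_exposure"); if (is.na(n_exp)) n_exp <- 1e5
  r2 <- min(sum(variant_r2(set$gamma, set$se_gamma, n_exp, eaf, "continuous")),
            0.999)
  n_out <- attr(set, "n_outcome")
  K <- attr(set, "case_fraction")
  or_alt <- or_alt %||% ivw$or_value
  if (!is.na(n_out)) {
    rep$power <- if ((attr(set, "outcome_type") %||% "binary") == "binary") {
      if (is.na(K)) K <- 0.5
      power_binary(n_out, K, r2, or_alt, alpha)
    } else {
      power_continuous(n_out, r2, log(or_alt), alpha)
    }
  }
  structure(rep, class = "sensitivity_report")
}

#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(exposure_id = x$exposure_id, outcome_id = x$outcome_id,
             n_snp = x$n_snp, q_ivw = x$q_ivw, q_ivw_pval = x$q_ivw_pval,
             q_egger = x$q_egger, q_egger_pval = x$q_egger_pval,
             egger_intercept = x$egger_intercept,
             egger_intercept_pval = x$egger_intercept_pval,
             i2_gx = x$i2_gx, nome_flag = x$nome_flag,
             steiger_direction = x$steiger_direction,
             steiger_pval = x$steiger_pval, loo_stable = x$loo_stable,
             presso_global_pval = x$presso_global_pval,
             presso_n_outliers = length(x$presso_outliers),
             presso_outliers = paste(x$presso_outliers, collapse = ","),
             presso_distortion_pval = x$presso_distortion_pval,
             power = x$power, stringsAsFactors = FALSE)
}
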