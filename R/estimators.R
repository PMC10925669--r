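#' Build an MR estimate record
#'
#' Internal constructor used by every estimator: one-row data frame with
#' the causal effect on the log scale, its standard error and p-value, and
#' the odds-ratio-scale transform `or = exp(beta)` with a 95% Wald
#' interval.
#'
#' @param method method identifier.
#' @param beta,se causal estimate and standard error (log scale).
#' @param n_snp number of instruments used.
#' @param pval p-value; computed from the normal reference when omitted.
#' @param ... extra scalar fields stored as additional columns (e.g.
#'   `intercept`, `q`, `se_fixed`).
#' @return A one-row `mr_estimate` data frame.
#' @export
mr_estimate <- function(method, beta, se, n_snp, pval = NULL, ...) {
  z <- qnorm(0.975)
  extras <- list(...)
  out <- data.frame(method = method, n_snp = as.integer(n_snp),
                    beta = beta, se = se,
                    pval = pval %||% 2 * pnorm(-abs(beta / se)),
                    or_value = exp(beta),
                    ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
                    stringsAsFactors = FALSE)
  for (nm in names(extras)) out[[nm]] <- extras[[nm]]
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Wald ratio for a single instrument
#'
#' The per-variant causal estimate `Gamma / gamma`.  The default standard
#' error is the first-order delta approximation `se_Gamma / |gamma|`;
#' `second_order = TRUE` adds the exposure-uncertainty term
#' `Gamma^2 se_gamma^2 / gamma^4`.
#'
#' @param gamma,se_gamma exposure effect and SE (`gamma` must be nonzero).
#' @param Gamma,se_Gamma outcome effect and SE.
#' @param second_order use the second-order delta SE.
#' @return An [mr_estimate].
#' @export
wald_ratio <- function(gamma, se_gamma, Gamma, se_Gamma, second_order = FALSE) {
  if (gamma == 0) stop("Wald ratio undefined for gamma = 0")
  beta <- Gamma / gamma
  se <- if (second_order)
    sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)
  else se_Gamma / abs(gamma)
  mr_estimate("wald", beta, se, n_snp = 1L)
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' The fixed-effect IVW solution — weighted regression of `Gamma` on
#' `gamma` through the origin with weights `1/se_Gamma^2` — with the
#' standard error inflated by `max(1, sqrt(Q/(J-1)))` under the
#' multiplicative random-effects model, so heterogeneity widens the
#' interval but never narrows it.  With a single instrument this reduces
#' exactly to the Wald ratio.
#'
#' @param set a [harmonized_set].
#' @return An [mr_estimate] with extra columns `q` (Cochran's Q at the
#'   fixed-effect estimate), `se_fixed` and `phi` (the inflation factor).
#' @export
ivw_mre <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  g <- set$gamma; G <- set$Gamma; sG <- set$se_Gamma
  if (all(g == 0)) stop("all instrument effects are zero")
  w <- 1 / sG^2
  den <- sum(w * g^2)
  theta <- sum(w * g * G) / den
  se_fixed <- sqrt(1 / den)
  J <- length(g)
  q <- sum(w * (G - theta * g)^2)
  phi <- if (J > 1) max(1, sqrt(q / (J - 1))) else 1
  mr_estimate("ivw_mre", theta, se_fixed * phi, n_snp = J,
              q = q, se_fixed = se_fixed, phi = phi)
}

# orient every instrument so its exposure effect is positive (required for
# an interpretable Egger intercept)
orient_positive <- function(set) {
  s <- ifelse(set$gamma < 0, -1, 1)
  list(g = s * set$gamma, G = s * set$Gamma, sG = set$se_Gamma,
       sg = set$se_gamma)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the (sign-oriented) outcome effects on
#' the exposure effects *with* an intercept, weights `1/se_Gamma^2`.  The
#' slope estimates the causal effect under InSIDE; the intercept estimates
#' the average directional pleiotropy, and its test is the standard
#' horizontal-pleiotropy diagnostic.  Standard errors carry the same
#' multiplicative random-effects inflation as [ivw_mre()], based on
#' Rucker's Q' (the residual heterogeneity after the intercept).
#' Inference uses the t reference with J - 2 degrees of freedom.
#'
#' @param set a [harmonized_set] with at least 3 variants.
#' @return An [mr_estimate] with `intercept`, `intercept_se`,
#'   `intercept_pval` and `q` (Rucker's Q') columns.
#' @export
egger <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  J <- nrow(set)
  if (J < 3) stop("MR-Egger needs at least 3 variants")
  o <- orient_positive(set)
  w <- 1 / o$sG^2
  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * o$g); swy <- sum(w * o$G)
  swxx <- sum(w * o$g^2); swxy <- sum(w * o$g * o$G)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design: no spread in instrument strengths")
  b <- (sw * swxy - swx * swy) / det
  a <- (swy * swxx - swx * swxy) / det
  resid <- o$G - a - b * o$g
  q_prime <- sum(w * resid^2)
  phi <- max(1, sqrt(q_prime / (J - 2)))
  se_b <- sqrt(sw / det) * phi
  se_a <- sqrt(swxx / det) * phi
  p_b <- 2 * pt(-abs(b / se_b), df = J - 2)
  p_a <- 2 * pt(-abs(a / se_a), df = J - 2)
  mr_estimate("egger", b, se_b, n_snp = J, pval = p_b,
              intercept = a, intercept_se = se_a, intercept_pval = p_a,
              q = q_prime, phi = phi)
}

# interpolated weighted median with the standardized cumulative-weight
# convention s_j = cumsum(w) - w/2
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_se <- function(set, point_fun, n_boot, seed) {
  with_seed(seed, {
    J <- nrow(set)
    reps <- vapply(seq_len(n_boot), function(i) {
      g <- rnorm(J, set$gamma, set$se_gamma)
      G <- rnorm(J, set$Gamma, set$se_Gamma)
      point_fun(G / g, g^2 / set$se_Gamma^2)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median estimator
#'
#' Robust to up to 50% invalid instruments: the estimate is the
#' interpolated weighted median of the per-variant Wald ratios with
#' inverse-variance weights `gamma^2 / se_Gamma^2`.  The standard error
#' comes from a seeded parametric bootstrap that resamples each variant's
#' exposure and outcome effects from their normal sampling distributions.
#'
#' @param set a [harmonized_set] with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return An [mr_estimate].
#' @export
weighted_median <- function(set, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) < 3) stop("weighted median needs at least 3 variants")
  b <- set$Gamma / set$gamma
  w <- set$gamma^2 / set$se_Gamma^2
  est <- weighted_median_point(b, w)
  se <- boot_se(set, weighted_median_point, n_boot, seed)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  mr_estimate("weighted_median", est, se, n_snp = nrow(set))
}

# weighted kernel density argmax; normal kernel, modified Silverman
# bandwidth on the ratio estimates
weighted_mode_point <- function(b, w, bandwidth_factor = 1) {
  w <- w / sum(w)
  spread <- min(sd(b), mad(b))
  if (!is.finite(spread) || spread == 0) {
    # degenerate: plurality value (all-equal cluster); fall back to the
    # most-weighted value
    tab <- tapply(w, b, sum)
    return(as.numeric(names(tab))[which.max(tab)])
  }
  h <- bandwidth_factor * 0.9 * spread / length(b)^(1 / 5)
  dens <- function(x) vapply(x, function(xi) sum(w * dnorm(xi, b, h)), numeric(1))
  lo <- min(b) - 3 * h; hi <- max(b) + 3 * h
  grid <- seq(lo, hi, length.out = 512L)
  fx <- dens(grid)
  k <- which.max(fx)
  step <- grid[2] - grid[1]
  optimize(dens, lower = max(lo, grid[k] - 2 * step),
           upper = min(hi, grid[k] + 2 * step), maximum = TRUE,
           tol = .Machine$double.eps^0.5)$maximum
}

#' Weighted-mode estimator
#'
#' Valid under the plurality assumption: the estimate is the argmax of a
#' normal-kernel-smoothed weighted density of the per-variant Wald ratios
#' (modified Silverman bandwidth `0.9 min(sd, mad) J^{-1/5}` scaled by
#' `bandwidth_factor`).  SE by seeded parametric bootstrap.
#'
#' @param set a [harmonized_set] with at least 3 variants.
#' @param bandwidth_factor multiplier on the default bandwidth.
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return An [mr_estimate].
#' @export
weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(set, "harmonized_set"))
  if (nrow(set) < 3) stop("weighted mode needs at least 3 variants")
  b <- set$Gamma / set$gamma
  w <- set$gamma^2 / set$se_Gamma^2
  est <- weighted_mode_point(b, w, bandwidth_factor)
  se <- boot_se(set, function(bb, ww) weighted_mode_point(bb, ww, bandwidth_factor),
                n_boot, seed)
  if (!is.finite(se) || se == 0) se <- .Machine$double.eps
  mr_estimate("weighted_mode", est, se, n_snp = nrow(set))
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Models idiosyncratic pleiotropy as a normal direct effect with mean
#' zero and variance tau^2: the standardized residual of variant j at
#' `(theta, tau^2)` is
#' `t_j = (Gamma_j - theta gamma_j) / sqrt(se_Gamma_j^2 + theta^2 se_gamma_j^2 + tau^2)`.
#' `theta` solves the M-estimation problem `min sum rho(t_j)` (squared or
#' Huber loss); with `overdispersion` on, `tau^2 >= 0` simultaneously
#' solves the moment condition `mean(psi(t_j) t_j) = delta`, where `delta`
#' is the value of that expectation under a standard normal residual.
#' The standard error is a sandwich estimate from the profiled score.
#'
#' @param set a [harmonized_set] with at least 3 variants.
#' @param overdispersion estimate tau^2 (default `TRUE`); otherwise
#'   tau^2 is fixed at 0.
#' @param loss `"huber"` (default, tuning constant 1.345) or `"l2"`.
#' @param max_iter maximum profile iterations.
#' @return An [mr_estimate] with extra columns `tau2` and `converged`.
#' @export
raps <- function(set, overdispersion = TRUE, loss = c("huber", "l2"),
                 max_iter = 50L) {
  stopifnot(inherits(set, "harmonized_set"))
  loss <- match.arg(loss)
  J <- nrow(set)
  if (J < 3) stop("RAPS needs at least 3 variants")
  g <- set$gamma; G <- set$Gamma; sg <- set$se_gamma; sG <- set$se_Gamma

  k <- 1.345
  psi <- if (loss == "l2") function(t) t else function(t) pmax(pmin(t, k), -k)
  rho <- if (loss == "l2") function(t) t^2 / 2 else
    function(t) ifelse(abs(t) <= k, t^2 / 2, k * abs(t) - k^2 / 2)
  # E[psi(Z) Z] for Z ~ N(0,1)
  delta <- if (loss == "l2") 1 else
    integrate(function(z) psi(z) * z * dnorm(z), -Inf, Inf)$value

  tfun <- function(theta, tau2) (G - theta * g) / sqrt(sG^2 + theta^2 * sg^2 + tau2)
  obj <- function(theta, tau2) sum(rho(tfun(theta, tau2)))
  ratios <- G / g
  span <- max(abs(ratios[is.finite(ratios)]), 1)
  theta_hat_at <- function(tau2)
    optimize(obj, lower = -3 * span, upper = 3 * span, tau2 = tau2,
             tol = 1e-12)$minimum

  tau2 <- 0
  converged <- TRUE
  if (overdispersion) {
    gap <- function(tau2) {
      th <- theta_hat_at(tau2)
      t <- tfun(th, tau2)
      mean(psi(t) * t) - delta
    }
    if (gap(0) > 0) {
      upper <- stats::var(G - theta_hat_at(0) * g) + mean(sG^2)
      it <- 0L
      while (gap(upper) > 0 && it < max_iter) { upper <- upper * 2; it <- it + 1L }
      if (gap(upper) > 0) converged <- FALSE
      else tau2 <- uniroot(gap, c(0, upper), tol = 1e-12)$root
    }
  }
  theta <- theta_hat_at(tau2)

  # sandwich SE from the profiled score in theta
  eps <- 1e-6 * max(abs(theta), 1)
  score <- function(th) {
    t1 <- tfun(th + eps, tau2); t0 <- tfun(th - eps, tau2)
    # per-variant derivative of rho(t_j) wrt theta
    (rho(t1) - rho(t0)) / (2 * eps)
  }
  s_mid <- score(theta)
  A <- (sum(score(theta + eps)) - sum(score(theta - eps))) / (2 * eps)
  B <- sum(s_mid^2)
  # under the model E[psi^2] scales B; guard degenerate noiseless fits
  se <- if (A > 0 && B > 0) sqrt(B) / A else .Machine$double.eps
  if (abs(sum(s_mid)) > 1e-4 * sqrt(B + 1)) converged <- FALSE
  if (!converged) warning("RAPS did not converge")
  mr_estimate("raps", theta, se, n_snp = J, tau2 = tau2, converged = converged)
}

#' All-estimator table for one harmonized set
#'
#' Convenience wrapper running the five estimators (IVW-MRE always;
#' Egger, weighted median, weighted mode and RAPS when at least 3
#' instruments are available; the Wald ratio when only one is).
#'
#' @param set a [harmonized_set].
#' @param seed seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates for median/mode.
#' @return An `mr_estimate` table with one row per method.
#' @export
mr_all_methods <- function(set, seed = 1L, n_boot = 1000) {
  stopifnot(inherits(set, "harmonized_set"))
  rows <- list()
  if (nrow(set) == 1L)
    rows$wald <- wald_ratio(set$gamma, set$se_gamma, set$Gamma, set$se_Gamma)
  rows$ivw <- ivw_mre(set)
  if (nrow(set) >= 3L) {
    rows$egger <- egger(set)
    rows$wmedian <- weighted_median(set, n_boot = n_boot, seed = seed)
    rows$wmode <- weighted_mode(set, n_boot = n_boot, seed = seed + 1L)
    rows$raps <- tryCatch(suppressWarnings(raps(set)), error = function(e) NULL)
  }
  rows <- Filter(Negate(is.null), rows)
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Odds ratio, confidence interval and percent risk change
#'
#' Converts a log-scale estimate to the odds-ratio scale and to a signed
#' integer percent change in risk, `100 (exp(beta) - 1)` rounded to the
#' nearest integer (ties rounded upward).
#'
#' @param estimate an [mr_estimate] row.
#' @return list with `or_value`, `ci` (length-2), and `percent_change`.
#' @export
or_and_percent <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"), nrow(estimate) == 1L)
  list(or_value = estimate$or_value,
       ci = c(estimate$ci_low, estimate$ci_high),
       percent_change = as.integer(round_half_up(100 * (estimate$or_value - 1))))
}

#' Rebuild an MR estimate from a printed odds ratio and 95% CI
#'
#' Published result tables usually print the odds ratio with its 95%
#' interval; this inverts the Wald transform (`beta = log(or)`,
#' `se = (log(hi) - log(lo)) / (2 z_{0.975})`) so such rows can feed
#' downstream operations like [two_step()].
#'
#' @param or_value,ci_low,ci_high printed odds ratio and interval bounds.
#' @param method method label (default `"reported"`).
#' @param n_snp instrument count if known.
#' @return An [mr_estimate].
#' @export
mr_estimate_from_or <- function(or_value, ci_low, ci_high,
                                method = "reported", n_snp = NA_integer_) {
  stopifnot(or_value > 0, ci_low > 0, ci_high > ci_low)
  beta <- log(or_value)
  se <- (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))
  mr_estimate(method, beta, se, n_snp = n_snp)
}
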