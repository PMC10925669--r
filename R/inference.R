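#' Primary-method decision rule
#'
#' Picks the method whose assumptions the diagnostics support:
#' \itemize{
#'   \item significant Egger intercept (p < `alpha`) — horizontal
#'     pleiotropy is present, so MR-Egger is primary (with the NOME flag
#'     carried along when I2_GX < 0.9);
#'   \item otherwise, significant Cochran's Q — heterogeneity without
#'     directional pleiotropy: the multiplicative random-effects IVW is
#'     primary, but a positive call additionally requires the weighted
#'     median to agree (same sign, p < `alpha`);
#'   \item otherwise the multiplicative random-effects IVW alone.
#' }
#' The rule is total: every report maps to exactly one method.
#'
#' @param sens a [sensitivity_report()].
#' @param alpha decision level (default 0.05).
#' @return list with `method` (`"egger"` or `"ivw_mre"`),
#'   `requires_median_support` and `nome_flag`.
#' @export
choose_primary <- function(sens, alpha = 0.05) {
  stopifnot(inherits(sens, "sensitivity_report"))
  ip <- sens$egger_intercept_pval
  qp <- sens$q_ivw_pval
  if (!is.na(ip) && ip < alpha) {
    list(method = "egger", requires_median_support = FALSE,
         nome_flag = isTRUE(sens$nome_flag))
  } else if (!is.na(qp) && qp < alpha) {
    list(method = "ivw_mre", requires_median_support = TRUE, nome_flag = FALSE)
  } else {
    list(method = "ivw_mre", requires_median_support = FALSE, nome_flag = FALSE)
  }
}

#' Benjamini-Hochberg adjustment within families
#'
#' Step-up FDR adjustment, applied separately within each level of
#' `family` (e.g. all outcomes tested against one exposure within one
#' analysis direction).
#'
#' @param pvals numeric p-values.
#' @param family optional grouping key (vector recycled against
#'   `pvals`); `NULL` treats all p-values as one family.
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvals, family = NULL) {
  if (is.null(family)) return(p.adjust(pvals, method = "BH"))
  out <- numeric(length(pvals))
  for (f in unique(family)) {
    idx <- which(family == f)
    out[idx] <- p.adjust(pvals[idx], method = "BH")
  }
  out
}

#' Bundle one exposure-outcome analysis
#'
#' @param exposure_id,outcome_id trait identifiers.
#' @param estimates an `mr_estimate` table from [mr_all_methods()].
#' @param sensitivity a [sensitivity_report()].
#' @param direction `"forward"` or `"reverse"` (used for FDR families).
#' @return A `batch_result` list.
#' @export
batch_result <- function(exposure_id, outcome_id, estimates, sensitivity,
                         direction = "forward") {
  stopifnot(inherits(estimates, "mr_estimate"),
            inherits(sensitivity, "sensitivity_report"))
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 estimates = estimates, sensitivity = sensitivity,
                 direction = direction),
            class = "batch_result")
}

#' Apply the decision rule, FDR correction and power filter across batches
#'
#' For each batch the primary method is chosen from its sensitivity
#' report; primary p-values are BH-adjusted within families (by default
#' one family per direction x exposure); and a batch is a positive call
#' only when its adjusted p-value is below `fdr_alpha`, its power is at
#' least `power_min`, and — under heterogeneity — the weighted median
#' supports the IVW conclusion (same sign, p < 0.05).
#'
#' @param batches list of [batch_result()] objects.
#' @param fdr_alpha FDR level (default 0.05).
#' @param power_min minimum power for a positive call (default 0.8).
#' @param family optional explicit FDR family key per batch.
#' @return A forest-plot-ready data frame: one row per batch with the
#'   primary method, OR and CI, instrument count, adjusted p-value, power
#'   and the positive-call flag.
#' @export
call_batches <- function(batches, fdr_alpha = 0.05, power_min = 0.8,
                         family = NULL) {
  if (length(batches) == 0L)
    return(data.frame(exposure_id = character(), outcome_id = character(),
                      direction = character(), primary_method = character(),
                      n_snp = integer(), beta = numeric(), or_value = numeric(),
                      ci_low = numeric(), ci_high = numeric(), pval = numeric(),
                      adjusted_pval = numeric(), power = numeric(),
                      nome_flag = logical(), positive_call = logical(),
                      stringsAsFactors = FALSE))
  stopifnot(all(vapply(batches, inherits, logical(1), "batch_result")))
  rows <- lapply(batches, function(b) {
    rule <- choose_primary(b$sensitivity)
    est <- b$estimates[b$estimates$method == rule$method, , drop = FALSE]
    if (nrow(est) == 0L)  # small sets have no Egger row; fall back to IVW
      est <- b$estimates[b$estimates$method == "ivw_mre", , drop = FALSE]
    wm <- b$estimates[b$estimates$method == "weighted_median", , drop = FALSE]
    median_ok <- if (!rule$requires_median_support) TRUE
      else nrow(wm) == 1L && sign(wm$beta) == sign(est$beta) && wm$pval < 0.05
    data.frame(exposure_id = b$exposure_id, outcome_id = b$outcome_id,
               direction = b$direction, primary_method = est$method,
               n_snp = est$n_snp, beta = est$beta, or_value = est$or_value,
               ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
               power = b$sensitivity$power %||% NA_real_,
               nome_flag = rule$nome_flag, median_ok = median_ok,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  fam <- family %||% paste(out$direction, out$exposure_id)
  out$adjusted_pval <- fdr_adjust(out$pval, fam)
  out$positive_call <- out$adjusted_pval < fdr_alpha &
    !is.na(out$power) & out$power >= power_min & out$median_ok
  out$median_ok <- NULL
  out[c("exposure_id", "outcome_id", "direction", "primary_method", "n_snp",
        "beta", "or_value", "ci_low", "ci_high", "pval", "adjusted_pval",
        "power", "nome_flag", "positive_call")]
}
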