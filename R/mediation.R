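#' Two-step MR mediation for one exposure-mediator-outcome triplet
#'
#' Product-of-coefficients mediation on the log(-odds) scale: the
#' indirect effect is `beta_xm * beta_my` with its delta-method standard
#' error.  When the total exposure-outcome effect is itself significant
#' (p < `alpha`) the mediated pathway is *partial* (PM) and the
#' proportion mediated is `100 * beta_xm * beta_my / beta_xy` percent;
#' when the total effect is not significant the association is attributed
#' entirely to the mediated pathway — *total* mediation (TM), reported as
#' 100% by convention rather than as a ratio against a near-zero,
#' unstable denominator.
#'
#' @param xy total-effect estimate (exposure on outcome), an
#'   [mr_estimate].
#' @param xm exposure-on-mediator estimate.
#' @param my mediator-on-outcome estimate.
#' @param alpha significance level for the TM/PM split (default 0.05).
#' @param exposure_id,mediator_id,outcome_id optional labels.
#' @return A one-row `mediation_result` data frame with the three step
#'   effects, the indirect effect and its SE, the mediated proportion (in
#'   percent) and the TM/PM label.
#' @export
two_step <- function(xy, xm, my, alpha = 0.05,
                     exposure_id = "exposure", mediator_id = "mediator",
                     outcome_id = "outcome") {
  for (e in list(xy, xm, my))
    stopifnot(inherits(e, "mr_estimate"), nrow(e) == 1L)
  indirect <- xm$beta * my$beta
  se_indirect <- sqrt(my$beta^2 * xm$se^2 + xm$beta^2 * my$se^2)
  if (xy$pval >= alpha) {
    type <- "TM"
    proportion <- 100
  } else {
    if (xy$beta == 0)
      stop("total effect is exactly zero; proportion mediated undefined")
    type <- "PM"
    proportion <- 100 * indirect / xy$beta
  }
  out <- data.frame(exposure_id = exposure_id, mediator_id = mediator_id,
                    outcome_id = outcome_id,
                    beta_xy = xy$beta, se_xy = xy$se, pval_xy = xy$pval,
                    beta_xm = xm$beta, se_xm = xm$se, pval_xm = xm$pval,
                    beta_my = my$beta, se_my = my$se, pval_my = my$pval,
                    indirect = indirect, se_indirect = se_indirect,
                    proportion = proportion, mediation_type = type,
                    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' Screen candidate mediators and classify each retained triplet
#'
#' Keeps the triplets in which both mediation steps are significant at
#' `alpha` (exposure on mediator, and mediator on outcome), deduplicates
#' repeated mediators, and classifies each retained triplet with
#' [two_step()].
#'
#' @param xy total-effect estimate shared by the triplets.
#' @param xm_list named list of exposure-on-mediator estimates (names =
#'   mediator ids).
#' @param my_list named list of mediator-on-outcome estimates (same
#'   names).
#' @param alpha step significance level (default 0.05).
#' @param exposure_id,outcome_id labels for the output rows.
#' @return A `mediation_result` table (possibly empty).
#' @export
screen_mediators <- function(xy, xm_list, my_list, alpha = 0.05,
                             exposure_id = "exposure", outcome_id = "outcome") {
  ids <- intersect(names(xm_list), names(my_list))
  ids <- ids[!duplicated(ids)]
  rows <- list()
  for (id in ids) {
    xm <- xm_list[[id]]; my <- my_list[[id]]
    if (xm$pval < alpha && my$pval < alpha)
      rows[[id]] <- two_step(xy, xm, my, alpha = alpha,
                             exposure_id = exposure_id, mediator_id = id,
                             outcome_id = outcome_id)
  }
  if (!length(rows)) {
    out <- two_step(mr_estimate("x", 0, 1, 1, pval = 1),
                    mr_estimate("x", 0, 1, 1), mr_estimate("x", 0, 1, 1))[0, ]
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mediation_result", "data.frame")
  out
}
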