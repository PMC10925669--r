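#' End-to-end run configuration
#'
#' Collects every tunable of a bidirectional run: the simulation (or
#' input) settings, the direction-specific instrument p-value thresholds
#' (the genome-wide 5e-8 in reverse, the relaxed 1e-6 forward), the
#' cascade parameters, the calling thresholds and the single seed from
#' which all randomness flows.
#'
#' @param sim_forward [simulation_config()] for the forward direction
#'   (continuous exposure, binary outcome).
#' @param sim_reverse [simulation_config()] for the reverse direction, or
#'   `NULL` to skip it.
#' @param p_threshold_forward,p_threshold_reverse instrument significance
#'   levels per direction.
#' @param clump_r2,clump_kb,f_min cascade parameters (see
#'   [cascade_config()]).
#' @param annotation,confounder_traits confounder screen inputs.
#' @param presso_nsim MR-PRESSO simulation count.
#' @param fdr_alpha,power_min calling thresholds.
#' @param methods method subset for the estimate tables; unknown names
#'   are rejected up front.
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(sim_forward = simulation_config(),
                       sim_reverse = NULL,
                       p_threshold_forward = 1e-6,
                       p_threshold_reverse = 5e-8,
                       clump_r2 = 0.01, clump_kb = 10000, f_min = 10,
                       annotation = NULL, confounder_traits = NULL,
                       presso_nsim = 1000,
                       fdr_alpha = 0.05, power_min = 0.8,
                       methods = c("ivw_mre", "egger", "weighted_median",
                                   "weighted_mode", "raps"),
                       seed = 1L) {
  known <- c("wald", "ivw_mre", "egger", "weighted_median", "weighted_mode",
             "raps")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method name(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment())[setdiff(ls(), c("known", "bad"))],
            class = "run_config")
}

run_direction <- function(exposure, outcome, ld, cfg, direction, seed) {
  p_thr <- if (direction == "forward") cfg$p_threshold_forward
           else cfg$p_threshold_reverse
  cc <- cascade_config(p_threshold = p_thr, clump_r2 = cfg$clump_r2,
                       clump_kb = cfg$clump_kb, ld = ld, f_min = cfg$f_min,
                       annotation = cfg$annotation,
                       confounder_traits = cfg$confounder_traits,
                       presso_nsim = cfg$presso_nsim, seed = seed)
  casc <- run_cascade(exposure, outcome, cc)
  est <- mr_all_methods(casc$set, seed = seed + 1L)
  est <- est[est$method %in% c("wald", cfg$methods), , drop = FALSE]
  sens <- sensitivity_report(casc$set, seed = seed + 2L,
                             n_presso = cfg$presso_nsim)
  batch <- batch_result(attr(casc$set, "exposure_id"),
                        attr(casc$set, "outcome_id"),
                        est, sens, direction = direction)
  list(set = casc$set, ledger = casc$ledger, estimates = est,
       sensitivity = sens, batch = batch)
}

#' Run the full bidirectional analysis on one simulated trait pair
#'
#' Generates the forward pair (and, when configured, an independent
#' reverse pair with exposure and outcome roles swapped), runs the
#' instrument cascade, all estimators, the sensitivity suite and the
#' calling step in each direction, and returns the complete results
#' bundle.  The bundle is deterministic given the configuration: rerunning
#' with the same config yields identical results.
#'
#' @param config a [run_config()].
#' @return list with per-direction results (`forward`, `reverse`: each
#'   holding `set`, `ledger`, `estimates`, `sensitivity`, `batch`), the
#'   combined `calls` table, and plot-ready `forest`, `scatter` and
#'   `funnel` tables for the forward direction.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  pair_f <- generate_pair(config$sim_forward)
  ld_f <- if (config$sim_forward$ld_block_size > 1) ld_table(config$sim_forward)
          else NULL
  fwd <- run_direction(pair_f$exposure, pair_f$outcome, ld_f, config,
                       "forward", config$seed)
  res <- list(forward = fwd)
  batches <- list(fwd$batch)
  if (!is.null(config$sim_reverse)) {
    pair_r <- generate_pair(config$sim_reverse)
    ld_r <- if (config$sim_reverse$ld_block_size > 1)
      ld_table(config$sim_reverse) else NULL
    rev <- run_direction(pair_r$exposure, pair_r$outcome, ld_r, config,
                         "reverse", config$seed + 100L)
    res$reverse <- rev
    batches <- c(batches, list(rev$batch))
  }
  res$calls <- call_batches(batches, fdr_alpha = config$fdr_alpha,
                            power_min = config$power_min)
  res$forest <- forest_table(res$calls)
  res$scatter <- scatter_table(fwd$set, fwd$estimates)
  res$funnel <- funnel_table(fwd$set)
  res
}

#' Forest-plot table
#'
#' One row per batch/method with the fields a forest plot needs: method,
#' OR, 95% CI bounds, instrument count and (adjusted) p-value.
#'
#' @param results a calls table from [call_batches()] or an
#'   `mr_estimate` table.
#' @return Plot-ready data frame (headers only when `results` is empty).
#' @export
forest_table <- function(results) {
  results <- as.data.frame(results)
  cols <- intersect(c("exposure_id", "outcome_id", "direction",
                      "primary_method", "method", "n_snp", "or_value",
                      "ci_low", "ci_high", "pval", "adjusted_pval",
                      "positive_call"), names(results))
  results[cols]
}

#' Scatter-plot table with per-method regression lines
#'
#' Per-variant effects (oriented so the exposure effect is positive, the
#' convention MR scatter plots use) plus one line per estimate: slope =
#' the method's causal estimate, intercept = its Egger intercept (zero
#' for the origin-constrained methods).
#'
#' @param set a [harmonized_set].
#' @param estimates an `mr_estimate` table for the same set.
#' @return list with `points` and `lines` data frames.
#' @export
scatter_table <- function(set, estimates) {
  stopifnot(inherits(set, "harmonized_set"))
  o <- orient_positive(set)
  pts <- data.frame(variant_id = set$variant_id, gamma = o$g, Gamma = o$G,
                    se_gamma = o$sg, se_Gamma = o$sG, stringsAsFactors = FALSE)
  est <- as.data.frame(estimates)
  lines <- data.frame(method = est$method, slope = est$beta,
                      intercept = if ("intercept" %in% names(est))
                        ifelse(is.na(est$intercept), 0, est$intercept)
                      else 0,
                      stringsAsFactors = FALSE)
  list(points = pts, lines = lines)
}

#' Funnel-plot table
#'
#' @param set a [harmonized_set].
#' @return The [funnel_data()] pairs plus the IVW reference estimate as
#'   an attribute `ivw_beta`.
#' @export
funnel_table <- function(set) {
  fd <- funnel_data(set)
  attr(fd, "ivw_beta") <- ivw_mre(set)$beta
  fd
}

#' Serialize an instrument ledger (or any list-like result) to JSON
#'
#' @param x an object with an `as.data.frame` method, e.g. an
#'   [ledger_new()] ledger.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
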