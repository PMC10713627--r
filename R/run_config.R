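#' Pipeline run configuration
#'
#' Bundles the protocol constants of the emulation pipeline. Defaults follow
#' the primary analysis: five-year (1825-day) follow-up, 100 emulations per
#' drug (50 random-comparator plus 50 same-ATC-L2-comparator), at least 500
#' treated initiators per screened drug, covariate imbalance flagged at
#' SMD > 0.1, a trial declared balanced when at most 2% of covariates remain
#' unbalanced after weighting, weights winsorized at the 1%/99% tails, and
#' 1000 bootstrap replicates at significance level 0.05.
#'
#' @param seed top-level integer seed; every random substream derives from it.
#' @param follow_up_days follow-up horizon in days (1825 primary; 730 for the
#'   two-year sensitivity analysis).
#' @param n_emulations_per_drug total emulated trials per drug, split evenly
#'   between random and ATC-L2 comparison groups.
#' @param min_treated minimum number of eligible treated initiators for a
#'   drug to be screened.
#' @param smd_threshold standardized mean difference above which a covariate
#'   counts as unbalanced.
#' @param unbalanced_ratio maximum fraction of unbalanced covariates for a
#'   trial to count as balanced.
#' @param trim_quantile two-sided tail quantile at which stabilized weights
#'   are winsorized.
#' @param bootstrap_reps bootstrap replicates for per-drug aggregation.
#' @param alpha family-wise significance level before Bonferroni correction.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       follow_up_days = 1825L,
                       n_emulations_per_drug = 100L,
                       min_treated = 500L,
                       smd_threshold = 0.1,
                       unbalanced_ratio = 0.02,
                       trim_quantile = 0.01,
                       bootstrap_reps = 1000L,
                       alpha = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    follow_up_days = as.integer(follow_up_days),
    n_emulations_per_drug = as.integer(n_emulations_per_drug),
    min_treated = as.integer(min_treated),
    smd_threshold = smd_threshold,
    unbalanced_ratio = unbalanced_ratio,
    trim_quantile = trim_quantile,
    bootstrap_reps = as.integer(bootstrap_reps),
    alpha = alpha
  )
  ints <- c("follow_up_days", "n_emulations_per_drug", "min_treated",
            "bootstrap_reps")
  bad <- ints[vapply(cfg[ints], function(x) is.na(x) || x <= 0L, logical(1))]
  fracs <- c("smd_threshold", "unbalanced_ratio", "alpha")
  bad <- c(bad, fracs[vapply(cfg[fracs],
                             function(x) !is.numeric(x) || x <= 0 || x >= 1,
                             logical(1))])
  if (!is.numeric(cfg$trim_quantile) || cfg$trim_quantile < 0 ||
      cfg$trim_quantile >= 0.5) {
    bad <- c(bad, "trim_quantile")
  }
  if (length(bad)) {
    stop("invalid run_config values for: ", paste(unique(bad), collapse = ", "))
  }
  class(cfg) <- "run_config"
  cfg
}
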