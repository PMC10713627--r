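# Standardized mean difference balance diagnostics.

#' Standardized mean differences between treatment arms
#'
#' Per covariate, `|mu_treat - mu_control| / sqrt((s2_treat + s2_control)/2)`.
#' With weights, each arm uses the weighted mean `sum(w x) / sum(w)` and the
#' weighted variance
#' `sum(w) / ((sum w)^2 - sum(w^2)) * sum(w (x - mu)^2)`, which reduces to the
#' ordinary unbiased (n-1) sample variance under unit weights. A covariate
#' constant in both arms has SMD 0 when the arm means agree (perfect balance)
#' and `Inf` otherwise.
#'
#' @param x covariate matrix (subjects x covariates).
#' @param z 0/1 treatment vector.
#' @param weights optional positive subject weights; `NULL` means unit weights.
#' @return nonnegative numeric vector of SMDs, one per covariate.
#' @export
smd <- function(x, z, weights = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(z), all(z %in% c(0, 1)))
  if (!any(z == 1) || !any(z == 0)) stop("both arms must be nonempty")
  if (is.null(weights)) weights <- rep(1, length(z))
  stopifnot(length(weights) == length(z), all(weights > 0))
  arm_stats <- function(idx) {
    w <- weights[idx]
    sw <- sum(w)
    mu <- colSums(x[idx, , drop = FALSE] * w) / sw
    dev2 <- (x[idx, , drop = FALSE] - rep(mu, each = length(idx)))^2
    s2 <- sw / (sw^2 - sum(w^2)) * colSums(dev2 * w)
    list(mu = mu, s2 = s2)
  }
  tr <- arm_stats(which(z == 1))
  co <- arm_stats(which(z == 0))
  pooled <- sqrt((tr$s2 + co$s2) / 2)
  num <- abs(tr$mu - co$mu)
  out <- num / pooled
  zero_var <- pooled == 0
  out[zero_var] <- ifelse(num[zero_var] < .Machine$double.eps^0.5, 0, Inf)
  unname(out)
}

#' Count unbalanced covariates
#'
#' A covariate is balanced when its SMD is at most the threshold; the count
#' is the number of entries strictly above it.
#'
#' @param smd_vector SMDs from [smd()].
#' @param threshold balance threshold (default 0.1).
#' @return integer count.
#' @export
count_unbalanced <- function(smd_vector, threshold = 0.1) {
  stopifnot(threshold > 0)
  sum(smd_vector > threshold)
}

#' Is an emulated trial balanced?
#'
#' Balanced when the unbalanced-covariate count is at most `ratio * D`, as a
#' real-valued bound (for D = 267 and ratio 0.02 the cutoff is 5.34, so 5
#' unbalanced covariates pass and 6 fail).
#'
#' @param n_unbalance unbalanced-covariate count.
#' @param d total number of covariates.
#' @param ratio maximum unbalanced fraction (default 0.02).
#' @return logical.
#' @export
is_trial_balanced <- function(n_unbalance, d, ratio = 0.02) {
  n_unbalance <= ratio * d
}

#' Balance report for one emulated trial
#'
#' @param x covariate matrix.
#' @param z 0/1 treatment vector.
#' @param weights post-weighting subject weights.
#' @param config run configuration (thresholds).
#' @param partition which data partition the report describes.
#' @return a `balance_report`: raw and weighted SMD vectors, unbalanced
#'   counts and trial-level balanced flags before and after weighting.
#' @export
balance_report <- function(x, z, weights, config = run_config(),
                           partition = c("all", "train", "test")) {
  partition <- match.arg(partition)
  d <- ncol(x)
  before <- smd(x, z)
  after <- smd(x, z, weights)
  n_before <- count_unbalanced(before, config$smd_threshold)
  n_after <- count_unbalanced(after, config$smd_threshold)
  structure(list(
    smd_before = before,
    smd_after = after,
    n_unbalance_before = n_before,
    n_unbalance_after = n_after,
    d = d,
    balanced_before = is_trial_balanced(n_before, d, config$unbalanced_ratio),
    balanced_after = is_trial_balanced(n_after, d, config$unbalanced_ratio),
    partition = partition
  ), class = "balance_report")
}

#' Per-drug balance success rate over emulations
#'
#' The fraction of a drug's emulated trials that are balanced after
#' weighting; screening admits drugs with a rate of at least 10%.
#'
#' @param reports list of `balance_report`s (or logical vector of
#'   post-weighting balanced flags), one per emulation of the drug.
#' @param drug drug identifier carried into the summary.
#' @return list with `drug`, `n_emulations`, `n_balanced`, `success_rate`.
#' @export
success_rate <- function(reports, drug = NA_character_) {
  if (length(reports) == 0) stop("at least one emulation report is required")
  flags <- if (is.logical(reports)) reports else
    vapply(reports, function(r) isTRUE(r$balanced_after), logical(1))
  list(drug = drug,
       n_emulations = length(flags),
       n_balanced = sum(flags),
       success_rate = mean(flags))
}

#' Write per-covariate balance data (Love-plot surface) to CSV
#'
#' @param report a `balance_report`.
#' @param names covariate names (optional).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(report, path, names = NULL) {
  stopifnot(inherits(report, "balance_report"))
  if (is.null(names)) names <- paste0("cov", seq_along(report$smd_before))
  utils::write.csv(data.frame(
    name = names,
    smd_before = report$smd_before,
    smd_after = report$smd_after
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
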