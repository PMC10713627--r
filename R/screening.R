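# Candidate screening and ranking across datasets.

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise significance level.
#' @param m_tests number of hypotheses tested (e.g. drug-dataset pairs).
#' @return `alpha / m_tests`.
#' @export
corrected_alpha <- function(alpha, m_tests) {
  stopifnot(alpha > 0, alpha < 1, m_tests >= 1)
  alpha / m_tests
}

#' Screen aggregated drug results for repurposing candidates
#'
#' A drug is a candidate when, in every supplied dataset: (i) the fraction of
#' balanced emulations is at least `min_success_rate`; (ii) the adjusted
#' hazard ratios of all its balanced trials are below 1 (the strict rule;
#' `rule = "mean"` relaxes this to the mean aHR being below 1); and (iii) the
#' bootstrap p-value is below the Bonferroni-corrected significance level.
#' Passing drugs are ranked ascending by their mean aHR across datasets;
#' non-candidates carry explicit failure reasons.
#'
#' @param results data frame with one row per drug x dataset and columns
#'   `drug`, `dataset`, `success_rate`, `mean_ahr`, `max_balanced_ahr`,
#'   `boot_p`.
#' @param alpha family-wise significance level (default 0.05).
#' @param m_tests number of tests for the Bonferroni correction; defaults to
#'   the number of drug-dataset rows supplied.
#' @param min_success_rate minimum balanced fraction (default 0.10).
#' @param rule `"all"` requires every balanced trial's aHR below 1;
#'   `"mean"` only the mean.
#' @return list with `candidates` (ranked data frame) and `decisions`
#'   (per drug x dataset flags and failure reasons).
#' @export
screen_drugs <- function(results, alpha = 0.05, m_tests = NULL,
                         min_success_rate = 0.10, rule = c("all", "mean")) {
  rule <- match.arg(rule)
  need <- c("drug", "dataset", "success_rate", "mean_ahr",
            "max_balanced_ahr", "boot_p")
  empty_candidates <- data.frame(drug = character(0), mean_ahr = numeric(0),
                                 rank = integer(0))
  if (nrow(results) == 0) {
    return(list(candidates = empty_candidates, decisions = data.frame(),
                alpha_corrected = NA_real_))
  }
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols)) {
    stop("results table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(m_tests)) m_tests <- nrow(results)
  thr <- corrected_alpha(alpha, m_tests)
  hr_ok <- if (rule == "all") results$max_balanced_ahr < 1 else
    results$mean_ahr < 1
  decisions <- data.frame(
    drug = results$drug,
    dataset = results$dataset,
    success_rate = results$success_rate,
    mean_ahr = results$mean_ahr,
    boot_p = results$boot_p,
    pass_success = !is.na(results$success_rate) &
      results$success_rate >= min_success_rate,
    pass_ahr = !is.na(hr_ok) & hr_ok,
    pass_p = !is.na(results$boot_p) & results$boot_p < thr,
    stringsAsFactors = FALSE
  )
  decisions$pass <- decisions$pass_success & decisions$pass_ahr & decisions$pass_p
  decisions$reasons <- vapply(seq_len(nrow(decisions)), function(i) {
    r <- character(0)
    if (!decisions$pass_success[i]) r <- c(r, "insufficient balanced trials")
    if (!decisions$pass_ahr[i]) r <- c(r, "aHR not below 1")
    if (!decisions$pass_p[i]) r <- c(r, "not significant at corrected alpha")
    paste(r, collapse = "; ")
  }, character(1))
  n_datasets <- length(unique(results$dataset))
  per_drug <- split(decisions, decisions$drug)
  cand_rows <- lapply(per_drug, function(d) {
    if (nrow(d) == n_datasets && all(d$pass)) {
      data.frame(drug = d$drug[1], mean_ahr = mean(d$mean_ahr),
                 stringsAsFactors = FALSE)
    }
  })
  candidates <- do.call(rbind, cand_rows[!vapply(cand_rows, is.null, logical(1))])
  if (is.null(candidates)) {
    candidates <- empty_candidates
  } else {
    candidates <- candidates[order(candidates$mean_ahr), , drop = FALSE]
    candidates$rank <- seq_len(nrow(candidates))
    rownames(candidates) <- NULL
  }
  list(candidates = candidates, decisions = decisions, alpha_corrected = thr)
}
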