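# Per-trial weighted survival estimation and per-drug bootstrap aggregation.

#' Weighted Cox proportional-hazards estimate of the treatment effect
#'
#' Fits `Surv(time, event) ~ z` with subject weights and a robust (sandwich)
#' standard error, as required for valid Wald inference under estimated
#' inverse-probability weights. The adjusted hazard ratio is the
#' exponentiated treatment coefficient; weights are relative, so rescaling
#' them by a positive constant leaves the estimate unchanged.
#'
#' @param z 0/1 treatment vector.
#' @param event 0/1 outcome indicator.
#' @param time nonnegative days to event or censoring.
#' @param weights positive subject weights (unit weights give the unweighted
#'   fit).
#' @return list with `ahr`, `log_ahr`, robust `se`, Wald `p`, a `converged`
#'   flag and a weight summary.
#' @export
weighted_cox <- function(z, event, time, weights = NULL) {
  stopifnot(length(z) == length(event), length(z) == length(time))
  if (!any(z == 1) || !any(z == 0)) stop("both arms must be nonempty")
  if (sum(event) == 0) stop("no events")
  if (is.null(weights)) weights <- rep(1, length(z))
  df <- data.frame(time = time, event = event, z = z, w = weights)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ z, data = df, weights = w,
                    robust = TRUE,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(wrn) {
      if (grepl("converge|infinite|beta", conditionMessage(wrn))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- unname(coef(fit)[1])
  se <- sqrt(fit$var[1, 1])
  if (!is.finite(beta) || !is.finite(se)) converged <- FALSE
  list(
    ahr = exp(beta),
    log_ahr = beta,
    se = se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged,
    weights_summary = c(min = min(weights), mean = mean(weights),
                        max = max(weights))
  )
}

#' Adjusted Kaplan-Meier survival difference at a horizon
#'
#' Difference of weighted Kaplan-Meier survival probabilities
#' (treated minus control) at `horizon` days.
#'
#' @inheritParams weighted_cox
#' @param horizon evaluation time in days (at most the follow-up length).
#' @return the survival-probability difference, in `[-1, 1]`.
#' @export
adjusted_km <- function(z, event, time, weights = NULL, horizon) {
  stopifnot(horizon >= 0)
  if (!any(z == 1) || !any(z == 0)) stop("both arms must be nonempty")
  if (is.null(weights)) weights <- rep(1, length(z))
  df <- data.frame(time = time, event = event, z = factor(z, levels = c(0, 1)),
                   w = weights)
  fit <- survival::survfit(survival::Surv(time, event) ~ z, data = df,
                           weights = w)
  s <- summary(fit, times = horizon, extend = TRUE)
  surv <- stats::setNames(s$surv, as.character(s$strata))
  unname(surv["z=1"] - surv["z=0"])
}

#' Aggregate per-trial estimates into a per-drug result
#'
#' Restricts to balanced trials and reports the mean adjusted hazard ratio
#' with a percentile bootstrap confidence interval over resamples of the
#' trial-level aHRs, the one-sided bootstrap p-value for the mean aHR being
#' below 1 (the fraction of bootstrap means at or above 1), and the mean
#' adjusted Kaplan-Meier difference with its interval.
#'
#' @param estimates data frame with one row per emulated trial and columns
#'   `ahr`, `balanced` (logical) and optionally `km_diff`.
#' @param b bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param drug drug identifier carried through.
#' @param exhaustive enumerate all `n^n` resamples instead of sampling
#'   (only for very small numbers of balanced trials).
#' @return a `drug_result` list; if no balanced trials exist it is marked
#'   `unscreenable`.
#' @export
aggregate_drug <- function(estimates, b = 1000, seed = 1, level = 0.95,
                           drug = NA_character_, exhaustive = FALSE) {
  stopifnot(is.data.frame(estimates), "ahr" %in% names(estimates),
            "balanced" %in% names(estimates))
  n_total <- nrow(estimates)
  bal <- estimates[which(estimates$balanced), , drop = FALSE]
  res <- list(drug = drug,
              n_emulations = n_total,
              n_balanced = nrow(bal),
              success_rate = if (n_total > 0) nrow(bal) / n_total else NA_real_)
  if (nrow(bal) == 0) {
    res$unscreenable <- TRUE
    class(res) <- "drug_result"
    return(res)
  }
  res$unscreenable <- FALSE
  boot_stats <- function(vals) {
    n <- length(vals)
    if (exhaustive) {
      if (n^n > 1e6) stop("exhaustive enumeration infeasible for n = ", n)
      idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
      means <- rowMeans(matrix(vals[idx], nrow = nrow(idx)))
    } else {
      set.seed(substream_seed(seed, "bootstrap"))
      means <- vapply(seq_len(b), function(i) {
        mean(vals[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
    }
    a <- (1 - level) / 2
    list(mean = mean(vals),
         ci = unname(quantile(means, c(a, 1 - a))),
         p_below_1 = mean(means >= 1))
  }
  ahr <- boot_stats(bal$ahr)
  res$mean_ahr <- ahr$mean
  res$ahr_ci <- ahr$ci
  res$boot_p <- ahr$p_below_1
  res$max_balanced_ahr <- max(bal$ahr)
  res$all_ahr_below_1 <- all(bal$ahr < 1)
  if ("km_diff" %in% names(bal) && !all(is.na(bal$km_diff))) {
    km <- boot_stats(bal$km_diff[!is.na(bal$km_diff)])
    res$mean_km_diff <- km$mean
    res$km_ci <- km$ci
  }
  res$b <- if (exhaustive) length(bal$ahr)^length(bal$ahr) else b
  class(res) <- "drug_result"
  res
}
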