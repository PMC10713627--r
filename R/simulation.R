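# Confounded Weibull survival simulation with 267 baseline covariates.
#
# The generating model is fixed: covariates X1..X267, a logistic treatment
# assignment (one linear and one nonlinear mechanism), and a Weibull
# time-to-event model with shape 2 and conditional treatment log-hazard -1,
# administratively censored at 200 days. Because the hazard ratio is
# non-collapsible, the marginal (population-level) HR differs from the
# conditional exp(-1) ~ 0.368; the marginal truth (~0.578) is recovered by a
# potential-outcomes Cox fit on a large simulated population.

SIM_INTERCEPT_LINEAR <- -6.84
SIM_INTERCEPT_NONLINEAR <- -5.72
SIM_INTERCEPT_OUTCOME <- -5.67
SIM_TREATMENT_COEF <- -1
SIM_CENSOR_TIME <- 200
SIM_N_COVARIATES <- 267L

#' Generate baseline covariates for the simulation study
#'
#' Draws the fixed 267-covariate layout: `X1, X3 ~ Bernoulli(0.5)`,
#' `X2 ~ Bernoulli(0.3 + 0.1 X1)`, `X4, X6 ~ Normal(0,1)`,
#' `X5 = 0.3 + 0.1 X6 + Normal(0,1)`, `X7..X11 ~ Bernoulli(0.4)` and
#' `X12..X267 ~ Bernoulli(0.2)`.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @return numeric matrix `n x 267` with columns `X1..X267`.
#' @export
sim_covariates <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(substream_seed(seed, "sim_covariates"))
  x <- matrix(0, nrow = n, ncol = SIM_N_COVARIATES,
              dimnames = list(NULL, paste0("X", seq_len(SIM_N_COVARIATES))))
  x[, 1] <- rbinom(n, 1, 0.5)
  x[, 3] <- rbinom(n, 1, 0.5)
  x[, 2] <- rbinom(n, 1, 0.3 + 0.1 * x[, 1])
  x[, 4] <- rnorm(n)
  x[, 6] <- rnorm(n)
  x[, 5] <- 0.3 + 0.1 * x[, 6] + rnorm(n)
  x[, 7:11] <- rbinom(n * 5L, 1, 0.4)
  x[, 12:267] <- rbinom(n * 256L, 1, 0.2)
  x
}

# Linear predictor of the treatment-assignment logit for each mechanism.
sim_assignment_logit <- function(x, mechanism) {
  tail_sum <- log(1.5) * rowSums(x[, 7:11, drop = FALSE]) +
    log(1.1) * rowSums(x[, 12:267, drop = FALSE])
  if (mechanism == "linear") {
    SIM_INTERCEPT_LINEAR + log(2) * x[, 2] + log(3) * x[, 3] +
      log(2) * x[, 5] + log(2) * x[, 6] + tail_sum
  } else if (mechanism == "nonlinear") {
    SIM_INTERCEPT_NONLINEAR +
      log(2) * x[, 2]^2 * x[, 1] + log(3) * x[, 3] * x[, 2] * x[, 1] +
      log(2) * x[, 5] * x[, 1] + log(2) * x[, 6] * x[, 1] +
      log(1.5) * rowSums(x[, 7:11, drop = FALSE]) * x[, 1] +
      log(1.1) * rowSums(x[, 12:267, drop = FALSE])
  } else {
    stop("unknown treatment assignment mechanism: ", mechanism)
  }
}

#' Assign treatment from the linear or nonlinear logistic mechanism
#'
#' @param x covariate matrix from [sim_covariates()].
#' @param mechanism `"linear"` or `"nonlinear"`.
#' @param seed integer seed.
#' @return integer 0/1 treatment vector.
#' @export
sim_treatment <- function(x, mechanism = c("linear", "nonlinear"), seed) {
  mechanism <- match.arg(mechanism)
  eta <- sim_assignment_logit(x, mechanism)
  set.seed(substream_seed(seed, "sim_treatment"))
  rbinom(nrow(x), 1, plogis(eta))
}

# Outcome-model linear predictor (log relative hazard), excluding treatment.
sim_outcome_loghazard <- function(x) {
  SIM_INTERCEPT_OUTCOME + log(1.8) * x[, 1] + log(1.8) * x[, 2] +
    log(1.8) * x[, 4] + log(2.3) * x[, 5]^2 +
    log(1.5) * rowSums(x[, 7:11, drop = FALSE]) +
    log(1.1) * rowSums(x[, 12:267, drop = FALSE])
}

# Weibull inverse-transform: raw event time given uniform draw u and linear
# predictor eta (shape 2, scale set by the 100 * sqrt form).
sim_weibull_time <- function(u, eta) {
  100 * sqrt(-log(u) / exp(eta))
}

#' Generate time-to-event outcomes from the Weibull model
#'
#' Raw times follow `100 * sqrt(-log(U) / exp(eta))` with treatment
#' log-hazard -1; observed times are administratively censored at 200 days
#' and events are `T* < 200` (no other censoring mechanism).
#'
#' @param x covariate matrix.
#' @param z 0/1 treatment vector aligned with `x`.
#' @param seed integer seed.
#' @param treatment_coef conditional treatment log-hazard (default -1).
#' @return list with observed times `time`, event indicators `event`, and the
#'   uncensored raw times `raw_time`.
#' @export
sim_time_to_event <- function(x, z, seed, treatment_coef = SIM_TREATMENT_COEF) {
  stopifnot(nrow(x) == length(z))
  eta <- sim_outcome_loghazard(x) + treatment_coef * z
  set.seed(substream_seed(seed, "sim_outcome"))
  u <- runif(nrow(x))
  raw <- sim_weibull_time(u, eta)
  list(time = pmin(raw, SIM_CENSOR_TIME),
       event = as.integer(raw < SIM_CENSOR_TIME),
       raw_time = raw)
}

#' Ground-truth marginal hazard ratio by the potential-outcomes Cox fit
#'
#' Generates a large population, computes both potential event times per
#' subject from the Weibull outcome model with a shared uniform draw (common
#' random numbers), censors both at 200 days, and fits a Cox model with
#' treatment as the sole covariate on the stacked `2 n` rows. The result is
#' the marginal HR that weighting-based estimators target; it differs from
#' the conditional `exp(-1)` because the hazard ratio is non-collapsible.
#'
#' @param n_pop population size (the reference value uses very large `n_pop`;
#'   200,000 keeps Monte-Carlo error near +/-0.01).
#' @param seed integer seed.
#' @param treatment_coef conditional treatment log-hazard (default -1).
#' @return the marginal hazard ratio (scalar).
#' @export
ground_truth_marginal_hr <- function(n_pop, seed,
                                     treatment_coef = SIM_TREATMENT_COEF) {
  stopifnot(n_pop >= 1e4)
  x <- sim_covariates(n_pop, seed)
  eta0 <- sim_outcome_loghazard(x)
  set.seed(substream_seed(seed, "sim_potential"))
  u <- runif(n_pop)
  raw0 <- sim_weibull_time(u, eta0)
  raw1 <- sim_weibull_time(u, eta0 + treatment_coef)
  df <- data.frame(
    time = pmin(c(raw1, raw0), SIM_CENSOR_TIME),
    event = as.integer(c(raw1, raw0) < SIM_CENSOR_TIME),
    z = rep(c(1L, 0L), each = n_pop)
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ z, data = df)
  unname(exp(coef(fit)))
}

#' Design matrix handed to the propensity model under a given specification
#'
#' Under the correct specification the design holds exactly the terms of the
#' generating assignment mechanism. The incorrect specification in the linear
#' scenario is `(X1^2, X2^2, X3^2, X4, X5, X6, X7:11, X12:267)` (squaring the
#' binary covariates is the identity, so this amounts to adding the inactive
#' `X1` and `X4` main effects); in the nonlinear scenario it is the raw main
#' effects `(X1, ..., X267)`, omitting every interaction of the generating
#' mechanism.
#'
#' @param x covariate matrix from [sim_covariates()].
#' @param mechanism `"linear"` or `"nonlinear"` generating mechanism.
#' @param specification `"correct"` or `"incorrect"`.
#' @return numeric design matrix for treatment-model fitting.
#' @export
sim_ps_design <- function(x, mechanism = c("linear", "nonlinear"),
                          specification = c("correct", "incorrect")) {
  mechanism <- match.arg(mechanism)
  specification <- match.arg(specification)
  if (specification == "incorrect") {
    if (mechanism == "linear") {
      out <- cbind(x[, 1]^2, x[, 2]^2, x[, 3]^2, x[, 4:267])
      colnames(out) <- c("X1sq", "X2sq", "X3sq", colnames(x)[4:267])
      return(out)
    }
    return(x)
  }
  if (mechanism == "linear") {
    x[, c(2, 3, 5, 6, 7:11, 12:267)]
  } else {
    out <- cbind(
      x[, 2]^2 * x[, 1],
      x[, 3] * x[, 2] * x[, 1],
      x[, 5] * x[, 1],
      x[, 6] * x[, 1],
      x[, 7:11] * x[, 1],
      x[, 12:267]
    )
    colnames(out) <- c("X2sqX1", "X3X2X1", "X5X1", "X6X1",
                       paste0(colnames(x)[7:11], "X1"), colnames(x)[12:267])
    out
  }
}

#' Enumerate the simulation scenario grid
#'
#' The full replication grid crosses sample size
#' (3000, 3500, 4000, 4500, 5000), generating mechanism (linear, nonlinear)
#' and treatment-model specification (correct, incorrect): 20 scenarios.
#'
#' @param sizes sample sizes.
#' @param mechanisms generating mechanisms.
#' @param specifications treatment-model specifications.
#' @return data frame with one row per scenario.
#' @export
sim_scenario_grid <- function(sizes = c(3000, 3500, 4000, 4500, 5000),
                              mechanisms = c("linear", "nonlinear"),
                              specifications = c("correct", "incorrect")) {
  stopifnot(length(sizes) > 0, length(mechanisms) > 0,
            length(specifications) > 0)
  expand.grid(n = sizes, mechanism = mechanisms,
              specification = specifications,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Run one simulation scenario across replicates and selection strategies
#'
#' For each replicate: generate covariates, treatment and outcomes; split
#' 80:20 stratified by treatment; run the cross-validated logistic propensity
#' model search once on the training set; let each selection strategy pick
#' its winner from the shared CV table; refit the winner on the training set;
#' compute trimmed stabilized weights and the unbalanced-covariate count on
#' the combined data; and estimate the marginal HR by a weighted Cox fit with
#' treatment as the sole covariate.
#'
#' @param n subjects per replicate.
#' @param mechanism,specification scenario factors (see [sim_ps_design()]).
#' @param strategies selection strategies to compare (see [select_cv()]).
#' @param n_replicates number of Monte-Carlo replicates.
#' @param seed integer seed; replicate r uses substream `seed + r`.
#' @param truth ground-truth marginal HR for bias/MSE/coverage.
#' @param k CV folds.
#' @param space propensity model space (default: the logistic-regression grid).
#' @param config run configuration (balance thresholds, trimming).
#' @param coverage_scale scale on which the Wald interval `psi_b +/- 1.96
#'   sigma` is formed for CI coverage: `"hr"` (default, the metric as
#'   defined) or `"log"` (intervals on the log-HR scale).
#' @return list with `replicates` (per replicate x strategy estimates) and
#'   `metrics` (one row per strategy: balanced ratio, mean unbalanced counts
#'   before/after weighting, HR mean/SD, bias, MSE, Wald coverage).
#' @export
run_scenario <- function(n, mechanism, specification,
                         strategies = c("balance_auc", "val_auc", "val_loss"),
                         n_replicates = 100, seed = 1, truth,
                         k = 10, space = NULL, config = run_config(),
                         coverage_scale = c("hr", "log")) {
  coverage_scale <- match.arg(coverage_scale)
  if (is.null(space)) space <- ps_model_space("LR")
  rows <- vector("list", n_replicates * length(strategies))
  ri <- 0L
  for (r in seq_len(n_replicates)) {
    rseed <- substream_seed(seed, paste0("replicate", r))
    x <- sim_covariates(n, rseed)
    z <- sim_treatment(x, mechanism, rseed)
    if (length(unique(z)) < 2L) next
    outc <- sim_time_to_event(x, z, rseed)
    design <- sim_ps_design(x, mechanism, specification)
    test <- split_train_test(z, 0.2, rseed)
    cv <- ps_cv(design[!test, , drop = FALSE], z[!test], space, k = k,
                seed = rseed, config = config,
                balance_x = x[!test, , drop = FALSE])
    n_before <- count_unbalanced(smd(x, z), config$smd_threshold)
    for (strat in strategies) {
      pick <- pick_from_cv_table(cv$table, strat)
      model <- fit_ps(design[!test, , drop = FALSE], z[!test],
                      space$settings[[pick]], seed = rseed)
      ps_all <- predict_ps(model, design)
      w <- stabilized_iptw(ps_all, z, trim_quantile = config$trim_quantile)
      n_after <- count_unbalanced(smd(x, z, w$weights), config$smd_threshold)
      balanced <- is_trial_balanced(n_after, ncol(x), config$unbalanced_ratio)
      est <- tryCatch(
        weighted_cox(z, outc$event, outc$time, w$weights),
        error = function(e) NULL
      )
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        replicate = r, strategy = strat,
        n_unbalanced_before = n_before, n_unbalanced_after = n_after,
        balanced = balanced,
        hr = if (is.null(est)) NA_real_ else est$ahr,
        converged = !is.null(est) && est$converged,
        stringsAsFactors = FALSE
      )
    }
  }
  reps <- do.call(rbind, rows[seq_len(ri)])
  metrics <- do.call(rbind, lapply(strategies, function(strat) {
    d <- reps[reps$strategy == strat & reps$converged & !is.na(reps$hr), ]
    sigma <- sd(d$hr)
    covered <- if (coverage_scale == "hr") {
      abs(d$hr - truth) <= 1.96 * sigma
    } else {
      abs(log(d$hr) - log(truth)) <= 1.96 * sd(log(d$hr))
    }
    data.frame(
      n = n, mechanism = mechanism, specification = specification,
      strategy = strat,
      n_replicates = nrow(d),
      balanced_ratio = mean(d$balanced),
      n_unbalanced_before = mean(d$n_unbalanced_before),
      n_unbalanced_after = mean(d$n_unbalanced_after),
      hr_mean = mean(d$hr),
      hr_sd = sigma,
      bias = mean(d$hr) - truth,
      mse = mean((d$hr - truth)^2),
      coverage = mean(covered),
      stringsAsFactors = FALSE
    )
  }))
  list(replicates = reps, metrics = metrics)
}

#' Run the full simulation grid
#'
#' @inheritParams run_scenario
#' @inheritParams sim_scenario_grid
#' @param truth ground-truth marginal HR; when `NULL` it is computed once by
#'   [ground_truth_marginal_hr()] with `n_pop = 2e5`.
#' @return `SimMetrics` data frame: one row per scenario x strategy.
#' @export
run_grid <- function(sizes = c(3000, 3500, 4000, 4500, 5000),
                     mechanisms = c("linear", "nonlinear"),
                     specifications = c("correct", "incorrect"),
                     strategies = c("balance_auc", "val_auc", "val_loss"),
                     n_replicates = 100, seed = 1, truth = NULL,
                     k = 10, config = run_config()) {
  grid <- sim_scenario_grid(sizes, mechanisms, specifications)
  if (is.null(truth)) {
    truth <- ground_truth_marginal_hr(2e5, substream_seed(seed, "truth"))
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    run_scenario(grid$n[i], grid$mechanism[i], grid$specification[i],
                 strategies = strategies, n_replicates = n_replicates,
                 seed = substream_seed(seed, paste0("scenario", i)),
                 truth = truth, k = k, config = config)$metrics
  })
  res <- do.call(rbind, out)
  attr(res, "truth") <- truth
  res
}
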