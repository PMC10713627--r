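# Balance-aware cross-validated propensity model selection and evaluation.

#' Cross-validated fit table over a propensity model space
#'
#' For each hyperparameter setting and each of `k` stratified folds, the
#' model is trained on the remaining folds, trimmed stabilized weights are
#' computed on the *whole* training set from the fold model and the
#' post-weighting unbalanced-covariate count is recorded, while AUC and
#' cross-entropy loss are computed on the held-out fold; all three are then
#' averaged over folds. Logistic settings sharing a penalty are fitted as a
#' single regularization path per fold, so the full 27-setting grid costs
#' three fits per fold.
#'
#' @param x design matrix handed to the treatment model.
#' @param z 0/1 treatment vector.
#' @param space a [ps_model_space()].
#' @param k number of folds (default 10).
#' @param seed integer seed (fold assignment and stochastic fits).
#' @param config run configuration (balance thresholds, trimming).
#' @param balance_x covariate matrix on which balance is diagnosed; defaults
#'   to `x`, but callers may diagnose balance on raw covariates while the
#'   model sees a transformed design.
#' @return list with `table` (one row per setting: mean `n_unbalance`, mean
#'   validation `auc`, mean validation `loss`) and the fold assignment.
#' @export
ps_cv <- function(x, z, space, k = 10, seed = 1, config = run_config(),
                  balance_x = NULL) {
  stopifnot(inherits(space, "ps_model_space"))
  x <- as.matrix(x)
  z <- as.integer(z)
  if (k > length(z)) stop("more folds than subjects")
  if (is.null(balance_x)) balance_x <- x
  fold <- make_folds(z, k, seed)
  n_set <- length(space$settings)
  nub <- matrix(NA_real_, n_set, k)
  auc <- matrix(NA_real_, n_set, k)
  loss <- matrix(NA_real_, n_set, k)
  for (fk in seq_len(k)) {
    tr <- fold != fk
    preds <- cv_fold_predictions(x, z, space, tr, seed)
    for (si in seq_len(n_set)) {
      ps_all <- preds[[si]]
      w <- stabilized_iptw(ps_all, z, trim_quantile = config$trim_quantile)
      nub[si, fk] <- count_unbalanced(smd(balance_x, z, w$weights),
                                      config$smd_threshold)
      auc[si, fk] <- auc_score(z[!tr], ps_all[!tr])
      loss[si, fk] <- bce_loss(z[!tr], ps_all[!tr])
    }
  }
  tab <- data.frame(
    setting = space$labels,
    n_unbalance = rowMeans(nub),
    auc = rowMeans(auc),
    loss = rowMeans(loss),
    stringsAsFactors = FALSE
  )
  list(table = tab, fold = fold, k = k)
}

# Predicted propensity scores on the full data for every setting, fitted on
# rows `tr`. LR penalty grids share one glmnet path per penalty.
cv_fold_predictions <- function(x, z, space, tr, seed) {
  preds <- vector("list", length(space$settings))
  if (space$family == "LR") {
    xs <- x[tr, , drop = FALSE]
    n_tr <- nrow(xs)
    for (penalty in c("l1", "l2")) {
      idx <- which(vapply(space$settings,
                          function(s) s$penalty == penalty, logical(1)))
      if (!length(idx)) next
      lams <- lr_lambda(vapply(space$settings[idx], `[[`, numeric(1), "C"), n_tr)
      # shared path on the standard strength grid (plus any extras), matching
      # the sequence fit_ps() uses, so grouped and single fits agree exactly
      path <- sort(unique(c(lr_lambda(10^seq(-3, 3, by = 0.5), n_tr), lams)),
                   decreasing = TRUE)
      set.seed(substream_seed(seed, "glmnet"))
      g <- glmnet::glmnet(xs, z[tr], family = "binomial",
                          alpha = if (penalty == "l1") 1 else 0,
                          lambda = path, standardize = FALSE)
      p <- predict(g, newx = x, s = lams, type = "response", exact = FALSE)
      for (j in seq_along(idx)) preds[[idx[j]]] <- clip_prob(as.numeric(p[, j]))
    }
    idx_none <- which(vapply(space$settings,
                             function(s) s$penalty == "none", logical(1)))
    for (si in idx_none) {
      m <- fit_ps(xs, z[tr], space$settings[[si]], seed = seed)
      preds[[si]] <- predict_ps(m, x)
    }
  } else {
    for (si in seq_along(space$settings)) {
      m <- fit_ps(x[tr, , drop = FALSE], z[tr], space$settings[[si]],
                  seed = seed)
      preds[[si]] <- predict_ps(m, x)
    }
  }
  preds
}

# Strict-inequality winner selection over the CV table, in grid order.
# balance_auc: minimize mean n_unbalance, ties (exact equality) broken by
# strictly larger mean AUC; val_auc: maximize AUC; val_loss: minimize loss.
pick_from_cv_table <- function(table, strategy) {
  best <- 1L
  if (strategy == "balance_auc") {
    for (i in seq_len(nrow(table))[-1]) {
      if (table$n_unbalance[i] < table$n_unbalance[best] ||
          (table$n_unbalance[i] == table$n_unbalance[best] &&
           table$auc[i] > table$auc[best])) {
        best <- i
      }
    }
  } else if (strategy == "val_auc") {
    for (i in seq_len(nrow(table))[-1]) {
      if (table$auc[i] > table$auc[best]) best <- i
    }
  } else if (strategy == "val_loss") {
    for (i in seq_len(nrow(table))[-1]) {
      if (table$loss[i] < table$loss[best]) best <- i
    }
  } else {
    stop("unknown selection strategy: ", strategy)
  }
  best
}

#' Select a propensity model by cross-validation
#'
#' Runs [ps_cv()] and picks the winning hyperparameter setting under one of
#' three strategies: `"balance_auc"` (the balance-aware rule: smallest mean
#' post-weighting unbalanced count on the whole training set, exact ties
#' broken by the largest mean validation AUC, remaining ties by grid order),
#' `"val_auc"` (largest mean validation AUC) or `"val_loss"` (smallest mean
#' validation cross-entropy). The winner is retrained on the full training
#' set.
#'
#' @inheritParams ps_cv
#' @param strategy selection strategy.
#' @return a `selection_result`: chosen `setting` (and its grid index), the
#'   retrained `model`, its post-weighting unbalanced count `n_unbalance` on
#'   the training data, its mean validation `auc`, and the full `cv_table`.
#' @export
select_cv <- function(x, z, space, k = 10,
                      strategy = c("balance_auc", "val_auc", "val_loss"),
                      seed = 1, config = run_config(), balance_x = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(balance_x)) balance_x <- x
  cv <- ps_cv(x, z, space, k = k, seed = seed, config = config,
              balance_x = balance_x)
  best <- pick_from_cv_table(cv$table, strategy)
  model <- fit_ps(x, z, space$settings[[best]], seed = seed)
  ps <- predict_ps(model, x)
  w <- stabilized_iptw(ps, z, trim_quantile = config$trim_quantile)
  n_unb <- count_unbalanced(smd(balance_x, z, w$weights), config$smd_threshold)
  structure(list(
    strategy = strategy,
    index = best,
    setting = space$settings[[best]],
    label = space$labels[best],
    model = model,
    n_unbalance = n_unb,
    auc = cv$table$auc[best],
    cv_table = cv$table
  ), class = "selection_result")
}

#' Nested cross-validated selection
#'
#' Sensitivity variant: an outer K-fold loop in which the inner loop runs
#' [select_cv()] on each outer-training partition; the outer table reports
#' each inner winner's held-out AUC on its outer fold and its post-weighting
#' unbalanced count on the full training data. The returned final model is
#' the flat [select_cv()] fit on the full training set.
#'
#' @inheritParams select_cv
#' @param k_outer,k_inner outer and inner fold counts (defaults 10 and 5).
#' @return a `selection_result` with an additional `outer_table` (one row per
#'   outer fold: chosen setting, held-out AUC, unbalanced count).
#' @export
select_nested_cv <- function(x, z, space, k_outer = 10, k_inner = 5,
                             strategy = c("balance_auc", "val_auc", "val_loss"),
                             seed = 1, config = run_config(), balance_x = NULL) {
  strategy <- match.arg(strategy)
  x <- as.matrix(x)
  if (k_outer > length(z)) stop("more outer folds than subjects")
  if (is.null(balance_x)) balance_x <- x
  fold <- make_folds(z, k_outer, substream_seed(seed, "outer"))
  outer_rows <- vector("list", k_outer)
  for (fk in seq_len(k_outer)) {
    tr <- fold != fk
    sel <- select_cv(x[tr, , drop = FALSE], z[tr], space, k = k_inner,
                     strategy = strategy,
                     seed = substream_seed(seed, paste0("inner", fk)),
                     config = config,
                     balance_x = balance_x[tr, , drop = FALSE])
    ps_all <- predict_ps(sel$model, x)
    w <- stabilized_iptw(ps_all, z, trim_quantile = config$trim_quantile)
    outer_rows[[fk]] <- data.frame(
      outer_fold = fk,
      setting = sel$label,
      auc_outer = auc_score(z[!tr], ps_all[!tr]),
      n_unbalance = count_unbalanced(smd(balance_x, z, w$weights),
                                     config$smd_threshold),
      stringsAsFactors = FALSE
    )
  }
  final <- select_cv(x, z, space, k = k_inner, strategy = strategy,
                     seed = seed, config = config, balance_x = balance_x)
  final$outer_table <- do.call(rbind, outer_rows)
  final
}

#' Evaluate a selected model's balance on train, test and combined data
#'
#' Weights are computed independently per partition (the empirical treated
#' fraction is recomputed on each), and the post-weighting
#' unbalanced-covariate count is reported for the training set, the test set
#' and their concatenation.
#'
#' @param model a `ps_fit`.
#' @param x_train,z_train training covariates/design and treatment.
#' @param x_test,z_test held-out covariates/design and treatment.
#' @param config run configuration.
#' @param balance_train,balance_test covariate matrices for balance
#'   diagnosis; default to the design matrices.
#' @return list with unbalanced counts `n_train`, `n_test`, `n_all`.
#' @export
evaluate_balance <- function(model, x_train, z_train, x_test, z_test,
                             config = run_config(),
                             balance_train = NULL, balance_test = NULL) {
  if (length(z_test) == 0) stop("empty test set")
  if (is.null(balance_train)) balance_train <- x_train
  if (is.null(balance_test)) balance_test <- x_test
  count_for <- function(xd, zd, bx) {
    ps <- predict_ps(model, xd)
    w <- stabilized_iptw(ps, zd, trim_quantile = config$trim_quantile)
    count_unbalanced(smd(bx, zd, w$weights), config$smd_threshold)
  }
  list(
    n_train = count_for(x_train, z_train, balance_train),
    n_test = count_for(x_test, z_test, balance_test),
    n_all = count_for(rbind(as.matrix(x_train), as.matrix(x_test)),
                      c(z_train, z_test),
                      rbind(as.matrix(balance_train), as.matrix(balance_test)))
  )
}
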