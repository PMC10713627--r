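# Propensity-score model spaces, fitting, and trimmed stabilized IPTW.

#' Define a propensity-score model space
#'
#' Three model families with fixed hyperparameter grids:
#' * `LR` - regularized logistic regression: penalties L1, L2 and none,
#'   crossed with 13 inverse regularization strengths
#'   `10^-3, 10^-2.5, ..., 10^3` (the strength is ignored for `none`),
#'   27 settings in all.
#' * `GBM` - gradient boosted trees: maximum depth (3, 4, 5) x maximum
#'   leaves (5, 25, 45, 65, 85, 105) x minimum samples per leaf
#'   (200, 250, 300), 54 settings.
#' * `MLP` - feed-forward networks: hidden layout (32, 64, 128, 32+32,
#'   64+64) x learning rate (1e-3, 1e-4) x weight decay (1e-3 ... 1e-6),
#'   trained 15 epochs with batch size 128, 40 settings.
#'
#' @param family `"LR"`, `"GBM"` or `"MLP"`.
#' @return a `ps_model_space`: list with `family` and `settings`, a list of
#'   hyperparameter settings in grid order.
#' @export
ps_model_space <- function(family = c("LR", "GBM", "MLP")) {
  family <- match.arg(family)
  settings <- switch(family,
    LR = {
      strengths <- 10^seq(-3, 3, by = 0.5)
      c(
        lapply(strengths, function(C) list(family = "LR", penalty = "l1", C = C)),
        lapply(strengths, function(C) list(family = "LR", penalty = "l2", C = C)),
        list(list(family = "LR", penalty = "none", C = Inf))
      )
    },
    GBM = {
      grid <- expand.grid(depth = c(3, 4, 5),
                          leaves = c(5, 25, 45, 65, 85, 105),
                          min_leaf = c(200, 250, 300))
      lapply(seq_len(nrow(grid)), function(i) {
        list(family = "GBM", depth = grid$depth[i], leaves = grid$leaves[i],
             min_leaf = grid$min_leaf[i])
      })
    },
    MLP = {
      hidden <- list(32L, 64L, 128L, c(32L, 32L), c(64L, 64L))
      grid <- expand.grid(h = seq_along(hidden), lr = c(1e-3, 1e-4),
                          decay = c(1e-3, 1e-4, 1e-5, 1e-6))
      lapply(seq_len(nrow(grid)), function(i) {
        list(family = "MLP", hidden = hidden[[grid$h[i]]], lr = grid$lr[i],
             decay = grid$decay[i], epochs = 15L, batch_size = 128L)
      })
    }
  )
  labels <- vapply(settings, setting_label, character(1))
  structure(list(family = family, settings = settings, labels = labels),
            class = "ps_model_space")
}

setting_label <- function(s) {
  switch(s$family,
    LR = sprintf("LR:%s:C=%g", s$penalty, s$C),
    GBM = sprintf("GBM:d=%d:l=%d:m=%d", s$depth, s$leaves, s$min_leaf),
    MLP = sprintf("MLP:h=%s:lr=%g:wd=%g", paste(s$hidden, collapse = "+"),
                  s$lr, s$decay)
  )
}

# Map an inverse regularization strength C to the glmnet penalty scale
# (glmnet averages the loss over n, so lambda = 1 / (n C)).
lr_lambda <- function(C, n) 1 / (n * C)

#' Fit a propensity-score model for one hyperparameter setting
#'
#' Binary treatment model minimizing cross-entropy. Logistic fits use
#' `glmnet` (L1/L2) or unpenalized `glm`; gradient boosting uses `xgboost`
#' with loss-guided leaf growth; networks use the package's minibatch Adam
#' trainer. Fits are deterministic given `seed`.
#'
#' @param x numeric covariate/design matrix.
#' @param z 0/1 treatment vector.
#' @param setting one element of `ps_model_space()$settings`.
#' @param seed integer seed.
#' @return a `ps_fit` object usable with [predict_ps()].
#' @export
fit_ps <- function(x, z, setting, seed = 1) {
  x <- as.matrix(x)
  z <- as.integer(z)
  if (nrow(x) < 2L || length(unique(z)) < 2L) {
    stop("degenerate treatment assignment: both classes required")
  }
  fit <- switch(setting$family,
    LR = fit_ps_lr(x, z, setting, seed),
    GBM = fit_ps_gbm(x, z, setting, seed),
    MLP = fit_ps_mlp(x, z, setting, seed),
    stop("unknown model family: ", setting$family)
  )
  structure(list(family = setting$family, setting = setting, fit = fit),
            class = "ps_fit")
}

fit_ps_lr <- function(x, z, setting, seed) {
  if (setting$penalty == "none") {
    # Drop constant columns: they carry no assignment information and break
    # the unpenalized normal equations.
    keep <- which(apply(x, 2, function(col) max(col) > min(col)))
    xd <- as.data.frame(x[, keep, drop = FALSE])
    names(xd) <- paste0("V", keep)
    g <- suppressWarnings(glm(z ~ ., data = cbind(z = z, xd),
                              family = binomial()))
    list(kind = "glm", model = g, keep = keep)
  } else {
    alpha <- if (setting$penalty == "l1") 1 else 0
    # Fit the whole 13-value strength path at once; extracting the requested
    # strength from the shared path keeps single fits and grid fits identical.
    lambdas <- sort(lr_lambda(10^seq(-3, 3, by = 0.5), nrow(x)),
                    decreasing = TRUE)
    lam <- lr_lambda(setting$C, nrow(x))
    lambdas <- sort(unique(c(lambdas, lam)), decreasing = TRUE)
    set.seed(substream_seed(seed, "glmnet"))
    g <- glmnet::glmnet(x, z, family = "binomial", alpha = alpha,
                        lambda = lambdas, standardize = FALSE)
    list(kind = "glmnet", model = g, lambda = lam)
  }
}

fit_ps_gbm <- function(x, z, setting, seed) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = z)
  params <- list(
    objective = "binary:logistic",
    max_depth = as.integer(setting$depth),
    max_leaves = as.integer(setting$leaves),
    grow_policy = "lossguide",
    min_child_weight = setting$min_leaf,
    eta = 0.1,
    nthread = 1,
    seed = substream_seed(seed, "xgb")
  )
  booster <- xgboost::xgb.train(params = params, data = dtrain, nrounds = 50,
                                verbose = 0)
  list(kind = "xgb", model = booster)
}

#' Predict propensity scores from a fitted model
#'
#' @param object a `ps_fit` from [fit_ps()].
#' @param x covariate/design matrix on the same columns as the fit.
#' @return predicted `P(Z = 1 | X)`, clipped to `[1e-6, 1 - 1e-6]` so that
#'   inverse weights remain finite under separation.
#' @export
predict_ps <- function(object, x) {
  stopifnot(inherits(object, "ps_fit"))
  x <- as.matrix(x)
  f <- object$fit
  p <- switch(f$kind,
    glm = {
      nd <- as.data.frame(x[, f$keep, drop = FALSE])
      names(nd) <- paste0("V", f$keep)
      # rank-deficient fits (n < p after fold splitting) predict with the
      # estimable subset; the warning is expected, predictions remain valid
      suppressWarnings(
        as.numeric(predict(f$model, newdata = nd, type = "response")))
    },
    glmnet = as.numeric(predict(f$model, newx = x, s = f$lambda,
                                type = "response", exact = FALSE)),
    xgb = as.numeric(predict(f$model, xgboost::xgb.DMatrix(data = x))),
    mlp = mlp_predict(f$model, x)
  )
  clip_prob(p)
}

#' @export
predict.ps_fit <- function(object, newdata, ...) predict_ps(object, newdata)

#' Trimmed stabilized inverse probability of treatment weights
#'
#' Stabilized weights `w_i = Z_i P(Z=1)/ps_i + (1 - Z_i) P(Z=0)/(1 - ps_i)`,
#' with `P(Z=1)` the empirical treated fraction of the supplied subjects, so
#' partitions (train, test, combined) are weighted independently. Extreme
#' weights are trimmed by winsorization: values outside the
#' `[trim_quantile, 1 - trim_quantile]` pooled empirical quantiles are capped
#' at the quantile values, keeping the sample size fixed.
#'
#' @param ps propensity scores in (0, 1).
#' @param z 0/1 treatment vector aligned with `ps`.
#' @param trim_quantile two-sided tail quantile for winsorization (default
#'   0.01, i.e. the top 1% smallest and biggest weights); 0 disables it.
#' @return list with `weights`, the `trim_quantile` used and the treated
#'   fraction `p_treated`.
#' @export
stabilized_iptw <- function(ps, z, trim_quantile = 0.01) {
  if (any(ps <= 0 | ps >= 1)) stop("propensity scores must lie in (0, 1)")
  stopifnot(length(ps) == length(z), all(z %in% c(0, 1)),
            trim_quantile >= 0, trim_quantile < 0.5)
  p1 <- mean(z)
  w <- ifelse(z == 1, p1 / ps, (1 - p1) / (1 - ps))
  if (trim_quantile > 0) {
    q <- quantile(w, c(trim_quantile, 1 - trim_quantile), names = FALSE)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  list(weights = w, trim_quantile = trim_quantile, p_treated = p1)
}

#' Summarize a fitted propensity model for audit output
#'
#' @param fit a `ps_fit`.
#' @return list with family, hyperparameters and coefficients (where the
#'   family has them), suitable for JSON serialization.
#' @export
ps_fit_summary <- function(fit) {
  stopifnot(inherits(fit, "ps_fit"))
  out <- list(family = fit$family, setting = fit$setting[-1])
  if (fit$family == "LR") {
    f <- fit$fit
    if (f$kind == "glm") {
      out$coefficients <- as.list(coef(f$model))
    } else {
      cf <- as.matrix(coef(f$model, s = f$lambda))
      out$coefficients <- as.list(stats::setNames(cf[, 1], rownames(cf)))
    }
  }
  out
}
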