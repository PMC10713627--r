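test_that("model spaces carry the printed hyperparameter grids", {
  lr <- ps_model_space("LR")
  expect_equal(length(lr$settings), 27)  # (L1 + L2) x 13 strengths + none
  cs <- vapply(lr$settings[1:13], `[[`, numeric(1), "C")
  expect_equal(cs, 10^seq(-3, 3, by = 0.5))
  expect_equal(unique(vapply(lr$settings, `[[`, character(1), "penalty")),
               c("l1", "l2", "none"))

  gbm <- ps_model_space("GBM")
  expect_equal(length(gbm$settings), 3 * 6 * 3)
  expect_setequal(unique(vapply(gbm$settings, `[[`, numeric(1), "depth")),
                  c(3, 4, 5))
  expect_setequal(unique(vapply(gbm$settings, `[[`, numeric(1), "leaves")),
                  c(5, 25, 45, 65, 85, 105))
  expect_setequal(unique(vapply(gbm$settings, `[[`, numeric(1), "min_leaf")),
                  c(200, 250, 300))

  mlp <- ps_model_space("MLP")
  expect_equal(length(mlp$settings), 5 * 2 * 4)
  expect_true(all(vapply(mlp$settings, `[[`, integer(1), "epochs") == 15L))
  expect_true(all(vapply(mlp$settings, `[[`, integer(1), "batch_size") == 128L))
})

test_that("stabilized weights match the hand-substituted example", {
  w <- stabilized_iptw(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0),
                       trim_quantile = 0)
  expect_equal(w$weights, c(0.625, 1, 1, 0.625))
  expect_equal(w$p_treated, 0.5)
  expect_equal(formals(stabilized_iptw)$trim_quantile, 0.01)
})

test_that("propensity equal to the treated fraction gives unit weights", {
  z <- rep(c(1, 0), c(30, 70))
  w <- stabilized_iptw(rep(0.3, 100), z, trim_quantile = 0)
  expect_equal(w$weights, rep(1, 100))
})

test_that("weight trimming winsorizes, preserves order, and rejects bad ps", {
  set.seed(12)
  ps <- runif(500, 0.01, 0.99)
  z <- rbinom(500, 1, ps)
  raw <- stabilized_iptw(ps, z, trim_quantile = 0)$weights
  trm <- stabilized_iptw(ps, z, trim_quantile = 0.01)$weights
  expect_lte(max(trm), max(raw))
  expect_gte(min(trm), min(raw))
  # monotone: winsorization never reorders
  expect_true(all(diff(trm[order(raw)]) >= -1e-12))
  expect_true(all(trm > 0 & is.finite(trm)))
  expect_error(stabilized_iptw(c(0, 0.5), c(1, 0)), "in \\(0, 1\\)")

  # permutation equivariance
  perm <- sample(500)
  expect_equal(stabilized_iptw(ps[perm], z[perm], 0.01)$weights, trm[perm])
})

test_that("mean stabilized weight approaches 1 per arm under a correct model", {
  set.seed(21)
  n <- 1e5
  x <- matrix(rnorm(n * 2), n, 2)
  ps_true <- plogis(-0.4 + 0.8 * x[, 1] - 0.5 * x[, 2])
  z <- rbinom(n, 1, ps_true)
  w <- stabilized_iptw(ps_true, z, trim_quantile = 0)$weights
  # MC standard error of the arm mean weight is ~sd(w)/sqrt(n_arm)
  for (arm in c(0, 1)) {
    idx <- z == arm
    se <- sd(w[idx]) / sqrt(sum(idx))
    expect_lt(abs(mean(w[idx]) - 1), 3 * se)
  }
})

test_that("logistic fits recover generating coefficients at n = 1e5", {
  set.seed(31)
  n <- 1e5
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  z <- rbinom(n, 1, plogis(0.3 + 0.7 * x[, 1] - 1.1 * x[, 2]))
  fit <- fit_ps(x, z, list(family = "LR", penalty = "none", C = Inf))
  cf <- coef(fit$fit$model)
  expect_equal(unname(cf), c(0.3, 0.7, -1.1), tolerance = 0.05)
})

test_that("treatment independent of covariates predicts the treated fraction", {
  set.seed(41)
  n <- 5000
  x <- matrix(rnorm(n * 5), n, 5)
  z <- rbinom(n, 1, 0.35)
  fit <- fit_ps(x, z, list(family = "LR", penalty = "l2", C = 1))
  p <- predict_ps(fit, x)
  expect_lt(max(abs(p - mean(z))), 0.1)
  expect_lt(abs(mean(p) - mean(z)), 0.02)
})

test_that("separable data yields clipped probabilities and finite weights", {
  x <- matrix(c(rep(0, 20), rep(1, 20)), ncol = 1)
  z <- rep(c(0L, 1L), each = 20)
  fit <- fit_ps(x, z, list(family = "LR", penalty = "none", C = Inf))
  p <- predict_ps(fit, x)
  expect_true(all(p > 0 & p < 1))
  w <- stabilized_iptw(p, z, 0.01)$weights
  expect_true(all(is.finite(w)))
  expect_error(fit_ps(x, rep(1L, 40), list(family = "LR", penalty = "none")),
               "degenerate treatment")
})

test_that("GBM and MLP families emit valid, seed-deterministic scores", {
  tr <- confounded_trial(n = 400, seed = 6)
  for (setting in list(list(family = "GBM", depth = 3, leaves = 25,
                            min_leaf = 20),
                       list(family = "MLP", hidden = c(16L, 16L), lr = 1e-2,
                            decay = 1e-4, epochs = 50L, batch_size = 64L))) {
    f1 <- fit_ps(tr$x, tr$z, setting, seed = 99)
    f2 <- fit_ps(tr$x, tr$z, setting, seed = 99)
    p1 <- predict_ps(f1, tr$x)
    expect_true(all(p1 > 0 & p1 < 1))
    expect_equal(p1, predict_ps(f2, tr$x))
    # better than chance on its training data
    expect_gt(naive_auc(tr$z, p1), 0.6)
  }
})

test_that("fit summaries expose logistic coefficients for audit", {
  tr <- confounded_trial(n = 300, seed = 8)
  fit <- fit_ps(tr$x, tr$z, list(family = "LR", penalty = "l2", C = 1))
  s <- ps_fit_summary(fit)
  expect_equal(s$family, "LR")
  expect_true(length(s$coefficients) >= ncol(tr$x))
})
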