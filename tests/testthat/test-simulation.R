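test_that("simulated covariates follow the stated marginal structure", {
  x <- sim_covariates(1e5, seed = 3)
  expect_equal(ncol(x), 267)
  expect_equal(mean(x[, 2]), 0.35, tolerance = 0.01)  # 0.3 + 0.1 * E[X1]
  expect_equal(mean(x[, 1]), 0.5, tolerance = 0.01)
  expect_equal(mean(x[, 7]), 0.4, tolerance = 0.01)
  expect_equal(mean(x[, 12]), 0.2, tolerance = 0.01)
  expect_equal(sd(x[, 4]), 1, tolerance = 0.02)
  # X5 = 0.3 + 0.1 X6 + noise
  expect_equal(mean(x[, 5]), 0.3, tolerance = 0.02)
  expect_gt(cor(x[, 5], x[, 6]), 0.05)
  expect_identical(x, sim_covariates(1e5, seed = 3))
})

test_that("assignment logits match closed-form sigmoid values at zero
           covariates", {
  x0 <- matrix(0, 1, 267)
  expect_equal(plogis(ttescreen:::sim_assignment_logit(x0, "linear")),
               1.07e-3, tolerance = 0.005)
  expect_equal(plogis(ttescreen:::sim_assignment_logit(x0, "nonlinear")),
               3.27e-3, tolerance = 0.005)
  expect_error(ttescreen:::sim_assignment_logit(x0, "quadratic"), "unknown")
  z <- sim_treatment(sim_covariates(2000, 4), "linear", seed = 4)
  expect_true(all(z %in% c(0L, 1L)))
})

test_that("Weibull times censor at 200 and invert exactly", {
  x <- sim_covariates(5000, seed = 6)
  z <- sim_treatment(x, "linear", seed = 6)
  out <- sim_time_to_event(x, z, seed = 6)
  expect_true(all(out$time <= 200))
  expect_identical(out$event, as.integer(out$raw_time < 200))
  # inverse-transform algebra: eta = -5.67, U = exp(-e^-5.67) gives T* = 100
  expect_equal(ttescreen:::sim_weibull_time(exp(-exp(-5.67)), -5.67), 100,
               tolerance = 1e-10)
})

test_that("a null treatment coefficient makes potential times identical", {
  x <- sim_covariates(500, seed = 8)
  a <- sim_time_to_event(x, rep(0L, 500), seed = 8, treatment_coef = 0)
  b <- sim_time_to_event(x, rep(1L, 500), seed = 8, treatment_coef = 0)
  expect_identical(a$time, b$time)
})

test_that("the potential-outcomes fit exposes non-collapsibility", {
  hr <- ground_truth_marginal_hr(2e4, seed = 5)
  # conditional HR is exp(-1) ~ 0.368; the marginal must sit well above it
  expect_gt(hr, 0.45)
  expect_lt(hr, 0.75)
  hr_null <- ground_truth_marginal_hr(2e4, seed = 5, treatment_coef = 0)
  expect_equal(hr_null, 1, tolerance = 0.03)
})

test_that("incorrect specifications follow the stated designs", {
  x <- sim_covariates(50, seed = 9)
  lin_inc <- sim_ps_design(x, "linear", "incorrect")
  expect_equal(ncol(lin_inc), 267)
  # squaring binary covariates is the identity
  expect_equal(unname(lin_inc[, "X1sq"]), unname(x[, 1]))
  expect_equal(unname(lin_inc[, "X3sq"]), unname(x[, 3]))
  # the correct linear design omits the inactive X1 and X4
  lin_cor <- sim_ps_design(x, "linear", "correct")
  expect_false(any(c("X1", "X4") %in% colnames(lin_cor)))
  expect_equal(ncol(lin_cor), 265)
  # nonlinear incorrect = raw main effects, no interactions
  nl_inc <- sim_ps_design(x, "nonlinear", "incorrect")
  expect_identical(nl_inc, x)
  nl_cor <- sim_ps_design(x, "nonlinear", "correct")
  expect_true(all(grepl("X1$|^X1", colnames(nl_cor)[1:9])))
  expect_equal(unname(nl_cor[, "X5X1"]), unname(x[, 5] * x[, 1]))
})

test_that("the replication grid enumerates the full factor crossing", {
  grid <- sim_scenario_grid()
  expect_equal(nrow(grid), 20)
  expect_equal(sort(unique(grid$n)), c(3000, 3500, 4000, 4500, 5000))
  expect_setequal(unique(grid$mechanism), c("linear", "nonlinear"))
  expect_setequal(unique(grid$specification), c("correct", "incorrect"))
  expect_equal(nrow(sim_scenario_grid(sizes = 3000)), 4)
})

test_that("scenario metrics have coherent bias/MSE/coverage accounting", {
  res <- run_scenario(500, "linear", "correct",
                      strategies = c("balance_auc", "val_auc"),
                      n_replicates = 4, seed = 30, truth = 0.578, k = 3,
                      space = small_lr_space(cs = c(1, 100)))
  m <- res$metrics
  expect_equal(nrow(m), 2)
  expect_true(all(m$coverage >= 0 & m$coverage <= 1))
  # MSE = bias^2 + variance (up to the replicate-count variance convention)
  nrep <- m$n_replicates
  expect_equal(m$mse, m$bias^2 + m$hr_sd^2 * (nrep - 1) / nrep,
               tolerance = 1e-8)
  expect_equal(nrow(res$replicates), 8)
  # the log-scale coverage option is accepted and stays a proportion
  res_log <- run_scenario(500, "linear", "correct",
                          strategies = "balance_auc", n_replicates = 3,
                          seed = 30, truth = 0.578, k = 3,
                          space = small_lr_space(cs = 1),
                          coverage_scale = "log")
  expect_true(res_log$metrics$coverage >= 0 && res_log$metrics$coverage <= 1)
})
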