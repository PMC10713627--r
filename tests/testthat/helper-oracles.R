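# Independent reference implementations used as oracles. These deliberately
# use naive per-element loops and their own formulas, not the package's
# vectorized code paths.

# Naive standardized mean differences, one covariate at a time.
naive_smd <- function(x, z, w = NULL) {
  if (is.null(w)) w <- rep(1, length(z))
  vapply(seq_len(ncol(x)), function(j) {
    stat <- function(idx) {
      wi <- w[idx]; xi <- x[idx, j]
      mu <- sum(wi * xi) / sum(wi)
      s2 <- sum(wi) / (sum(wi)^2 - sum(wi^2)) * sum(wi * (xi - mu)^2)
      c(mu, s2)
    }
    a <- stat(which(z == 1)); b <- stat(which(z == 0))
    abs(a[1] - b[1]) / sqrt((a[2] + b[2]) / 2)
  }, numeric(1))
}

# Rank-statistic AUC (Mann-Whitney), independent of pROC.
naive_auc <- function(z, s) {
  r <- rank(s)
  n1 <- sum(z == 1); n0 <- sum(z == 0)
  (sum(r[z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Hand-rolled stabilized weights with pooled winsorization.
naive_weights <- function(ps, z, trim = 0.01) {
  p1 <- mean(z)
  w <- ifelse(z == 1, p1 / ps, (1 - p1) / (1 - ps))
  if (trim > 0) {
    q <- quantile(w, c(trim, 1 - trim), names = FALSE)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  w
}

# Brute-force cross-validated model selection: a literal transcription of the
# selection loop (train on K-1 folds, weights and unbalanced count on the
# whole training data, AUC/loss on the held-out fold, strict-inequality
# winner updates in grid order). Shares only the fold assignment and the
# model-fitting primitive with the package; all diagnostics are the naive
# implementations above.
brute_force_select <- function(x, z, settings, k, seed, trim = 0.01,
                               threshold = 0.1) {
  fold <- ttescreen:::make_folds(z, k, seed)
  n_set <- length(settings)
  mean_nub <- mean_auc <- mean_loss <- numeric(n_set)
  for (si in seq_len(n_set)) {
    nubs <- aucs <- losses <- numeric(k)
    for (fk in seq_len(k)) {
      tr <- fold != fk
      m <- fit_ps(x[tr, , drop = FALSE], z[tr], settings[[si]], seed = seed)
      ps <- predict_ps(m, x)
      w <- naive_weights(ps, z, trim)
      nubs[fk] <- sum(naive_smd(x, z, w) > threshold)
      pv <- ps[!tr]
      aucs[fk] <- naive_auc(z[!tr], pv)
      losses[fk] <- -mean(z[!tr] * log(pv) + (1 - z[!tr]) * log(1 - pv))
    }
    mean_nub[si] <- mean(nubs)
    mean_auc[si] <- mean(aucs)
    mean_loss[si] <- mean(losses)
  }
  pick <- function(strategy) {
    best <- 1L
    for (i in seq_len(n_set)[-1]) {
      better <- switch(strategy,
        balance_auc = mean_nub[i] < mean_nub[best] ||
          (mean_nub[i] == mean_nub[best] && mean_auc[i] > mean_auc[best]),
        val_auc = mean_auc[i] > mean_auc[best],
        val_loss = mean_loss[i] < mean_loss[best])
      if (better) best <- i
    }
    best
  }
  list(n_unbalance = mean_nub, auc = mean_auc, loss = mean_loss,
       balance_auc = pick("balance_auc"), val_auc = pick("val_auc"),
       val_loss = pick("val_loss"))
}

# Product-limit (Kaplan-Meier) survival at a horizon, computed by a direct
# loop over distinct event times.
naive_km_surv <- function(time, event, horizon) {
  s <- 1
  for (tt in sort(unique(time[event == 1 & time <= horizon]))) {
    d <- sum(time == tt & event == 1)
    at_risk <- sum(time >= tt)
    s <- s * (1 - d / at_risk)
  }
  s
}
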