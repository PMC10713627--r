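# Internal helpers shared across modules.

# data.table [] syntax is used inside this package.
.datatable.aware <- TRUE

# Derive a reproducible sub-seed from a top-level seed and a stream name so
# that cohort sampling, CV folds, bootstrap and simulation draws are
# independently reproducible. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Clip probabilities away from {0, 1} so inverse-probability weights stay
# finite under (near-)separation.
clip_prob <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

# Area under the ROC curve for a binary response and a score.
auc_score <- function(z, score) {
  if (length(unique(z)) < 2L) return(NA_real_)
  as.numeric(pROC::auc(response = z, predictor = as.numeric(score),
                       levels = c(0, 1), direction = "<", quiet = TRUE))
}

# Mean binary cross-entropy of predicted probabilities.
bce_loss <- function(z, p) {
  p <- clip_prob(p)
  -mean(z * log(p) + (1 - z) * log(1 - p))
}

# Stratified fold assignment: within each treatment class, subjects are
# shuffled and dealt round-robin, so every fold holds both classes whenever
# each class has at least K members.
make_folds <- function(z, k, seed) {
  stopifnot(k >= 2)
  if (k > length(z)) stop("more folds than subjects")
  set.seed(substream_seed(seed, "folds"))
  fold <- integer(length(z))
  for (cls in unique(z)) {
    idx <- which(z == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Stratified train/test split (default 80:20) by treatment class.
split_train_test <- function(z, test_frac = 0.2, seed) {
  set.seed(substream_seed(seed, "traintest"))
  test <- logical(length(z))
  for (cls in unique(z)) {
    idx <- which(z == cls)
    n_test <- max(1L, round(length(idx) * test_frac))
    test[idx[sample.int(length(idx), n_test)]] <- TRUE
  }
  test
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run manifest written next to machine-readable results; deliberately free
# of timestamps so reruns with the same seed are byte-identical.
write_manifest <- function(path, seed, config) {
  manifest <- list(
    package = "ttescreen",
    version = as.character(utils::packageVersion("ttescreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
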