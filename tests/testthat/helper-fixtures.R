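# Fixtures built in code, shared across test files.

# A tiny, fully hand-checkable event table with one valid target initiator,
# one invalid (single fill) and one comparator initiator.
toy_events <- function() {
  as_event_table(data.frame(
    patient_id = c(rep("A", 6), rep("B", 4), rep("C", 5)),
    date = c(
      0, 400, 500, 545, 900, 2500,      # A: visit, MCI, 2 target fills, AD
      0, 400, 500, 2500,                # B: single target fill
      0, 400, 520, 560, 2500            # C: comparator fills
    ),
    kind = c("DX", "DX", "RX", "RX", "DX", "DX",
             "DX", "DX", "RX", "DX",
             "DX", "DX", "RX", "RX", "DX"),
    code = c("VISIT", "MCI", "RX1", "RX1", "AD", "VISIT",
             "VISIT", "MCI", "RX1", "VISIT",
             "VISIT", "MCI", "RX2", "RX2", "VISIT"),
    stringsAsFactors = FALSE
  ))
}

toy_vocab <- function() {
  vocabulary(
    comorbidity_map = c(DXH = "CAT_HTN", DXH2 = "CAT_HTN", DXD = "CAT_DM"),
    drug_map = c(RX1 = "ING_A", RX2 = "ING_B", RX3 = "ING_C"),
    atc_map = c(ING_A = "ATC1", ING_B = "ATC1", ING_C = "ATC2")
  )
}

toy_demo <- function() {
  data.frame(
    patient_id = c("A", "B", "C"),
    birth_date = c(400L - 70L * 365L, 400L - 70L * 365L, 400L - 70L * 365L),
    sex = c(1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# Small confounded binary-treatment dataset with a known logistic assignment
# model; used for propensity/selection tests.
confounded_trial <- function(n = 500, p = 10, seed = 11) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  eta <- -0.3 + 0.9 * x[, 1] - 0.7 * x[, 2] + 0.4 * x[, 3]
  z <- rbinom(n, 1, plogis(eta))
  # survival outcome with a protective conditional effect and confounding
  haz <- exp(-0.7 * z + 0.5 * x[, 1] + 0.3 * x[, 2]) * 0.02
  t_raw <- rexp(n, haz)
  list(x = x, z = z, time = pmin(t_raw, 100), event = as.integer(t_raw < 100))
}

# A reduced logistic model space (subset of the full grid) for fast tests.
small_lr_space <- function(cs = c(1e-2, 1, 1e2)) {
  settings <- c(
    lapply(cs, function(C) list(family = "LR", penalty = "l2", C = C)),
    list(list(family = "LR", penalty = "none", C = Inf))
  )
  structure(list(family = "LR", settings = settings,
                 labels = vapply(settings, ttescreen:::setting_label,
                                 character(1))),
            class = "ps_model_space")
}

small_ehr <- function(seed = 5, n_patients = 1200, n_ingredients = 25, ...) {
  generate_ehr(ehr_sim_config(n_patients = n_patients,
                              n_ingredients = n_ingredients, seed = seed, ...))
}
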