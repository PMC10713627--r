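test_that("the generator honours count contracts and structural guarantees", {
  sim <- small_ehr(seed = 101, n_patients = 100)
  expect_equal(length(unique(sim$events$patient_id)), 100)
  expect_equal(nrow(sim$demographics), 100)
  ev <- as.data.frame(sim$events)
  # every patient has an MCI diagnosis
  mci_pats <- unique(ev$patient_id[ev$kind == "DX" &
                                     ev$code %in% sim$vocab$mci_codes])
  expect_setequal(mci_pats, sim$demographics$patient_id)
  # fills come in streams: at least some patients have repeat target fills
  # and some have single fills, so the initiation rule is exercisable
  target_rx <- names(sim$vocab$drug_map)[sim$vocab$drug_map == "ING0001"]
  fills <- table(ev$patient_id[ev$kind == "RX" & ev$code == target_rx])
  expect_gt(length(fills), 0)
  expect_true(sum(sim$truth$z_true) > 0)
  expect_true(sum(sim$truth$z_true) < sum(fills >= 1) ||
                all(fills >= 2))
  # the default vocabulary has exactly 64 comorbidity categories
  expect_length(unique(unname(sim$vocab$comorbidity_map)), 64)
  expect_identical(as.data.frame(small_ehr(seed = 101, n_patients = 100)$events),
                   ev)
})

test_that("zero confounding yields balanced arms without weighting", {
  confounder_smd <- function(confounding) {
    sim <- generate_ehr(ehr_sim_config(n_patients = 6000, n_ingredients = 10,
                                       confounding_strength = confounding,
                                       true_log_hr = 0, seed = 7))
    cfg <- run_config(seed = 7, min_treated = 50, n_emulations_per_drug = 2)
    trials <- emulate_drug(sim$events, sim$demographics, sim$vocab, "ING0001",
                           cfg)
    tr <- trials[[1]]
    s <- smd(tr$X, tr$Z)
    # the generator's confounders are the first eight comorbidity categories
    conf_cols <- match(sprintf("como_CAT%02d", 1:8), colnames(tr$X))
    list(conf = mean(s[conf_cols]), all = mean(s[is.finite(s)]))
  }
  s0 <- confounder_smd(0)
  # randomized prescribing: only sampling noise remains anywhere
  expect_lt(s0$conf, 0.06)
  expect_lt(s0$all, 0.05)
  # confounded prescribing imbalances exactly those categories
  expect_gt(confounder_smd(1)$conf, 3 * s0$conf)
})

test_that("a null effect without confounding gives an unadjusted HR near 1", {
  hrs <- vapply(1:3, function(s) {
    sim <- generate_ehr(ehr_sim_config(n_patients = 3000, n_ingredients = 15,
                                       confounding_strength = 0,
                                       true_log_hr = 0, seed = 100 + s))
    cfg <- run_config(seed = s, min_treated = 50, n_emulations_per_drug = 2)
    trials <- emulate_drug(sim$events, sim$demographics, sim$vocab, "ING0001",
                           cfg)
    mean(vapply(trials, function(tr) {
      weighted_cox(tr$Z, tr$Y, tr$T)$log_ahr
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(hrs)), 0.15)
})

test_that("planted edge cases are excluded for the matching reasons and the
           compliant control is retained", {
  sim <- plant_edge_cases(small_ehr(seed = 23, n_patients = 300))
  expect_equal(nrow(sim$truth$planted), 7)
  ev <- sim$events
  demo <- sim$demographics
  vocab <- sim$vocab
  target <- sim$truth$config$target_drug

  # initiation-rule violations never produce an index date
  expect_true(is.na(find_initiation(ev, "EC_SINGLE_FILL", target, vocab)))
  expect_true(is.na(find_initiation(ev, "EC_SHORT_GAP", target, vocab)))

  # eligibility violations fire the named rule at the planted index (day 600)
  idx <- find_initiation(ev, "EC_AGE", target, vocab)
  expect_equal(idx, 600L)
  expect_equal(check_eligibility(ev, demo, "EC_AGE", idx, vocab)$reasons,
               "age")
  expect_true("mci_after_index" %in%
                check_eligibility(ev, demo, "EC_MCI_AFTER", 600L,
                                  vocab)$reasons)
  expect_equal(check_eligibility(ev, demo, "EC_PRIOR_AD", 600L, vocab)$reasons,
               "prior_ad")
  expect_equal(check_eligibility(ev, demo, "EC_HISTORY", 600L, vocab)$reasons,
               "insufficient_history")

  # the compliant patient is a valid, eligible initiator of its control drug
  other <- unname(vocab$drug_map[["RX0002"]])
  idx_ok <- find_initiation(ev, "EC_OK", other, vocab)
  expect_equal(idx_ok, 600L)
  expect_true(check_eligibility(ev, demo, "EC_OK", idx_ok, vocab)$eligible)

  # no violating patient enters any emulated arm
  cfg <- run_config(seed = 23, min_treated = 5, n_emulations_per_drug = 4)
  trials <- emulate_drug(ev, demo, vocab, target, cfg)
  bad <- setdiff(sim$truth$planted$patient_id, "EC_OK")
  for (tr in trials) expect_false(any(bad %in% tr$patient_id))
})

test_that("the synthetic EHR serializes to the standard file set", {
  sim <- small_ehr(seed = 31, n_patients = 60)
  dir <- withr::local_tempdir()
  write_ehr_sim(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "events.csv", "demographics.csv", "comorbidity_map.csv", "drug_map.csv",
    "atc_map.csv", "truth.json")))))
  back <- read_event_table(file.path(dir, "events.csv"))
  expect_identical(as.data.frame(back), as.data.frame(sim$events))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$config$n_patients, 60)
})
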