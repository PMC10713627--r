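test_that("initiation requires a second fill at least 30 days after the first", {
  ev <- as_event_table(data.frame(
    patient_id = "P", date = c(0, 45), kind = "RX", code = "RX1"))
  vocab <- toy_vocab()
  expect_equal(find_initiation(ev, "P", "ING_A", vocab), 0L)
  ev_single <- as_event_table(data.frame(
    patient_id = "P", date = 0, kind = "RX", code = "RX1"))
  expect_true(is.na(find_initiation(ev_single, "P", "ING_A", vocab)))
  ev_short <- as_event_table(data.frame(
    patient_id = "P", date = c(0, 20), kind = "RX", code = "RX1"))
  expect_true(is.na(find_initiation(ev_short, "P", "ING_A", vocab)))
  # a third fill past 30 days rescues an early refill
  ev_three <- as_event_table(data.frame(
    patient_id = "P", date = c(0, 20, 40), kind = "RX", code = "RX1"))
  expect_equal(find_initiation(ev_three, "P", "ING_A", vocab), 0L)
})

test_that("eligibility rules fire individually with named reasons", {
  ev <- toy_events()
  demo <- toy_demo()
  vocab <- toy_vocab()
  # patient A initiates ING_A at day 500: MCI at 400 < 500, 500 days history,
  # age 70, AD only after index
  el <- check_eligibility(ev, demo, "A", 500L, vocab)
  expect_true(el$eligible)
  expect_length(el$reasons, 0)

  # age below 50 at MCI
  demo_young <- demo
  demo_young$birth_date[1] <- 400L - 49L * 365L
  el <- check_eligibility(ev, demo_young, "A", 500L, vocab)
  expect_false(el$eligible)
  expect_equal(el$reasons, "age")

  # index before the first MCI diagnosis
  el <- check_eligibility(ev, demo, "A", 300L, vocab)
  expect_false(el$eligible)
  expect_true("mci_after_index" %in% el$reasons)

  # under one year of history
  el <- check_eligibility(ev, demo, "A", 364L, vocab)
  expect_true("insufficient_history" %in% el$reasons)

  # AD within five years before index
  ev_ad <- as_event_table(rbind(
    as.data.frame(ev),
    data.frame(patient_id = "A", date = 450L, kind = "DX", code = "AD")))
  el <- check_eligibility(ev_ad, demo, "A", 500L, vocab)
  expect_false(el$eligible)
  expect_equal(el$reasons, "prior_ad")
})

test_that("outcomes classify as event, negative, or censored", {
  vocab <- toy_vocab()
  # AD at index + 400 within follow-up
  ev <- as_event_table(data.frame(
    patient_id = "P",
    date = c(0, 100, 500, 2500),
    kind = c("DX", "RX", "DX", "DX"),
    code = c("MCI", "RX1", "AD", "VISIT")))
  out <- classify_outcome(ev, "P", 100L, 1825L, vocab)
  expect_equal(out, list(y = 1L, t = 400L))
  # no AD, data extends past follow-up: negative at the full horizon
  ev2 <- as_event_table(data.frame(
    patient_id = "P", date = c(0, 100, 2100), kind = c("DX", "RX", "DX"),
    code = c("MCI", "RX1", "VISIT")))
  expect_equal(classify_outcome(ev2, "P", 100L, 1825L, vocab),
               list(y = 0L, t = 1825L))
  # no AD, last RX at index+300, last DX at index+500: censored at 500
  ev3 <- as_event_table(data.frame(
    patient_id = "P", date = c(0, 100, 400, 600), kind = c("DX", "RX", "RX", "DX"),
    code = c("MCI", "RX1", "RX1", "DXH")))
  expect_equal(classify_outcome(ev3, "P", 100L, 1825L, vocab),
               list(y = 0L, t = 500L))
  # an AD diagnosis before the index does not count as an outcome event;
  # patient A (AD at day 900) indexed at 1000 is censored at the last record
  expect_equal(classify_outcome(toy_events(), "A", 1000L, 1825L, vocab),
               list(y = 0L, t = 1500L))
})

test_that("the default covariate schema has 267 slots in the stated order", {
  sim <- small_ehr()
  schema <- build_covariate_schema(sim$events, sim$vocab)
  expect_length(schema$names, 267)
  expect_equal(schema$names[1:2], c("age", "gender"))
  expect_equal(schema$names[267], "mci_lag")
  expect_length(schema$categories, 64)
  expect_length(schema$medications, 200)
  expect_false(schema$is_binary[1])
  expect_false(schema$is_binary[267])
  expect_true(all(schema$is_binary[2:266]))
})

test_that("hand-built toy covariates hit exactly the mapped indicators", {
  vocab <- toy_vocab()
  ev <- as_event_table(data.frame(
    patient_id = "P",
    date = c(0, 10, 20, 30, 200, 400, 410, 2400),
    kind = c("DX", "DX", "DX", "RX", "DX", "RX", "RX", "DX"),
    code = c("MCI", "DXH", "DXH2", "RX2", "UNMAPPED", "RX1", "RX1", "VISIT")))
  demo <- data.frame(patient_id = "P", birth_date = -73 * 365L, sex = 1L)
  schema <- build_covariate_schema(ev, vocab)
  # toy vocabulary: 2 comorbidity categories, so 2 + 2 + 200 + 1 slots
  expect_length(v <- build_covariates(ev, demo, "P", 400L, schema, vocab), 205)
  # two DXH* codes collapse into one category; RX2 -> ING_B used pre-index;
  # the unmapped DX code is ignored
  como_on <- names(v)[v == 1 & grepl("^como_", names(v))]
  med_on <- names(v)[v == 1 & grepl("^med_", names(v))]
  expect_equal(como_on, "como_CAT_HTN")
  expect_equal(med_on, "med_ING_B")
  expect_equal(sum(v[grepl("^como_|^med_", names(v))]), 2)
  expect_equal(unname(v["age"]), (400 + 73 * 365) / 365.25)
  expect_equal(unname(v["mci_lag"]), 400)
  expect_equal(unname(v["gender"]), 1)
})

test_that("covariates never use information on or after the index date", {
  vocab <- toy_vocab()
  base <- data.frame(
    patient_id = "P",
    date = c(0, 50, 100, 400, 500, 700, 2400),
    kind = c("DX", "DX", "RX", "DX", "RX", "DX", "DX"),
    code = c("MCI", "DXH", "RX2", "DXD", "RX1", "DXH", "VISIT"))
  demo <- data.frame(patient_id = "P", birth_date = -70 * 365L, sex = 0L)
  schema <- build_covariate_schema(as_event_table(base), vocab)
  v1 <- build_covariates(as_event_table(base), demo, "P", 500L, schema, vocab)
  shifted <- base
  shifted$date[shifted$date >= 500] <- shifted$date[shifted$date >= 500] + 100
  v2 <- build_covariates(as_event_table(shifted), demo, "P", 500L, schema,
                         vocab)
  expect_identical(v1, v2)
  # the index-day fill itself is not medication history
  expect_equal(unname(v1["med_ING_A"]), 0)
})

test_that("emulation respects arm disjointness, control modes and skip rules", {
  sim <- small_ehr(seed = 19)
  cfg <- run_config(seed = 19, min_treated = 40, n_emulations_per_drug = 6)
  trials <- emulate_drug(sim$events, sim$demographics, sim$vocab, "ING0001",
                         cfg)
  expect_gt(length(trials), 0)
  modes <- vapply(trials, function(t) t$meta$control_mode, character(1))
  expect_lte(sum(modes == "random"), 3)
  expect_lte(sum(modes == "atc"), 3)
  for (tr in trials) {
    expect_false(any(tr$patient_id[tr$Z == 1] %in% tr$patient_id[tr$Z == 0]))
    expect_equal(ncol(tr$X), 267)
    expect_true(all(tr$Y %in% 0:1))
    expect_true(all(tr$T >= 0))
    expect_true(all(tr$T[tr$Y == 1] <= cfg$follow_up_days))
    # ATC comparators share the target's therapeutic class
    if (tr$meta$control_mode == "atc") {
      expect_equal(unname(sim$vocab$atc_map[tr$meta$control_drug]),
                   unname(sim$vocab$atc_map["ING0001"]))
    }
    expect_false(tr$meta$control_drug == "ING0001")
  }
  # a drug with fewer treated than min_treated is skipped with a message
  cfg_strict <- run_config(seed = 19, min_treated = 100000)
  expect_message(
    skipped <- emulate_drug(sim$events, sim$demographics, sim$vocab,
                            "ING0001", cfg_strict),
    "skipped")
  expect_length(skipped, 0)
  expect_equal(attr(skipped, "reason"), "insufficient_treated")
})

test_that("trial datasets round-trip through their disk format", {
  sim <- small_ehr(seed = 19)
  cfg <- run_config(seed = 19, min_treated = 40, n_emulations_per_drug = 2)
  trials <- emulate_drug(sim$events, sim$demographics, sim$vocab, "ING0001",
                         cfg)
  prefix <- file.path(withr::local_tempdir(), "trial")
  write_trial_dataset(trials[[1]], prefix)
  x_back <- as.matrix(read.csv(paste0(prefix, "_X.csv")))
  o_back <- read.csv(paste0(prefix, "_outcomes.csv"),
                     colClasses = c(patient_id = "character"))
  expect_equal(unname(x_back), unname(trials[[1]]$X), tolerance = 1e-8)
  expect_equal(o_back$Z, trials[[1]]$Z)
  expect_equal(o_back$T, trials[[1]]$T)
  expect_equal(o_back$patient_id, trials[[1]]$patient_id)
})
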