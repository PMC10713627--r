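# Synthetic longitudinal EHR generator with known ground truth.
#
# Emulates the structure the cohort pipeline consumes: every patient has an
# MCI diagnosis, comorbidity diagnosis events drawn from 64 categories, drug
# prescription streams with repeat fills (so the two-fills-30-days-apart
# initiation rule sees both passing and failing patients), and AD outcome
# events drawn from an exponential proportional-hazards model whose treatment
# coefficient and confounding strength are configurable and recorded in a
# truth record. Comorbidity burden raises both the odds of receiving the
# target drug and the AD hazard, creating genuine confounding.

#' Configuration of the synthetic EHR generator
#'
#' @param n_patients number of patients.
#' @param n_ingredients number of drug ingredients in the catalog (the first
#'   is the default target); ingredients are grouped ten-per-ATC-L2-class.
#' @param n_comorbidity_codes number of diagnosis codes, mapped round-robin
#'   onto the 64 comorbidity categories.
#' @param target_drug ingredient id of the drug under study.
#' @param true_log_hr log hazard ratio of the target drug on the outcome.
#' @param confounding_strength common effect of the confounding comorbidities
#'   on both prescription log-odds and outcome log-hazard (0 = randomized).
#' @param baseline_hazard outcome hazard per day at zero covariates.
#' @param enrollment_span days over which first records are spread.
#' @param seed integer seed.
#' @return an `ehr_sim_config` list.
#' @export
ehr_sim_config <- function(n_patients = 4000,
                           n_ingredients = 250,
                           n_comorbidity_codes = 128,
                           target_drug = "ING0001",
                           true_log_hr = log(0.6),
                           confounding_strength = 0.5,
                           baseline_hazard = 1e-4,
                           enrollment_span = 1500,
                           seed = 1L) {
  stopifnot(n_patients > 0, n_ingredients > 1, n_comorbidity_codes >= 64,
            baseline_hazard > 0, enrollment_span > 0)
  structure(list(
    n_patients = as.integer(n_patients),
    n_ingredients = as.integer(n_ingredients),
    n_comorbidity_codes = as.integer(n_comorbidity_codes),
    target_drug = target_drug,
    true_log_hr = true_log_hr,
    confounding_strength = confounding_strength,
    baseline_hazard = baseline_hazard,
    enrollment_span = as.integer(enrollment_span),
    seed = as.integer(seed)
  ), class = "ehr_sim_config")
}

N_COMORBIDITY_CATEGORIES <- 64L
N_CONFOUNDER_CATEGORIES <- 8L  # categories that drive treatment and outcome

# Default vocabulary implied by a generator config: diagnosis codes map
# round-robin onto the 64 categories; drug codes map one-to-one onto
# ingredients; ingredients group ten-per-ATC-L2 class.
ehr_sim_vocabulary <- function(config) {
  dx_codes <- sprintf("DX%04d", seq_len(config$n_comorbidity_codes))
  categories <- sprintf("CAT%02d",
                        ((seq_len(config$n_comorbidity_codes) - 1L) %%
                           N_COMORBIDITY_CATEGORIES) + 1L)
  ingredients <- sprintf("ING%04d", seq_len(config$n_ingredients))
  rx_codes <- sprintf("RX%04d", seq_len(config$n_ingredients))
  atc <- sprintf("ATC%02d", ((seq_len(config$n_ingredients) - 1L) %/% 10L) + 1L)
  vocabulary(
    comorbidity_map = stats::setNames(categories, dx_codes),
    drug_map = stats::setNames(ingredients, rx_codes),
    atc_map = stats::setNames(atc, ingredients)
  )
}

# Fill dates for one prescription stream: n_fills fills starting at `start`,
# with geometric-plus-offset inter-fill gaps so the 30-day initiation rule is
# sometimes met and sometimes not.
stream_fill_dates <- function(start, n_fills) {
  if (n_fills == 1L) return(start)
  gaps <- 10L + rgeom(n_fills - 1L, 1 / 25)
  start + c(0L, cumsum(gaps))
}

#' Generate a synthetic longitudinal EHR
#'
#' @param config an [ehr_sim_config()].
#' @return an `ehr_sim` list with `events` (an `event_table`), `demographics`,
#'   `vocab` (a [vocabulary()]) and `truth` (generating parameters, each
#'   patient's true exposure, confounder score and outcome anchor).
#' @export
generate_ehr <- function(config = ehr_sim_config()) {
  stopifnot(inherits(config, "ehr_sim_config"))
  n <- config$n_patients
  vocab <- ehr_sim_vocabulary(config)
  ids <- sprintf("P%05d", seq_len(n))
  ingredients <- unname(vocab$drug_map)
  rx_code_of <- stats::setNames(names(vocab$drug_map), ingredients)
  dx_codes_of_cat <- split(names(vocab$comorbidity_map),
                           vocab$comorbidity_map)
  set.seed(substream_seed(config$seed, "ehr_population"))
  cat_prev <- runif(N_COMORBIDITY_CATEGORIES, 0.05, 0.25)
  ing_pop <- 1 / seq_len(config$n_ingredients)  # popularity weights

  set.seed(substream_seed(config$seed, "ehr_patients"))
  first_rec <- sample.int(config$enrollment_span, n, replace = TRUE)
  mci_date <- first_rec + sample(365:1000, n, replace = TRUE)
  age_mci <- pmin(pmax(round(rnorm(n, 72, 8)), 45), 95)
  birth_date <- mci_date - age_mci * 365L - sample(0:364, n, replace = TRUE)
  sex <- rbinom(n, 1, 0.55)

  # Baseline comorbidity indicators and the confounder score on the first
  # eight categories.
  como <- matrix(rbinom(n * N_COMORBIDITY_CATEGORIES, 1,
                        rep(cat_prev, each = n)),
                 nrow = n)
  conf_score <- rowSums(como[, seq_len(N_CONFOUNDER_CATEGORIES), drop = FALSE])
  conf_centered <- config$confounding_strength *
    (conf_score - sum(cat_prev[seq_len(N_CONFOUNDER_CATEGORIES)]))

  # Target-drug exposure: confounded prescription odds, then fill streams.
  p_rx <- plogis(qlogis(0.12) + conf_centered)
  prescribed <- rbinom(n, 1, p_rx) == 1L
  target_index <- mci_date + sample(30:365, n, replace = TRUE)
  target_fill_counts <- pmin(1L + rgeom(n, 0.35), 8L)

  # Non-target prescription streams (history and potential comparator
  # initiations), independent of the confounders.
  n_other <- 1L + rpois(n, 3)
  other_ing <- lapply(seq_len(n), function(i) {
    k <- min(n_other[i], config$n_ingredients - 1L)
    1L + sample.int(config$n_ingredients - 1L, k, prob = ing_pop[-1])
  })

  events <- vector("list", 8L)
  # first-record and comorbidity DX events
  events[[1]] <- data.frame(patient_id = ids, date = first_rec, kind = "DX",
                            code = "VISIT", stringsAsFactors = FALSE)
  which_como <- which(como == 1L, arr.ind = TRUE)
  como_codes <- vapply(sprintf("CAT%02d", which_como[, 2]), function(cat) {
    codes <- dx_codes_of_cat[[cat]]
    codes[sample.int(length(codes), 1L)]
  }, character(1), USE.NAMES = FALSE)
  como_pat <- which_como[, 1]
  events[[2]] <- data.frame(
    patient_id = ids[como_pat],
    date = first_rec[como_pat] +
      floor(runif(nrow(which_como)) * pmax(mci_date - first_rec, 1L)[como_pat]),
    kind = "DX", code = como_codes, stringsAsFactors = FALSE
  )
  events[[3]] <- data.frame(patient_id = ids, date = mci_date, kind = "DX",
                            code = vocab$mci_codes[1], stringsAsFactors = FALSE)

  # target drug fills
  rx_rows <- lapply(which(prescribed), function(i) {
    dates <- stream_fill_dates(target_index[i], target_fill_counts[i])
    data.frame(patient_id = ids[i], date = dates, kind = "RX",
               code = rx_code_of[[config$target_drug]],
               stringsAsFactors = FALSE)
  })
  events[[4]] <- do.call(rbind, rx_rows)

  # other drug streams
  other_rows <- lapply(seq_len(n), function(i) {
    ings <- other_ing[[i]]
    if (!length(ings)) return(NULL)
    starts <- mci_date[i] - 200L +
      sample.int(565L, length(ings), replace = TRUE)  # in [mci-199, mci+365]
    starts <- pmax(starts, first_rec[i])
    fills <- pmin(1L + rgeom(length(ings), 0.35), 8L)
    do.call(rbind, lapply(seq_along(ings), function(j) {
      data.frame(patient_id = ids[i],
                 date = stream_fill_dates(starts[j], fills[j]),
                 kind = "RX", code = rx_code_of[[ingredients[ings[j]]]],
                 stringsAsFactors = FALSE)
    }))
  })
  events[[5]] <- do.call(rbind, other_rows)

  # True exposure = valid initiation of the target drug (a later fill at
  # least 30 days after the first), derived from the emitted fill rows.
  tf <- events[[4]]
  if (!is.null(tf)) {
    valid <- tapply(tf$date, tf$patient_id, function(d) any(d >= min(d) + 30L))
    valid_target <- ids %in% names(which(valid))
  } else {
    valid_target <- rep(FALSE, n)
  }

  # Outcome anchor: the target index for the exposed, otherwise the patient's
  # earliest post-MCI alternative initiation, otherwise six months after MCI.
  t0 <- mci_date + 180L
  if (!is.null(events[[5]])) {
    ot <- events[[5]]
    ot$ing <- unname(vocab$drug_map[ot$code])
    key <- paste(ot$patient_id, ot$ing)
    first_fill <- tapply(ot$date, key, min)
    ok_init <- tapply(ot$date, key, function(d) any(d >= min(d) + 30L))
    pat_of_key <- sub(" .*$", "", names(first_fill))
    init_ok <- ok_init & first_fill > mci_date[match(pat_of_key, ids)]
    if (any(init_ok)) {
      alt <- tapply(first_fill[init_ok], pat_of_key[init_ok], min)
      hit <- match(names(alt), ids)
      t0[hit] <- as.integer(alt)
    }
  }
  t0[valid_target] <- target_index[valid_target]

  # AD outcome from an exponential proportional-hazards model.
  set.seed(substream_seed(config$seed, "ehr_outcome"))
  lambda <- config$baseline_hazard *
    exp(config$true_log_hr * valid_target + conf_centered)
  ad_gap <- rexp(n, lambda)
  end_of_data <- t0 + sample(1400:2600, n, replace = TRUE)
  has_ad <- (t0 + ad_gap) <= end_of_data
  events[[6]] <- data.frame(
    patient_id = ids[has_ad],
    date = as.integer(floor(t0[has_ad] + ad_gap[has_ad])),
    kind = "DX", code = vocab$ad_codes[1], stringsAsFactors = FALSE
  )
  events[[7]] <- data.frame(patient_id = ids, date = end_of_data, kind = "DX",
                            code = "VISIT", stringsAsFactors = FALSE)

  ev <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  ev <- ev[order(ev$patient_id, ev$date, ev$kind, ev$code), ]
  rownames(ev) <- NULL
  demo <- data.frame(patient_id = ids, birth_date = birth_date, sex = sex,
                     stringsAsFactors = FALSE)
  structure(list(
    events = as_event_table(ev),
    demographics = demo,
    vocab = vocab,
    truth = list(
      config = unclass(config),
      z_true = stats::setNames(valid_target, ids),
      confounder_score = stats::setNames(conf_score, ids),
      outcome_anchor = stats::setNames(t0, ids),
      planted = NULL
    )
  ), class = "ehr_sim")
}

#' Append labeled eligibility edge-case patients
#'
#' Adds one constructed patient per eligibility rule violation (age below 50
#' at MCI, MCI after index, AD within five years before index, under 365
#' days of history, single fill, second fill under 30 days) plus one fully
#' eligible comparator patient, and records the labels in the truth record.
#' Cohort construction must exclude each violating patient for the matching
#' reason and retain the compliant one.
#'
#' @param sim an `ehr_sim` from [generate_ehr()].
#' @return the `ehr_sim` with appended patients and `truth$planted` set to a
#'   data frame of `patient_id`, `violation`.
#' @export
plant_edge_cases <- function(sim) {
  stopifnot(inherits(sim, "ehr_sim"))
  vocab <- sim$vocab
  target_rx <- names(vocab$drug_map)[match(sim$truth$config$target_drug,
                                           vocab$drug_map)]
  other_rx <- names(vocab$drug_map)[match(sim$truth$config$target_drug,
                                          vocab$drug_map) %% length(vocab$drug_map) + 1L]
  mci <- vocab$mci_codes[1]
  ad <- vocab$ad_codes[1]

  # template: first record day 100, MCI day 500, index day 600, fills 600/645
  mk <- function(id, rows, age = 70L) {
    rows$patient_id <- id
    list(events = rows[, c("patient_id", "date", "kind", "code")],
         demo = data.frame(patient_id = id,
                           birth_date = 500L - age * 365L, sex = 1L,
                           stringsAsFactors = FALSE))
  }
  base_rows <- function(drug = target_rx, fills = c(600L, 645L),
                        mci_day = 500L, first = 100L, extra = NULL) {
    rbind(
      data.frame(date = first, kind = "DX", code = "VISIT"),
      data.frame(date = mci_day, kind = "DX", code = mci),
      data.frame(date = fills, kind = "RX", code = drug),
      data.frame(date = 2700L, kind = "DX", code = "VISIT"),
      extra
    )
  }
  cases <- list(
    age = mk("EC_AGE", base_rows(), age = 49L),
    mci_after_index = mk("EC_MCI_AFTER", base_rows(mci_day = 700L)),
    prior_ad = mk("EC_PRIOR_AD", base_rows(
      extra = data.frame(date = 600L - 1095L, kind = "DX", code = ad))),
    history = mk("EC_HISTORY", base_rows(first = 400L, mci_day = 450L)),
    single_fill = mk("EC_SINGLE_FILL", base_rows(fills = 600L)),
    short_gap = mk("EC_SHORT_GAP", base_rows(fills = c(600L, 620L))),
    compliant_control = mk("EC_OK", base_rows(drug = other_rx))
  )
  new_events <- do.call(rbind, lapply(cases, `[[`, "events"))
  new_demo <- do.call(rbind, lapply(cases, `[[`, "demo"))
  rownames(new_events) <- rownames(new_demo) <- NULL
  sim$events <- as_event_table(rbind(as.data.frame(sim$events), new_events))
  sim$demographics <- rbind(sim$demographics, new_demo)
  sim$truth$planted <- data.frame(
    patient_id = vapply(cases, function(cs) cs$demo$patient_id, character(1)),
    violation = names(cases),
    stringsAsFactors = FALSE
  )
  rownames(sim$truth$planted) <- NULL
  sim
}

#' Write a synthetic EHR to disk
#'
#' Emits the standard event-table and vocabulary CSVs, the demographics CSV
#' and the truth record as JSON.
#'
#' @param sim an `ehr_sim`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_ehr_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "ehr_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_event_table(sim$events, file.path(dir, "events.csv"))
  write_demographics(sim$demographics, file.path(dir, "demographics.csv"))
  write_vocabulary(sim$vocab,
                   file.path(dir, "comorbidity_map.csv"),
                   file.path(dir, "drug_map.csv"),
                   file.path(dir, "atc_map.csv"))
  truth <- sim$truth
  truth$z_true <- as.list(truth$z_true)
  truth$confounder_score <- as.list(truth$confounder_score)
  truth$outcome_anchor <- as.list(truth$outcome_anchor)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
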