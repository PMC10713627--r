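# Target-trial cohort construction: new-user initiation, eligibility,
# outcomes, baseline covariates and the high-throughput emulation driver.

utils::globalVariables(c("kind", "code", "date", "patient_id", "ingredient",
                         "first_fill", "valid", ".", "category", "idx", "n",
                         "ad_date"))

# Prescription events annotated with their ingredient; unmapped drug codes
# are dropped (their count is reported via attribute, not an error).
rx_with_ingredient <- function(events, vocab) {
  rx <- data.table::as.data.table(events)[kind == "RX"]
  rx[, ingredient := unname(vocab$drug_map[code])]
  n_unmapped <- sum(is.na(rx$ingredient))
  rx <- rx[!is.na(ingredient)]
  data.table::setattr(rx, "n_unmapped", n_unmapped)
  rx
}

# Initiation table over all (patient, ingredient) streams: first fill date
# and whether a later fill occurs at least 30 days after it.
initiation_table <- function(events, vocab) {
  rx <- rx_with_ingredient(events, vocab)
  if (nrow(rx) == 0) {
    return(data.frame(patient_id = character(0), ingredient = character(0),
                      first_fill = integer(0), valid = logical(0)))
  }
  out <- rx[, .(first_fill = min(date), valid = any(date >= min(date) + 30L)),
            by = .(patient_id, ingredient)]
  data.table::setDF(out)  # plain data.frame: callers subset with base idioms
  out
}

#' Find a patient's valid initiation date of an ingredient
#'
#' The index date is the first prescription date of the ingredient, valid
#' only if at least one later fill of the same ingredient occurs 30 or more
#' days after it (the new-user two-fill rule).
#'
#' @param events an `event_table`.
#' @param patient patient id.
#' @param ingredient ingredient id.
#' @param vocab a [vocabulary()].
#' @return the index date (integer day) or `NA` when initiation is invalid.
#' @export
find_initiation <- function(events, patient, ingredient, vocab) {
  rx <- events[events$kind == "RX" & events$patient_id == patient, ]
  dates <- rx$date[!is.na(vocab$drug_map[rx$code]) &
                     vocab$drug_map[rx$code] == ingredient]
  if (length(dates) < 2L) return(NA_integer_)
  d1 <- min(dates)
  if (any(dates >= d1 + 30L)) d1 else NA_integer_
}

# Per-patient record summaries used by eligibility and outcomes.
patient_summaries <- function(events, vocab) {
  ev <- data.table::as.data.table(events)
  rec <- ev[, .(first_record = min(date), last_record = max(date)),
            by = patient_id]
  mci <- ev[kind == "DX" & code %in% vocab$mci_codes,
            .(first_mci = min(date)), by = patient_id]
  ad <- ev[kind == "DX" & code %in% vocab$ad_codes,
           .(patient_id, ad_date = date)]
  list(rec = data.table::setDF(rec), mci = data.table::setDF(mci),
       ad = data.table::setDF(ad))
}

# Vectorized eligibility over a cohort of (patient, index_date) pairs.
# Rules: has an MCI diagnosis; age at first MCI >= 50; first MCI strictly
# before index; at least 365 days from first record to index; no AD diagnosis
# in the five years (1825 days) before index.
eligibility_flags <- function(cohort, summaries, demo, config = run_config()) {
  n <- nrow(cohort)
  rec <- summaries$rec[match(cohort$patient_id, summaries$rec$patient_id), ,
                       drop = FALSE]
  mci_first <- summaries$mci$first_mci[match(cohort$patient_id,
                                             summaries$mci$patient_id)]
  birth <- demo$birth_date[match(cohort$patient_id, demo$patient_id)]
  reasons <- vector("list", n)
  has_mci <- !is.na(mci_first)
  age_mci <- (mci_first - birth) / 365.25
  ok_age <- has_mci & !is.na(birth) & age_mci >= 50
  ok_order <- has_mci & mci_first < cohort$index_date
  ok_history <- !is.na(rec$first_record) &
    (cohort$index_date - rec$first_record) >= 365L
  # prior AD within [index - 1825, index)
  ad <- summaries$ad
  prior_ad <- logical(n)
  if (nrow(ad) > 0) {
    idx_by_pat <- split(seq_len(n), cohort$patient_id)
    ad_by_pat <- split(ad$ad_date, ad$patient_id)
    for (pid in intersect(names(idx_by_pat), names(ad_by_pat))) {
      for (i in idx_by_pat[[pid]]) {
        idx <- cohort$index_date[i]
        prior_ad[i] <- any(ad_by_pat[[pid]] >= idx - 1825L &
                             ad_by_pat[[pid]] < idx)
      }
    }
  }
  for (i in seq_len(n)) {
    r <- character(0)
    if (!has_mci[i]) r <- c(r, "no_mci")
    if (has_mci[i] && !ok_age[i]) r <- c(r, "age")
    if (has_mci[i] && !ok_order[i]) r <- c(r, "mci_after_index")
    if (!ok_history[i]) r <- c(r, "insufficient_history")
    if (prior_ad[i]) r <- c(r, "prior_ad")
    reasons[[i]] <- r
  }
  list(eligible = lengths(reasons) == 0L, reasons = reasons)
}

#' Check a patient's trial eligibility at an index date
#'
#' @param events an `event_table`.
#' @param demo demographics table (see [read_demographics()]).
#' @param patient patient id.
#' @param index_date candidate index date (integer day), typically from
#'   [find_initiation()].
#' @param vocab a [vocabulary()].
#' @param config run configuration.
#' @return list with `eligible` flag and `reasons`, a character vector naming
#'   every failed rule (`no_mci`, `age`, `mci_after_index`,
#'   `insufficient_history`, `prior_ad`).
#' @export
check_eligibility <- function(events, demo, patient, index_date, vocab,
                              config = run_config()) {
  cohort <- data.frame(patient_id = patient, index_date = index_date,
                       stringsAsFactors = FALSE)
  flags <- eligibility_flags(cohort, patient_summaries(events, vocab), demo,
                             config)
  list(eligible = flags$eligible[1], reasons = flags$reasons[[1]])
}

# Vectorized outcome classification.
outcome_flags <- function(cohort, events, vocab, follow_up_days) {
  ev <- data.table::as.data.table(events)
  last_rec <- ev[, .(last_record = max(date)), by = patient_id]
  ad <- ev[kind == "DX" & code %in% vocab$ad_codes]
  n <- nrow(cohort)
  y <- integer(n)
  t <- integer(n)
  last <- last_rec$last_record[match(cohort$patient_id, last_rec$patient_id)]
  ad_by_pat <- split(ad$date, ad$patient_id)
  for (i in seq_len(n)) {
    idx <- cohort$index_date[i]
    horizon <- idx + follow_up_days
    ad_dates <- ad_by_pat[[cohort$patient_id[i]]]
    hit <- ad_dates[ad_dates > idx & ad_dates <= horizon]
    if (length(hit)) {
      y[i] <- 1L
      t[i] <- min(hit) - idx
    } else if (!is.na(last[i]) && last[i] >= horizon) {
      y[i] <- 0L
      t[i] <- follow_up_days
    } else {
      y[i] <- 0L
      t[i] <- max(0L, (if (is.na(last[i])) idx else last[i]) - idx)
    }
  }
  list(y = y, t = t)
}

#' Classify a patient's outcome over the follow-up window
#'
#' The first AD diagnosis strictly after the index date and within the
#' follow-up window is a positive event with time measured from index.
#' Without such a diagnosis, a patient whose end of data (last diagnosis or
#' prescription date, whichever is later) reaches the end of follow-up is a
#' negative event at the full follow-up time; otherwise the patient is
#' censored at the end of data.
#'
#' @inheritParams check_eligibility
#' @param follow_up_days follow-up horizon in days.
#' @return list with outcome indicator `y` and days `t`.
#' @export
classify_outcome <- function(events, patient, index_date, follow_up_days,
                             vocab) {
  cohort <- data.frame(patient_id = patient, index_date = index_date,
                       stringsAsFactors = FALSE)
  out <- outcome_flags(cohort, events, vocab, follow_up_days)
  list(y = out$y[1], t = out$t[1])
}

#' Build the default covariate schema from a study population
#'
#' Ordered covariate names: age, gender, one indicator per comorbidity
#' category (64 under the default vocabulary), one indicator per
#' most-prevalent prescribed ingredient (200 slots; prevalence is the number
#' of distinct patients ever prescribed the ingredient, computed once over
#' the full population and frozen so covariates mean the same thing in every
#' emulation of a dataset), and the MCI-to-index time lag. With the default
#' 64-category vocabulary the schema has 1 + 1 + 64 + 200 + 1 = 267 entries.
#'
#' @param events an `event_table` for the full study population.
#' @param vocab a [vocabulary()].
#' @param n_medications number of medication-history slots (default 200;
#'   slots beyond the catalog are kept as all-zero placeholders so the
#'   schema length is stable).
#' @return a `covariate_schema` with `names`, `categories`, `medications` and
#'   logical `is_binary`.
#' @export
build_covariate_schema <- function(events, vocab, n_medications = 200L) {
  categories <- sort(unique(unname(vocab$comorbidity_map)))
  rx <- rx_with_ingredient(events, vocab)
  prev <- if (nrow(rx)) {
    counts <- rx[, .(n = data.table::uniqueN(patient_id)), by = ingredient]
    counts[order(-n, ingredient)]$ingredient
  } else character(0)
  meds <- head(prev, n_medications)
  if (length(meds) < n_medications) {
    meds <- c(meds, sprintf("unused_med_%03d",
                            seq_len(n_medications - length(meds))))
  }
  nm <- c("age", "gender", paste0("como_", categories), paste0("med_", meds),
          "mci_lag")
  structure(list(
    names = nm,
    categories = categories,
    medications = meds,
    n_medications = as.integer(n_medications),
    is_binary = c(FALSE, TRUE, rep(TRUE, length(categories)),
                  rep(TRUE, n_medications), FALSE)
  ), class = "covariate_schema")
}

# Vectorized baseline covariate matrix for a cohort of (patient, index) pairs.
# Indicators use any occurrence strictly before the index date; age (years at
# index) and MCI-to-index lag (days) are continuous.
covariate_matrix <- function(cohort, events, demo, schema, vocab) {
  n <- nrow(cohort)
  d <- length(schema$names)
  x <- matrix(0, nrow = n, ncol = d, dimnames = list(NULL, schema$names))
  ev <- data.table::as.data.table(events)
  ev <- ev[patient_id %in% cohort$patient_id]
  ev[, idx := cohort$index_date[match(patient_id, cohort$patient_id)]]
  pre <- ev[date < idx]

  dx <- pre[kind == "DX"]
  dx[, category := unname(vocab$comorbidity_map[code])]
  dx <- unique(dx[!is.na(category), .(patient_id, category)])
  ci <- match(dx$category, schema$categories)
  ri <- match(dx$patient_id, cohort$patient_id)
  keep <- !is.na(ci)
  x[cbind(ri[keep], 2L + ci[keep])] <- 1

  rx <- pre[kind == "RX"]
  rx[, ingredient := unname(vocab$drug_map[code])]
  rx <- unique(rx[!is.na(ingredient), .(patient_id, ingredient)])
  mi <- match(rx$ingredient, schema$medications)
  ri <- match(rx$patient_id, cohort$patient_id)
  keep <- !is.na(mi)
  med_offset <- 2L + length(schema$categories)
  x[cbind(ri[keep], med_offset + mi[keep])] <- 1

  birth <- demo$birth_date[match(cohort$patient_id, demo$patient_id)]
  sex <- demo$sex[match(cohort$patient_id, demo$patient_id)]
  mci <- data.table::as.data.table(events)[kind == "DX" &
                                             code %in% vocab$mci_codes,
                                           .(first_mci = min(date)),
                                           by = patient_id]
  first_mci <- mci$first_mci[match(cohort$patient_id, mci$patient_id)]
  x[, 1] <- (cohort$index_date - birth) / 365.25
  x[, 2] <- sex
  x[, d] <- cohort$index_date - first_mci
  x
}

#' Baseline covariate vector for one patient
#'
#' Age at index (years) and MCI-to-index lag (days) are continuous; gender,
#' comorbidity-category and medication-history entries are 0/1 indicators of
#' any occurrence strictly before the index date. Codes absent from the
#' vocabulary maps are ignored.
#'
#' @inheritParams check_eligibility
#' @param schema a [build_covariate_schema()].
#' @return named numeric vector of length `length(schema$names)` (267 under
#'   the default schema).
#' @export
build_covariates <- function(events, demo, patient, index_date, schema, vocab) {
  cohort <- data.frame(patient_id = patient, index_date = index_date,
                       stringsAsFactors = FALSE)
  covariate_matrix(cohort, events, demo, schema, vocab)[1, ]
}

# Construct one emulated trial dataset from treated/control cohorts.
make_trial <- function(treated, control, events, demo, schema, vocab, config,
                       meta) {
  cohort <- rbind(treated, control)
  x <- covariate_matrix(cohort, events, demo, schema, vocab)
  out <- outcome_flags(cohort, events, vocab, config$follow_up_days)
  structure(list(
    X = x,
    Z = c(rep(1L, nrow(treated)), rep(0L, nrow(control))),
    Y = out$y,
    T = out$t,
    patient_id = cohort$patient_id,
    meta = meta
  ), class = "trial_dataset")
}

# All eligible initiators of one ingredient.
eligible_initiators <- function(ingredient, inits, summaries, demo, config) {
  cand <- inits[inits$ingredient == ingredient & inits$valid, ]
  if (nrow(cand) == 0) {
    return(data.frame(patient_id = character(0), index_date = integer(0)))
  }
  cohort <- data.frame(patient_id = cand$patient_id,
                       index_date = cand$first_fill,
                       stringsAsFactors = FALSE)
  flags <- eligibility_flags(cohort, summaries, demo, config)
  cohort[flags$eligible, , drop = FALSE]
}

#' Emulate trials for one target drug
#'
#' Builds the treated arm from eligible valid initiators of the target drug,
#' then emulates up to `n_emulations_per_drug` trials: half against random
#' comparator drugs (eligible initiators of one sampled non-target
#' ingredient) and half against active comparators sampled from the target's
#' ATC level-2 class. Comparison arms exclude anyone in the treated arm or
#' with any target-drug prescription before their own index date. Comparator
#' ingredients are sampled without replacement across a mode's emulations
#' while the catalog allows, with replacement afterwards.
#'
#' @param events an `event_table` for the study population.
#' @param demo demographics table.
#' @param vocab a [vocabulary()].
#' @param target_drug target ingredient id.
#' @param config run configuration (`min_treated`, `n_emulations_per_drug`,
#'   `follow_up_days`, `seed`).
#' @param schema covariate schema; built from the full population when `NULL`.
#' @param control_mode `"both"`, `"random"` or `"atc"`.
#' @return list of `trial_dataset`s; empty (with attribute `reason`) when the
#'   drug has fewer than `min_treated` eligible initiators.
#' @export
emulate_drug <- function(events, demo, vocab, target_drug,
                         config = run_config(), schema = NULL,
                         control_mode = c("both", "random", "atc")) {
  control_mode <- match.arg(control_mode)
  inits <- initiation_table(events, vocab)
  summaries <- patient_summaries(events, vocab)
  if (is.null(schema)) schema <- build_covariate_schema(events, vocab)

  treated <- eligible_initiators(target_drug, inits, summaries, demo, config)
  if (nrow(treated) < config$min_treated) {
    message(sprintf("drug %s skipped: %d eligible treated < %d required",
                    target_drug, nrow(treated), config$min_treated))
    return(structure(list(), reason = "insufficient_treated"))
  }

  # Patients with any target-drug fill (at any time) are excluded from
  # comparison arms when that fill precedes their own index date.
  target_first_fill <- inits[inits$ingredient == target_drug, ]
  target_fill_of <- stats::setNames(target_first_fill$first_fill,
                                    target_first_fill$patient_id)

  catalog <- setdiff(unique(inits$ingredient[inits$valid]), target_drug)
  atc_class <- vocab$atc_map[target_drug]
  siblings <- intersect(
    setdiff(names(vocab$atc_map)[vocab$atc_map == atc_class], target_drug),
    catalog)

  n_each <- config$n_emulations_per_drug %/% 2L
  plan <- switch(control_mode,
                 both = c(rep("random", n_each), rep("atc", n_each)),
                 random = rep("random", config$n_emulations_per_drug),
                 atc = rep("atc", config$n_emulations_per_drug))
  if (any(plan == "atc") && length(siblings) == 0) {
    message(sprintf("drug %s: no ATC-L2 sibling with eligible initiators; %s",
                    target_drug, "ATC-comparator emulations skipped"))
    plan <- plan[plan != "atc"]
  }

  sample_controls <- function(pool, n_draw, seed) {
    set.seed(substream_seed(seed, "control_drugs"))
    if (length(pool) == 0) return(character(0))
    if (length(pool) >= n_draw) {
      sample(pool, n_draw)
    } else {
      c(sample(pool, length(pool)),
        sample(pool, n_draw - length(pool), replace = TRUE))
    }
  }
  draws <- character(length(plan))
  draws[plan == "random"] <- sample_controls(
    catalog, sum(plan == "random"),
    substream_seed(config$seed, paste0(target_drug, "_random")))
  draws[plan == "atc"] <- sample_controls(
    siblings, sum(plan == "atc"),
    substream_seed(config$seed, paste0(target_drug, "_atc")))

  trials <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    ing <- draws[i]
    control <- eligible_initiators(ing, inits, summaries, demo, config)
    control <- control[!control$patient_id %in% treated$patient_id, ,
                       drop = FALSE]
    prior_target <- target_fill_of[control$patient_id]
    control <- control[is.na(prior_target) |
                         prior_target >= control$index_date, , drop = FALSE]
    if (nrow(control) == 0) next
    trials[[i]] <- make_trial(
      treated, control, events, demo, schema, vocab, config,
      meta = list(target_drug = target_drug, control_mode = plan[i],
                  control_drug = ing, emulation = i, seed = config$seed))
  }
  trials[!vapply(trials, is.null, logical(1))]
}

#' Write one emulated trial to disk
#'
#' Covariates go to a matrix CSV, the aligned `(patient_id, Z, Y, T)` table
#' to a second CSV and the metadata to a JSON sidecar.
#'
#' @param trial a `trial_dataset`.
#' @param prefix output path prefix.
#' @return the three paths, invisibly.
#' @export
write_trial_dataset <- function(trial, prefix) {
  stopifnot(inherits(trial, "trial_dataset"))
  paths <- paste0(prefix, c("_X.csv", "_outcomes.csv", "_meta.json"))
  utils::write.csv(as.data.frame(trial$X), paths[1], row.names = FALSE)
  utils::write.csv(data.frame(patient_id = trial$patient_id, Z = trial$Z,
                              Y = trial$Y, T = trial$T),
                   paths[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trial$meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
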