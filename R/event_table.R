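#' Read a longitudinal patient event table
#'
#' An event table is the raw input of the pipeline: one row per recorded
#' diagnosis (`DX`) or prescription (`RX`) event. The on-disk dialect is
#' comma-separated UTF-8 with a header naming the four columns
#' `patient_id,date,kind,code`; dates are ISO-8601 calendar days. Internally
#' dates are integer days since 1970-01-01 so that all window arithmetic
#' (30-day fill gaps, 365-day history, 1825-day follow-up) is exact day
#' counting.
#'
#' @param path path to a CSV file with columns `patient_id,date,kind,code`.
#' @return an `event_table`: a `data.frame` with character `patient_id`,
#'   integer `date` (days since epoch), `kind` (`"DX"` or `"RX"`) and
#'   character `code`, in file row order.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("event table file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "date", "kind", "code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  as_event_table(df[, need])
}

#' Validate and coerce a data frame into an event table
#'
#' @param df data frame with columns `patient_id`, `date`, `kind`, `code`;
#'   `date` may be ISO-8601 strings, `Date` values, or integer day counts.
#' @return validated `event_table` (see [read_event_table()]).
#' @export
as_event_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("patient_id", "date", "kind", "code")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("event table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  df$patient_id <- as.character(df$patient_id)
  df$code <- as.character(df$code)
  df$kind <- as.character(df$kind)
  bad_kind <- which(!df$kind %in% c("DX", "RX"))
  if (length(bad_kind)) {
    stop(sprintf("invalid event kind '%s' in row %d (must be DX or RX)",
                 df$kind[bad_kind[1]], bad_kind[1]))
  }
  df$date <- parse_event_dates(df$date)
  class(df) <- c("event_table", "data.frame")
  df
}

parse_event_dates <- function(x) {
  if (inherits(x, "Date")) return(as.integer(x))
  if (is.numeric(x)) {
    if (any(!is.finite(x))) stop("unparseable date in row ", which(!is.finite(x))[1])
    return(as.integer(x))
  }
  x <- as.character(x)
  iso <- grepl("^-?\\d{1,6}$", x)
  out <- integer(length(x))
  out[iso] <- as.integer(x[iso])
  if (any(!iso)) {
    d <- as.Date(x[!iso], format = "%Y-%m-%d")
    if (anyNA(d)) {
      bad <- which(!iso)[which(is.na(d))[1]]
      stop(sprintf("unparseable date '%s' in row %d", x[bad], bad))
    }
    out[!iso] <- as.integer(d)
  }
  out
}

#' Write an event table to CSV
#'
#' Inverse of [read_event_table()]: integer day counts are rendered back as
#' ISO-8601 calendar dates, so a write/read round trip is the identity.
#'
#' @param events an `event_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  out <- data.frame(
    patient_id = events$patient_id,
    date = format(as.Date(events$date, origin = "1970-01-01")),
    kind = events$kind,
    code = events$code,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble the vocabulary maps used by cohort construction
#'
#' Three code maps abstract the source coding systems: diagnosis code to one
#' of the comorbidity categories (64 under the default schema), drug code to
#' active ingredient, and ingredient to its ATC level-2 therapeutic class.
#' Reserved diagnosis code sets mark the at-risk condition (MCI) and the
#' outcome (AD).
#'
#' @param comorbidity_map named character vector: diagnosis code -> category id.
#' @param drug_map named character vector: drug code -> ingredient id.
#' @param atc_map named character vector: ingredient id -> ATC-L2 class id.
#' @param mci_codes diagnosis codes marking mild cognitive impairment.
#' @param ad_codes diagnosis codes marking Alzheimer's disease (and related
#'   dementias) outcomes.
#' @return a `vocabulary` list.
#' @export
vocabulary <- function(comorbidity_map, drug_map, atc_map,
                       mci_codes = "MCI", ad_codes = "AD") {
  stopifnot(!is.null(names(comorbidity_map)), !is.null(names(drug_map)),
            !is.null(names(atc_map)))
  if (anyDuplicated(names(atc_map))) {
    stop("every ingredient must map to exactly one ATC-L2 class")
  }
  structure(list(
    comorbidity_map = comorbidity_map,
    drug_map = drug_map,
    atc_map = atc_map,
    mci_codes = mci_codes,
    ad_codes = ad_codes
  ), class = "vocabulary")
}

#' Read vocabulary maps from two-column CSV files
#'
#' @param comorbidity_path CSV with columns `code,category`.
#' @param drug_path CSV with columns `code,ingredient`.
#' @param atc_path CSV with columns `ingredient,atc_l2`.
#' @inheritParams vocabulary
#' @return a `vocabulary` list (see [vocabulary()]).
#' @export
read_vocabulary <- function(comorbidity_path, drug_path, atc_path,
                            mci_codes = "MCI", ad_codes = "AD") {
  read_map <- function(path) {
    df <- utils::read.csv(path, colClasses = "character")
    if (ncol(df) < 2) stop("vocabulary file needs two columns: ", path)
    stats::setNames(df[[2]], df[[1]])
  }
  vocabulary(read_map(comorbidity_path), read_map(drug_path), read_map(atc_path),
             mci_codes = mci_codes, ad_codes = ad_codes)
}

#' Write vocabulary maps to two-column CSV files
#'
#' @param vocab a `vocabulary` object.
#' @param comorbidity_path,drug_path,atc_path output CSV paths.
#' @return invisibly, the three paths.
#' @export
write_vocabulary <- function(vocab, comorbidity_path, drug_path, atc_path) {
  stopifnot(inherits(vocab, "vocabulary"))
  write_map <- function(map, path, cols) {
    utils::write.csv(stats::setNames(
      data.frame(names(map), unname(map), stringsAsFactors = FALSE), cols),
      path, row.names = FALSE, quote = FALSE)
  }
  write_map(vocab$comorbidity_map, comorbidity_path, c("code", "category"))
  write_map(vocab$drug_map, drug_path, c("code", "ingredient"))
  write_map(vocab$atc_map, atc_path, c("ingredient", "atc_l2"))
  invisible(c(comorbidity_path, drug_path, atc_path))
}

#' Read a demographics table
#'
#' Baseline age and gender enter both the eligibility rules and the covariate
#' vector but are not event-stream data, so they travel in a separate table:
#' one row per patient with `patient_id`, `birth_date` (ISO-8601) and `sex`
#' (0/1 indicator).
#'
#' @param path CSV with columns `patient_id,birth_date,sex`.
#' @return data frame with character `patient_id`, integer `birth_date`
#'   (days since epoch) and integer `sex`.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("patient_id", "birth_date", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("demographics table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  data.frame(
    patient_id = df$patient_id,
    birth_date = parse_event_dates(df$birth_date),
    sex = as.integer(df$sex),
    stringsAsFactors = FALSE
  )
}

#' Write a demographics table
#' @param demo data frame as returned by [read_demographics()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_demographics <- function(demo, path) {
  out <- data.frame(
    patient_id = demo$patient_id,
    birth_date = format(as.Date(demo$birth_date, origin = "1970-01-01")),
    sex = demo$sex,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
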