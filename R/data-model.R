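#' Read long-format EHR event tables
#'
#' Ingests a delimited long-format event table and returns a cleaned,
#' deterministically sorted event `data.table` together with an ingest
#' summary. Diagnosis files must contain the columns `patient_id`, `date`,
#' `code_system`, `code`; medication files must contain `patient_id`, `date`,
#' `drug`. Diagnosis codes are carried as opaque namespaced tokens of the
#' form `"<SYSTEM>:<code>"` (e.g. `"ICD10:M80.08"`); ICD-9 and ICD-10 codes
#' are never cross-walked onto each other. Drug names are normalised to
#' lower case.
#'
#' Rows with unparseable dates, empty identifiers or empty tokens are
#' rejected and counted (never silently dropped and never fatal); a missing
#' required column is a fatal error naming the column. Exact duplicate
#' (patient, date, token) rows are de-duplicated. Events are sorted by
#' patient, then date, then token, so same-day ordering is deterministic.
#'
#' @param path path to a CSV file.
#' @param schema `"diagnosis"` or `"medication"`.
#' @param study_period optional length-2 vector of dates; events outside the
#'   period are rejected with reason `out_of_period`.
#' @param drug_dictionary optional character vector of known drug tokens;
#'   unknown drugs are flagged in the summary (`unknown_drug`), not dropped.
#' @return a list with elements `events` (a `data.table` with columns
#'   `patient_id`, `date`, and `code` or `drug`) and `summary` (rows read,
#'   rows kept, and a named vector of drop reasons).
#' @export
read_events <- function(path, schema = c("diagnosis", "medication"),
                        study_period = NULL, drug_dictionary = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, colClasses = "character")
  required <- if (schema == "diagnosis") {
    c("patient_id", "date", "code_system", "code")
  } else {
    c("patient_id", "date", "drug")
  }
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  clean_events(dt, schema, study_period, drug_dictionary)
}

# shared cleaning path so in-memory tables follow the same contract as files
clean_events <- function(dt, schema, study_period = NULL, drug_dictionary = NULL) {
  rows_read <- nrow(dt)
  reasons <- c(bad_date = 0L, missing_field = 0L, out_of_period = 0L, duplicate = 0L)
  if (rows_read == 0L) {
    ev <- if (schema == "diagnosis") {
      data.table::data.table(patient_id = character(), date = as_idate(integer(0)),
                             code = character())
    } else {
      data.table::data.table(patient_id = character(), date = as_idate(integer(0)),
                             drug = character())
    }
    return(list(events = ev,
                summary = list(rows_read = 0L, rows_kept = 0L, dropped = reasons,
                               unknown_drug = 0L)))
  }
  dt <- data.table::copy(dt)
  dt[, date_parsed := parse_iso_date(date)]
  if (schema == "diagnosis") {
    dt[, token := ifelse(nzchar(code_system) & nzchar(code),
                         paste(code_system, code, sep = ":"), NA_character_)]
  } else {
    dt[, token := ifelse(nzchar(drug), tolower(trimws(drug)), NA_character_)]
  }
  bad_field <- !nzchar(dt$patient_id) | is.na(dt$token)
  bad_date <- !bad_field & is.na(dt$date_parsed)
  keep <- !bad_field & !bad_date
  reasons["missing_field"] <- sum(bad_field)
  reasons["bad_date"] <- sum(bad_date)
  out <- dt[keep, .(patient_id, date = date_parsed, token)]
  if (!is.null(study_period)) {
    sp <- as_idate(study_period)
    inside <- out$date >= sp[1] & out$date <= sp[2]
    reasons["out_of_period"] <- sum(!inside)
    out <- out[inside]
  }
  n_before <- nrow(out)
  out <- unique(out, by = c("patient_id", "date", "token"))
  reasons["duplicate"] <- n_before - nrow(out)
  data.table::setorder(out, patient_id, date, token)
  unknown_drug <- 0L
  if (schema == "medication") {
    data.table::setnames(out, "token", "drug")
    if (!is.null(drug_dictionary)) {
      unknown <- !(out$drug %in% tolower(drug_dictionary))
      unknown_drug <- sum(unknown)
      out[, known := !unknown]
    }
  } else {
    data.table::setnames(out, "token", "code")
  }
  list(events = out[],
       summary = list(rows_read = rows_read, rows_kept = nrow(out),
                      dropped = reasons, unknown_drug = unknown_drug))
}

#' Write event tables in the package's CSV schemas
#'
#' Inverse of [read_events()]: diagnosis tokens are split at the first `:`
#' back into `code_system` and `code` columns; dates are serialised as ISO
#' days so a write/read round trip is byte-stable.
#'
#' @param events event `data.table` as returned by [read_events()].
#' @param path output CSV path.
#' @param schema `"diagnosis"` or `"medication"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, schema = c("diagnosis", "medication")) {
  schema <- match.arg(schema)
  if (schema == "diagnosis") {
    pos <- regexpr(":", events$code, fixed = TRUE)
    out <- data.table::data.table(
      patient_id = events$patient_id,
      date = format(events$date),
      code_system = substr(events$code, 1L, pos - 1L),
      code = substr(events$code, pos + 1L, nchar(events$code)))
  } else {
    out <- data.table::data.table(
      patient_id = events$patient_id,
      date = format(events$date),
      drug = events$drug)
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read a demographics table
#'
#' Expects columns `patient_id`, `birth_date`, `sex`. Sex values are
#' normalised to `female` / `male`; anything else becomes `unknown`
#' (counted). Duplicate patient rows keep the first occurrence.
#'
#' @param path CSV path.
#' @return list of `demographics` (`data.table`) and `summary`.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, colClasses = "character")
  required <- c("patient_id", "birth_date", "sex")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  clean_demographics(dt)
}

clean_demographics <- function(dt) {
  rows_read <- nrow(dt)
  dt <- data.table::copy(dt)
  dt[, birth_parsed := parse_iso_date(birth_date)]
  dt[, sex_norm := tolower(trimws(sex))]
  dt[!(sex_norm %in% c("female", "male")), sex_norm := "unknown"]
  n_unknown_sex <- sum(dt$sex_norm == "unknown")
  bad <- !nzchar(dt$patient_id)
  out <- dt[!bad, .(patient_id, birth_date = birth_parsed, sex = sex_norm)]
  n_before <- nrow(out)
  out <- unique(out, by = "patient_id")
  data.table::setorder(out, patient_id)
  list(demographics = out[],
       summary = list(rows_read = rows_read, rows_kept = nrow(out),
                      duplicates = n_before - nrow(out),
                      missing_id = sum(bad), unknown_sex = n_unknown_sex))
}

#' Write a demographics table
#' @param demographics demographics `data.table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_demographics <- function(demographics, path) {
  out <- data.table::data.table(
    patient_id = demographics$patient_id,
    birth_date = format(demographics$birth_date),
    sex = demographics$sex)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Assemble per-patient records from ingested event tables
#'
#' Builds an `ehr_cohort`: the keyed diagnosis, medication and demographics
#' tables plus an anomaly summary. Every patient with at least one diagnosis
#' event appears; patients present only in demographics are excluded and
#' counted; patients with events but no demographics row are kept with
#' `sex = "unknown"`, a missing birth date, and are flagged. Birth dates that
#' do not precede all of a patient's events are reported as anomalies (the
#' rows are kept; downstream age filters exclude them explicitly).
#'
#' @param diagnoses diagnosis events (`patient_id`, `date`, `code`).
#' @param medications medication events (`patient_id`, `date`, `drug`);
#'   may be `NULL`.
#' @param demographics demographics table (`patient_id`, `birth_date`, `sex`);
#'   may be `NULL`.
#' @return an `ehr_cohort` object.
#' @export
assemble_records <- function(diagnoses, medications = NULL, demographics = NULL) {
  diagnoses <- data.table::as.data.table(diagnoses)
  data.table::setorder(diagnoses, patient_id, date, code)
  diagnoses <- unique(diagnoses, by = c("patient_id", "date", "code"))
  patients <- unique(diagnoses$patient_id)

  if (is.null(medications)) {
    medications <- data.table::data.table(patient_id = character(),
                                          date = as_idate(integer(0)),
                                          drug = character())
  } else {
    medications <- data.table::as.data.table(medications)
    data.table::setorder(medications, patient_id, date, drug)
  }
  orphan_meds <- sum(!(medications$patient_id %in% patients))
  medications <- medications[patient_id %in% patients]

  if (is.null(demographics)) {
    demographics <- data.table::data.table(patient_id = character(),
                                           birth_date = as_idate(integer(0)),
                                           sex = character())
  } else {
    demographics <- data.table::as.data.table(demographics)
  }
  eventless <- setdiff(demographics$patient_id, patients)
  demographics <- demographics[patient_id %in% patients]
  missing_demo <- setdiff(patients, demographics$patient_id)
  if (length(missing_demo) > 0L) {
    demographics <- rbind(demographics,
                          data.table::data.table(patient_id = missing_demo,
                                                 birth_date = as_idate(NA_integer_),
                                                 sex = "unknown"))
  }
  data.table::setorder(demographics, patient_id)

  first_event <- diagnoses[, .(first_date = min(date)), by = patient_id]
  chk <- merge(first_event, demographics, by = "patient_id")
  birth_violation <- chk[!is.na(birth_date) & birth_date >= first_date, patient_id]

  data.table::setkey(diagnoses, patient_id)
  data.table::setkey(medications, patient_id)
  data.table::setkey(demographics, patient_id)

  structure(list(
    diagnoses = diagnoses,
    medications = medications,
    demographics = demographics,
    summary = list(
      n_patients = length(patients),
      n_diagnoses = nrow(diagnoses),
      n_medications = nrow(medications),
      eventless_patients = length(eventless),
      missing_demographics = missing_demo,
      orphan_medications = orphan_meds,
      birth_after_event = birth_violation)),
    class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ehr_cohort> %d patients, %d diagnosis events, %d medication events\n",
              s$n_patients, s$n_diagnoses, s$n_medications))
  if (length(s$missing_demographics) > 0L) {
    cat(sprintf("  %d patient(s) without demographics (sex set to unknown)\n",
                length(s$missing_demographics)))
  }
  invisible(x)
}

#' List patient identifiers in a cohort
#' @param cohort an `ehr_cohort`.
#' @return character vector of patient ids.
#' @export
cohort_patients <- function(cohort) {
  cohort$demographics$patient_id
}

#' Extract one patient's record
#'
#' @param cohort an `ehr_cohort`.
#' @param id patient identifier.
#' @return a `patient_record`: demographics row plus that patient's sorted
#'   diagnosis and medication events.
#' @export
patient_record <- function(cohort, id) {
  demo <- cohort$demographics[patient_id == id]
  if (nrow(demo) == 0L) stopf("unknown patient: %s", id)
  structure(list(
    patient_id = id,
    birth_date = demo$birth_date[1],
    sex = demo$sex[1],
    diagnoses = cohort$diagnoses[patient_id == id],
    medications = cohort$medications[patient_id == id]),
    class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s (sex %s), %d diagnoses, %d medications\n",
              x$patient_id, x$sex, nrow(x$diagnoses), nrow(x$medications)))
  invisible(x)
}
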