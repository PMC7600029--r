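# Qualifying fracture events: claims-style case definition with site-specific
# code catalogs, a chronological scan, and a same-site washout so follow-up
# coding of one clinical fracture is not counted as a new event.

fracture_sites <- c("hip", "vertebral", "wrist/forearm", "humerus", "pelvis",
                    "clinical-other")

#' Read a fracture-code catalog
#'
#' The catalog is a CSV with columns `code_pattern` and `site`. Patterns are
#' matched as prefixes of namespaced code tokens; when several patterns match
#' a token the longest (most specific) pattern wins.
#'
#' @param path CSV path; defaults to the catalog shipped with the package.
#' @return a `fracture_catalog` (`data.table` of patterns and sites).
#' @export
read_fracture_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fracture_catalog.csv",
                                package = "fracrisk", mustWork = TRUE)
  cat <- data.table::fread(path, colClasses = "character")
  if (!all(c("code_pattern", "site") %in% names(cat))) {
    stopf("fracture catalog needs columns code_pattern, site")
  }
  bad <- setdiff(unique(cat$site), fracture_sites)
  if (length(bad) > 0L) stopf("unknown fracture site(s): %s", paste(bad, collapse = ", "))
  data.table::setorder(cat, -code_pattern) # longer patterns first within ties
  cat <- cat[order(-nchar(code_pattern), code_pattern)]
  structure(cat[], class = c("fracture_catalog", class(cat)))
}

#' Default fracture-code catalog
#' @return the catalog shipped under `extdata/fracture_catalog.csv`.
#' @export
default_fracture_catalog <- function() read_fracture_catalog()

# vectorised longest-prefix site lookup; NA where no pattern matches
match_fracture_site <- function(codes, catalog) {
  site <- rep(NA_character_, length(codes))
  unmatched <- rep(TRUE, length(codes))
  # catalog is ordered longest-first, so the first hit is the longest match
  for (i in seq_len(nrow(catalog))) {
    hit <- unmatched & startsWith(codes, catalog$code_pattern[i])
    site[hit] <- catalog$site[i]
    unmatched[hit] <- FALSE
  }
  site
}

#' Test a code token against the fracture catalog
#'
#' @param code a single namespaced code token.
#' @param catalog a `fracture_catalog`.
#' @return list with `is_fracture` (logical) and `site` (site name or `NA`).
#' @export
is_fracture_code <- function(code, catalog = default_fracture_catalog()) {
  site <- match_fracture_site(code, catalog)
  list(is_fracture = !is.na(site), site = site)
}

# ICD-10-CM style aftercare/sequela coding: a 7th character of D or S marks
# follow-up care of an earlier fracture, never a new clinical event.
is_followup_code <- function(codes) {
  is_icd10 <- startsWith(codes, "ICD10:")
  body <- sub("^[^:]+:", "", codes)
  body <- gsub(".", "", body, fixed = TRUE)
  is_icd10 & nchar(body) >= 7L & substr(body, 7L, 7L) %in% c("D", "S")
}

# core scan shared by the record-level and cohort-level interfaces;
# takes sorted vectors for one patient
qualify_scan <- function(dates, sites, followup, washout_days) {
  n <- length(dates)
  keep_date <- integer(0)
  keep_site <- character(0)
  last_by_site <- numeric(0) # named by site: date of last qualifying event
  for (i in seq_len(n)) {
    if (followup[i]) next
    s <- sites[i]
    last <- if (s %in% names(last_by_site)) last_by_site[[s]] else NA_real_
    if (!is.na(last) && dates[i] - last <= washout_days) next # follow-up coding

    keep_date <- c(keep_date, dates[i])
    keep_site <- c(keep_site, s)
    last_by_site[s] <- dates[i]
  }
  list(date = keep_date, site = keep_site)
}

#' Identify qualifying fracture events for one patient
#'
#' Scans a patient's fracture-coded diagnoses chronologically. A fracture
#' code opens a new event unless (a) it carries ICD-10-CM aftercare/sequela
#' 7th-character coding (`D`/`S`), or (b) a qualifying event at the same site
#' exists within `washout_days` before it; in either case it is absorbed as
#' follow-up coding of the earlier event. Events at different sites are
#' always distinct. `is_subsequent` marks events preceded by any earlier
#' qualifying event of the patient.
#'
#' @param record a `patient_record`.
#' @param catalog a `fracture_catalog`.
#' @param washout_days same-site washout in days (default 90).
#' @return `data.table` with `patient_id`, `date`, `site`, `is_subsequent`,
#'   strictly ordered in date.
#' @export
qualify_fracture_events <- function(record, catalog = default_fracture_catalog(),
                                    washout_days = 90L) {
  stopifnot(washout_days > 0L)
  dx <- record$diagnoses
  empty <- data.table::data.table(patient_id = character(),
                                  date = as_idate(integer(0)),
                                  site = character(), is_subsequent = logical())
  if (nrow(dx) == 0L) return(empty)
  site <- match_fracture_site(dx$code, catalog)
  frak <- dx[!is.na(site)]
  if (nrow(frak) == 0L) return(empty)
  fsite <- site[!is.na(site)]
  res <- qualify_scan(as.numeric(frak$date), fsite, is_followup_code(frak$code),
                      washout_days)
  if (length(res$date) == 0L) return(empty)
  data.table::data.table(patient_id = record$patient_id,
                         date = as_idate(as.integer(res$date)),
                         site = res$site,
                         is_subsequent = seq_along(res$date) > 1L)
}

#' Identify qualifying fracture events for a whole cohort
#'
#' Vectorised wrapper around the same chronological washout scan as
#' [qualify_fracture_events()], run per patient over the cohort's
#' fracture-coded diagnoses only.
#'
#' @param cohort an `ehr_cohort`.
#' @inheritParams qualify_fracture_events
#' @return `data.table` of qualifying events across all patients.
#' @export
qualify_fractures <- function(cohort, catalog = default_fracture_catalog(),
                              washout_days = 90L) {
  stopifnot(washout_days > 0L)
  dx <- cohort$diagnoses
  site <- match_fracture_site(dx$code, catalog)
  sel <- which(!is.na(site))
  site_sel <- site[sel]
  frak <- dx[sel]
  frak[, site := site_sel]
  if (nrow(frak) == 0L) {
    return(data.table::data.table(patient_id = character(),
                                  date = as_idate(integer(0)),
                                  site = character(), is_subsequent = logical()))
  }
  frak[, followup := is_followup_code(code)]
  out <- frak[, {
    res <- qualify_scan(as.numeric(date), site, followup, washout_days)
    list(date = as_idate(as.integer(res$date)), site = res$site,
         is_subsequent = seq_along(res$date) > 1L)
  }, by = patient_id]
  data.table::setorder(out, patient_id, date)
  out[]
}

#' Anchor events for prediction windows
#'
#' Every qualifying fracture is an anchor. A patient with no qualifying
#' fracture contributes exactly one anchor at the date of their last
#' recorded diagnosis of any kind.
#'
#' @param cohort an `ehr_cohort`.
#' @param fractures qualifying events from [qualify_fractures()].
#' @return `data.table` with `patient_id`, `date`,
#'   `kind` (`fracture`/`last_diagnosis`), `site`, `is_subsequent`.
#' @export
anchor_events <- function(cohort, fractures) {
  frac_anchors <- fractures[, .(patient_id, date, kind = "fracture", site,
                                is_subsequent)]
  nonfrac <- setdiff(cohort_patients(cohort), unique(fractures$patient_id))
  last_dx <- cohort$diagnoses[patient_id %in% nonfrac,
                              .(date = max(date), kind = "last_diagnosis",
                                site = NA_character_, is_subsequent = FALSE),
                              by = patient_id]
  out <- rbind(frac_anchors, last_dx, use.names = TRUE)
  data.table::setorder(out, patient_id, date)
  out[]
}

#' Anchor events for a single patient record
#'
#' @param record a `patient_record`.
#' @param fractures that patient's qualifying events
#'   (defaults to recomputing them).
#' @inheritParams qualify_fracture_events
#' @return `data.table` of anchors for this patient (empty for an empty record).
#' @export
anchor_events_record <- function(record,
                                 fractures = qualify_fracture_events(record, catalog,
                                                                     washout_days),
                                 catalog = default_fracture_catalog(),
                                 washout_days = 90L) {
  if (nrow(record$diagnoses) == 0L) {
    return(data.table::data.table(patient_id = character(),
                                  date = as_idate(integer(0)), kind = character(),
                                  site = character(), is_subsequent = logical()))
  }
  if (nrow(fractures) > 0L) {
    return(fractures[, .(patient_id, date, kind = "fracture", site, is_subsequent)])
  }
  data.table::data.table(patient_id = record$patient_id,
                         date = max(record$diagnoses$date),
                         kind = "last_diagnosis", site = NA_character_,
                         is_subsequent = FALSE)
}
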