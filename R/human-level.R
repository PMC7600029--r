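# Retrospective human-level-performance approximation: a window counts as
# "physician-identified risk, worthy of intervention" when it contains any
# catalogued bone-health intervention (diagnostic test, treatment, or
# osteoporosis diagnosis). The cohort analysis cross-tabulates model flags
# against intervention status and outcome; the overlap analysis scores each
# treated patient's history up to their first pharmacologic intervention.

#' Read an intervention catalog
#'
#' CSV with columns `name`, `kind` (`dx`/`proc`/`med`), `pattern`,
#' `pharmacologic` (`yes`/`no`). Diagnosis and procedure patterns are
#' matched as prefixes of namespaced code tokens; medication patterns are
#' matched case-insensitively as prefixes of the normalised drug token (so
#' a base drug name also matches its combination products).
#'
#' @param path CSV path; defaults to the catalog shipped with the package.
#' @return an `intervention_catalog` (`data.table`).
#' @export
read_intervention_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "intervention_catalog.csv",
                                package = "fracrisk", mustWork = TRUE)
  cat <- data.table::fread(path, colClasses = "character")
  need <- c("name", "kind", "pattern", "pharmacologic")
  if (!all(need %in% names(cat))) {
    stopf("intervention catalog needs columns %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(cat$kind), c("dx", "proc", "med"))
  if (length(bad) > 0L) stopf("unknown intervention kind(s): %s",
                              paste(bad, collapse = ", "))
  if (any(!nzchar(cat$pattern))) stopf("empty intervention pattern")
  cat[, pharmacologic := tolower(pharmacologic) %in% c("yes", "true", "1")]
  structure(cat[], class = c("intervention_catalog", class(cat)))
}

#' Default intervention catalog
#' @return the catalog shipped under `extdata/intervention_catalog.csv`.
#' @export
default_intervention_catalog <- function() read_intervention_catalog()

match_any_prefix <- function(tokens, patterns) {
  hit <- rep(FALSE, length(tokens))
  for (p in patterns) hit <- hit | startsWith(tokens, p)
  hit
}

#' Detect interventions inside one patient's window
#'
#' Scans the record's diagnosis (including procedure tokens) and medication
#' events with dates in `(window_end - span_days, window_end]` against the
#' catalog.
#'
#' @param record a `patient_record`.
#' @param window_end window end date.
#' @param catalog an `intervention_catalog`.
#' @param span_days window span (default 730).
#' @return list with `any_intervention` and a `matches` table
#'   (`name`, `kind`, `pattern`, `pharmacologic`, `date`).
#' @export
detect_interventions <- function(record, window_end,
                                 catalog = default_intervention_catalog(),
                                 span_days = 730L) {
  window_end <- as_idate(window_end)
  lo <- window_end - span_days
  dxcat <- catalog[kind %in% c("dx", "proc")]
  medcat <- catalog[kind == "med"]
  matches <- list()
  dx <- record$diagnoses[date > lo & date <= window_end]
  if (nrow(dx) > 0L && nrow(dxcat) > 0L) {
    for (i in seq_len(nrow(dxcat))) {
      hit <- startsWith(dx$code, dxcat$pattern[i])
      if (any(hit)) {
        matches[[length(matches) + 1L]] <- data.table::data.table(
          name = dxcat$name[i], kind = dxcat$kind[i],
          pattern = dxcat$pattern[i], pharmacologic = dxcat$pharmacologic[i],
          date = dx$date[hit])
      }
    }
  }
  med <- record$medications[date > lo & date <= window_end]
  if (nrow(med) > 0L && nrow(medcat) > 0L) {
    drugs <- tolower(med$drug)
    for (i in seq_len(nrow(medcat))) {
      hit <- startsWith(drugs, tolower(medcat$pattern[i]))
      if (any(hit)) {
        matches[[length(matches) + 1L]] <- data.table::data.table(
          name = medcat$name[i], kind = "med", pattern = medcat$pattern[i],
          pharmacologic = medcat$pharmacologic[i], date = med$date[hit])
      }
    }
  }
  m <- if (length(matches) > 0L) data.table::rbindlist(matches) else
    data.table::data.table(name = character(), kind = character(),
                           pattern = character(), pharmacologic = logical(),
                           date = as_idate(integer(0)))
  data.table::setorder(m, date, name)
  list(any_intervention = nrow(m) > 0L, matches = m[])
}

# vectorised window-level intervention status for a whole windows table:
# returns the windows table order with columns any_intervention / any_treatment
window_intervention_status <- function(windows, cohort, catalog,
                                       span_days = 730L) {
  w <- windows[, .(window_id, patient_id, hi = as.numeric(window_end),
                   lo = as.numeric(window_end) - span_days)]
  dxcat <- catalog[kind %in% c("dx", "proc")]
  dx <- cohort$diagnoses[patient_id %in% w$patient_id]
  dx_hit_ids <- character(0)
  if (nrow(dx) > 0L && nrow(dxcat) > 0L) {
    sel <- match_any_prefix(dx$code, dxcat$pattern)
    dxm <- dx[sel, .(patient_id, d = as.numeric(date))]
    if (nrow(dxm) > 0L) {
      j <- dxm[w, on = .(patient_id, d > lo, d <= hi), nomatch = NULL,
               .(window_id = i.window_id)]
      dx_hit_ids <- unique(j$window_id)
    }
  }
  medcat <- catalog[kind == "med"]
  med <- cohort$medications[patient_id %in% w$patient_id]
  med_hit_ids <- character(0)
  if (nrow(med) > 0L && nrow(medcat) > 0L) {
    sel <- match_any_prefix(tolower(med$drug), tolower(medcat$pattern))
    medm <- med[sel, .(patient_id, d = as.numeric(date))]
    if (nrow(medm) > 0L) {
      j <- medm[w, on = .(patient_id, d > lo, d <= hi), nomatch = NULL,
                .(window_id = i.window_id)]
      med_hit_ids <- unique(j$window_id)
    }
  }
  data.table::data.table(
    window_id = windows$window_id,
    any_intervention = windows$window_id %in% c(dx_hit_ids, med_hit_ids),
    any_treatment = windows$window_id %in% med_hit_ids)
}

#' Build a cohort-analysis report from cell counts
#'
#' The arithmetic core of the cohort analysis: given flagged/total window
#' counts for the four intervention-by-outcome cells (plus, optionally, the
#' unique-event roll-up of the no-intervention fracture cell and the
#' treatment share of intervention windows), computes all row percentages.
#'
#' @param no_int_fracture,no_int_nonfracture,int_fracture,int_nonfracture
#'   length-2 vectors `c(flagged, total)` of window counts per cell.
#' @param unique_events optional `c(flagged_events, total_events)` for the
#'   no-intervention fracture cell.
#' @param treatments optional `c(treatment_windows, intervention_windows)`.
#' @return a `cohort_analysis_report`.
#' @export
cohort_analysis_report <- function(no_int_fracture, no_int_nonfracture,
                                   int_fracture, int_nonfracture,
                                   unique_events = NULL, treatments = NULL) {
  cell <- function(cohort, outcome, x) {
    data.table::data.table(cohort = cohort, outcome = outcome,
                           n = x[2], flagged = x[1], not_flagged = x[2] - x[1],
                           pct_flagged = 100 * x[1] / x[2],
                           pct_not_flagged = 100 * (x[2] - x[1]) / x[2])
  }
  tab <- rbind(cell("no_intervention", "fracture", no_int_fracture),
               cell("no_intervention", "nonfracture", no_int_nonfracture),
               cell("intervention", "fracture", int_fracture),
               cell("intervention", "nonfracture", int_nonfracture))
  n_no_int <- no_int_fracture[2] + no_int_nonfracture[2]
  n_int <- int_fracture[2] + int_nonfracture[2]
  total <- n_no_int + n_int
  rollup <- if (!is.null(unique_events)) {
    list(events_flagged = unique_events[1], events_total = unique_events[2],
         pct_events_flagged = 100 * unique_events[1] / unique_events[2])
  }
  treat <- if (!is.null(treatments)) {
    list(treatment_windows = treatments[1], intervention_windows = treatments[2],
         pct_treatment = 100 * treatments[1] / treatments[2])
  }
  structure(list(table = tab, n_windows = total,
                 n_no_intervention = n_no_int, n_intervention = n_int,
                 pct_no_intervention = 100 * n_no_int / total,
                 pct_intervention = 100 * n_int / total,
                 unique_events = rollup, treatments = treat),
            class = "cohort_analysis_report")
}

#' @export
print.cohort_analysis_report <- function(x, ...) {
  cat(sprintf("<cohort_analysis_report> %d windows (%.1f%% no intervention / %.1f%% intervention)\n",
              x$n_windows, x$pct_no_intervention, x$pct_intervention))
  tab <- data.table::copy(x$table)
  tab[, `:=`(pct_flagged = sprintf("%.1f", pct_flagged),
             pct_not_flagged = sprintf("%.1f", pct_not_flagged))]
  print(tab, row.names = FALSE)
  if (!is.null(x$unique_events)) {
    cat(sprintf("  unique fracture events flagged (no intervention): %d of %d (%.1f%%)\n",
                x$unique_events$events_flagged, x$unique_events$events_total,
                x$unique_events$pct_events_flagged))
  }
  if (!is.null(x$treatments)) {
    cat(sprintf("  intervention windows containing treatments: %d of %d (%.1f%%)\n",
                x$treatments$treatment_windows, x$treatments$intervention_windows,
                x$treatments$pct_treatment))
  }
  invisible(x)
}

#' Cohort analysis: model flags vs physician interventions
#'
#' Partitions the scored windows into intervention / no-intervention by
#' catalog detection inside each window span, splits each side by outcome
#' label, cross-tabulates model flags, and rolls the no-intervention
#' fracture cell up to unique fracture events (an event counts as flagged
#' when at least one of its windows is flagged). Intervention effects on
#' subsequent risk are not adjusted for; the intervention-side cells must
#' be read with that caveat.
#'
#' @param windows scored (typically holdout) windows.
#' @param predictions prediction table for those windows.
#' @param cohort the `ehr_cohort` (for event scanning).
#' @param catalog an `intervention_catalog`.
#' @param span_days window span (default 730).
#' @return a `cohort_analysis_report`.
#' @export
cohort_analysis <- function(windows, predictions, cohort,
                            catalog = default_intervention_catalog(),
                            span_days = 730L) {
  st <- window_intervention_status(windows, cohort, catalog, span_days)
  x <- merge(windows[, .(window_id, patient_id, anchor_date, label)],
             predictions[, .(window_id, flag)], by = "window_id")
  x <- merge(x, st, by = "window_id")
  cell <- function(iv, lab) {
    sel <- x[any_intervention == iv & label == lab]
    c(sum(sel$flag), nrow(sel))
  }
  nif <- x[any_intervention == FALSE & label == TRUE]
  ev <- nif[, .(flagged = any(flag)), by = .(patient_id, anchor_date)]
  cohort_analysis_report(
    no_int_fracture = cell(FALSE, TRUE),
    no_int_nonfracture = cell(FALSE, FALSE),
    int_fracture = cell(TRUE, TRUE),
    int_nonfracture = cell(TRUE, FALSE),
    unique_events = c(sum(ev$flagged), nrow(ev)),
    treatments = c(sum(x$any_intervention & x$any_treatment),
                   sum(x$any_intervention)))
}

#' Build an overlap-analysis report from counts
#'
#' @param n_treated patients with any pharmacologic intervention.
#' @param n_sufficient of those, patients with enough prior history.
#' @param n_flagged of those, patients flagged by the model.
#' @param n_flagged_fracture flagged patients fracturing within the horizon.
#' @param n_fracture all sufficient-history treated patients fracturing
#'   within the horizon.
#' @param n_fracture_flagged of those, patients flagged by the model
#'   (defaults to `n_flagged_fracture`, the consistent single-definition
#'   value).
#' @return an `overlap_analysis_report` with nested counts and percentages.
#' @export
overlap_analysis_report <- function(n_treated, n_sufficient, n_flagged,
                                    n_flagged_fracture, n_fracture,
                                    n_fracture_flagged = n_flagged_fracture) {
  if (!(n_flagged <= n_sufficient && n_sufficient <= n_treated)) {
    stopf("overlap counts must nest: flagged <= sufficient <= treated")
  }
  structure(list(
    n_treated = n_treated, n_sufficient = n_sufficient, n_flagged = n_flagged,
    pct_flagged = 100 * n_flagged / n_sufficient,
    n_flagged_fracture = n_flagged_fracture,
    pct_fracture_among_flagged = 100 * n_flagged_fracture / n_flagged,
    n_fracture = n_fracture, n_fracture_flagged = n_fracture_flagged,
    pct_flagged_among_fracture = 100 * n_fracture_flagged / n_fracture),
    class = "overlap_analysis_report")
}

#' @export
print.overlap_analysis_report <- function(x, ...) {
  cat("<overlap_analysis_report>\n")
  cat(sprintf("  treated patients: %d; with sufficient history: %d\n",
              x$n_treated, x$n_sufficient))
  cat(sprintf("  flagged by model: %d (%.1f%%)\n", x$n_flagged, x$pct_flagged))
  cat(sprintf("  fracture within horizon among flagged: %d (%.1f%%)\n",
              x$n_flagged_fracture, x$pct_fracture_among_flagged))
  cat(sprintf("  flagged among all fracturing treated patients: %d of %d (%.1f%%)\n",
              x$n_fracture_flagged, x$n_fracture, x$pct_flagged_among_fracture))
  invisible(x)
}

#' Overlap analysis: scoring histories up to the first treatment
#'
#' For every patient with a pharmacologic intervention, takes the first
#' such intervention date, builds one window ending the day before it
#' (subject to the usual full-history coverage requirement), scores it with
#' the model, and reports: the flag rate, the rate of qualifying fracture
#' within the horizon among flagged patients, and the flag rate among all
#' treated patients who fracture within the horizon.
#'
#' @param cohort the `ehr_cohort`.
#' @param model a fitted `risk_model`.
#' @param fractures qualifying fracture table from [qualify_fractures()].
#' @param catalog an `intervention_catalog` (its pharmacologic subset is
#'   used).
#' @param horizon_days fracture horizon after the window end (default 730).
#' @param history_days required history coverage (default 730).
#' @return an `overlap_analysis_report`.
#' @export
overlap_analysis <- function(cohort, model, fractures,
                             catalog = default_intervention_catalog(),
                             horizon_days = 730L, history_days = 730L) {
  medcat <- catalog[kind == "med" & pharmacologic == TRUE]
  med <- cohort$medications
  sel <- match_any_prefix(tolower(med$drug), tolower(medcat$pattern))
  pharm <- med[sel, .(first_date = min(date)), by = patient_id]
  n_treated <- nrow(pharm)
  if (n_treated == 0L) stopf("no patient has a pharmacologic intervention")

  first_dx <- cohort$diagnoses[patient_id %in% pharm$patient_id,
                               .(first_dx = min(date)), by = patient_id]
  x <- merge(pharm, first_dx, by = "patient_id")
  x <- merge(x, cohort$demographics[, .(patient_id, birth_date, sex)],
             by = "patient_id")
  x[, window_end := first_date - 1L]
  x <- x[first_dx <= window_end - history_days]
  n_sufficient <- nrow(x)
  if (n_sufficient == 0L) {
    return(overlap_analysis_report(n_treated, 0L, 0L, 0L, 0L))
  }

  # one window per treated patient, ending the day before first treatment
  dx <- cohort$diagnoses[patient_id %in% x$patient_id]
  dx_list <- split(dx[, .(d = as.numeric(date), code)], dx$patient_id)
  codes <- vector("list", n_sufficient)
  for (i in seq_len(n_sufficient)) {
    p <- dx_list[[x$patient_id[i]]]
    lo <- as.numeric(x$window_end[i]) - history_days
    hi <- as.numeric(x$window_end[i])
    codes[[i]] <- p$code[p$d > lo & p$d <= hi]
  }
  w <- data.table::data.table(
    window_id = sprintf("%s@%s", x$patient_id, format(x$window_end)),
    patient_id = x$patient_id, window_end = x$window_end,
    age = age_years(x$birth_date, x$window_end), sex = x$sex,
    dx_count = vapply(codes, length, 1L), codes = codes)
  pred <- predict(model, w)

  frac_next <- merge(
    x[, .(patient_id, window_end)],
    fractures[, .(patient_id, fdate = date)],
    by = "patient_id", allow.cartesian = TRUE)
  frac_next <- frac_next[fdate > window_end & fdate <= window_end + horizon_days]
  fractured <- unique(frac_next$patient_id)

  flagged <- x$patient_id[pred$flag]
  overlap_analysis_report(
    n_treated = n_treated, n_sufficient = n_sufficient,
    n_flagged = length(flagged),
    n_flagged_fracture = length(intersect(flagged, fractured)),
    n_fracture = length(fractured))
}
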