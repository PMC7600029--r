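# Cohort eligibility, the sliding-window construction, vocabulary building,
# patient-level train/holdout splitting, and class-balancing oversampling.

#' Filter anchors to the eligible cohort
#'
#' Keeps anchor events where the patient is at least `min_age` years old at
#' the anchor date and has at least `min_history_days` of recorded history
#' (first diagnosis on or before `anchor - min_history_days`). Exclusions
#' are counted by reason in the `"exclusions"` attribute.
#'
#' @param anchors anchor table from [anchor_events()].
#' @param cohort the `ehr_cohort` the anchors were derived from.
#' @param min_age minimum age in years (default 50).
#' @param min_history_days minimum prior history in days (default 730).
#' @return the eligible subset of `anchors`.
#' @export
select_cohort <- function(anchors, cohort, min_age = 50, min_history_days = 730L) {
  first_dx <- cohort$diagnoses[, .(first_date = min(date)), by = patient_id]
  x <- merge(anchors, cohort$demographics[, .(patient_id, birth_date)],
             by = "patient_id")
  x <- merge(x, first_dx, by = "patient_id")
  age <- age_years(x$birth_date, x$date)
  under_age <- is.na(age) | age < min_age
  short_history <- !under_age & x$first_date > (x$date - min_history_days)
  out <- x[!under_age & !short_history,
           .(patient_id, date, kind, site, is_subsequent)]
  data.table::setorder(out, patient_id, date)
  data.table::setattr(out, "exclusions",
                      c(under_age = sum(under_age & !is.na(age)),
                        missing_birth_date = sum(is.na(age)),
                        short_history = sum(short_history)))
  out[]
}

# windows for one patient given plain sorted vectors; shared by the
# record-level and cohort-level interfaces
windows_for_patient <- function(pid, anchor_dates, anchor_kinds, anchor_sites,
                                anchor_subseq, dx_dates, dx_codes, frac_dates,
                                birth_date, sex, cohort_tag, horizon_days,
                                max_windows, stride_days, history_days) {
  first_dx <- dx_dates[1]
  rows <- vector("list", length(anchor_dates) * max_windows)
  nr <- 0L
  seen_ends <- numeric(0)
  for (ai in seq_along(anchor_dates)) {
    a_date <- anchor_dates[ai]
    own <- if (anchor_kinds[ai] == "fracture") a_date else NA_real_
    other_frac <- if (is.na(own)) frac_dates else frac_dates[frac_dates != own]
    for (k in 0:(max_windows - 1L)) {
      w_end <- a_date - 1 - k * stride_days
      # the span (w_end - history, w_end] holds `history_days` calendar days,
      # the earliest being w_end - history + 1; coverage requires the record
      # to reach back to that first day
      if (first_dx > w_end - history_days + 1) next # incomplete coverage
      if (length(other_frac) > 0L &&
          any(other_frac > w_end - history_days &
              other_frac <= w_end + horizon_days)) next # overlapping coverage
      if (w_end %in% seen_ends) next # per-patient de-duplication
      lohi <- findInterval(c(w_end - history_days, w_end), dx_dates)
      i1 <- lohi[1] + 1L
      i2 <- lohi[2]
      codes <- if (i2 >= i1) dx_codes[i1:i2] else character(0)
      label <- any(frac_dates > w_end & frac_dates <= w_end + horizon_days)
      nr <- nr + 1L
      seen_ends <- c(seen_ends, w_end)
      rows[[nr]] <- list(
        patient_id = pid, anchor_date = a_date, anchor_kind = anchor_kinds[ai],
        anchor_site = anchor_sites[ai], is_subsequent = anchor_subseq[ai],
        window_end = w_end, label = label, time_to_event = a_date - w_end,
        age = if (is.na(birth_date)) NA_real_ else (w_end - birth_date) / 365.25,
        sex = sex, dx_count = length(codes), codes = list(codes))
    }
  }
  if (nr == 0L) return(NULL)
  data.table::rbindlist(rows[seq_len(nr)])
}

#' Build labeled sliding windows for eligible anchors
#'
#' Implements the sliding-window construction: each anchor event yields up
#' to `max_windows` candidate windows ending at
#' `anchor - 1 - k * stride_days` (`k = 0, 1, ...`), each covering the
#' `history_days` (default 730) before its end. A candidate is dropped when
#' the patient's first diagnosis falls inside the span (incomplete
#' coverage), or when a different qualifying fracture of the same patient
#' falls inside the span or the prediction horizon after it (ambiguous,
#' potentially overlapping coverage). A window is labeled positive iff a
#' qualifying fracture occurs within `(window_end, window_end +
#' horizon_days]` -- so candidates further than the horizon before a
#' fracture anchor carry a nonfracture label. Window ends are de-duplicated
#' per patient.
#'
#' @param anchors eligible anchors from [select_cohort()].
#' @param cohort the `ehr_cohort`.
#' @param fractures qualifying fracture table from [qualify_fractures()].
#' @param horizon_days prediction horizon (default 730; 365 supported).
#' @param max_windows maximum windows per anchor (default 5).
#' @param stride_days spacing between consecutive window ends (default 183).
#' @param history_days history span covered by each window (default 730).
#' @param cohort_tag `"pan_therapeutic"` or `"bone_health"` provenance tag.
#' @return a windows `data.table`; `codes` is a list column of
#'   chronologically ordered token vectors.
#' @export
build_all_windows <- function(anchors, cohort, fractures, horizon_days = 730L,
                              max_windows = 5L, stride_days = 183L,
                              history_days = 730L,
                              cohort_tag = "pan_therapeutic") {
  stopifnot(max_windows >= 1L, stride_days >= 1L)
  dx <- cohort$diagnoses
  demo <- cohort$demographics
  frac_by_pid <- split(as.numeric(fractures$date), fractures$patient_id)
  out <- vector("list", length(unique(anchors$patient_id)))
  j <- 0L
  pids <- unique(anchors$patient_id)
  dx_split <- dx[patient_id %in% pids]
  dx_list <- split(dx_split[, .(date = as.numeric(date), code)],
                   dx_split$patient_id)
  demo_sub <- demo[patient_id %in% pids]
  birth_by_pid <- stats::setNames(as.numeric(demo_sub$birth_date),
                                  demo_sub$patient_id)
  sex_by_pid <- stats::setNames(demo_sub$sex, demo_sub$patient_id)
  anch_list <- split(anchors, anchors$patient_id)
  for (pid in names(anch_list)) {
    an <- anch_list[[pid]]
    pdx <- dx_list[[pid]]
    if (is.null(pdx) || nrow(pdx) == 0L) next
    res <- windows_for_patient(
      pid, as.numeric(an$date), an$kind, an$site, an$is_subsequent,
      pdx$date, pdx$code, frac_by_pid[[pid]] %||% numeric(0),
      birth_by_pid[[pid]], sex_by_pid[[pid]], cohort_tag,
      horizon_days, max_windows, stride_days, history_days)
    if (!is.null(res)) {
      j <- j + 1L
      out[[j]] <- res
    }
  }
  if (j == 0L) {
    return(data.table::data.table(
      window_id = character(), patient_id = character(),
      anchor_date = as_idate(integer(0)), anchor_kind = character(),
      anchor_site = character(), is_subsequent = logical(),
      window_end = as_idate(integer(0)), label = logical(),
      time_to_event = numeric(0), age = numeric(0), sex = character(),
      dx_count = integer(0), cohort_tag = character(), codes = list(),
      origin = character()))
  }
  w <- data.table::rbindlist(out[seq_len(j)])
  w[, `:=`(anchor_date = as_idate(as.integer(anchor_date)),
           window_end = as_idate(as.integer(window_end)),
           cohort_tag = cohort_tag,
           origin = "native")]
  w[, window_id := sprintf("%s@%s", patient_id, format(window_end))]
  data.table::setcolorder(w, c("window_id", "patient_id", "anchor_date",
                               "anchor_kind", "anchor_site", "is_subsequent",
                               "window_end", "label", "time_to_event", "age",
                               "sex", "dx_count", "cohort_tag", "codes",
                               "origin"))
  data.table::setorder(w, patient_id, window_end)
  w[]
}

#' Build windows for a single anchor of one patient record
#'
#' @param anchor one-row anchor table (`date`, `kind`, `site`,
#'   `is_subsequent`).
#' @param record a `patient_record`.
#' @param fractures that patient's qualifying fracture table.
#' @inheritParams build_all_windows
#' @return windows `data.table` for this anchor.
#' @export
build_windows <- function(anchor, record, fractures, horizon_days = 730L,
                          max_windows = 5L, stride_days = 183L,
                          history_days = 730L,
                          cohort_tag = "pan_therapeutic") {
  res <- windows_for_patient(
    record$patient_id, as.numeric(anchor$date), anchor$kind, anchor$site,
    anchor$is_subsequent, as.numeric(record$diagnoses$date),
    record$diagnoses$code, as.numeric(fractures$date),
    as.numeric(record$birth_date), record$sex, cohort_tag,
    horizon_days, max_windows, stride_days, history_days)
  if (is.null(res)) return(res)
  res[, `:=`(anchor_date = as_idate(as.integer(anchor_date)),
             window_end = as_idate(as.integer(window_end)),
             cohort_tag = cohort_tag, origin = "native")]
  res[, window_id := sprintf("%s@%s", patient_id, format(window_end))]
  res[]
}

#' Build the diagnosis-code vocabulary
#'
#' Counts token occurrences across the reference windows and keeps tokens
#' occurring at least `min_count` times. Indices are contiguous from 1 in
#' frequency-then-lexicographic order; tokens below the threshold map to
#' the unknown token (index 0, zero embedding vector) downstream.
#'
#' @param windows windows table (uses the `codes` list column).
#' @param min_count minimum corpus frequency (default 5).
#' @return a `vocabulary` object.
#' @export
build_vocabulary <- function(windows, min_count = 5L) {
  toks <- unlist(windows$codes, use.names = FALSE)
  if (length(toks) == 0L) stopf("cannot build a vocabulary from an empty corpus")
  tab <- table(toks)
  counts <- as.integer(tab)
  tokens <- names(tab)
  keep <- counts >= min_count
  tokens <- tokens[keep]
  counts <- counts[keep]
  ord <- order(-counts, tokens)
  tokens <- tokens[ord]
  counts <- counts[ord]
  structure(list(tokens = tokens, counts = counts,
                 index = stats::setNames(seq_along(tokens), tokens),
                 min_count = as.integer(min_count),
                 pad_token = "<pad>", unknown_token = "<unk>"),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary> %d tokens (min_count %d)\n",
              length(x$tokens), x$min_count))
  invisible(x)
}

# token -> integer index; 0 for out-of-vocabulary (unknown)
token_indices <- function(vocab, tokens) {
  idx <- vocab$index[tokens]
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Patient-level train/holdout split
#'
#' Randomly partitions patients (never windows) into train and holdout
#' sides, so no patient contributes windows to both. The holdout side keeps
#' its natural class distribution.
#'
#' @param windows windows table.
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return a `split_plan` with `train_patients` and `holdout_patients`.
#' @export
split_train_holdout <- function(windows, ratio = 0.7, seed = 1L) {
  patients <- sort(unique(windows$patient_id))
  n_train <- round(ratio * length(patients))
  train <- with_seed(seed, sort(sample(patients, n_train)))
  structure(list(train_patients = train,
                 holdout_patients = setdiff(patients, train),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d holdout patients (ratio %.2f, seed %d)\n",
              length(x$train_patients), length(x$holdout_patients),
              x$ratio, x$seed))
  invisible(x)
}

#' Balance a training set by oversampling fracture windows
#'
#' Appends fracture (positive) windows sampled from the bone-health pool
#' until the positive count equals the negative count (sampling with
#' replacement when the pool is smaller than the deficit). Appended rows
#' carry `origin = "oversampled"`; the holdout set is never touched.
#'
#' @param train_windows training windows.
#' @param pool positive bone-health windows to sample from.
#' @param seed integer seed.
#' @return the balanced training table.
#' @export
oversample_balance <- function(train_windows, pool, seed = 1L) {
  n_pos <- sum(train_windows$label)
  n_neg <- sum(!train_windows$label)
  deficit <- n_neg - n_pos
  if (deficit <= 0L) return(data.table::copy(train_windows))
  if (nrow(pool) == 0L) {
    stopf("training set is imbalanced (%d positives, %d negatives) but the oversampling pool is empty",
          n_pos, n_neg)
  }
  if (any(!pool$label)) stopf("oversampling pool must contain only positive windows")
  idx <- with_seed(seed, sample(nrow(pool), deficit, replace = deficit > nrow(pool)))
  extra <- pool[idx]
  extra[, origin := "oversampled"]
  out <- rbind(train_windows, extra, use.names = TRUE)
  out[]
}
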