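# Synthetic EHR cohort generator. Emulates the statistical structure the
# pipeline assumes -- a pan-therapeutic population with ~8.5% fracture
# incidence among over-50s and a bone-health population with ~39% -- with
# multi-year Zipf-distributed code streams, risk-signal codes enriched in a
# lead window before each fracture, and bone-health interventions injected
# before a configurable fraction of fractures.

synthetic_sites <- c("hip", "vertebral", "wrist/forearm", "humerus", "pelvis")

# initial-encounter and follow-up (7th character D) codes per site; the
# follow-up codes exercise the aftercare rule, the extra same-site initial
# code exercises the washout rule
site_initial_codes <- c(
  "hip" = "ICD10:S72.001A", "vertebral" = "ICD10:S22.000A",
  "wrist/forearm" = "ICD10:S52.501A", "humerus" = "ICD10:S42.201A",
  "pelvis" = "ICD10:S32.301A")
site_followup_codes <- c(
  "hip" = "ICD10:S72.001D", "vertebral" = "ICD10:S22.000D",
  "wrist/forearm" = "ICD10:S52.501D", "humerus" = "ICD10:S42.201D",
  "pelvis" = "ICD10:S32.301D")

synthetic_pharma_drugs <- c(
  "alendronate", "risedronate", "ibandronate", "zoledronic acid", "denosumab",
  "teriparatide", "raloxifene", "romosozumab", "abaloparatide", "calcitonin")
synthetic_proc_tokens <- c("CPT:77080", "CPT:77081", "CPT:77078", "CPT:76977",
                           "CPT:82523")
synthetic_dx_tokens <- c("ICD10:M81.0", "ICD9:733.01")
synthetic_benign_drugs <- c("lisinopril", "metformin", "atorvastatin",
                            "amlodipine", "omeprazole")

#' Default pre-fracture signal codes
#'
#' Eight mid-frequency background tokens whose occurrence rate is multiplied
#' in the lead window before each scheduled fracture. Multiplier 6 gives a
#' clearly recoverable (but not separable) sequence signal.
#'
#' @param vocabulary_size size of the background vocabulary.
#' @param multiplier relative-risk multiplier applied in the lead window.
#' @return named numeric vector token -> multiplier.
#' @export
default_signal_codes <- function(vocabulary_size = 2000L, multiplier = 6) {
  stats::setNames(rep(multiplier, 8L), sprintf("SYN:%04d", 21:28))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults are the study conditions the pipeline targets: a pan-therapeutic
#' cohort calibrated to 8.5% fracture incidence among over-50s (or 39% for
#' the bone-health cohort), a 2007-2018 study period, a mean of 12 coded
#' events per patient-year over a 2,000-token Zipf vocabulary, and a
#' 540-day pre-fracture signal lead time.
#'
#' @param n_patients number of patients.
#' @param cohort_kind `"pan_therapeutic"` or `"bone_health"`; sets the
#'   default target incidence (0.085 / 0.39).
#' @param study_period length-2 date vector.
#' @param mean_events_per_patient_year mean background coding rate.
#' @param vocabulary_size number of background tokens (Zipf-distributed).
#' @param target_fracture_incidence proportion of anchor events that are
#'   qualifying fractures among patients over 50; must lie in \[0, 1\].
#' @param signal_codes named numeric vector token -> relative-risk
#'   multiplier active in the pre-fracture lead window; a multiplier of 1
#'   disables the signal.
#' @param signal_lead_time days before a fracture in which signal codes are
#'   up-weighted.
#' @param intervention_rate proportion of fracture events preceded by a
#'   bone-health intervention.
#' @param background_intervention_rate proportion of non-fracture patients
#'   given an intervention at a random date.
#' @param subsequent_fracture_prob probability a fracture patient suffers a
#'   second (different-site) fracture 200-1400 days later.
#' @param subsequent_signal_boost extra multiplier on the signal injection
#'   before subsequent (second) fractures.
#' @param age_effect log relative risk of fracture per decade of age.
#' @param sex_effect log relative risk for female sex.
#' @param frailty_sd standard deviation of the lognormal patient frailty.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   cohorts.
#' @return a validated `generator_config`.
#' @export
generator_config <- function(n_patients,
                             cohort_kind = c("pan_therapeutic", "bone_health"),
                             study_period = c("2007-01-01", "2018-12-31"),
                             mean_events_per_patient_year = 12,
                             vocabulary_size = 2000L,
                             target_fracture_incidence = NULL,
                             signal_codes = default_signal_codes(vocabulary_size),
                             signal_lead_time = 540L,
                             intervention_rate = 0.3,
                             background_intervention_rate = 0.05,
                             subsequent_fracture_prob = 0.15,
                             subsequent_signal_boost = 1,
                             age_effect = 0.45,
                             sex_effect = 0.3,
                             frailty_sd = 0.3,
                             seed = 1L) {
  cohort_kind <- match.arg(cohort_kind)
  target_fracture_incidence <- target_fracture_incidence %||%
    switch(cohort_kind, pan_therapeutic = 0.085, bone_health = 0.39)
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0) {
    stopf("n_patients must be a single non-negative integer")
  }
  if (target_fracture_incidence < 0 || target_fracture_incidence > 1) {
    stopf("target_fracture_incidence must lie in [0, 1]")
  }
  if (vocabulary_size < 30L) stopf("vocabulary_size must be at least 30")
  if (mean_events_per_patient_year <= 0) {
    stopf("mean_events_per_patient_year must be positive")
  }
  if (length(signal_codes) > 0 &&
      (is.null(names(signal_codes)) || any(!nzchar(names(signal_codes))))) {
    stopf("signal_codes must be a named vector token -> multiplier")
  }
  structure(list(
    n_patients = as.integer(n_patients), cohort_kind = cohort_kind,
    study_period = as.character(study_period),
    mean_events_per_patient_year = mean_events_per_patient_year,
    vocabulary_size = as.integer(vocabulary_size),
    target_fracture_incidence = target_fracture_incidence,
    signal_codes = signal_codes, signal_lead_time = as.integer(signal_lead_time),
    intervention_rate = intervention_rate,
    background_intervention_rate = background_intervention_rate,
    subsequent_fracture_prob = subsequent_fracture_prob,
    subsequent_signal_boost = subsequent_signal_boost,
    age_effect = age_effect, sex_effect = sex_effect, frailty_sd = frailty_sd,
    seed = as.integer(seed)),
    class = "generator_config")
}

empty_synthetic_cohort <- function(config) {
  structure(list(
    diagnoses = data.table::data.table(patient_id = character(),
                                       date = as_idate(integer(0)),
                                       code = character()),
    medications = data.table::data.table(patient_id = character(),
                                         date = as_idate(integer(0)),
                                         drug = character()),
    demographics = data.table::data.table(patient_id = character(),
                                          birth_date = as_idate(integer(0)),
                                          sex = character()),
    fracture_schedule = data.table::data.table(patient_id = character(),
                                               date = as_idate(integer(0)),
                                               site = character(),
                                               is_subsequent = logical()),
    intervention_schedule = data.table::data.table(patient_id = character(),
                                                   date = as_idate(integer(0)),
                                                   kind = character(),
                                                   item = character(),
                                                   pharmacologic = logical()),
    config = config),
    class = "synthetic_cohort")
}

#' Generate a synthetic EHR cohort
#'
#' Each patient receives an observation window of 5-11 years inside the
#' study period, a birth date placing them at 45-84 years of age at entry
#' (so almost all are over 50 by the time of their anchor event), a Poisson
#' background stream of Zipf-distributed synthetic diagnosis codes, and
#' occasional benign medications. Fractures are scheduled per patient with
#' probability proportional to an age/sex/frailty risk multiplier, rescaled
#' by root-finding so that the expected proportion of qualifying fracture
#' events among over-50 anchor events equals `target_fracture_incidence`.
#' Scheduled fractures inject site-specific initial-encounter codes plus
#' follow-up/aftercare coding; signal codes are up-weighted in the lead
#' window before each fracture, and bone-health interventions
#' (medications, bone-density procedures, osteoporosis diagnoses) are
#' injected before a configurable fraction of fractures.
#'
#' @param config a [generator_config()].
#' @return a `synthetic_cohort`: diagnosis, medication and demographics
#'   tables in the package's schemas, plus the ground-truth fracture and
#'   intervention schedules.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_patients == 0L) return(empty_synthetic_cohort(config))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  sp <- as.numeric(as_idate(config$study_period))
  total_days <- sp[2] - sp[1]

  # observation windows and demographics -------------------------------------
  dur <- pmin(round(runif(n, 5 * 365.25, 11 * 365.25)), total_days - 1)
  obs_start <- sp[1] + floor(runif(n) * (total_days - dur + 1))
  obs_end <- obs_start + dur
  age_start <- runif(n, 45, 84)
  birth <- round(obs_start - age_start * 365.25)
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.55, 0.45))
  pid <- sprintf("P%06d", seq_len(n))

  # candidate fracture dates (drawn for everyone; realised per propensity) ---
  f1 <- obs_start + 760 + floor(runif(n) * pmax(1, dur - 1400))
  has_second <- runif(n) < config$subsequent_fracture_prob
  # inter-fracture gaps straddle the window span (730 d), so some windows of
  # subsequent fractures survive the overlap-drop rule and some are dropped;
  # second fractures must stay inside the study period
  f2 <- f1 + round(runif(n, 200, 1400))
  has_second <- has_second & f2 <= sp[2]
  site1 <- sample(synthetic_sites, n, replace = TRUE)
  shift <- sample.int(length(synthetic_sites) - 1L, n, replace = TRUE)
  site2 <- synthetic_sites[((match(site1, synthetic_sites) - 1L + shift) %%
                              length(synthetic_sites)) + 1L]

  # calibration: solve the scale s so the expected over-50 event-level
  # incidence equals the target, given the realised age/sex/frailty mix
  age_end <- (obs_end - birth) / 365.25
  k50 <- as.numeric((f1 - birth) / 365.25 >= 50) +
    has_second * as.numeric((f2 - birth) / 365.25 >= 50)
  e50 <- as.numeric(age_end >= 50)
  w <- exp(config$age_effect * (age_end - 70) / 10 +
             config$sex_effect * (sex == "female") +
             rnorm(n, 0, config$frailty_sd))
  t_target <- config$target_fracture_incidence
  if (t_target == 0) {
    p <- rep(0, n)
  } else if (t_target == 1) {
    p <- rep(1, n)
  } else {
    a_mult <- 1 + config$subsequent_fracture_prob
    q <- t_target / (a_mult * (1 - t_target) + t_target)
    gap <- function(s) {
      pr <- pmin(s * q * w, 0.98)
      sum(pr * k50) / (sum(pr * k50) + sum((1 - pr) * e50)) - t_target
    }
    s_star <- uniroot(gap, interval = c(1e-9, 1e6), tol = 1e-12)$root
    p <- pmin(s_star * q * w, 0.98)
  }
  is_frac <- runif(n) < p

  # ground-truth fracture schedule -------------------------------------------
  idx1 <- which(is_frac)
  idx2 <- which(is_frac & has_second)
  fracture_schedule <- data.table::data.table(
    patient_id = c(pid[idx1], pid[idx2]),
    date = as_idate(as.integer(c(f1[idx1], f2[idx2]))),
    site = c(site1[idx1], site2[idx2]),
    is_subsequent = c(rep(FALSE, length(idx1)), rep(TRUE, length(idx2))))
  data.table::setorder(fracture_schedule, patient_id, date)

  # background diagnosis stream ----------------------------------------------
  vocab <- sprintf("SYN:%04d", seq_len(config$vocabulary_size))
  zipf_p <- (1 / seq_len(config$vocabulary_size))
  zipf_p <- zipf_p / sum(zipf_p)
  lam <- config$mean_events_per_patient_year * dur / 365.25
  n_ev <- rpois(n, lam)
  zero_ev <- which(n_ev == 0L)
  bg_pid <- rep(pid, n_ev)
  bg_date <- rep(obs_start, n_ev) + floor(runif(sum(n_ev)) * rep(dur + 1, n_ev))
  bg_code <- sample(vocab, sum(n_ev), replace = TRUE, prob = zipf_p)
  diag_parts <- list(data.table::data.table(patient_id = bg_pid,
                                            date = bg_date, code = bg_code))
  if (length(zero_ev) > 0L) { # guarantee every patient has >= 1 diagnosis
    diag_parts[[length(diag_parts) + 1L]] <- data.table::data.table(
      patient_id = pid[zero_ev], date = obs_end[zero_ev], code = vocab[1])
  }

  # pre-fracture signal-code enrichment --------------------------------------
  sig_tokens <- names(config$signal_codes)
  sig_mult <- as.numeric(config$signal_codes)
  sig_rank <- match(sig_tokens, vocab)
  if (length(sig_tokens) > 0L && anyNA(sig_rank)) {
    stopf("signal code(s) outside the background vocabulary: %s",
          paste(sig_tokens[is.na(sig_rank)], collapse = ", "))
  }
  ev_pid <- fracture_schedule$patient_id
  ev_date <- as.numeric(fracture_schedule$date)
  ev_sub <- fracture_schedule$is_subsequent
  if (length(sig_tokens) > 0L && nrow(fracture_schedule) > 0L &&
      any(sig_mult > 1)) {
    daily <- config$mean_events_per_patient_year / 365.25 * zipf_p[sig_rank]
    lead <- config$signal_lead_time
    boost <- ifelse(ev_sub, config$subsequent_signal_boost, 1)
    nE <- length(ev_date)
    nC <- length(sig_tokens)
    mean_extra <- rep(pmax(0, sig_mult - 1) * daily, each = nE) * lead *
      rep(boost, times = nC)
    extra <- rpois(nE * nC, mean_extra)
    tot <- sum(extra)
    if (tot > 0L) {
      rid <- rep(rep(seq_len(nE), times = nC), extra)
      cidx <- rep(rep(seq_len(nC), each = nE), extra)
      diag_parts[[length(diag_parts) + 1L]] <- data.table::data.table(
        patient_id = ev_pid[rid],
        date = ev_date[rid] - 1 - floor(runif(tot) * lead),
        code = sig_tokens[cidx])
    }
  }

  # fracture coding: initial-encounter code on the event day, aftercare codes
  # a week and three weeks later, and (half the time) a second same-site
  # initial-style code inside the washout
  if (nrow(fracture_schedule) > 0L) {
    init <- site_initial_codes[fracture_schedule$site]
    fup <- site_followup_codes[fracture_schedule$site]
    extra_init <- runif(length(ev_date)) < 0.5
    diag_parts[[length(diag_parts) + 1L]] <- data.table::data.table(
      patient_id = c(ev_pid, ev_pid, ev_pid, ev_pid[extra_init]),
      date = c(ev_date, ev_date + 7, ev_date + 21, ev_date[extra_init] + 35),
      code = c(init, fup, fup, init[extra_init]))
  }

  # interventions -------------------------------------------------------------
  iv_pid <- character(0); iv_date <- numeric(0)
  iv_kind <- character(0); iv_item <- character(0)
  if (nrow(fracture_schedule) > 0L && config$intervention_rate > 0) {
    sel <- runif(length(ev_date)) < config$intervention_rate
    if (any(sel)) {
      m <- sum(sel)
      kind <- sample(c("med", "proc", "dx"), m, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
      item <- character(m)
      item[kind == "med"] <- sample(synthetic_pharma_drugs, sum(kind == "med"),
                                    replace = TRUE)
      item[kind == "proc"] <- sample(synthetic_proc_tokens, sum(kind == "proc"),
                                     replace = TRUE)
      item[kind == "dx"] <- sample(synthetic_dx_tokens, sum(kind == "dx"),
                                   replace = TRUE)
      iv_pid <- ev_pid[sel]
      iv_date <- ev_date[sel] - round(runif(m, 30, 600))
      iv_kind <- kind
      iv_item <- item
    }
  }
  nonfrac_idx <- which(!is_frac)
  if (length(nonfrac_idx) > 0L && config$background_intervention_rate > 0) {
    sel <- nonfrac_idx[runif(length(nonfrac_idx)) <
                         config$background_intervention_rate]
    if (length(sel) > 0L) {
      m <- length(sel)
      kind <- sample(c("med", "proc", "dx"), m, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
      item <- character(m)
      item[kind == "med"] <- sample(synthetic_pharma_drugs, sum(kind == "med"),
                                    replace = TRUE)
      item[kind == "proc"] <- sample(synthetic_proc_tokens, sum(kind == "proc"),
                                     replace = TRUE)
      item[kind == "dx"] <- sample(synthetic_dx_tokens, sum(kind == "dx"),
                                   replace = TRUE)
      iv_pid <- c(iv_pid, pid[sel])
      iv_date <- c(iv_date, obs_start[sel] + 100 +
                     floor(runif(m) * pmax(1, dur[sel] - 200)))
      iv_kind <- c(iv_kind, kind)
      iv_item <- c(iv_item, item)
    }
  }
  intervention_schedule <- data.table::data.table(
    patient_id = iv_pid, date = as_idate(as.integer(iv_date)), kind = iv_kind,
    item = iv_item, pharmacologic = iv_kind == "med")
  data.table::setorder(intervention_schedule, patient_id, date)
  iv_dx <- intervention_schedule[kind %in% c("proc", "dx"),
                                 .(patient_id, date = as.numeric(date),
                                   code = item)]
  if (nrow(iv_dx) > 0L) diag_parts[[length(diag_parts) + 1L]] <- iv_dx

  # medications ---------------------------------------------------------------
  n_med <- rpois(n, dur / 365.25)
  med_pid <- rep(pid, n_med)
  med_date <- rep(obs_start, n_med) + floor(runif(sum(n_med)) * rep(dur + 1, n_med))
  med_drug <- sample(synthetic_benign_drugs, sum(n_med), replace = TRUE)
  medications <- data.table::data.table(patient_id = med_pid, date = med_date,
                                        drug = med_drug)
  iv_med <- intervention_schedule[kind == "med",
                                  .(patient_id, date = as.numeric(date),
                                    drug = item)]
  if (nrow(iv_med) > 0L) medications <- rbind(medications, iv_med)
  medications[, date := as_idate(as.integer(date))]
  medications <- unique(medications, by = c("patient_id", "date", "drug"))
  data.table::setorder(medications, patient_id, date, drug)

  diagnoses <- data.table::rbindlist(diag_parts, use.names = TRUE)
  diagnoses[, date := as_idate(as.integer(date))]
  diagnoses <- unique(diagnoses, by = c("patient_id", "date", "code"))
  data.table::setorder(diagnoses, patient_id, date, code)

  demographics <- data.table::data.table(patient_id = pid,
                                         birth_date = as_idate(as.integer(birth)),
                                         sex = sex)

  structure(list(diagnoses = diagnoses[], medications = medications[],
                 demographics = demographics[],
                 fracture_schedule = fracture_schedule[],
                 intervention_schedule = intervention_schedule[],
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cohort> %s: %d patients, %d diagnoses, ",
                     "%d medications, %d scheduled fractures\n"),
              x$config$cohort_kind, x$config$n_patients, nrow(x$diagnoses),
              nrow(x$medications), nrow(x$fracture_schedule)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of CSV files
#'
#' Emits `diagnoses.csv`, `medications.csv`, `demographics.csv` in the
#' package's ingest schemas plus `ground_truth_fractures.csv` and
#' `ground_truth_interventions.csv`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(cohort$diagnoses, file.path(dir, "diagnoses.csv"), "diagnosis")
  write_events(cohort$medications, file.path(dir, "medications.csv"), "medication")
  write_demographics(cohort$demographics, file.path(dir, "demographics.csv"))
  gt <- data.table::copy(cohort$fracture_schedule)[, date := format(date)]
  data.table::fwrite(gt, file.path(dir, "ground_truth_fractures.csv"))
  gi <- data.table::copy(cohort$intervention_schedule)[, date := format(date)]
  data.table::fwrite(gi, file.path(dir, "ground_truth_interventions.csv"))
  invisible(dir)
}

#' Event-level fracture incidence rate
#'
#' The proportion of anchor events that are qualifying fracture events
#' (patients may contribute multiple fracture events) among patients at
#' least `min_age` years old at the event date.
#'
#' @param anchors anchor table from [anchor_events()].
#' @param demographics demographics table (for ages).
#' @param min_age minimum age in years at the event (default 50).
#' @return proportion in \[0, 1\].
#' @export
incidence_rate <- function(anchors, demographics, min_age = 50) {
  if (nrow(anchors) == 0L) stopf("incidence_rate is undefined: no anchor events")
  x <- merge(anchors, demographics[, .(patient_id, birth_date)],
             by = "patient_id")
  x <- x[!is.na(birth_date) & age_years(birth_date, date) >= min_age]
  if (nrow(x) == 0L) {
    stopf("incidence_rate is undefined: no anchor events at age >= %s", min_age)
  }
  mean(x$kind == "fracture")
}
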