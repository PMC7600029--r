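test_that("cohort selection applies age and history boundaries inclusively", {
  # anchor at age 49.9 excluded; at 50 with 731 days of history included
  co <- make_cohort(
    data.table(patient_id = c("A", "A", "B", "B"),
               date = c("2013-01-01", "2015-06-01", "2013-01-01", "2015-06-01"),
               code = "ICD10:I10"),
    demo = data.table(patient_id = c("A", "B"),
                      birth_date = c("1965-07-10", "1964-01-01"),
                      sex = "female"))
  an <- anchor_events(co, qualify_fractures(co))
  el <- select_cohort(an, co, min_age = 50, min_history_days = 730)
  expect_equal(el$patient_id, "B")
  excl <- attr(el, "exclusions")
  expect_equal(unname(excl["under_age"]), 1L)

  # exactly 730 days of history qualifies; 729 does not
  co2 <- make_cohort(
    data.table(patient_id = c("C", "C", "D", "D"),
               date = c("2013-06-01", "2015-06-01", "2013-06-02", "2015-06-01"),
               code = "ICD10:I10"),
    demo = data.table(patient_id = c("C", "D"),
                      birth_date = "1940-01-01", sex = "male"))
  an2 <- anchor_events(co2, qualify_fractures(co2))
  el2 <- select_cohort(an2, co2)
  expect_equal(el2$patient_id, "C")
})

test_that("window candidates follow the stride/horizon arithmetic", {
  # fracture anchor with >= 4 years of history: 5 windows, the first four
  # inside the horizon (gaps 1, 184, 367, 550) and the fifth outside (733)
  base <- idate("2016-01-01")
  dates <- format(c(base - 1500, base - 1200, base - 900, base - 400, base))
  r <- make_record(dates, c("ICD10:I10", "ICD10:J45", "ICD10:E11.9",
                            "ICD10:K21.9", "ICD10:S72.001A"),
                   birth = "1940-01-01")
  fr <- qualify_fracture_events(r)
  an <- anchor_events_record(r, fr)
  w <- build_windows(an, r, fr)
  expect_equal(nrow(w), 5L)
  expect_setequal(as.numeric(an$date) - as.numeric(w$window_end),
                  c(733, 550, 367, 184, 1))
  expect_equal(w[order(window_end)]$label, c(FALSE, TRUE, TRUE, TRUE, TRUE))

  # minimal history: exactly one window survives
  r2 <- make_record(format(c(base - 730, base)),
                    c("ICD10:I10", "ICD10:S72.001A"), birth = "1940-01-01")
  fr2 <- qualify_fracture_events(r2)
  w2 <- build_windows(anchor_events_record(r2, fr2), r2, fr2)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$window_end, base - 1L)

  # non-fracture anchors only produce negative windows
  r3 <- make_record(format(c(base - 1500, base - 800, base)),
                    rep("ICD10:I10", 3), birth = "1940-01-01")
  fr3 <- qualify_fracture_events(r3)
  w3 <- build_windows(anchor_events_record(r3, fr3), r3, fr3)
  expect_true(all(!w3$label))
})

test_that("windows drop ambiguous coverage and de-duplicate ends", {
  syn <- default_pan_1000()
  co <- assemble_records(syn$diagnoses, syn$medications, syn$demographics)
  fr <- qualify_fractures(co)
  an <- anchor_events(co, fr)
  el <- select_cohort(an, co)
  w <- build_all_windows(el, co, fr)

  # never more than max_windows per anchor; unique ends per patient
  per_anchor <- w[, .N, by = .(patient_id, anchor_date)]
  expect_true(all(per_anchor$N <= 5L))
  expect_false(any(duplicated(w[, .(patient_id, window_end)])))

  # no window's span crosses the patient's first diagnosis date
  first_dx <- co$diagnoses[, .(first = min(date)), by = patient_id]
  wf <- merge(w, first_dx, by = "patient_id")
  expect_true(all(wf$first <= wf$window_end - 729))
  # and every code in a window dates from inside its span
  spot <- wf[seq_len(min(.N, 200))]
  for (i in seq_len(nrow(spot))) {
    pdx <- co$diagnoses[patient_id == spot$patient_id[i] &
                          date > spot$window_end[i] - 730 &
                          date <= spot$window_end[i]]
    expect_equal(spot$codes[[i]], pdx$code)
  }

  # labels equal brute-force recomputation from the ground-truth schedule
  truth <- split(as.numeric(syn$fracture_schedule$date),
                 syn$fracture_schedule$patient_id)
  brute <- mapply(function(pid, wend) {
    fd <- truth[[pid]]
    !is.null(fd) && any(fd > wend & fd <= wend + 730)
  }, w$patient_id, as.numeric(w$window_end))
  expect_equal(w$label, unname(brute))

  # no other fracture intrudes into a window's span or horizon
  ww <- merge(w, syn$fracture_schedule[, .(patient_id, fdate = as.numeric(date))],
              by = "patient_id", allow.cartesian = TRUE)
  ww <- ww[fdate != as.numeric(anchor_date)]
  intrude <- ww[fdate > as.numeric(window_end) - 730 &
                  fdate <= as.numeric(window_end) + 730]
  expect_equal(nrow(intrude), 0L)
})

test_that("vocabulary applies the min-count threshold deterministically", {
  w <- data.table(codes = list(rep("A", 4), c(rep("B", 5), "A" , "C"),
                               c("C", "C", "C", "C")))
  v <- build_vocabulary(w, min_count = 5)
  # brute-force counter over the same corpus
  toks <- unlist(w$codes)
  counts <- table(toks)
  keep <- names(counts)[counts >= 5]
  ord <- order(-counts[keep], keep)
  expect_equal(v$tokens, keep[ord])
  expect_equal(unname(v$index[v$tokens]), seq_along(v$tokens))
  # threshold boundary: 4 occurrences excluded, 5 included
  w2 <- data.table(codes = list(rep("X", 4), rep("Y", 5)))
  v2 <- build_vocabulary(w2)
  expect_equal(v2$tokens, "Y")
  expect_error(build_vocabulary(data.table(codes = list(character(0)))),
               "empty")
})

test_that("the split is by patient, deterministic, and 70:30 by count", {
  w <- data.table(patient_id = rep(sprintf("P%02d", 1:10), each = 3),
                  window_id = sprintf("w%d", 1:30))
  plan <- split_train_holdout(w, 0.7, seed = 4L)
  expect_equal(length(plan$train_patients), 7L)
  expect_equal(length(plan$holdout_patients), 3L)
  plan2 <- split_train_holdout(w, 0.7, seed = 4L)
  expect_identical(plan, plan2)
  for (s in 1:25) {
    p <- split_train_holdout(w, 0.7, seed = s)
    expect_equal(length(intersect(p$train_patients, p$holdout_patients)), 0L)
    expect_setequal(c(p$train_patients, p$holdout_patients), unique(w$patient_id))
  }
})

test_that("oversampling balances the classes exactly", {
  mk <- function(n_pos, n_neg) {
    data.table(patient_id = sprintf("P%d", seq_len(n_pos + n_neg)),
               label = rep(c(TRUE, FALSE), c(n_pos, n_neg)),
               cohort_tag = "pan_therapeutic", origin = "native")
  }
  pool <- data.table(patient_id = sprintf("B%d", 1:40), label = TRUE,
                     cohort_tag = "bone_health", origin = "native")

  # already balanced -> unchanged
  bal <- oversample_balance(mk(5, 5), pool, seed = 1)
  expect_equal(nrow(bal), 10L)

  # 90 negatives + 10 positives -> 80 pool windows appended
  bal <- oversample_balance(mk(10, 90), pool, seed = 1)
  expect_equal(sum(bal$origin == "oversampled"), 80L)
  expect_equal(sum(bal$label), sum(!bal$label))

  # exact 50:50 for arbitrary imbalance (with-replacement when pool is small)
  for (s in 1:10) {
    np <- sample(0:20, 1); nn <- np + sample(1:60, 1)
    bal <- oversample_balance(mk(np, nn), pool, seed = s)
    expect_equal(sum(bal$label), sum(!bal$label))
  }
  expect_error(oversample_balance(mk(2, 8), pool[0], seed = 1), "pool is empty")
  expect_error(oversample_balance(mk(2, 8), mk(0, 5), seed = 1), "positive")
})
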