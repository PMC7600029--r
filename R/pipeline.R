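# End-to-end orchestration: simulate (or ingest), qualify fractures, build
# windows, split, embed, train, predict, evaluate, and run the human-level
# analyses, with per-stage seeds, config-hash-stamped cached artifacts and
# structured stage logging.

#' Pipeline configuration
#'
#' Collects every tunable constant of the experiment in one (YAML-friendly)
#' object. Each stage derives its own seed from `seed` so stages are
#' independently reproducible.
#'
#' @param seed base seed.
#' @param n_patients pan-therapeutic cohort size when simulating.
#' @param n_bone_health bone-health cohort size when simulating.
#' @param min_age cohort minimum age at the anchor (years).
#' @param min_history_days required history before an anchor.
#' @param horizon_days label horizon (730 by default; 365 supported).
#' @param max_windows windows per anchor cap.
#' @param stride_days window-end stride.
#' @param history_days window span.
#' @param min_count vocabulary frequency threshold.
#' @param code_dim,window_dim embedding dimensions.
#' @param split_ratio train fraction of the patient-level split.
#' @param threshold decision threshold for flags.
#' @param embed_epochs,window_embed_epochs embedding training epochs.
#' @param lstm,generator named lists of overrides passed to [train_lstm()]
#'   and [generator_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 4000L,
                            n_bone_health = 2000L, min_age = 50,
                            min_history_days = 730L, horizon_days = 730L,
                            max_windows = 5L, stride_days = 183L,
                            history_days = 730L, min_count = 5L,
                            code_dim = 100L, window_dim = 128L,
                            split_ratio = 0.7, threshold = 0.5,
                            embed_epochs = 5L, window_embed_epochs = 20L,
                            lstm = list(), generator = list()) {
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_bone_health = as.integer(n_bone_health), min_age = min_age,
                 min_history_days = as.integer(min_history_days),
                 horizon_days = as.integer(horizon_days),
                 max_windows = as.integer(max_windows),
                 stride_days = as.integer(stride_days),
                 history_days = as.integer(history_days),
                 min_count = as.integer(min_count),
                 code_dim = as.integer(code_dim),
                 window_dim = as.integer(window_dim),
                 split_ratio = split_ratio, threshold = threshold,
                 embed_epochs = as.integer(embed_epochs),
                 window_embed_epochs = as.integer(window_embed_epochs),
                 lstm = lstm, generator = generator),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Serialise windows to the one-row-per-window CSV schema
#' @param windows windows table.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  out <- data.table::copy(windows)
  out[, codes := vapply(codes, paste, "", collapse = " ")]
  out[, `:=`(anchor_date = format(anchor_date), window_end = format(window_end))]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read windows back from the CSV schema
#' @param path CSV produced by [write_windows()].
#' @return windows table with the `codes` list column restored.
#' @export
read_windows <- function(path) {
  w <- data.table::fread(path, colClasses = list(character = "codes"))
  w[, codes := strsplit(codes, " ", fixed = TRUE)]
  w[, `:=`(anchor_date = as_idate(anchor_date), window_end = as_idate(window_end))]
  w[]
}

# cached stage runner: recompute when the stamped hash changes
run_stage <- function(name, hash, dir, fn, verbose = TRUE) {
  rds <- file.path(dir, paste0(name, ".rds"))
  hfile <- file.path(dir, paste0(name, ".hash"))
  if (file.exists(rds) && file.exists(hfile) &&
      identical(readLines(hfile, warn = FALSE)[1], hash)) {
    if (verbose) message(sprintf("[%s] cached", name))
    return(readRDS(rds))
  }
  if (verbose) message(sprintf("[%s] running", name))
  t0 <- Sys.time()
  res <- fn()
  saveRDS(res, rds)
  writeLines(hash, hfile)
  if (verbose) {
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  res
}

report_to_list <- function(r) {
  if (is.null(r)) return(NULL)
  out <- unclass(r)
  if (!is.null(out$confusion)) out$confusion <- as.list(out$confusion)
  out
}

#' Run the full risk-modelling experiment
#'
#' Executes the stages in dependency order: simulate (or load) the
#' pan-therapeutic and bone-health cohorts, qualify fractures, build
#' eligible windows, split patients 70:30, build the vocabulary and both
#' embeddings from pan-therapeutic training windows, balance the training
#' set by bone-health oversampling, train the two frameworks, both
#' baselines and the ensemble, score the untouched holdout, and produce
#' evaluation plus human-level (cohort and overlap) reports. Artifacts are
#' written under `out_dir` and stamped with a config hash; rerunning with
#' an identical config reuses cached artifacts (changing only `threshold`
#' does not retrain).
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory.
#' @param verbose log stage progress.
#' @return list with the fitted models, holdout predictions, evaluation
#'   reports and human-level reports.
#' @export
run_pipeline <- function(config, out_dir = tempfile("fracrisk_run_"),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sd <- config$seed

  gen_cfg <- function(kind, n, seed) {
    do.call(generator_config,
            c(list(n_patients = n, cohort_kind = kind, seed = seed),
              config$generator))
  }
  data_hash <- config_hash(list(config$n_patients, config$n_bone_health,
                                config$generator, sd))
  cohorts <- run_stage("cohorts", data_hash, out_dir, function() {
    pan <- generate_cohort(gen_cfg("pan_therapeutic", config$n_patients, sd + 1L))
    bone <- generate_cohort(gen_cfg("bone_health", config$n_bone_health, sd + 2L))
    list(pan = pan, bone = bone)
  }, verbose)

  win_hash <- config_hash(list(data_hash, config$min_age, config$min_history_days,
                               config$horizon_days, config$max_windows,
                               config$stride_days, config$history_days))
  windows <- run_stage("windows", win_hash, out_dir, function() {
    build_side <- function(synth, tag) {
      cohort <- assemble_records(synth$diagnoses, synth$medications,
                                 synth$demographics)
      fr <- qualify_fractures(cohort)
      an <- anchor_events(cohort, fr)
      el <- select_cohort(an, cohort, config$min_age, config$min_history_days)
      w <- build_all_windows(el, cohort, fr, config$horizon_days,
                             config$max_windows, config$stride_days,
                             config$history_days, tag)
      list(cohort = cohort, fractures = fr, anchors = an, eligible = el,
           windows = w)
    }
    list(pan = build_side(cohorts$pan, "pan_therapeutic"),
         bone = build_side(cohorts$bone, "bone_health"))
  }, verbose)
  pan_w <- windows$pan$windows

  split_hash <- config_hash(list(win_hash, config$split_ratio, sd))
  plan <- run_stage("split", split_hash, out_dir, function() {
    split_train_holdout(pan_w, config$split_ratio, sd + 3L)
  }, verbose)
  train_w <- pan_w[patient_id %in% plan$train_patients]
  holdout_w <- pan_w[patient_id %in% plan$holdout_patients]

  emb_hash <- config_hash(list(split_hash, config$min_count, config$code_dim,
                               config$window_dim, config$embed_epochs,
                               config$window_embed_epochs))
  emb <- run_stage("embeddings", emb_hash, out_dir, function() {
    vocab <- build_vocabulary(train_w, config$min_count)
    code <- train_code_embedding(train_w, vocab, dim = config$code_dim,
                                 epochs = config$embed_epochs, seed = sd + 4L)
    win <- train_window_embedding(train_w, vocab, dim = config$window_dim,
                                  epochs = config$window_embed_epochs,
                                  seed = sd + 5L)
    list(vocab = vocab, code = code, window = win)
  }, verbose)

  model_hash <- config_hash(list(emb_hash, config$lstm, sd))
  models <- run_stage("models", model_hash, out_dir, function() {
    pool <- windows$bone$windows[label == TRUE]
    balanced <- oversample_balance(train_w, pool, sd + 6L)
    cal_rows <- validation_rows(balanced, 0.1, sd + 11L)
    fit_w <- balanced[setdiff(seq_len(nrow(balanced)), cal_rows)]
    cal_w <- balanced[cal_rows]
    lstm <- do.call(train_lstm,
                    c(list(train_windows = fit_w, code_embedding = emb$code,
                           threshold = config$threshold, seed = sd + 7L),
                      config$lstm))
    gbdt <- train_gbdt(fit_w, emb$window, threshold = config$threshold,
                       seed = sd + 8L)
    b2 <- train_baseline(fit_w, c("age", "sex"), threshold = config$threshold,
                         seed = sd + 9L)
    b3 <- train_baseline(fit_w, c("age", "sex", "dx_count"),
                         threshold = config$threshold, seed = sd + 10L)
    ens <- train_ensemble(lstm, gbdt, cal_w, threshold = config$threshold)
    list(lstm_seq = lstm, gbdt_vec = gbdt, baseline_age_sex = b2,
         baseline_age_sex_count = b3, ensemble = ens,
         balanced_n = nrow(balanced))
  }, verbose)

  pred_hash <- config_hash(list(model_hash, config$threshold))
  model_names <- c("lstm_seq", "gbdt_vec", "baseline_age_sex",
                   "baseline_age_sex_count", "ensemble")
  predictions <- run_stage("predictions", pred_hash, out_dir, function() {
    lapply(stats::setNames(model_names, model_names), function(nm) {
      m <- models[[nm]]
      m$threshold <- config$threshold
      predict(m, holdout_w)
    })
  }, verbose)

  eval_hash <- config_hash(list(pred_hash, "evaluation"))
  reports <- run_stage("evaluation", eval_hash, out_dir, function() {
    lapply(predictions, function(p) {
      evaluate_stratified(p, holdout_w, config$threshold)
    })
  }, verbose)

  hlp_hash <- config_hash(list(pred_hash, "hlp"))
  hlp <- run_stage("human_level", hlp_hash, out_dir, function() {
    lstm <- models$lstm_seq
    lstm$threshold <- config$threshold
    holdout_cohort <- windows$pan$cohort
    ca <- cohort_analysis(holdout_w, predictions$lstm_seq, holdout_cohort)
    ov <- tryCatch(
      overlap_analysis(holdout_cohort, lstm, windows$pan$fractures,
                       horizon_days = config$horizon_days,
                       history_days = config$history_days),
      error = function(e) NULL)
    list(cohort_analysis = ca, overlap_analysis = ov)
  }, verbose)

  write_windows(holdout_w, file.path(out_dir, "holdout_windows.csv"))
  pred_out <- data.table::rbindlist(predictions, idcol = "model")
  data.table::fwrite(pred_out, file.path(out_dir, "predictions.csv"))
  json <- list(
    config_hash = config_hash(unclass(config)),
    evaluation = lapply(reports, function(r) lapply(r, report_to_list)),
    human_level = list(
      cohort_analysis = if (!is.null(hlp$cohort_analysis))
        unclass(hlp$cohort_analysis),
      overlap_analysis = if (!is.null(hlp$overlap_analysis))
        unclass(hlp$overlap_analysis)))
  jsonlite::write_json(json, file.path(out_dir, "reports.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  list(config = config, out_dir = out_dir, windows = windows, plan = plan,
       holdout_windows = holdout_w, embeddings = emb, models = models,
       predictions = predictions, evaluation = reports, human_level = hlp)
}
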