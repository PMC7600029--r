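# The two sequence-based frameworks, the two demographic baselines, and the
# logistic-regression ensemble. All models predict the probability of a
# qualifying fracture within the horizon after a window's end.

sex_numeric <- function(sex) ifelse(sex == "female", 1,
                                    ifelse(sex == "male", 0, NA_real_))

# statics for the neural branch: scaled age, sex one-hot + unknown
# indicator, damped diagnosis count
lstm_statics <- function(windows) {
  cbind(age = windows$age / 100,
        sex_female = as.numeric(windows$sex == "female"),
        sex_unknown = as.numeric(!(windows$sex %in% c("female", "male"))),
        dx_count = log1p(windows$dx_count) / 5)
}

# token index sequences for the recurrent branch; OOV stays as 0 so the
# zero (unknown) vector is fed at that timestep, truncating oldest first
lstm_sequences <- function(windows, vocab, max_len) {
  lapply(windows$codes, function(s) {
    n <- length(s)
    if (n > max_len) s <- s[(n - max_len + 1L):n]
    token_indices(vocab, s)
  })
}

check_trainable <- function(windows) {
  if (nrow(windows) == 0L) stopf("empty training set")
  if (length(unique(windows$label)) < 2L) {
    stopf("training set contains a single class")
  }
}

# patient-level carve-out: returns indices of validation rows
validation_rows <- function(windows, fraction, seed) {
  patients <- sort(unique(windows$patient_id))
  n_val <- max(1L, round(fraction * length(patients)))
  val_p <- with_seed(seed, sample(patients, n_val))
  which(windows$patient_id %in% val_p)
}

#' Train the recurrent (LSTM) sequence classifier
#'
#' Framework 1's back end: the embedded code sequence of each window is
#' consumed by a single LSTM layer; the final hidden state is concatenated
#' with a dense transform of the static features (age, sex, diagnosis
#' count) and passed through a merge layer and sigmoid head. Trained with
#' binary cross-entropy and Adam on the balanced training set; the epoch
#' with the best AUROC on a patient-level validation carve-out is kept.
#' Code embeddings are frozen. Single-threaded, deterministic given the
#' seed.
#'
#' @param train_windows balanced training windows.
#' @param code_embedding a [train_code_embedding()] result.
#' @param hidden LSTM units (default 64).
#' @param dense_statics units of the statics branch (default 32).
#' @param dense_merge units of the merge layer (default 32).
#' @param max_len sequence length cap; older codes are truncated first.
#' @param epochs training epochs (the best validation epoch is kept).
#' @param batch minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction patient fraction carved out for epoch selection.
#' @param threshold decision threshold attached to the model.
#' @param seed integer seed.
#' @return a `risk_model` of kind `"lstm_seq"`.
#' @export
train_lstm <- function(train_windows, code_embedding, hidden = 64L,
                       dense_statics = 32L, dense_merge = 32L, max_len = 200L,
                       epochs = 6L, batch = 32L, lr = 2e-3,
                       val_fraction = 0.1, threshold = 0.5, seed = 1L) {
  check_trainable(train_windows)
  vocab <- code_embedding$vocab
  seqs <- lstm_sequences(train_windows, vocab, max_len)
  statics <- lstm_statics(train_windows)
  labels <- as.numeric(train_windows$label)
  val <- validation_rows(train_windows, val_fraction, seed + 101L)
  train_idx <- setdiff(seq_len(nrow(train_windows)), val)
  fit <- cpp_lstm_train(seqs, code_embedding$matrix, statics, labels,
                        as.integer(train_idx), as.integer(val),
                        as.integer(hidden), as.integer(dense_statics),
                        as.integer(dense_merge), as.integer(epochs),
                        as.integer(batch), lr, as.integer(seed))
  cfg <- list(hidden = as.integer(hidden), dense_statics = as.integer(dense_statics),
              dense_merge = as.integer(dense_merge), max_len = as.integer(max_len),
              epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
              val_fraction = val_fraction, seed = as.integer(seed))
  structure(list(kind = "lstm_seq", fit = fit, embedding = code_embedding,
                 threshold = threshold, config = cfg,
                 config_hash = config_hash(cfg),
                 val_auc = fit$best_val_auc, best_epoch = fit$best_epoch),
            class = "risk_model")
}

xgb_feature_matrix <- function(windows, window_model = NULL, features = NULL,
                               seed = 1L) {
  statics <- cbind(age = windows$age, sex = sex_numeric(windows$sex),
                   dx_count = as.numeric(windows$dx_count))
  if (!is.null(features)) {
    return(statics[, features, drop = FALSE])
  }
  vecs <- infer_window_vectors(window_model, windows$codes, seed = seed)
  colnames(vecs) <- sprintf("wv%03d", seq_len(ncol(vecs)))
  cbind(vecs, statics)
}

# shared xgboost fit with a small AUROC-tuned grid and early stopping
fit_xgb <- function(X, y, val_rows, seed, tuning_grid = NULL,
                    nrounds = 300L) {
  if (is.null(tuning_grid)) {
    tuning_grid <- list(list(max_depth = 3L, eta = 0.1),
                        list(max_depth = 5L, eta = 0.1),
                        list(max_depth = 4L, eta = 0.3))
  }
  train_rows <- setdiff(seq_len(nrow(X)), val_rows)
  dtrain <- xgboost::xgb.DMatrix(X[train_rows, , drop = FALSE],
                                 label = y[train_rows])
  dval <- xgboost::xgb.DMatrix(X[val_rows, , drop = FALSE],
                               label = y[val_rows])
  best <- NULL
  best_auc <- -Inf
  best_params <- NULL
  for (g in tuning_grid) {
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = g$max_depth, eta = g$eta, nthread = 1L,
                   seed = as.integer(seed))
    bst <- with_seed(seed, xgboost::xgb.train(
      params = params, data = dtrain, nrounds = nrounds,
      evals = list(val = dval), early_stopping_rounds = 25L, verbose = 0))
    auc <- xgboost::xgb.attr(bst, "best_score")
    auc <- if (is.null(auc)) -Inf else as.numeric(auc)
    if (auc > best_auc) {
      best_auc <- auc
      best <- bst
      best_params <- g
    }
  }
  list(booster = best, val_auc = best_auc, params = best_params)
}

#' Train the gradient-boosted trees over window embeddings
#'
#' Framework 2's back end: gradient-boosted decision trees over the
#' 128-dimensional inferred window vector plus the static features (age,
#' sex, diagnosis count) -- a 131-feature table. A small hyperparameter
#' grid is tuned for AUROC on a patient-level validation carve-out with
#' early stopping.
#'
#' @param train_windows balanced training windows.
#' @param window_model a [train_window_embedding()] model.
#' @param tuning_grid list of `max_depth`/`eta` combinations to try.
#' @inheritParams train_lstm
#' @return a `risk_model` of kind `"gbdt_vec"`.
#' @export
train_gbdt <- function(train_windows, window_model, val_fraction = 0.1,
                       tuning_grid = NULL, threshold = 0.5, seed = 1L) {
  check_trainable(train_windows)
  X <- xgb_feature_matrix(train_windows, window_model = window_model,
                          seed = seed)
  y <- as.numeric(train_windows$label)
  val <- validation_rows(train_windows, val_fraction, seed + 103L)
  fit <- fit_xgb(X, y, val, seed, tuning_grid)
  cfg <- list(kind = "gbdt_vec", val_fraction = val_fraction,
              seed = as.integer(seed), params = fit$params)
  structure(list(kind = "gbdt_vec", fit = fit$booster,
                 window_model = window_model, feature_names = colnames(X),
                 threshold = threshold, config = cfg,
                 config_hash = config_hash(cfg), val_auc = fit$val_auc),
            class = "risk_model")
}

#' Train a demographic baseline classifier
#'
#' Gradient-boosted trees restricted to the named static features: either
#' age and sex, or age, sex and total diagnosis count. These are the
#' experimental baselines the sequence models are compared against.
#'
#' @param train_windows balanced training windows.
#' @param features `c("age", "sex")` or `c("age", "sex", "dx_count")`.
#' @inheritParams train_gbdt
#' @return a `risk_model` of kind `"baseline_age_sex"` or
#'   `"baseline_age_sex_count"`.
#' @export
train_baseline <- function(train_windows, features = c("age", "sex"),
                           val_fraction = 0.1, tuning_grid = NULL,
                           threshold = 0.5, seed = 1L) {
  stopifnot(all(features %in% c("age", "sex", "dx_count")))
  check_trainable(train_windows)
  kind <- if ("dx_count" %in% features) "baseline_age_sex_count" else
    "baseline_age_sex"
  X <- xgb_feature_matrix(train_windows, features = features)
  y <- as.numeric(train_windows$label)
  val <- validation_rows(train_windows, val_fraction, seed + 107L)
  fit <- fit_xgb(X, y, val, seed, tuning_grid)
  cfg <- list(kind = kind, features = features, val_fraction = val_fraction,
              seed = as.integer(seed), params = fit$params)
  structure(list(kind = kind, fit = fit$booster, features = features,
                 feature_names = colnames(X), threshold = threshold,
                 config = cfg, config_hash = config_hash(cfg),
                 val_auc = fit$val_auc),
            class = "risk_model")
}

#' Train the logistic-regression ensemble
#'
#' Combines the probabilities of the two frameworks with a two-feature
#' logistic regression metaclassifier. The calibration windows should not
#' have been used to fit the base models (e.g. the validation carve-out).
#'
#' @param model_lstm the fitted framework-1 model.
#' @param model_gbdt the fitted framework-2 model.
#' @param calibration_windows windows used to fit the metaclassifier.
#' @param threshold decision threshold attached to the model.
#' @return a `risk_model` of kind `"ensemble"` carrying both base models.
#' @export
train_ensemble <- function(model_lstm, model_gbdt, calibration_windows,
                           threshold = 0.5) {
  check_trainable(calibration_windows)
  p1 <- predict(model_lstm, calibration_windows)$probability
  p2 <- predict(model_gbdt, calibration_windows)$probability
  if (stats::sd(p1) == 0 || stats::sd(p2) == 0) {
    stopf("ensemble inputs are constant; cannot fit the metaclassifier")
  }
  df <- data.frame(y = as.numeric(calibration_windows$label), p1 = p1, p2 = p2)
  fit <- stats::glm(y ~ p1 + p2, family = stats::binomial(), data = df)
  structure(list(kind = "ensemble", fit = fit, base_lstm = model_lstm,
                 base_gbdt = model_gbdt, threshold = threshold,
                 coefficients = stats::coef(fit),
                 config_hash = config_hash(stats::coef(fit))),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> %s (threshold %.3g)", x$kind, x$threshold))
  if (!is.null(x$val_auc) && is.finite(x$val_auc)) {
    cat(sprintf(", validation AUROC %.3f", x$val_auc))
  }
  cat("\n")
  invisible(x)
}

#' Predict fracture risk for windows
#'
#' Returns one probability and flag per window; predictions are
#' deterministic after fitting and independent of batch composition and
#' order.
#'
#' @param object a fitted `risk_model`.
#' @param windows windows table.
#' @param ... unused.
#' @return `data.table` with `window_id`, `probability`,
#'   `flag = probability >= threshold`.
#' @export
predict.risk_model <- function(object, windows, ...) {
  if (nrow(windows) == 0L) {
    return(data.table::data.table(window_id = character(),
                                  probability = numeric(), flag = logical()))
  }
  p <- switch(object$kind,
    lstm_seq = {
      vocab <- object$embedding$vocab
      seqs <- lstm_sequences(windows, vocab, object$config$max_len)
      as.numeric(cpp_lstm_predict(object$fit$theta, object$fit$dims, seqs,
                                  object$embedding$matrix,
                                  lstm_statics(windows)))
    },
    gbdt_vec = {
      X <- xgb_feature_matrix(windows, window_model = object$window_model,
                              seed = object$config$seed)
      predict(object$fit, xgboost::xgb.DMatrix(X))
    },
    baseline_age_sex = ,
    baseline_age_sex_count = {
      X <- xgb_feature_matrix(windows, features = object$features)
      predict(object$fit, xgboost::xgb.DMatrix(X))
    },
    ensemble = {
      p1 <- predict(object$base_lstm, windows)$probability
      p2 <- predict(object$base_gbdt, windows)$probability
      as.numeric(stats::predict(object$fit,
                                newdata = data.frame(p1 = p1, p2 = p2),
                                type = "response"))
    },
    stopf("unknown model kind: %s", object$kind))
  data.table::data.table(window_id = windows$window_id, probability = p,
                         flag = p >= object$threshold)
}
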