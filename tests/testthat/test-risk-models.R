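# a small shared modelling fixture: synthetic windows, vocabulary, both
# embeddings and a balanced training set, built once per test run
model_fixture <- function() {
  if (exists("modelfix", .synth_cache)) return(get("modelfix", .synth_cache))
  syn <- default_pan_1000()
  co <- assemble_records(syn$diagnoses, syn$medications, syn$demographics)
  fr <- qualify_fractures(co)
  w <- build_all_windows(select_cohort(anchor_events(co, fr), co), co, fr)
  plan <- split_train_holdout(w, 0.7, seed = 8L)
  train_w <- w[patient_id %in% plan$train_patients]
  holdout_w <- w[patient_id %in% plan$holdout_patients]
  vocab <- build_vocabulary(train_w)
  emb <- train_code_embedding(train_w, vocab, dim = 24, epochs = 3, seed = 2L)
  wemb <- train_window_embedding(train_w, vocab, dim = 32, epochs = 8,
                                 seed = 2L)
  fix <- list(windows = w, train = train_w, holdout = holdout_w, vocab = vocab,
              emb = emb, wemb = wemb, plan = plan)
  assign("modelfix", fix, .synth_cache)
  fix
}

test_that("gbdt separates a perfectly separable toy problem", {
  fx <- model_fixture()
  toy <- data.table::copy(fx$train)[seq_len(200)]
  toy[, label := rep(c(TRUE, FALSE), 100)]
  toy[, age := ifelse(label, 80, 60)] # single separating feature
  m <- train_baseline(toy, c("age", "sex"), seed = 1L)
  pred <- predict(m, toy)
  cm <- confusion_at_threshold(pred$probability, toy$label, 0.5)
  expect_equal(unname(cm["fn"]), 0L) # training recall 1.0 at threshold 0.5
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
})

test_that("baseline feature sets honour their contracts", {
  fx <- model_fixture()
  b2 <- train_baseline(fx$train, c("age", "sex"), seed = 3L)
  b3 <- train_baseline(fx$train, c("age", "sex", "dx_count"), seed = 3L)
  expect_equal(b2$kind, "baseline_age_sex")
  expect_equal(b3$kind, "baseline_age_sex_count")
  expect_false("dx_count" %in% b2$feature_names)
  expect_true("dx_count" %in% b3$feature_names)
  # age drives the synthetic hazard, so even age+sex beats chance
  pred <- predict(b2, fx$holdout)
  expect_gt(auroc(pred$probability, fx$holdout$label), 0.5)
})

test_that("gbdt over window vectors uses the full 131-feature-style table", {
  fx <- model_fixture()
  m <- train_gbdt(fx$train, fx$wemb, seed = 4L)
  expect_equal(length(m$feature_names), 32L + 3L) # dim + age, sex, dx_count
  pred <- predict(m, fx$holdout)
  expect_true(all(is.finite(pred$probability)))
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
})

test_that("lstm training is deterministic and beats the age/sex baseline here", {
  fx <- model_fixture()
  m1 <- train_lstm(fx$train, fx$emb, hidden = 16, dense_statics = 8,
                   dense_merge = 8, epochs = 2, seed = 5L)
  m2 <- train_lstm(fx$train, fx$emb, hidden = 16, dense_statics = 8,
                   dense_merge = 8, epochs = 2, seed = 5L)
  p1 <- predict(m1, fx$holdout)
  p2 <- predict(m2, fx$holdout)
  expect_identical(p1$probability, p2$probability)
  b2 <- train_baseline(fx$train, c("age", "sex"), seed = 5L)
  pb <- predict(b2, fx$holdout)
  expect_gt(auroc(p1$probability, fx$holdout$label),
            auroc(pb$probability, fx$holdout$label))
})

test_that("degenerate training inputs are rejected", {
  fx <- model_fixture()
  empty <- fx$train[0]
  expect_error(train_lstm(empty, fx$emb), "empty")
  one_class <- fx$train[label == FALSE]
  expect_error(train_lstm(one_class, fx$emb), "single class")
  expect_error(train_gbdt(one_class, fx$wemb), "single class")
  expect_error(train_baseline(fx$train, c("age", "height")), "age")
})

test_that("the ensemble is a sane logistic combination of its bases", {
  fx <- model_fixture()
  m_l <- train_lstm(fx$train, fx$emb, hidden = 16, dense_statics = 8,
                    dense_merge = 8, epochs = 2, seed = 6L)
  m_g <- train_gbdt(fx$train, fx$wemb, seed = 6L)
  ens <- train_ensemble(m_l, m_g, fx$train)
  pe <- predict(ens, fx$holdout)
  expect_true(all(pe$probability >= 0 & pe$probability <= 1))

  # identical base probabilities leave the ranking unchanged (the base must
  # carry real signal on the calibration fold for the sign to be identified)
  ens_same <- train_ensemble(m_g, m_g, fx$train)
  ps <- predict(ens_same, fx$holdout)
  pg <- predict(m_g, fx$holdout)
  expect_equal(auroc(ps$probability, fx$holdout$label),
               auroc(pg$probability, fx$holdout$label))

  # constant inputs are rejected
  const <- structure(list(kind = "lstm_seq"), class = "risk_model")
  expect_error({
    fake1 <- m_l; fake1$fit$theta[] <- 0
    train_ensemble(fake1, fake1, fx$train)
  }, "constant")
})

test_that("ensemble coefficients recover a known logistic mixture", {
  set.seed(99)
  n <- 5000
  p1 <- runif(n); p2 <- runif(n)
  beta <- c(-2, 1.5, 2.5)
  y <- runif(n) < plogis(beta[1] + beta[2] * p1 + beta[3] * p2)
  fit <- glm(y ~ p1 + p2, family = binomial())
  ci <- confint.default(fit)
  expect_true(all(beta >= ci[, 1] & beta <= ci[, 2]))
})

test_that("prediction is order-independent and batch equals single", {
  fx <- model_fixture()
  m <- train_gbdt(fx$train, fx$wemb, seed = 7L)
  h <- fx$holdout[seq_len(30)]
  p <- predict(m, h)
  perm <- sample(nrow(h))
  pp <- predict(m, h[perm])
  expect_equal(pp$probability, p$probability[perm])
  expect_equal(pp$flag, pp$probability >= m$threshold)
  # one at a time
  singles <- vapply(seq_len(10), function(i) {
    predict(m, h[i])$probability
  }, numeric(1))
  expect_equal(singles, p$probability[1:10])

  m_l <- train_lstm(fx$train, fx$emb, hidden = 16, dense_statics = 8,
                    dense_merge = 8, epochs = 1, seed = 7L)
  pl <- predict(m_l, h)
  singles_l <- vapply(seq_len(10), function(i) {
    predict(m_l, h[i])$probability
  }, numeric(1))
  expect_equal(singles_l, pl$probability[1:10])
})

test_that("all models collapse to chance under label shuffling", {
  fx <- model_fixture()
  set.seed(17)
  sh <- data.table::copy(fx$train)
  sh[, label := sample(label)] # shuffled labels, same features
  m <- train_baseline(sh, c("age", "sex", "dx_count"), seed = 9L)
  pred <- predict(m, fx$holdout)
  expect_lt(abs(auroc(pred$probability, sample(fx$holdout$label)) - 0.5), 0.08)
})
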