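test_that("auroc matches hand-computed concordance", {
  # perfect separation
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # positives {0.9, 0.4} vs negatives {0.6, 0.2}: 3 of 4 pairs concordant
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # total ties
  expect_equal(auroc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  # single-class input is an error
  expect_error(auroc(c(0.1, 0.2), c(TRUE, TRUE)), "single-class")
})

test_that("auroc equals the brute-force pairwise oracle on random inputs", {
  set.seed(1203)
  for (rep in 1:30) {
    n <- sample(5:200, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    p <- round(runif(n), sample(c(1, 2, 6), 1)) # coarse rounding forces ties
    expect_equal(auroc(p, y), brute_force_auroc(p, y))
  }
})

test_that("auprc follows step-wise average precision", {
  # perfect ranking
  expect_equal(auprc(c(0.9, 0.8, 0.2), c(TRUE, TRUE, FALSE)), 1)
  # 4-point hand example: AP = (1 * 1 + (2/3) * 1) / 2 = 5/6
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, FALSE, TRUE, FALSE)), 5 / 6)
  # random scores at prevalence pi converge to pi
  set.seed(7)
  y <- runif(20000) < 0.15
  p <- runif(20000)
  expect_lt(abs(auprc(p, y) - 0.15), 0.02)
  expect_error(auprc(c(0.1, 0.9), c(FALSE, FALSE)), "no positive")
})

test_that("ranking metrics are invariant to strictly monotone transforms", {
  set.seed(42)
  p <- runif(300)
  y <- runif(300) < plogis(3 * (p - 0.5))
  y[1:2] <- c(TRUE, FALSE)
  for (f in list(function(x) 10 * x - 2, function(x) x^3, plogis)) {
    expect_equal(auroc(f(p), y), auroc(p, y))
    expect_equal(auprc(f(p), y), auprc(p, y))
  }
})

test_that("confusion counts follow the flag rule", {
  p <- c(0.9, 0.8, 0.7, 0.55, 0.5, 0.4, 0.3, 0.2, 0.15, 0.05)
  y <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)
  # hand tally at 0.5: flags = first five
  expect_equal(confusion_at_threshold(p, y, 0.5),
               c(tp = 3L, fp = 2L, tn = 3L, fn = 2L))
  # threshold 0 flags everything; above 1 flags nothing
  expect_equal(unname(confusion_at_threshold(p, y, 0)[c("tn", "fn")]), c(0L, 0L))
  expect_equal(unname(confusion_at_threshold(p, y, 1 + 1e-9)[c("tp", "fp")]),
               c(0L, 0L))
  # report metrics recompute from its own confusion counts
  r <- evaluate(p, y, 0.5)
  cm <- r$confusion
  expect_equal(r$recall, cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]))
  expect_equal(r$specificity, cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]))
  expect_equal(r$precision, cm[["tp"]] / (cm[["tp"]] + cm[["fp"]]))
  expect_equal(sum(cm), r$n)
})

test_that("label permutation drives auroc to chance", {
  set.seed(11)
  p <- runif(2000)
  y <- runif(2000) < plogis(4 * (p - 0.5))
  expect_gt(auroc(p, y), 0.7)
  aucs <- replicate(100, auroc(p, sample(y)))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)
  expect_lt(abs(auroc(p, sample(y)) - 0.5), 3 * sd(aucs) + 0.02)
})

test_that("stratified evaluation partitions positives and shares negatives", {
  w <- data.table(
    window_id = sprintf("w%d", 1:12),
    label = rep(c(TRUE, FALSE), each = 6),
    is_subsequent = c(rep(FALSE, 3), rep(TRUE, 3), rep(FALSE, 6)))
  set.seed(3)
  pred <- data.table(window_id = w$window_id, probability = runif(12))
  pred[, flag := probability >= 0.5]
  rep3 <- evaluate_stratified(pred, w, 0.5)
  cm_all <- rep3$overall$confusion
  cm_pri <- rep3$primary$confusion
  cm_sub <- rep3$subsequent$confusion
  # positives partition across strata; negatives join both
  expect_equal(cm_pri[["tp"]] + cm_pri[["fn"]] + cm_sub[["tp"]] + cm_sub[["fn"]],
               cm_all[["tp"]] + cm_all[["fn"]])
  expect_equal(cm_pri[["tn"]] + cm_pri[["fp"]], cm_all[["tn"]] + cm_all[["fp"]])
  expect_equal(cm_sub[["tn"]] + cm_sub[["fp"]], cm_all[["tn"]] + cm_all[["fp"]])
})

test_that("stronger subsequent-fracture signal yields higher subsequent AUROC", {
  # generator with boosted signal before subsequent fractures
  cfg <- generator_config(n_patients = 2500, seed = 909L,
                          subsequent_fracture_prob = 0.35,
                          subsequent_signal_boost = 4)
  syn <- generate_cohort(cfg)
  co <- assemble_records(syn$diagnoses, syn$medications, syn$demographics)
  fr <- qualify_fractures(co)
  w <- build_all_windows(select_cohort(anchor_events(co, fr), co), co, fr)
  # score windows by their signal-code count (a direct proxy classifier)
  sig <- names(default_signal_codes())
  score <- vapply(w$codes, function(s) sum(s %in% sig), 1L)
  pred <- data.table(window_id = w$window_id, probability = score / max(score))
  rep3 <- evaluate_stratified(pred, w, 0.5)
  expect_gt(rep3$subsequent$auroc, rep3$primary$auroc)
})
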