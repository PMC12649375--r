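test_that("SMOTE balances classes by convex interpolation", {
  # already balanced: unchanged
  X <- matrix(rnorm(20), ncol = 2)
  y <- rep(c(0, 1), each = 5)
  out <- smote_balance(X, y, seed = 1)
  expect_identical(out$X, X)
  expect_equal(out$n_synthetic, 0L)

  # minority {(0,0), (1,1)}: synthetic points lie on the segment
  X2 <- rbind(matrix(rnorm(24, 10), ncol = 2), c(0, 0), c(1, 1))
  y2 <- c(rep(0, 12), 1, 1)
  out2 <- smote_balance(X2, y2, seed = 2)
  expect_equal(sum(out2$y == 1), 12)
  synth <- out2$X[(nrow(X2) + 1):nrow(out2$X), , drop = FALSE]
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth >= 0 & synth <= 1))
  expect_equal(out2$k_used, 1L)  # min(3, minority - 1)

  # 30 minority / 52 majority -> 52/52 with 22 synthetic rows
  set.seed(3)
  X3 <- matrix(rnorm(82 * 4), ncol = 4)
  y3 <- c(rep(1, 30), rep(0, 52))
  out3 <- smote_balance(X3, y3, seed = 3)
  expect_equal(as.vector(table(out3$y)), c(52, 52))
  expect_equal(out3$n_synthetic, 22L)
  expect_equal(out3$k_used, 3L)

  expect_error(smote_balance(X3, rep(0, 82)), "both classes")
  expect_error(smote_balance(X3, c(1, rep(0, 81))), "fewer than 2")
})

test_that("metrics match the confusion-matrix oracle", {
  m <- compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0),
                       c(0.9, 0.4, 0.3, 0.2))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$roc_auc, 1)      # probabilities rank perfectly
  expect_equal(m$aupr, 1)

  # constant probabilities: rank ties give AUC 0.5
  m2 <- suppressWarnings(compute_metrics(c(1, 0, 1, 0), c(0, 0, 0, 0),
                                         rep(0.5, 4)))
  expect_equal(m2$roc_auc, 0.5)
  expect_equal(m2$precision, 0)   # no positive predictions, warned
  expect_warning(compute_metrics(c(1, 0), c(0, 0), c(0.1, 0.2)),
                 "precision")

  # single-class truth: threshold-free metrics undefined, not zero
  m3 <- compute_metrics(c(1, 1), c(1, 1), c(0.9, 0.8))
  expect_true(is.na(m3$roc_auc))
})

test_that("rank AUC and step AUPR agree with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:5) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    pr <- runif(40)
    m <- suppressWarnings(compute_metrics(y, as.integer(pr >= 0.5), pr))
    ref <- as.numeric(pROC::auc(pROC::roc(y, pr, quiet = TRUE,
                                          direction = "<")))
    expect_equal(m$roc_auc, ref, tolerance = 1e-10)
  }
})

test_that("stratified folds partition subjects and preserve class balance", {
  y <- c(rep(0, 23), rep(1, 17))
  f <- stratified_folds(y, 5, seed = 4)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 40)
  for (k in 1:5) {
    expect_gte(sum(y[f == k] == 0), 4)
    expect_gte(sum(y[f == k] == 1), 3)
  }
  expect_error(stratified_folds(c(0, 0, 1), 5), "at least as many")
})

test_that("cross-validation separates separable data and covers all subjects", {
  sep <- separable_features(n_per_class = 15, p = 5, gap = 6, seed = 9)
  cfg <- cv_config(classifiers = c("RF", "LR", "KNN"), repeats = 2,
                   seed = 5)
  sel <- selection_config(max_keep = 5, rf_trees = 100)
  ev <- suppressWarnings(run_cv(sep$X, sep$y, cfg, sel))
  auc <- ev$pooled$mean[ev$pooled$metric == "roc_auc"]
  expect_gte(auc, 0.95)

  # every subject appears exactly once per classifier per repeat
  counts <- table(ev$oof$subject_id, ev$oof$classifier, ev$oof$repeat_)
  expect_true(all(counts == 1))

  # determinism: identical config and seed reproduce the report
  ev2 <- suppressWarnings(run_cv(sep$X, sep$y, cfg, sel))
  expect_equal(ev2$pooled, ev$pooled)
  expect_equal(ev2$oof, ev$oof)
})

test_that("label-permuted features yield chance-level AUC", {
  set.seed(21)
  aucs <- vapply(1:6, function(s) {
    X <- matrix(rnorm(40 * 5), ncol = 5,
                dimnames = list(sprintf("S%02d", 1:40),
                                paste0("f", 1:5)))
    y <- sample(rep(0:1, each = 20))
    cfg <- cv_config(classifiers = c("RF", "LR"), repeats = 1, seed = s)
    ev <- suppressWarnings(run_cv(X, y, cfg,
                                  selection_config(rf_trees = 100)))
    ev$pooled$mean[ev$pooled$metric == "roc_auc"]
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("fold preparation depends only on training rows (leakage guard)", {
  for (s in 1:3) {
    sep <- separable_features(n_per_class = 12, p = 6, gap = 2,
                              seed = s + 40)
    train_idx <- 1:18
    base <- prepare_fold(sep$X, sep$y, train_idx,
                         selection_config(rf_trees = 100), seed = s)
    # arbitrarily corrupt the held-out rows: prepared output identical
    X2 <- sep$X
    X2[19:24, ] <- 1e6
    mod <- prepare_fold(X2, sep$y, train_idx,
                        selection_config(rf_trees = 100), seed = s)
    expect_identical(mod$selected, base$selected)
    expect_identical(mod$X_train, base$X_train)
    expect_identical(mod$y_train, base$y_train)
  }
})
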