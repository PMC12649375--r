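test_that("top-5 type frequency counts and tie-breaking", {
  # one model whose top 5 are all DTW-named
  v <- setNames(c(5, 4, 3, 2, 1, 0.5, 0.1),
                c(paste0("DTW-COP-", c("LX", "LY", "RX", "RY", "CX")),
                  "LSTM-COP-CX-1", "cv_COP-CX"))
  s1 <- top5_type_frequency(list(M = v))
  expect_equal(as.vector(s1$type_frequency),
               c(5, 0, 0))

  # four models each with 2 DTW in the top 5 -> DTW frequency 8
  v2 <- setNames(c(9, 8, 3, 2.5, 2, 1, 0.5),
                 c("DTW-COP-CX", "DTW-COP-CY", "slope_COP-CX",
                   "slope_COP-CY", "iqr_COP-LX", "LSTM-COP-LX-1",
                   "DTW-COP-LX"))
  s2 <- top5_type_frequency(list(A = v2, B = v2, C = v2, D = v2))
  expect_equal(as.vector(s2$type_frequency["DTW"]), 8)
  expect_equal(sum(s2$type_frequency), 20)

  # ties broken lexicographically, stable across calls
  vt <- setNames(rep(1, 6), c("b", "a", "f", "d", "c", "e"))
  st <- top5_type_frequency(list(M = vt))
  expect_equal(st$per_model_top5$M, c("a", "b", "c", "d", "e"))
  expect_identical(top5_type_frequency(list(M = vt))$per_model_top5,
                   st$per_model_top5)

  # negative attributions rank by magnitude
  vn <- setNames(c(-10, 1, 2, 3, 4, 0.5), paste0("x", 1:6))
  expect_true("x1" %in% top5_type_frequency(list(M = vn))$per_model_top5$M)

  expect_warning(top5_type_frequency(list(M = vt[1:3])), "fewer than 5")
})

test_that("Spearman correlations match the rank-formula oracle", {
  f <- data.frame(feat = c(1, 2, 3, 4), row.names = sprintf("S%d", 1:4))
  cl <- data.frame(ind = c(2, 1, 4, 3), row.names = sprintf("S%d", 1:4))
  res <- clinical_correlations(f, cl)
  expect_equal(res$rho, 0.6)  # 1 - 6*sum(d^2)/(n(n^2-1)) with d^2 sum 4
  expect_equal(res$n, 4)

  # perfect monotone increasing / decreasing
  f2 <- data.frame(feat = exp(1:6), row.names = sprintf("S%d", 1:6))
  cl2 <- data.frame(up = 1:6, down = 6:1,
                    row.names = sprintf("S%d", 1:6))
  res2 <- clinical_correlations(f2, cl2)
  expect_equal(res2$rho[res2$indicator == "up"], 1)
  expect_equal(res2$rho[res2$indicator == "down"], -1)

  # p-value agrees with cor.test's t approximation
  set.seed(13)
  x <- rnorm(20); z <- x + rnorm(20)
  f3 <- data.frame(feat = x, row.names = sprintf("S%02d", 1:20))
  cl3 <- data.frame(ind = z, row.names = sprintf("S%02d", 1:20))
  res3 <- clinical_correlations(f3, cl3)
  ref <- suppressWarnings(cor.test(x, z, method = "spearman"))
  expect_equal(res3$rho, unname(ref$estimate), tolerance = 1e-12)

  # pairwise deletion: missing values reduce n; < 3 pairs skipped
  cl4 <- data.frame(ind = c(1, 2, NA, 4, NA, 6),
                    row.names = sprintf("S%d", 1:6))
  res4 <- clinical_correlations(f2, cl4)
  expect_equal(res4$n, 4)
  cl5 <- data.frame(ind = c(1, 2, rep(NA, 4)),
                    row.names = sprintf("S%d", 1:6))
  expect_null(clinical_correlations(f2, cl5))
})

fake_eval <- function(probs_by_subject, labels) {
  oof <- data.frame(subject_id = names(probs_by_subject),
                    label = labels, classifier = "RF", repeat_ = 1,
                    fold = 1, prob = unname(probs_by_subject))
  structure(list(oof = oof), class = "eval_report")
}

test_that("reserve report statistics match direct arithmetic", {
  # {0.4, 0.6}: mean 0.5, population SD 0.1, CV 20%
  ev <- fake_eval(c(A = 0.4, B = 0.6), c(1, 1))
  r <- reserve_report(ev, "ST")
  expect_equal(r$range, c(0.4, 0.6))
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, 0.1)
  expect_equal(r$cv_percent, 20)

  # degenerate distribution
  ev2 <- fake_eval(c(A = 0.5, B = 0.5, C = 0.5), c(1, 1, 1))
  r2 <- reserve_report(ev2, "FT")
  expect_equal(r2$range, c(0.5, 0.5))
  expect_equal(r2$sd, 0)
  expect_equal(r2$cv_percent, 0)

  # controls excluded by default, included with group = "all"
  ev3 <- fake_eval(c(A = 0.8, B = 0.6, C = 0.1), c(1, 1, 0))
  expect_length(reserve_report(ev3, "ST")$probabilities, 2)
  expect_length(reserve_report(ev3, "ST", group = "all")$probabilities, 3)
  ev4 <- fake_eval(c(C = 0.1), 0)
  expect_error(reserve_report(ev4, "ST"), "no sarcopenia")

  # scale consistency of CV (hypothetical rescaling)
  pr <- c(A = 0.2, B = 0.4, C = 0.3)
  cv1 <- reserve_report(fake_eval(pr, c(1, 1, 1)), "ST")$cv_percent
  cv2 <- reserve_report(fake_eval(pr * 2, c(1, 1, 1)), "ST")$cv_percent
  expect_equal(cv1, cv2)
})

test_that("permutation attribution favours the informative feature", {
  sep <- separable_features(n_per_class = 15, p = 5, gap = 5, seed = 17)
  att <- permutation_attribution(sep$X, sep$y,
                                 selected = colnames(sep$X),
                                 classifiers = c("RF", "KNN"), seed = 1,
                                 n_perm = 5)
  expect_named(att, c("RF", "KNN"))
  for (v in att) {
    expect_length(v, 5)
    # the two informative columns carry the top importance
    expect_true(all(names(sort(-v))[1:2] %in% c("feat1", "feat2")))
  }
})
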