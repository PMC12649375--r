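test_that("composite score follows the equal-weight normalized sum", {
  # direct arithmetic: f = [10, 5], p = [0.1, 0.4]
  f <- c(10, 5); p <- c(0.1, 0.4)
  S <- f / max(f) + p / max(p)
  expect_equal(S, c(1.25, 1.5))

  # the feature attaining both maxima scores exactly 2
  sep <- separable_features(n_per_class = 20, p = 4, gap = 6, seed = 3)
  sc <- composite_scores(sep$X, sep$y, selection_config(rf_seed = 1))
  expect_true(all(sc$S >= 0 & sc$S <= 2))
  expect_equal(max(sc$S[sc$f == max(sc$f) & sc$p == max(sc$p)]), 2,
               tolerance = 1e-12)

  # a label-independent feature has f ~ 0, so S ~ p / max(p)
  X0 <- sep$X
  X0[, 3] <- rep(c(1, 2), length.out = nrow(X0))  # same in both classes
  sc0 <- composite_scores(X0, sep$y, selection_config(rf_seed = 1))
  expect_lt(sc0$f[3] / max(sc0$f), 0.01)
  expect_equal(sc0$S[3], sc0$p[3] / max(sc0$p), tolerance = 0.01)

  expect_error(composite_scores(sep$X, rep(1, nrow(sep$X))),
               "both classes")
})

test_that("correlation pruning removes redundant features and stops at max_keep", {
  set.seed(5)
  n <- 60
  X <- matrix(rnorm(n * 10), ncol = 10)
  colnames(X) <- sprintf("f%02d", 1:10)
  y <- rbinom(n, 1, 0.5)
  # uncorrelated features: the top max_keep by S are kept in rank order
  sc <- data.frame(feature = colnames(X), f = 10:1, p = (10:1) / 10,
                   S = 2 * (10:1) / 10)
  res <- suppressWarnings(
    correlation_prune(X, sc, selection_config(max_keep = 7)))
  expect_length(res$selected, 7)
  expect_equal(res$selected, res$ranked[1:7])

  # a duplicated feature (rho = 1) is pruned with its blocker recorded
  X2 <- cbind(X[, 1:5], dup = X[, 1])
  colnames(X2) <- c(colnames(X)[1:5], "dup")
  sc2 <- data.frame(feature = colnames(X2), f = c(6:2, 1),
                    p = c(6:2, 1) / 6, S = 2 * c(6:2, 1) / 6)
  res2 <- correlation_prune(X2, sc2, selection_config())
  expect_false("dup" %in% res2$selected)
  expect_equal(unname(res2$pruned["dup"]), "f01")

  # fewer than min_keep survivors -> warning, survivors returned
  X3 <- X[, 1:3]
  X3[, 2] <- X3[, 1] + rnorm(n, 0, 1e-6)
  X3[, 3] <- -X3[, 1] + rnorm(n, 0, 1e-6)
  sc3 <- data.frame(feature = colnames(X)[1:3], f = 3:1, p = (3:1) / 3,
                    S = 2 * (3:1) / 3)
  expect_warning(res3 <- correlation_prune(X3, sc3, selection_config()),
                 "survive")
  expect_length(res3$selected, 1)

  expect_error(correlation_prune(X, sc[0, ], selection_config()), "empty")
})

test_that("selected features are pairwise below the rho threshold", {
  for (s in 1:3) {
    set.seed(s)
    n <- 50
    base <- matrix(rnorm(n * 4), ncol = 4)
    X <- cbind(base, base[, 1] + rnorm(n, 0, 0.1),
               base[, 2] * 2 + rnorm(n, 0, 0.1),
               matrix(rnorm(n * 4), ncol = 4))
    colnames(X) <- sprintf("v%02d", seq_len(ncol(X)))
    y <- as.integer(base[, 1] + rnorm(n) > 0)
    res <- suppressWarnings(select_features(X, y,
                                            selection_config(rf_seed = s)))
    rho <- cor(X[, res$selected], method = "spearman")
    off <- abs(rho[upper.tri(rho)])
    expect_true(all(off < 0.7))
    expect_lte(length(res$selected), 7)
  }
})

test_that("tie-breaking is deterministic: higher f, then name", {
  set.seed(8)
  X <- matrix(rnorm(40 * 4), ncol = 4)
  colnames(X) <- c("b", "a", "d", "c")
  sc <- data.frame(feature = colnames(X), f = c(2, 5, 5, 5),
                   p = c(1, 1, 1, 1), S = c(1, 1.5, 1.5, 1.5))
  res <- correlation_prune(X, sc, selection_config(min_keep = 1,
                                                   max_keep = 2))
  # equal S and f for a, c, d: lexicographic order decides
  expect_equal(res$ranked, c("a", "c", "d", "b"))
  expect_equal(res$selected, c("a", "c"))
})
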