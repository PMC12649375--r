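#' Feature-selection configuration
#'
#' @param rho_threshold Spearman redundancy threshold (default 0.7): a
#'   candidate correlated at `|rho| >=` this with any higher-ranked kept
#'   feature is pruned.
#' @param min_keep,max_keep Target band for the number of surviving
#'   features (defaults 4 and 7, keeping `N/p >= 10` at cohort size 82).
#' @param np_ratio Floor for subjects-per-feature (default 10).
#' @param rf_trees Trees in the importance forest (default 500).
#' @param rf_seed Seed for the importance forest.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(rho_threshold = 0.7, min_keep = 4,
                             max_keep = 7, np_ratio = 10, rf_trees = 500,
                             rf_seed = 1) {
  stopifnot(rho_threshold > 0, rho_threshold <= 1, min_keep <= max_keep,
            min_keep >= 1, rf_trees >= 1)
  structure(list(rho_threshold = rho_threshold,
                 min_keep = as.integer(min_keep),
                 max_keep = as.integer(max_keep), np_ratio = np_ratio,
                 rf_trees = as.integer(rf_trees),
                 rf_seed = as.integer(rf_seed)),
            class = "selection_config")
}

#' Composite feature scores: ANOVA F plus forest importance
#'
#' For each feature, `f(i)` is the one-way ANOVA F statistic of the feature
#' against the binary label and `p(i)` is the mean-decrease-in-impurity
#' importance from a seeded random forest fit on all features jointly. The
#' composite score is the equal-weight normalized sum
#' `S(i) = f(i)/max(f) + p(i)/max(p)`, in `[0, 2]`.
#'
#' @param features Numeric matrix or data frame (subjects x features).
#' @param labels 0/1 vector; both classes must be present.
#' @param config A [selection_config()].
#' @return Data frame with columns `feature`, `f`, `p`, `S`, ordered as the
#'   input features.
#' @export
composite_scores <- function(features, labels, config = selection_config()) {
  X <- as.matrix(features)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to score features")
  g <- factor(labels)
  f <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::var(X[, j]) == 0) return(0)
    anova(lm(X[, j] ~ g))[["F value"]][1]
  }, numeric(1))
  f[!is.finite(f)] <- 0
  set.seed(config$rf_seed)
  Xdf <- as.data.frame(X)
  names(Xdf) <- paste0("V", seq_len(ncol(X)))  # forest-safe names
  rf <- randomForest::randomForest(Xdf, g, ntree = config$rf_trees,
                                   importance = FALSE)
  p <- as.numeric(randomForest::importance(rf, type = 2))
  fmax <- max(f); pmax <- max(p)
  S <- (if (fmax > 0) f / fmax else rep(0, length(f))) +
       (if (pmax > 0) p / pmax else rep(0, length(p)))
  data.frame(feature = colnames(X) %||% paste0("V", seq_len(ncol(X))),
             f = f, p = p, S = S, stringsAsFactors = FALSE)
}

#' Correlation pruning of ranked features
#'
#' Traverses features in descending composite score `S` (ties broken by
#' higher `f`, then lexicographic name). A candidate is kept unless its
#' absolute Spearman correlation with any already-kept feature reaches
#' `rho_threshold`; traversal stops once `max_keep` features are kept. If
#' fewer than `min_keep` survive the full traversal, the survivors are
#' returned with a warning.
#'
#' @param features Subjects x features matrix or data frame (the data the
#'   correlations are computed on).
#' @param scores Output of [composite_scores()].
#' @param config A [selection_config()].
#' @return An object of class `selection_result`: `scores`, `ranked`
#'   (ordered names), `selected`, and `pruned` (named character vector
#'   mapping each removed feature to the kept feature that blocked it).
#' @export
correlation_prune <- function(features, scores,
                              config = selection_config()) {
  if (!nrow(scores)) stop("empty feature set")
  X <- as.matrix(features)[, scores$feature, drop = FALSE]
  ord <- order(-scores$S, -scores$f, scores$feature)
  ranked <- scores$feature[ord]
  rho <- suppressWarnings(cor(X, method = "spearman"))
  rho[is.na(rho)] <- 0
  selected <- character(0)
  pruned <- character(0)
  for (feat in ranked) {
    if (length(selected) >= config$max_keep) break
    if (length(selected)) {
      r <- abs(rho[feat, selected])
      if (any(r >= config$rho_threshold)) {
        pruned[feat] <- selected[which.max(r)]
        next
      }
    }
    selected <- c(selected, feat)
  }
  if (length(selected) < config$min_keep)
    warning(sprintf("only %d features survive pruning (minimum target %d)",
                    length(selected), config$min_keep))
  n <- nrow(X)
  if (length(selected) * config$np_ratio > n)
    warning(sprintf("N/p = %.1f below the %d floor", n / length(selected),
                    config$np_ratio))
  structure(list(scores = scores, ranked = ranked, selected = selected,
                 pruned = pruned, n = n),
            class = "selection_result")
}

#' Run scoring and pruning in one step
#'
#' @inheritParams composite_scores
#' @return A `selection_result` (see [correlation_prune()]).
#' @export
select_features <- function(features, labels, config = selection_config()) {
  correlation_prune(features, composite_scores(features, labels, config),
                    config)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection: %d of %d kept (N = %d, N/p = %.1f)\n",
              length(x$selected), nrow(x$scores), x$n,
              x$n / length(x$selected)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
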