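#' Cross-validation configuration
#'
#' @param folds Stratified folds (default 5).
#' @param classifiers Subset of `c("KNN", "RF", "ET", "SVM", "DT", "NB",
#'   "LR")` (default all seven).
#' @param grids Named list of hyperparameter grids per classifier; each grid
#'   is a list of parameter lists. Defaults to small published-default
#'   grids (see [default_grids()]).
#' @param smote_k_cap Cap on the SMOTE neighbour count (default 3); the
#'   effective `k` is `min(smote_k_cap, minority_count - 1)`.
#' @param repeats Number of CV repetitions used to stabilise out-of-fold
#'   probability distributions (default 5).
#' @param seed Base seed; repeat seeds are derived from it.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 5, classifiers = c("KNN", "RF", "ET", "SVM",
                                                 "DT", "NB", "LR"),
                      grids = default_grids(), smote_k_cap = 3,
                      repeats = 5, seed = 1) {
  stopifnot(folds >= 2, repeats >= 1)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(list(folds = as.integer(folds), classifiers = classifiers,
                 grids = grids, smote_k_cap = as.integer(smote_k_cap),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_config")
}

#' Default hyperparameter grids
#'
#' Small grids around the published defaults of each model family; grid
#' search maximises mean F1.
#'
#' @return Named list of grids (one list of parameter lists per classifier).
#' @export
default_grids <- function() {
  list(
    KNN = lapply(c(3, 5, 7, 9), function(k) list(k = k)),
    RF  = lapply(c(200, 500), function(n) list(ntree = n)),
    ET  = lapply(c(200, 500), function(n) list(num.trees = n)),
    SVM = lapply(c(0.1, 1, 10), function(C) list(cost = C)),
    DT  = lapply(c(3, 5, 30), function(d) list(maxdepth = d)),
    NB  = list(list()),
    LR  = list(list())
  )
}

# internal classifier registry: fit / class-1 probability / scaling need
clf_registry <- function() {
  list(
    KNN = list(scale = TRUE, fit = function(X, y, p, seed) {
      caret::knn3(X, factor(y, levels = c(0, 1)), k = p$k %||% 5)
    }, prob = function(m, X) predict(m, X, type = "prob")[, "1"]),
    RF = list(scale = FALSE, fit = function(X, y, p, seed) {
      set.seed(seed)
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = p$ntree %||% 500)
    }, prob = function(m, X) predict(m, X, type = "prob")[, "1"]),
    ET = list(scale = FALSE, fit = function(X, y, p, seed) {
      ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                     probability = TRUE, splitrule = "extratrees",
                     num.random.splits = 1, replace = FALSE,
                     sample.fraction = 1,
                     num.trees = p$num.trees %||% 500, seed = seed)
    }, prob = function(m, X) predict(m, data = X)$predictions[, "1"]),
    SVM = list(scale = TRUE, fit = function(X, y, p, seed) {
      set.seed(seed)
      e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = p$cost %||% 1, probability = TRUE)
    }, prob = function(m, X) {
      pr <- predict(m, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }),
    DT = list(scale = FALSE, fit = function(X, y, p, seed) {
      d <- data.frame(X)
      d$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = d, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = p$maxdepth %||% 30, cp = 0.01))
    }, prob = function(m, X) predict(m, data.frame(X), type = "prob")[, "1"]),
    NB = list(scale = FALSE, fit = function(X, y, p, seed) {
      e1071::naiveBayes(X, factor(y, levels = c(0, 1)))
    }, prob = function(m, X) predict(m, X, type = "raw")[, "1"]),
    LR = list(scale = TRUE, fit = function(X, y, p, seed) {
      d <- data.frame(X)
      d$.y <- y
      suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
    }, prob = function(m, X)
      suppressWarnings(predict(m, data.frame(X), type = "response")))
  )
}

#' SMOTE: balance classes by minority interpolation
#'
#' Upsamples the minority class to the majority count. Each synthetic point
#' is `x + lambda * (x_nn - x)` with `lambda ~ uniform(0, 1)` and `x_nn`
#' drawn among the `k = min(k_cap, minority_count - 1)` nearest minority
#' neighbours (Euclidean distance). Majority rows are untouched; an already
#' balanced input is returned unchanged.
#'
#' @param X Numeric matrix (rows = samples).
#' @param y 0/1 labels.
#' @param seed Integer seed.
#' @param k_cap Neighbour cap (default 3).
#' @return List with `X`, `y`, `n_synthetic` and `k_used` (the effective
#'   neighbour count).
#' @export
smote_balance <- function(X, y, seed = 1, k_cap = 3) {
  X <- as.matrix(X)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0)) stop("both classes must be present")
  if (tab[1] == tab[2])
    return(list(X = X, y = y, n_synthetic = 0L, k_used = 0L))
  minority <- as.integer(names(tab)[which.min(tab)])
  n_needed <- abs(diff(as.integer(tab)))
  idx_min <- which(y == minority)
  if (length(idx_min) < 2)
    stop("minority class has fewer than 2 samples: interpolation undefined")
  k <- min(k_cap, length(idx_min) - 1L)
  Xm <- X[idx_min, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(Xm)), function(i)
    order(D[i, ])[seq_len(k)]))
  set.seed(seed)
  base <- sample(seq_len(nrow(Xm)), n_needed, replace = TRUE)
  pick <- vapply(base, function(b) nn[b, sample.int(k, 1)], integer(1))
  lambda <- runif(n_needed)
  synth <- Xm[base, , drop = FALSE] +
    lambda * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  rownames(synth) <- sprintf("synth%03d", seq_len(n_needed))
  list(X = rbind(X, synth), y = c(y, rep(minority, n_needed)),
       n_synthetic = n_needed, k_used = k)
}

#' Binary classification metrics
#'
#' Standard binary definitions with positive class `Y = 1`: accuracy,
#' precision (0 with a warning when no positive predictions), recall, F1,
#' ROC-AUC by the rank (Mann-Whitney) method with average-rank tie
#' handling, and AUPR by precision-recall step integration. With a
#' single-class truth vector the threshold-free metrics are undefined and
#' reported as `NA`.
#'
#' @param y_true,y_pred 0/1 vectors.
#' @param y_prob Predicted probabilities of class 1.
#' @return Named list of the six metrics.
#' @export
compute_metrics <- function(y_true, y_pred, y_prob = NULL) {
  stopifnot(length(y_true) >= 1, length(y_true) == length(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  acc <- mean(y_true == y_pred)
  if (tp + fp == 0) {
    warning("no positive predictions: precision reported as 0")
    prec <- 0
  } else prec <- tp / (tp + fp)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(rec) || prec + rec == 0) 0 else
    2 * prec * rec / (prec + rec)
  auc <- aupr <- NA_real_
  if (!is.null(y_prob) && length(unique(y_true)) == 2) {
    n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
    r <- rank(y_prob)
    auc <- (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aupr <- average_precision(y_true, y_prob)
  }
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1,
       roc_auc = auc, aupr = aupr)
}

# step-integrated area under the precision-recall curve (ties grouped)
average_precision <- function(y_true, y_prob) {
  ord <- order(-y_prob)
  y <- y_true[ord]; p <- y_prob[ord]
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y == 1); n_pos <- sum(y == 1)
  last <- !duplicated(grp, fromLast = TRUE)   # end of each tie group
  tp_g <- tp[last]; n_g <- which(last)
  prec_g <- tp_g / n_g
  rec_g <- tp_g / n_pos
  sum(diff(c(0, rec_g)) * prec_g)
}

#' Stratified fold assignment
#'
#' @param labels 0/1 vector.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per subject (each class spread evenly).
#' @export
stratified_folds <- function(labels, folds, seed = 1) {
  if (any(table(labels) < folds))
    stop("each class needs at least as many subjects as folds")
  out <- integer(length(labels))
  set.seed(seed)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    out[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  out
}

#' Prepare the training inputs of one fold
#'
#' Performs the training-side work of one outer CV fold: feature selection
#' restricted to the training rows (per-fold scope) and SMOTE balancing of
#' the training portion. This function never sees test-fold rows, which is
#' the package's leakage guard: its output is invariant to any change in
#' the held-out subjects.
#'
#' @param X Full feature matrix (subjects x features).
#' @param y Full 0/1 label vector.
#' @param train_idx Row indices of the training portion.
#' @param selection A [selection_config()].
#' @param seed Fold-level seed.
#' @param selected Optional pre-computed feature names (global scope);
#'   when supplied, selection is skipped.
#' @param smote_k_cap Neighbour cap for SMOTE.
#' @return List with `selected` (feature names), `X_train`, `y_train`
#'   (SMOTE-balanced, restricted to selected features) and `n_synthetic`.
#' @export
prepare_fold <- function(X, y, train_idx, selection = selection_config(),
                         seed = 1, selected = NULL, smote_k_cap = 3) {
  X <- as.matrix(X)
  if (is.null(selected)) {
    sel_cfg <- selection
    sel_cfg$rf_seed <- mix_seed(seed, 11L)
    sel <- suppressWarnings(
      select_features(X[train_idx, , drop = FALSE], y[train_idx], sel_cfg))
    selected <- sel$selected
  }
  sm <- smote_balance(X[train_idx, selected, drop = FALSE], y[train_idx],
                      seed = mix_seed(seed, 12L), k_cap = smote_k_cap)
  list(selected = selected, X_train = sm$X, y_train = sm$y,
       n_synthetic = sm$n_synthetic)
}

# standardize train/test with training statistics
scale_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sdv, "/"))
}

# inner 3-fold grid search maximizing mean F1 on the (balanced) training set
tune_inner <- function(clf, grid, Xtr, ytr, seed) {
  if (length(grid) <= 1) return(grid[[1]] %||% list())
  inner <- stratified_folds(ytr, min(3L, min(table(ytr))), seed)
  f1s <- vapply(grid, function(params) {
    mean(vapply(unique(inner), function(f) {
      tr <- inner != f; te <- !tr
      if (length(unique(ytr[tr])) < 2) return(NA_real_)
      m <- clf$fit(Xtr[tr, , drop = FALSE], ytr[tr], params,
                   mix_seed(seed, f))
      pr <- clf$prob(m, Xtr[te, , drop = FALSE])
      suppressWarnings(
        compute_metrics(ytr[te], as.integer(pr >= 0.5), pr)$f1)
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(f1s)]]
}

#' SMOTE-balanced stratified cross-validation over classifier families
#'
#' Runs repeated stratified k-fold CV. Per outer fold: feature selection on
#' training rows only (default `per_fold` scope; `global` reproduces a
#' single selection on all data before CV), SMOTE on the training portion
#' only, hyperparameter grid search maximising mean F1 (inner 3-fold on the
#' balanced training portion in `strict` mode; across the outer folds in
#' `outer` mode), model fit, and prediction of the held-out fold. Collects
#' per-fold metrics and out-of-fold probabilities `P(Y = 1)` per subject,
#' classifier and repeat.
#'
#' @param features Data frame or matrix of features (a `label` column, if
#'   present, is removed); rownames identify subjects.
#' @param labels 0/1 vector aligned with rows.
#' @param config A [cv_config()].
#' @param selection A [selection_config()].
#' @param selection_scope `"per_fold"` (default) or `"global"`.
#' @param mode `"strict"` (nested tuning, default) or `"outer"` (grid
#'   scored on the outer folds).
#' @return An object of class `eval_report`: `per_classifier` (metric mean
#'   and SD across folds and repeats), `pooled` (mean and SD across
#'   classifiers), `oof` (long data frame of out-of-fold probabilities) and
#'   `selected_per_fold`.
#' @export
run_cv <- function(features, labels, config = cv_config(),
                   selection = selection_config(),
                   selection_scope = c("per_fold", "global"),
                   mode = c("strict", "outer")) {
  selection_scope <- match.arg(selection_scope)
  mode <- match.arg(mode)
  feats <- as.data.frame(features, check.names = FALSE)
  feats$label <- NULL
  feats$subject_id <- NULL
  X <- as.matrix(feats)
  y <- as.integer(labels)
  ids <- rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  reg <- clf_registry()[config$classifiers]
  global_sel <- if (selection_scope == "global")
    suppressWarnings(select_features(X, y, selection))$selected else NULL

  fold_rows <- list(); oof_rows <- list(); sel_log <- list()
  for (r in seq_len(config$repeats)) {
    rseed <- mix_seed(config$seed, 101L, r)
    fold_id <- stratified_folds(y, config$folds, rseed)
    # per-fold prepared inputs (selection + SMOTE on training rows only)
    prep <- lapply(seq_len(config$folds), function(f) {
      prepare_fold(X, y, which(fold_id != f), selection,
                   seed = mix_seed(rseed, f), selected = global_sel,
                   smote_k_cap = config$smote_k_cap)
    })
    for (nm in names(reg)) {
      clf <- reg[[nm]]
      grid <- config$grids[[nm]] %||% list(list())
      eval_grid_point <- function(params) {
        lapply(seq_len(config$folds), function(f) {
          p <- prep[[f]]
          te <- which(fold_id == f)
          Xte <- X[te, p$selected, drop = FALSE]
          Xtr <- p$X_train
          if (clf$scale) {
            sc <- scale_pair(Xtr, Xte); Xtr <- sc$train; Xte <- sc$test
          }
          fit_seed <- mix_seed(rseed, f, match(nm, names(reg)))
          if (mode == "strict" && length(grid) > 1 && is.null(params))
            params <- tune_inner(clf, grid, Xtr, p$y_train,
                                 mix_seed(fit_seed, 5L))
          params <- params %||% grid[[1]]
          m <- clf$fit(Xtr, p$y_train, params, fit_seed)
          pr <- as.numeric(clf$prob(m, Xte))
          met <- suppressWarnings(
            compute_metrics(y[te], as.integer(pr >= 0.5), pr))
          list(metrics = met, prob = pr, test = te)
        })
      }
      res <- if (mode == "outer" && length(grid) > 1) {
        cand <- lapply(grid, eval_grid_point)
        f1m <- vapply(cand, function(rr)
          mean(vapply(rr, function(z) z$metrics$f1, numeric(1))), numeric(1))
        cand[[which.max(f1m)]]
      } else eval_grid_point(NULL)
      for (f in seq_len(config$folds)) {
        met <- res[[f]]$metrics
        fold_rows[[length(fold_rows) + 1L]] <-
          data.frame(classifier = nm, repeat_ = r, fold = f,
                     accuracy = met$accuracy, precision = met$precision,
                     recall = met$recall, f1 = met$f1,
                     roc_auc = met$roc_auc, aupr = met$aupr)
        oof_rows[[length(oof_rows) + 1L]] <-
          data.frame(subject_id = ids[res[[f]]$test],
                     label = y[res[[f]]$test], classifier = nm,
                     repeat_ = r, fold = f, prob = res[[f]]$prob)
      }
    }
    sel_log[[r]] <- lapply(prep, `[[`, "selected")
  }
  folds_df <- do.call(rbind, fold_rows)
  metric_names <- c("accuracy", "precision", "recall", "f1", "roc_auc",
                    "aupr")
  per_clf <- do.call(rbind, lapply(split(folds_df, folds_df$classifier),
    function(d) {
      means <- vapply(metric_names, function(mn) mean(d[[mn]], na.rm = TRUE),
                      numeric(1))
      sds <- vapply(metric_names, function(mn) sd(d[[mn]], na.rm = TRUE),
                    numeric(1))
      data.frame(classifier = d$classifier[1],
                 metric = metric_names, mean = means, sd = sds,
                 row.names = NULL)
    }))
  pooled <- do.call(rbind, lapply(metric_names, function(mn) {
    v <- per_clf$mean[per_clf$metric == mn]
    data.frame(metric = mn, mean = mean(v), sd = sd(v))
  }))
  structure(list(per_classifier = per_clf, pooled = pooled,
                 oof = do.call(rbind, oof_rows),
                 selected_per_fold = sel_log,
                 config = config, mode = mode,
                 selection_scope = selection_scope),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Cross-validated evaluation (%d folds x %d repeats, %s tuning, %s selection)\n",
              x$config$folds, x$config$repeats, x$mode, x$selection_scope))
  p <- x$pooled
  cat("  pooled across classifiers (mean +/- SD):\n")
  for (i in seq_len(nrow(p)))
    cat(sprintf("    %-9s %.3f +/- %.3f\n", p$metric[i], p$mean[i],
                p$sd[i]))
  invisible(x)
}
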