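#' Feature type from its name
#'
#' Features are grouped by name prefix: `DTW-` (template deviation),
#' `LSTM-` (embedding), anything else is a statistical descriptor.
#'
#' @param feature Character vector of feature names.
#' @return Character vector in `c("DTW", "LSTM", "Statistical")`.
#' @export
feature_type <- function(feature) {
  ifelse(startsWith(feature, "DTW-"), "DTW",
         ifelse(startsWith(feature, "LSTM-"), "LSTM", "Statistical"))
}

#' Permutation-based attribution for fitted classifiers
#'
#' A dependency-free attribution backend: each classifier is fitted on the
#' full (SMOTE-balanced) data restricted to the selected features, and a
#' feature's importance is the mean decrease in ROC-AUC over `n_perm`
#' seeded permutations of that feature's column. Only the resulting
#' importance ranking feeds the frequency summary, so any backend producing
#' a per-feature importance vector (e.g. Shapley-value estimates) can be
#' substituted.
#'
#' @param features Feature data frame or matrix (label column removed if
#'   present).
#' @param labels 0/1 vector.
#' @param selected Feature names to attribute over.
#' @param classifiers Classifier names (default the four high-performing
#'   families used for attribution: KNN, RF, ET, SVM).
#' @param seed Integer seed.
#' @param n_perm Permutations per feature (default 10).
#' @param smote_k_cap SMOTE neighbour cap.
#' @return Named list: classifier -> named importance vector.
#' @export
permutation_attribution <- function(features, labels, selected,
                                    classifiers = c("KNN", "RF", "ET",
                                                    "SVM"),
                                    seed = 1, n_perm = 10,
                                    smote_k_cap = 3) {
  feats <- as.data.frame(features, check.names = FALSE)
  feats$label <- NULL
  X <- as.matrix(feats)[, selected, drop = FALSE]
  y <- as.integer(labels)
  sm <- smote_balance(X, y, seed = mix_seed(seed, 1L), k_cap = smote_k_cap)
  reg <- clf_registry()[classifiers]
  out <- list()
  for (nm in names(reg)) {
    clf <- reg[[nm]]
    Xf <- sm$X
    if (clf$scale) Xf <- scale_pair(Xf, Xf)$train
    m <- clf$fit(Xf, sm$y, list(), mix_seed(seed, 2L, match(nm, classifiers)))
    base_auc <- suppressWarnings(compute_metrics(
      sm$y, as.integer(clf$prob(m, Xf) >= 0.5), clf$prob(m, Xf))$roc_auc)
    imp <- vapply(seq_len(ncol(Xf)), function(j) {
      drops <- vapply(seq_len(n_perm), function(b) {
        set.seed(mix_seed(seed, 3L, match(nm, classifiers), j, b))
        Xp <- Xf
        Xp[, j] <- sample(Xp[, j])
        auc <- suppressWarnings(compute_metrics(
          sm$y, as.integer(clf$prob(m, Xp) >= 0.5),
          clf$prob(m, Xp))$roc_auc)
        base_auc - auc
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    names(imp) <- colnames(Xf)
    out[[nm]] <- imp
  }
  out
}

#' Top-5 attribution frequency by feature type
#'
#' For each classifier, ranks features by mean absolute attribution (ties
#' broken by lexicographic name) and takes the top five; then counts how
#' often each feature type (DTW, LSTM, Statistical) appears across all
#' classifiers' top-5 lists.
#'
#' @param attributions Named list: classifier -> named per-feature
#'   importance vector.
#' @return An object of class `attribution_summary` with `per_model_top5`
#'   and `type_frequency`.
#' @export
top5_type_frequency <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  per_model <- lapply(attributions, function(v) {
    if (length(v) < 5)
      warning("fewer than 5 features available: taking all")
    nm <- names(v)
    ord <- order(-abs(v), nm)
    nm[ord][seq_len(min(5L, length(v)))]
  })
  types <- factor(feature_type(unlist(per_model)),
                  levels = c("DTW", "LSTM", "Statistical"))
  structure(list(per_model_top5 = per_model,
                 type_frequency = table(types)),
            class = "attribution_summary")
}

#' @export
print.attribution_summary <- function(x, ...) {
  cat("Top-5 attribution frequency by feature type:\n")
  print(x$type_frequency)
  invisible(x)
}

#' Spearman correlations between features and clinical indicators
#'
#' Exploratory correlations, computed pair by pair with pairwise deletion
#' of missing clinical values. Spearman's rho uses average-rank tie
#' handling; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. No multiplicity correction by
#' default (set `adjust = TRUE` for Benjamini-Hochberg).
#'
#' @param features Data frame of features, rownames = subject ids.
#' @param clinical Data frame of clinical indicators, rownames = subject
#'   ids (missing values allowed).
#' @param adjust Apply Benjamini-Hochberg across all tested pairs.
#' @return Data frame with columns `feature`, `indicator`, `rho`, `p`, `n`.
#' @export
clinical_correlations <- function(features, clinical, adjust = FALSE) {
  feats <- as.data.frame(features, check.names = FALSE)
  feats$label <- NULL
  common <- intersect(rownames(feats), rownames(clinical))
  rows <- list()
  for (fe in colnames(feats)) {
    for (ind in colnames(clinical)) {
      x <- feats[common, fe]
      z <- suppressWarnings(as.numeric(clinical[common, ind]))
      ok <- is.finite(x) & is.finite(z)
      n <- sum(ok)
      if (n < 3) next
      rho <- suppressWarnings(cor(x[ok], z[ok], method = "spearman"))
      if (is.na(rho)) next
      p <- if (abs(rho) >= 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * pt(-abs(tt), df = n - 2)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(feature = fe, indicator = ind, rho = rho, p = p, n = n)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out) && adjust) out$p_adj <- stats::p.adjust(out$p, "BH")
  out
}

#' Compensatory reserve variability report
#'
#' Summarises the out-of-fold predicted probabilities `P(Y = 1)` of the
#' sarcopenia (label 1) subjects: each subject's probabilities are averaged
#' over classifiers and repeats, and the distribution over subjects is
#' characterised by its range, mean, population SD and coefficient of
#' variation `CV% = 100 * SD / mean`. Lower `P(Y = 1)` indicates greater
#' compensatory reserve (COP dynamics closer to the healthy template).
#' Report annotations flag cohort-derived interpretation cutoffs
#' (probability > 0.7 depleted reserve, < 0.5 high reserve) as not
#' externally validated. Set `group = "all"` to summarise every subject
#' instead of patients only.
#'
#' @param eval An [run_cv()] `eval_report`.
#' @param posture Posture code carried into the report.
#' @param group `"patients"` (default) or `"all"`.
#' @return An object of class `reserve_report`.
#' @export
reserve_report <- function(eval, posture = "ST",
                           group = c("patients", "all")) {
  group <- match.arg(group)
  oof <- eval$oof
  if (group == "patients") oof <- oof[oof$label == 1, , drop = FALSE]
  if (!nrow(oof)) stop("no sarcopenia subjects with out-of-fold probabilities")
  probs <- tapply(oof$prob, oof$subject_id, mean)
  probs <- probs[order(names(probs))]
  mu <- mean(probs)
  sdev <- pop_sd(probs)
  structure(list(posture = posture, probabilities = probs,
                 range = c(min(probs), max(probs)), mean = mu, sd = sdev,
                 cv_percent = if (mu > 0) 100 * sdev / mu else 0,
                 group = group,
                 annotations = c(
                   depleted = "P(Y=1) > 0.7: depleted reserve (cohort-derived cutoff, not validated)",
                   high = "P(Y=1) < 0.5: high reserve (cohort-derived cutoff, not validated)")),
            class = "reserve_report")
}

#' @export
print.reserve_report <- function(x, ...) {
  cat(sprintf("Compensatory reserve report (%s, %s):\n", x$posture,
              x$group))
  cat(sprintf("  n = %d; Range (%.2f, %.2f); Mean +/- SD %.2f +/- %.2f; CV %.1f%%\n",
              length(x$probabilities), x$range[1], x$range[2], x$mean,
              x$sd, x$cv_percent))
  invisible(x)
}
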