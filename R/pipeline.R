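#' Pipeline configuration
#'
#' Bundles the stage configurations of the end-to-end analysis.
#'
#' @param dtw A [dtw_params()].
#' @param lstm An [lstm_spec()].
#' @param selection A [selection_config()].
#' @param cv A [cv_config()].
#' @param stats_on Series variant for the statistical descriptors
#'   (`"translated"` default; `"standardized"` reproduces the literal
#'   Z-scored reading for sensitivity analysis).
#' @param trial_aggregation `"mean"` (default; the subject is the analysis
#'   unit) or `"per_trial"`.
#' @param selection_scope `"per_fold"` (default, leakage-safe) or
#'   `"global"`.
#' @param mode `"strict"` or `"outer"` hyperparameter tuning (see
#'   [run_cv()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(dtw = dtw_params(), lstm = lstm_spec(),
                            selection = selection_config(),
                            cv = cv_config(),
                            stats_on = c("translated", "standardized"),
                            trial_aggregation = c("mean", "per_trial"),
                            selection_scope = c("per_fold", "global"),
                            mode = c("strict", "outer")) {
  structure(list(dtw = dtw, lstm = lstm, selection = selection, cv = cv,
                 stats_on = match.arg(stats_on),
                 trial_aggregation = match.arg(trial_aggregation),
                 selection_scope = match.arg(selection_scope),
                 mode = match.arg(mode)),
            class = "pipeline_config")
}

# clinical indicator table for a cohort (rows = subjects)
clinical_table <- function(cohort) {
  keys <- unique(unlist(lapply(cohort$subjects, function(s)
    names(s$clinical))))
  keys <- setdiff(keys, "sex")
  if (!length(keys)) return(NULL)
  df <- as.data.frame(lapply(keys, function(k)
    vapply(cohort$subjects, function(s)
      as.numeric(s$clinical[[k]] %||% NA_real_), numeric(1))))
  names(df) <- keys
  rownames(df) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  df
}

#' Fit the compensatory-reserve analysis to a cohort
#'
#' The main entry point. Executes, per posture and independently:
#' preprocessing (outlier replacement, origin translation, Z-score),
#' healthy-template construction from controls, extraction of the
#' 36-dimensional temporal feature vector per subject, hybrid feature
#' selection, SMOTE-balanced repeated stratified cross-validation over the
#' configured classifiers, permutation attribution with top-5 type
#' frequencies, Spearman feature-clinical correlations, and the
#' compensatory-reserve variability report.
#'
#' @param cohort A [cop_cohort()] (e.g. from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param postures Postures to analyse (default: those present).
#' @param seed Integer seed governing every stochastic stage.
#' @param attribution Compute permutation attribution and the top-5 summary
#'   (default TRUE; set FALSE for speed in repeated simulations).
#' @return An object of class `reserve_analysis` with per-posture elements
#'   `template`, `features`, `selection`, `eval`, `attribution`,
#'   `correlations`, `reserve`, plus a `manifest` recording configuration
#'   and seeds.
#' @export
fit_reserve <- function(cohort, config = pipeline_config(),
                        postures = NULL, seed = 1, attribution = TRUE) {
  stopifnot(inherits(cohort, "cop_cohort"))
  present <- unique(vapply(cohort$trials, `[[`, character(1), "posture"))
  postures <- postures %||% intersect(POSTURES, present)
  pre <- preprocess_cohort(cohort)
  labels <- cohort_labels(cohort)
  clin <- clinical_table(cohort)
  out <- list()
  for (pp in postures) {
    tpl <- build_template(cohort, pp, pre = pre,
                          trial_aggregation = config$trial_aggregation)
    feats <- feature_table(cohort, pp, tpl, pre = pre, dtw = config$dtw,
                           lstm = config$lstm, stats_on = config$stats_on,
                           trial_aggregation = config$trial_aggregation)
    y <- feats$label
    cv_cfg <- config$cv
    cv_cfg$seed <- mix_seed(seed, match(pp, POSTURES))
    ev <- run_cv(feats, y, cv_cfg, config$selection,
                 selection_scope = config$selection_scope,
                 mode = config$mode)
    sel <- suppressWarnings(select_features(
      feats[, feature_names(), drop = FALSE], y, config$selection))
    attr_sum <- NULL; attrs <- NULL
    if (attribution) {
      attrs <- permutation_attribution(
        feats, y, sel$selected,
        classifiers = intersect(c("KNN", "RF", "ET", "SVM"),
                                cv_cfg$classifiers),
        seed = mix_seed(seed, 21L, match(pp, POSTURES)))
      attr_sum <- suppressWarnings(top5_type_frequency(attrs))
    }
    cors <- if (!is.null(clin))
      clinical_correlations(feats[, sel$selected, drop = FALSE], clin)
    else NULL
    res <- if (any(y == 1)) reserve_report(ev, posture = pp) else NULL
    out[[pp]] <- list(template = tpl, features = feats, selection = sel,
                      eval = ev, attribution = attr_sum,
                      attribution_raw = attrs, correlations = cors,
                      reserve = res)
  }
  structure(list(postures = out,
                 manifest = list(seed = seed, config = config,
                                 n_subjects = length(cohort$subjects),
                                 n_trials = length(cohort$trials),
                                 version = as.character(
                                   utils::packageVersion("copreserve")))),
            class = "reserve_analysis")
}

#' @export
print.reserve_analysis <- function(x, ...) {
  cat(sprintf("Compensatory-reserve analysis: %d subjects, postures %s\n",
              x$manifest$n_subjects,
              paste(names(x$postures), collapse = ", ")))
  for (pp in names(x$postures)) {
    ev <- x$postures[[pp]]$eval$pooled
    acc <- ev[ev$metric == "accuracy", ]
    auc <- ev[ev$metric == "roc_auc", ]
    cat(sprintf("  %s: accuracy %.2f +/- %.2f, ROC-AUC %.2f +/- %.2f, %d features\n",
                pp, acc$mean, acc$sd, auc$mean, auc$sd,
                length(x$postures[[pp]]$selection$selected)))
  }
  invisible(x)
}

#' @export
summary.reserve_analysis <- function(object, ...) {
  print(object)
  for (pp in names(object$postures)) {
    el <- object$postures[[pp]]
    cat(sprintf("\n-- %s --\n", pp))
    print(el$selection)
    if (!is.null(el$reserve)) print(el$reserve)
    if (!is.null(el$attribution)) print(el$attribution)
  }
  invisible(object)
}

#' @export
plot.reserve_analysis <- function(x, ...) {
  pts <- names(x$postures)
  probs <- lapply(pts, function(pp) {
    r <- x$postures[[pp]]$reserve
    if (is.null(r)) numeric(0) else r$probabilities
  })
  names(probs) <- pts
  graphics::boxplot(probs, ylab = "out-of-fold P(Y = 1)",
                    xlab = "posture",
                    main = "Compensatory reserve distribution", ...)
  invisible(x)
}

#' Sweep the DTW cost exponent
#'
#' Re-runs the pipeline at each cost exponent in `gammas` and reports the
#' pooled mean F1 and ROC-AUC across the analysed postures, plus the
#' arg-max by mean F1 (ties by mean ROC-AUC).
#'
#' @param cohort A [cop_cohort()].
#' @param config A [pipeline_config()]; its DTW gamma is overridden.
#' @param gammas Candidate exponents (default `c(0.5, 1, 1.5, 2)`).
#' @param postures Postures to include.
#' @param seed Integer seed (shared across gammas so the comparison is
#'   paired).
#' @return List with `table` (gamma, mean_f1, mean_roc_auc) and `best`.
#' @export
gamma_sweep <- function(cohort, config = pipeline_config(),
                        gammas = c(0.5, 1, 1.5, 2), postures = NULL,
                        seed = 1) {
  rows <- lapply(gammas, function(g) {
    cfg <- config
    cfg$dtw$gamma <- g
    fit <- fit_reserve(cohort, cfg, postures = postures, seed = seed,
                       attribution = FALSE)
    f1 <- mean(vapply(fit$postures, function(el)
      el$eval$pooled$mean[el$eval$pooled$metric == "f1"], numeric(1)))
    auc <- mean(vapply(fit$postures, function(el)
      el$eval$pooled$mean[el$eval$pooled$metric == "roc_auc"], numeric(1)))
    data.frame(gamma = g, mean_f1 = f1, mean_roc_auc = auc)
  })
  tab <- do.call(rbind, rows)
  best <- tab$gamma[order(-tab$mean_f1, -tab$mean_roc_auc)][1]
  list(table = tab, best = best)
}
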