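#' Two-sided Grubbs test for a single outlier
#'
#' Computes the Grubbs statistic `G = max |x - mean| / s` (sample SD) and
#' compares it with the t-distribution-based critical value at level
#' `alpha`. Diagnostic use only: values are flagged, never removed, during
#' template construction. Vectors with fewer than 3 values or zero variance
#' are not testable and return an NA flag.
#'
#' @param values Numeric vector.
#' @param alpha Significance level (default 0.05).
#' @return List with `is_outlier` (logical, NA when not applicable), `G`,
#'   `critical` and `n`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  s <- sd(values)
  if (n < 3 || is.na(s) || s == 0)
    return(list(is_outlier = NA, G = NA_real_, critical = NA_real_, n = n))
  G <- max(abs(values - mean(values))) / s
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  list(is_outlier = G > crit, G = G, critical = crit, n = n)
}

# columnwise Grubbs over a controls x timepoints matrix; returns logical
# flags per column (FALSE where not testable)
grubbs_flags_matrix <- function(M, alpha) {
  n <- nrow(M)
  if (n < 3) return(rep(FALSE, ncol(M)))
  mu <- colMeans(M)
  s <- sqrt(colSums(sweep(M, 2, mu)^2) / (n - 1))
  G <- apply(abs(sweep(M, 2, mu)), 2, max)
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  ok <- s > 0
  flags <- rep(FALSE, ncol(M))
  flags[ok] <- G[ok] / s[ok] > crit
  flags
}

# per-subject channel series: mean across the subject's preprocessed trials
# (standardized variant by default)
subject_series <- function(pre_trials, variant = c("standardized",
                                                   "translated"),
                           aggregation = c("mean", "per_trial")) {
  variant <- match.arg(variant)
  aggregation <- match.arg(aggregation)
  ids <- vapply(pre_trials, `[[`, character(1), "subject_id")
  out <- list()
  for (sid in unique(ids)) {
    mine <- pre_trials[ids == sid]
    if (aggregation == "mean") {
      chans <- lapply(COP_CHANNELS, function(ch) {
        rowMeans(vapply(mine, function(p) p[[variant]][[ch]],
                        numeric(length(mine[[1]][[variant]][[ch]]))))
      })
      names(chans) <- COP_CHANNELS
      out[[sid]] <- list(chans)
    } else {
      out[[sid]] <- lapply(mine, function(p) p[[variant]])
    }
  }
  out
}

#' Build the posture-specific healthy template
#'
#' The normative reference for DTW deviation features: per channel and per
#' timepoint, the median of the control (label 0) subjects' standardized
#' series. Before taking the median, a Grubbs test (level `grubbs_alpha`)
#' screens each timepoint across controls; flags are counted and logged but
#' values are not removed (set `exclude_flagged = TRUE` to drop the single
#' most extreme value at flagged timepoints, for sensitivity analysis).
#' Patient data never enters template construction.
#'
#' @param cohort A [cop_cohort()].
#' @param posture Posture code.
#' @param pre Optional precomputed [preprocess_cohort()] output.
#' @param trial_aggregation `"mean"` (default: average each subject's trials
#'   before the median) or `"per_trial"` (each trial contributes a row).
#' @param grubbs_alpha Level for the diagnostic Grubbs screen.
#' @param exclude_flagged Drop the most extreme value at flagged timepoints.
#' @return An object of class `healthy_template` with `curves` (named list
#'   of 6 series), `posture`, `n_controls`, `grubbs_flags`.
#' @export
build_template <- function(cohort, posture, pre = NULL,
                           trial_aggregation = c("mean", "per_trial"),
                           grubbs_alpha = 0.05, exclude_flagged = FALSE) {
  trial_aggregation <- match.arg(trial_aggregation)
  labels <- cohort_labels(cohort)
  control_ids <- names(labels)[labels == 0]
  if (!length(control_ids)) stop("no control subjects: cannot build template")
  if (is.null(pre)) pre <- preprocess_cohort(cohort)
  keep <- vapply(pre, function(p)
    p$posture == posture && p$subject_id %in% control_ids, logical(1))
  pre <- pre[keep]
  if (!length(pre))
    stop(sprintf("no control trials for posture %s", posture))
  ser <- subject_series(pre, "standardized", trial_aggregation)
  rows <- unlist(ser, recursive = FALSE, use.names = FALSE)
  T_ <- length(rows[[1]][[1]])
  n_flags <- 0L
  curves <- lapply(COP_CHANNELS, function(ch) {
    M <- do.call(rbind, lapply(rows, function(r) r[[ch]]))
    flags <- grubbs_flags_matrix(M, grubbs_alpha)
    n_flags <<- n_flags + sum(flags)
    if (exclude_flagged && any(flags) && nrow(M) >= 3) {
      vapply(seq_len(ncol(M)), function(j) {
        v <- M[, j]
        if (flags[j]) v <- v[-which.max(abs(v - mean(v)))]
        median(v)
      }, numeric(1))
    } else {
      apply(M, 2, median)
    }
  })
  names(curves) <- COP_CHANNELS
  structure(list(posture = posture, curves = curves,
                 n_controls = length(control_ids),
                 grubbs_alpha = grubbs_alpha,
                 grubbs_flags = n_flags, length = T_),
            class = "healthy_template")
}

#' @export
print.healthy_template <- function(x, ...) {
  cat(sprintf("Healthy template: posture %s, %d controls, length %d, %d Grubbs flags\n",
              x$posture, x$n_controls, x$length, x$grubbs_flags))
  invisible(x)
}

#' Write / read a healthy template as CSV plus JSON sidecar
#'
#' @param template A [build_template()] result.
#' @param csv_path Timepoint-by-channel CSV path.
#' @param json_path Sidecar with posture, control count and Grubbs flags.
#' @return Invisibly, the paths (write) or the template (read).
#' @export
write_template <- function(template, csv_path, json_path) {
  df <- as.data.frame(lapply(template$curves, signif, 12),
                      check.names = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  jsonlite::write_json(list(posture = template$posture,
                            n_controls = template$n_controls,
                            grubbs_alpha = template$grubbs_alpha,
                            grubbs_flags = template$grubbs_flags),
                       json_path, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}

#' @rdname write_template
#' @export
read_template <- function(csv_path, json_path) {
  df <- read.csv(csv_path, check.names = FALSE)
  meta <- jsonlite::read_json(json_path)
  structure(list(posture = meta$posture,
                 curves = as.list(df)[COP_CHANNELS],
                 n_controls = meta$n_controls,
                 grubbs_alpha = meta$grubbs_alpha,
                 grubbs_flags = meta$grubbs_flags, length = nrow(df)),
            class = "healthy_template")
}
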