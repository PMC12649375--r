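#' DTW parameters
#'
#' @param gamma Cost exponent for the pointwise cost `|a - b|^gamma`;
#'   the supported sensitivity grid is `c(0.5, 1, 1.5, 2)` and the default
#'   1.5 weights subtle temporal misalignments over large benign sway.
#' @param band_fraction Alignment-window half-width as a fraction of the
#'   longer series (default 0.1, i.e. a 10% band).
#' @return An object of class `dtw_params`.
#' @export
dtw_params <- function(gamma = 1.5, band_fraction = 0.1) {
  stopifnot(gamma > 0, band_fraction > 0, band_fraction <= 1)
  structure(list(gamma = gamma, band_fraction = band_fraction),
            class = "dtw_params")
}

#' Banded dynamic time warping distance
#'
#' Cumulative cost `D(n, m)` of the optimal monotone warping path between a
#' sample series and a template series, with pointwise cost
#' `|s1[i] - s2[j]|^gamma` and template indices constrained to a window of
#' half-width `w = max(1, ceiling(band_fraction * max(m, n)))` around the
#' sample index (at the default 10% fraction and 2000-sample trials,
#' `w = 200`). The boundary `D(0, 0) = 0` means the first matched pair
#' contributes its own cost; cells outside the band are infeasible.
#'
#' @param sample,template Finite numeric vectors (lengths n, m >= 1).
#' @param params A [dtw_params()].
#' @return Non-negative distance.
#' @export
dtw_distance <- function(sample, template, params = dtw_params()) {
  stopifnot(length(sample) >= 1, length(template) >= 1,
            all(is.finite(sample)), all(is.finite(template)))
  n <- length(sample); m <- length(template)
  w <- max(1L, as.integer(ceiling(params$band_fraction * max(m, n))))
  .dtw_band_cpp(as.numeric(sample), as.numeric(template), params$gamma, w)
}

#' Fixed-weight LSTM specification
#'
#' A single-layer LSTM cell used as a deterministic, untrained temporal
#' transformer: scalar input per step, zero biases, zero initial state, and
#' weights drawn once from a seeded uniform(-0.5, 0.5) initializer. One
#' weight set is shared across all six channels.
#'
#' @param units Hidden units (default 2, giving a 2-D embedding per channel).
#' @param seed Seed for the weight draw (default 42).
#' @return An object of class `lstm_spec`.
#' @export
lstm_spec <- function(units = 2, seed = 42) {
  stopifnot(units >= 1)
  structure(list(units = as.integer(units), seed = as.integer(seed),
                 input_dim = 1L, init_halfwidth = 0.5),
            class = "lstm_spec")
}

#' Generate the fixed LSTM weight set
#'
#' Draws, in a fixed order (input weights `W` then recurrent matrices `U`,
#' each in gate order input/forget/candidate/output), `4 * (u + u^2)`
#' values from uniform(-0.5, 0.5) under the seed in `spec`. Biases are zero.
#'
#' @param spec An [lstm_spec()].
#' @return Named list of `Wi, Wf, Wg, Wo` (length-u vectors) and
#'   `Ui, Uf, Ug, Uo` (u x u matrices).
#' @export
lstm_weights <- function(spec = lstm_spec()) {
  u <- spec$units
  set.seed(spec$seed)
  draws <- runif(4 * (u + u * u), -spec$init_halfwidth, spec$init_halfwidth)
  W <- matrix(draws[seq_len(4 * u)], nrow = u)          # columns: i f g o
  Um <- array(draws[-seq_len(4 * u)], dim = c(u, u, 4))
  list(Wi = W[, 1], Wf = W[, 2], Wg = W[, 3], Wo = W[, 4],
       Ui = Um[, , 1], Uf = Um[, , 2], Ug = Um[, , 3], Uo = Um[, , 4])
}

#' Fixed-weight LSTM embedding of a series
#'
#' Runs the standard LSTM recurrence (logistic input/forget/output gates,
#' tanh candidate; `c_t = f * c + i * g`, `h_t = o * tanh(c_t)`) from zero
#' initial state over the series and returns the final hidden state `h_T`.
#' No training or label information is involved, so the embedding is a
#' deterministic function of the series and the seed.
#'
#' @param series Numeric vector (standardized COP channel), length >= 1.
#' @param spec An [lstm_spec()].
#' @param weights Optional explicit weight set (as [lstm_weights()]); by
#'   default generated from `spec`.
#' @return Numeric vector of length `spec$units`, each value in (-1, 1).
#' @export
lstm_embedding <- function(series, spec = lstm_spec(), weights = NULL) {
  stopifnot(length(series) >= 1, all(is.finite(series)))
  w <- weights %||% lstm_weights(spec)
  .lstm_forward_cpp(as.numeric(series), w$Wi, w$Wf, w$Wg, w$Wo,
                    as.matrix(w$Ui), as.matrix(w$Uf), as.matrix(w$Ug),
                    as.matrix(w$Uo))
}

#' Global statistical descriptors of a series
#'
#' Coefficient of variation `sigma / mu` (population SD; when `|mu|` is
#' below 1e-8 the denominator is guarded as `|mu| + 1e-8` with a warning),
#' ordinary-least-squares linear trend slope against the time index
#' `t = 1..T`, and interquartile range `Q3 - Q1` with linear-interpolation
#' quantiles.
#'
#' @param series Numeric vector, length >= 2.
#' @return Named list `cv`, `slope`, `iqr`.
#' @export
statistical_features <- function(series) {
  stopifnot(length(series) >= 2)
  mu <- mean(series)
  sigma <- pop_sd(series)
  if (sigma == 0) {
    cv <- 0
  } else if (abs(mu) < 1e-8) {
    warning("near-zero mean: coefficient of variation guarded")
    cv <- sigma / (abs(mu) + 1e-8)
  } else {
    cv <- sigma / mu
  }
  t_ <- seq_along(series)
  slope <- sum((t_ - mean(t_)) * (series - mu)) / sum((t_ - mean(t_))^2)
  qs <- quantile(series, c(0.25, 0.75), names = FALSE, type = 7)
  list(cv = cv, slope = slope, iqr = qs[2] - qs[1])
}

#' Feature names of the 36-dimensional temporal feature vector
#'
#' @return Character vector: 6 DTW deviations, 12 LSTM embedding values,
#'   18 statistical descriptors.
#' @export
feature_names <- function() {
  c(paste0("DTW-", COP_CHANNELS),
    as.vector(t(outer(COP_CHANNELS, 1:2,
                      function(ch, k) paste0("LSTM-", ch, "-", k)))),
    paste0("cv_", COP_CHANNELS),
    paste0("slope_", COP_CHANNELS),
    paste0("iqr_", COP_CHANNELS))
}

#' Extract the 36 temporal features for one preprocessed trial
#'
#' DTW distances are computed between the trial's standardized channels and
#' the healthy template; LSTM embeddings run on the standardized channels;
#' statistical descriptors use the variant named by `stats_on` (default
#' `"translated"`, since the coefficient of variation is degenerate on
#' Z-scored data).
#'
#' @param pre A [preprocess_trial()] result.
#' @param template A [build_template()] result for the same posture.
#' @param dtw A [dtw_params()].
#' @param lstm An [lstm_spec()].
#' @param stats_on `"translated"` or `"standardized"`.
#' @param lstm_w Optional precomputed [lstm_weights()] (avoids regenerating
#'   per trial).
#' @return Named numeric vector of length 36 in [feature_names()] order.
#' @export
extract_features <- function(pre, template, dtw = dtw_params(),
                             lstm = lstm_spec(),
                             stats_on = c("translated", "standardized"),
                             lstm_w = NULL) {
  stats_on <- match.arg(stats_on)
  if (pre$posture != template$posture)
    stop(sprintf("posture mismatch: trial %s vs template %s",
                 pre$posture, template$posture))
  lstm_w <- lstm_w %||% lstm_weights(lstm)
  dtw_v <- vapply(COP_CHANNELS, function(ch)
    dtw_distance(pre$standardized[[ch]], template$curves[[ch]], dtw),
    numeric(1))
  lstm_v <- unlist(lapply(COP_CHANNELS, function(ch)
    lstm_embedding(pre$standardized[[ch]], lstm, weights = lstm_w)))
  st <- lapply(COP_CHANNELS, function(ch)
    statistical_features(pre[[stats_on]][[ch]]))
  out <- c(dtw_v, lstm_v,
           vapply(st, `[[`, numeric(1), "cv"),
           vapply(st, `[[`, numeric(1), "slope"),
           vapply(st, `[[`, numeric(1), "iqr"))
  names(out) <- feature_names()
  out
}

#' Per-subject feature table for one posture
#'
#' Extracts the 36 features for every trial of the posture and, by default,
#' averages the trial-level vectors within subject (the analysis unit is
#' the subject). Returns a data frame with one row per subject (or per
#' trial), the 36 named feature columns, and a `label` column.
#'
#' @param cohort A [cop_cohort()].
#' @param posture Posture code.
#' @param template Matching [build_template()] result.
#' @param pre Optional precomputed [preprocess_cohort()] output.
#' @param dtw,lstm,stats_on Passed to [extract_features()].
#' @param trial_aggregation `"mean"` (default) or `"per_trial"`.
#' @return Data frame with rownames = subject ids (mean mode).
#' @export
feature_table <- function(cohort, posture, template, pre = NULL,
                          dtw = dtw_params(), lstm = lstm_spec(),
                          stats_on = "translated",
                          trial_aggregation = c("mean", "per_trial")) {
  trial_aggregation <- match.arg(trial_aggregation)
  if (is.null(pre)) pre <- preprocess_cohort(cohort)
  pre <- pre[vapply(pre, function(p) p$posture == posture, logical(1))]
  if (!length(pre)) stop(sprintf("no trials for posture %s", posture))
  lstm_w <- lstm_weights(lstm)
  rows <- t(vapply(pre, extract_features, numeric(36), template = template,
                   dtw = dtw, lstm = lstm, stats_on = stats_on,
                   lstm_w = lstm_w))
  ids <- vapply(pre, `[[`, character(1), "subject_id")
  labels <- cohort_labels(cohort)
  if (trial_aggregation == "mean") {
    agg <- rowsum(rows, ids) / as.vector(table(ids)[sort(unique(ids))])
    agg <- agg[order(rownames(agg)), , drop = FALSE]
    df <- as.data.frame(agg, check.names = FALSE)
    df$label <- as.integer(labels[rownames(df)])
  } else {
    df <- as.data.frame(rows, check.names = FALSE)
    df$subject_id <- ids
    df$trial_index <- vapply(pre, `[[`, integer(1), "trial_index")
    df$label <- as.integer(labels[ids])
  }
  df
}
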