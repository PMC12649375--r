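#' Replace isolated outliers by the series mean
#'
#' Flags points deviating more than 3 population SD from the series mean
#' (both computed once, over the full input, before any replacement) and
#' replaces them by the mean. A constant series (SD = 0) is returned
#' unchanged.
#'
#' @param series Numeric vector, length >= 2.
#' @return List with `series` (cleaned vector) and `count` (replacements).
#' @export
clean_outliers <- function(series) {
  stopifnot(length(series) >= 2)
  mu <- mean(series)
  sdev <- pop_sd(series)
  if (sdev == 0) return(list(series = series, count = 0L))
  bad <- abs(series - mu) > 3 * sdev
  if (any(bad)) {
    runs <- rle(bad)
    if (any(runs$lengths[runs$values] >= 5))
      warning("five or more contiguous outliers replaced in one run")
    series[bad] <- mu
  }
  list(series = series, count = sum(bad))
}

#' Translate channels so each starts at the origin
#'
#' Subtracts every channel's first sample from all its samples, removing
#' initial alignment differences while leaving relative displacement
#' unchanged. Idempotent.
#'
#' @param channels Named list of numeric vectors.
#' @return The translated channel list.
#' @export
translate_to_origin <- function(channels) {
  lapply(channels, function(x) x - x[1])
}

#' Z-score a series
#'
#' Centres and scales by the population SD; a constant series maps to all
#' zeros.
#'
#' @param series Numeric vector, length >= 2.
#' @return The standardized vector.
#' @export
zscore <- function(series) {
  stopifnot(length(series) >= 2)
  sdev <- pop_sd(series)
  if (sdev == 0) return(rep(0, length(series)))
  (series - mean(series)) / sdev
}

# population SD (divide by n); the convention used throughout preprocessing
# and the reserve report
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Preprocess one trial
#'
#' Applies, per channel and in this fixed order: outlier replacement
#' ([clean_outliers()]), origin translation ([translate_to_origin()]) and
#' Z-scoring ([zscore()]). Both the translated (mm) and the standardized
#' (unitless) variants are retained: template construction, DTW and LSTM
#' features consume the standardized variant, while the statistical
#' descriptors default to the translated one (the coefficient of variation
#' is degenerate on Z-scored data, whose mean is 0 by construction).
#'
#' @param trial A [cop_trial()].
#' @return An object of class `preprocessed_trial` with fields
#'   `subject_id`, `posture`, `trial_index`, `translated`, `standardized`
#'   and `outlier_count`.
#' @export
preprocess_trial <- function(trial) {
  stopifnot(inherits(trial, "cop_trial"))
  cleaned <- lapply(trial$channels, clean_outliers)
  translated <- translate_to_origin(lapply(cleaned, `[[`, "series"))
  standardized <- lapply(translated, zscore)
  structure(list(subject_id = trial$subject_id, posture = trial$posture,
                 trial_index = trial$trial_index,
                 sampling_rate_hz = trial$sampling_rate_hz,
                 translated = translated, standardized = standardized,
                 outlier_count = vapply(cleaned, `[[`, integer(1), "count")),
            class = "preprocessed_trial")
}

#' Preprocess every trial in a cohort
#'
#' @param cohort A [cop_cohort()].
#' @return List of [preprocess_trial()] results, in cohort trial order.
#' @export
preprocess_cohort <- function(cohort) {
  lapply(cohort$trials, preprocess_trial)
}
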