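#' Construct a single COP trial
#'
#' A trial is one continuous quiet-standing recording for one subject in one
#' posture: six synchronized displacement channels (left foot, right foot and
#' overall centre, each in the mediolateral X and anteroposterior Y
#' direction), sampled at a common rate.
#'
#' @param subject_id Character scalar.
#' @param posture One of `"FT"` (feet together), `"FA"` (feet apart),
#'   `"ST"` (semi-tandem).
#' @param trial_index Integer >= 1.
#' @param channels Named list of six equal-length finite numeric vectors with
#'   names `COP-LX`, `COP-LY`, `COP-RX`, `COP-RY`, `COP-CX`, `COP-CY`
#'   (displacement, mm).
#' @param sampling_rate_hz Positive sampling rate (default 100 Hz).
#' @return An object of class `cop_trial`.
#' @export
cop_trial <- function(subject_id, posture, trial_index, channels,
                      sampling_rate_hz = 100) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  posture <- match.arg(posture, POSTURES)
  trial_index <- as.integer(trial_index)
  stopifnot(trial_index >= 1L, is.numeric(sampling_rate_hz),
            sampling_rate_hz > 0)
  if (!is.list(channels) || !setequal(names(channels), COP_CHANNELS)) {
    missing <- setdiff(COP_CHANNELS, names(channels))
    stop(sprintf("trial %s/%s/%d: missing or misnamed channels (%s)",
                 subject_id, posture, trial_index,
                 paste(missing, collapse = ", ")))
  }
  channels <- channels[COP_CHANNELS]
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1L || lens[1] < 2L)
    stop(sprintf("trial %s/%s/%d: ragged or too-short channels (lengths %s)",
                 subject_id, posture, trial_index,
                 paste(lens, collapse = ",")))
  if (!all(vapply(channels, function(x) all(is.finite(x)), logical(1))))
    stop(sprintf("trial %s/%s/%d: non-finite values", subject_id, posture,
                 trial_index))
  structure(list(subject_id = subject_id, posture = posture,
                 trial_index = trial_index,
                 sampling_rate_hz = sampling_rate_hz,
                 channels = lapply(channels, as.numeric)),
            class = "cop_trial")
}

#' Construct a subject record
#'
#' @param subject_id Character scalar.
#' @param label 0 (control) or 1 (sarcopenia, the positive class Y = 1).
#' @param clinical Optional named list of clinical indicators (e.g. `ASMI`
#'   kg/m^2, `grip` kg, `TCS5` s, `MW6` m/s, `age` y); values must be
#'   positive when present.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, label, clinical = list()) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            label %in% c(0, 1))
  clinical <- clinical[!vapply(clinical, is.null, logical(1))]
  if (length(clinical)) {
    vals <- unlist(clinical)
    num <- vals[names(vals) != "sex"]
    if (length(num) && any(!is.na(suppressWarnings(as.numeric(num))) &
                           as.numeric(num) <= 0))
      stop(sprintf("subject %s: clinical indicators must be positive",
                   subject_id))
  }
  structure(list(subject_id = subject_id, label = as.integer(label),
                 clinical = clinical),
            class = "subject_record")
}

#' Assemble a cohort of subjects and trials
#'
#' @param subjects List of [subject_record()] objects.
#' @param trials List of [cop_trial()] objects; each trial's `subject_id`
#'   must appear among `subjects`.
#' @return An object of class `cop_cohort`.
#' @export
cop_cohort <- function(subjects, trials) {
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  for (tr in trials) {
    if (!tr$subject_id %in% ids)
      stop(sprintf("trial %s/%s/%d: subject missing from metadata",
                   tr$subject_id, tr$posture, tr$trial_index))
  }
  structure(list(subjects = subjects, trials = trials), class = "cop_cohort")
}

#' @export
print.cop_cohort <- function(x, ...) {
  labs <- vapply(x$subjects, function(s) s$label, integer(1))
  cat(sprintf("COP cohort: %d subjects (%d control, %d sarcopenia), %d trials\n",
              length(x$subjects), sum(labs == 0), sum(labs == 1),
              length(x$trials)))
  post <- table(vapply(x$trials, function(t) t$posture, character(1)))
  cat("  trials per posture:",
      paste(sprintf("%s=%d", names(post), post), collapse = ", "), "\n")
  invisible(x)
}

cohort_labels <- function(cohort) {
  ids <- vapply(cohort$subjects, function(s) s$subject_id, character(1))
  stats::setNames(vapply(cohort$subjects, function(s) s$label, integer(1)), ids)
}

cohort_trials <- function(cohort, posture = NULL, subject_id = NULL) {
  keep <- vapply(cohort$trials, function(tr) {
    (is.null(posture) || tr$posture == posture) &&
      (is.null(subject_id) || tr$subject_id == subject_id)
  }, logical(1))
  cohort$trials[keep]
}
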