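#' Read a cohort from long-format CSV plus JSON metadata
#'
#' The data file is long-format delimited text with columns
#' `subject_id, posture, trial_index, sample_index, channel, value`
#' (sample indices 0-based and contiguous per trial x channel). The metadata
#' file is JSON mapping subject id to `label` and optional clinical
#' indicators.
#'
#' @param data_path Path to the long-format CSV.
#' @param meta_path Path to the JSON metadata.
#' @param sampling_rate_hz Sampling rate to attach to trials (default 100).
#' @return A [cop_cohort()].
#' @export
read_cohort <- function(data_path, meta_path, sampling_rate_hz = 100) {
  meta <- jsonlite::read_json(meta_path)
  subjects <- lapply(names(meta), function(id) {
    m <- meta[[id]]
    subject_record(id, m$label,
                   clinical = m[setdiff(names(m), "label")])
  })
  dat <- read.csv(data_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "posture", "trial_index", "sample_index",
            "channel", "value")
  if (!all(need %in% names(dat)))
    stop("data file must have columns: ", paste(need, collapse = ", "))
  trials <- list()
  if (nrow(dat)) {
    ids <- names(meta)
    key <- interaction(dat$subject_id, dat$posture, dat$trial_index,
                       drop = TRUE)
    for (grp in split(dat, key)) {
      sid <- grp$subject_id[1]
      if (!sid %in% ids)
        stop(sprintf("subject %s present in data but absent from metadata", sid))
      if (!grp$posture[1] %in% POSTURES)
        stop(sprintf("subject %s: unknown posture code '%s'", sid,
                     grp$posture[1]))
      chans <- lapply(split(grp, grp$channel), function(g) {
        g <- g[order(g$sample_index), ]
        if (!identical(g$sample_index, seq_len(nrow(g)) - 1L) &&
            !all(g$sample_index == seq_len(nrow(g)) - 1))
          stop(sprintf("subject %s/%s/%d channel %s: sample indices not contiguous from 0",
                       sid, grp$posture[1], grp$trial_index[1], g$channel[1]))
        g$value
      })
      missing <- setdiff(COP_CHANNELS, names(chans))
      if (length(missing))
        stop(sprintf("subject %s posture %s trial %d: missing channel %s",
                     sid, grp$posture[1], grp$trial_index[1],
                     paste(missing, collapse = ", ")))
      trials[[length(trials) + 1L]] <-
        cop_trial(sid, grp$posture[1], grp$trial_index[1], chans,
                  sampling_rate_hz = sampling_rate_hz)
    }
  }
  trials <- trials[order(vapply(trials, function(t)
    sprintf("%s|%s|%05d", t$subject_id, t$posture, t$trial_index),
    character(1)))]
  cop_cohort(subjects, trials)
}

#' Write a cohort to long-format CSV plus JSON metadata
#'
#' Row ordering is deterministic (subject, posture, trial, channel, sample)
#' and values are serialized at 12 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces `x` to that precision.
#'
#' @param cohort A [cop_cohort()].
#' @param data_path Output CSV path.
#' @param meta_path Output JSON path.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, data_path, meta_path) {
  rows <- lapply(cohort$trials, function(tr) {
    do.call(rbind, lapply(COP_CHANNELS, function(ch) {
      v <- tr$channels[[ch]]
      data.frame(subject_id = tr$subject_id, posture = tr$posture,
                 trial_index = tr$trial_index,
                 sample_index = seq_along(v) - 1L, channel = ch,
                 value = signif(v, 12), stringsAsFactors = FALSE)
    }))
  })
  dat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), posture = character(),
               trial_index = integer(), sample_index = integer(),
               channel = character(), value = numeric())
  if (nrow(dat))
    dat <- dat[order(dat$subject_id, dat$posture, dat$trial_index,
                     match(dat$channel, COP_CHANNELS), dat$sample_index), ]
  write.csv(dat, data_path, row.names = FALSE, quote = FALSE)
  meta <- lapply(cohort$subjects, function(s) c(list(label = s$label),
                                               s$clinical))
  names(meta) <- vapply(cohort$subjects, function(s) s$subject_id,
                        character(1))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(data_path, meta_path))
}
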