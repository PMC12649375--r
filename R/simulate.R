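#' Simulation profile for synthetic COP cohorts
#'
#' Defines the generative conditions for a synthetic quiet-standing cohort.
#' Controls sway as a stationary band-limited process (second-order
#' autoregression with a resonance in the typical 0.3-1 Hz quiet-stance
#' band). Patients are generated from the same process with three pathology
#' signatures, each scaled by `(1 - reserve)` so that `reserve = 1` is an
#' exact null (the patient is generated on the identical path as a control):
#' directional drift (a linear trend added to every channel), delayed
#' corrective responses (the sway process lagged by a fixed number of
#' samples), and inflated sway dispersion (the sway component multiplied by
#' `1 + (1 - reserve) * (sway_scale - 1)`).
#'
#' @param n_controls,n_patients Subject counts (controls >= 1).
#' @param postures Subset of `c("FT", "FA", "ST")`.
#' @param trials_per_posture Trials per subject per posture (default 3).
#' @param T_samples Samples per trial (default 2000, i.e. 20 s at 100 Hz).
#' @param fs Sampling rate in Hz (default 100).
#' @param drift_per_sample Patient mean trend, mm per sample (default 0.002,
#'   i.e. 4 mm of directional drift over a 20 s trial at full severity).
#' @param delay_samples Patient corrective lag in samples at full severity
#'   (default 30, a 0.3 s delay).
#' @param sway_scale Patient sway dispersion multiplier at full severity
#'   (default 1.5).
#' @param reserve Per-patient compensatory reserve in `[0, 1]`; either a
#'   vector of length `n_patients`, a scalar recycled to all patients, or
#'   `NULL` to draw uniformly on `[0, 1]` (the default gradient condition).
#' @param base_sway_sd Stationary sway SD of a control channel, mm
#'   (default 2).
#' @param seed Integer seed; the same `(profile, seed)` always yields a
#'   bit-identical cohort.
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(n_controls = 40, n_patients = 42,
                        postures = POSTURES, trials_per_posture = 3,
                        T_samples = 2000, fs = 100,
                        drift_per_sample = 0.002, delay_samples = 30,
                        sway_scale = 1.5, reserve = NULL,
                        base_sway_sd = 2, seed = 1) {
  stopifnot(n_controls >= 1, n_patients >= 0, T_samples >= 2,
            trials_per_posture >= 1, fs > 0, delay_samples >= 0,
            sway_scale >= 1, base_sway_sd > 0)
  postures <- match.arg(postures, POSTURES, several.ok = TRUE)
  if (!is.null(reserve)) {
    if (length(reserve) == 1L) reserve <- rep(reserve, n_patients)
    stopifnot(length(reserve) == n_patients,
              all(reserve >= 0 & reserve <= 1))
  }
  structure(list(n_controls = n_controls, n_patients = n_patients,
                 postures = postures,
                 trials_per_posture = as.integer(trials_per_posture),
                 T_samples = as.integer(T_samples), fs = fs,
                 drift_per_sample = drift_per_sample,
                 delay_samples = as.integer(delay_samples),
                 sway_scale = sway_scale, reserve = reserve,
                 base_sway_sd = base_sway_sd, seed = as.integer(seed)),
            class = "sim_profile")
}

# AR(2) sway with a resonance at f0 Hz and pole radius r; innovation SD set
# from the closed-form stationary variance so the process SD equals sd_target.
ar2_sway <- function(T_samples, fs, sd_target, f0 = 0.5, r = 0.97,
                     burn = 300) {
  phi1 <- 2 * r * cos(2 * pi * f0 / fs)
  phi2 <- -r^2
  svar <- (1 - phi2) / ((1 + phi2) * ((1 - phi2)^2 - phi1^2))
  sd_eps <- sd_target / sqrt(svar)
  n <- T_samples + burn
  eps <- rnorm(n, 0, sd_eps)
  x <- numeric(n)
  x[1] <- eps[1]
  x[2] <- phi1 * x[1] + eps[2]
  for (t in 3:n) x[t] <- phi1 * x[t - 1] + phi2 * x[t - 2] + eps[t]
  x[(burn + 1):n]
}

#' Simulate one COP trial
#'
#' @param profile A [sim_profile()].
#' @param subject_kind `"control"` or `"patient"`.
#' @param reserve Compensatory reserve in `[0, 1]`; ignored for controls.
#' @param seed Integer seed for this trial.
#' @param amp Optional subject-level sway amplitude multiplier (the cohort
#'   generator draws one per subject, uniform within +/-20%); default 1.
#' @param subject_id,posture,trial_index Identity fields for the trial.
#' @return A [cop_trial()] with 6 channels of `profile$T_samples` samples.
#' @export
simulate_trial <- function(profile, subject_kind = c("control", "patient"),
                           reserve = 1, seed = 1, amp = 1,
                           subject_id = "S1", posture = "ST",
                           trial_index = 1) {
  subject_kind <- match.arg(subject_kind)
  if (profile$T_samples < 2) stop("T must be >= 2")
  sev <- if (subject_kind == "patient") 1 - reserve else 0
  T_ <- profile$T_samples
  set.seed(seed)
  disp <- 1 + sev * (profile$sway_scale - 1)
  k <- min(as.integer(round(sev * profile$delay_samples)), T_ - 1L)
  drift <- sev * profile$drift_per_sample * seq_len(T_)
  channels <- lapply(COP_CHANNELS, function(ch) {
    x <- ar2_sway(T_, profile$fs, profile$base_sway_sd * amp)
    if (k > 0) x <- c(rep(x[1], k), x[seq_len(T_ - k)])
    disp * x + drift
  })
  names(channels) <- COP_CHANNELS
  cop_trial(subject_id, posture, trial_index, channels,
            sampling_rate_hz = profile$fs)
}

#' Simulate a labelled cohort
#'
#' Generates `n_controls + n_patients` subjects with
#' `trials_per_posture` trials in each requested posture. Patients carry a
#' compensatory-reserve value; all pathology terms scale with
#' `(1 - reserve)`. Clinical indicators are generated as monotone noisy
#' functions of severity `(1 - reserve)`: ASMI, grip strength and 6-minute
#' walk speed decrease with severity, five-time chair-stand time increases,
#' so correlation analyses have a known expected sign.
#'
#' @param profile A [sim_profile()].
#' @return A [cop_cohort()] with labels and clinical metadata.
#' @export
simulate_cohort <- function(profile) {
  seed <- profile$seed
  n_c <- profile$n_controls
  n_p <- profile$n_patients
  reserve <- profile$reserve
  if (is.null(reserve) && n_p > 0) {
    set.seed(mix_seed(seed, 1L))
    reserve <- runif(n_p)
  }
  set.seed(mix_seed(seed, 2L))
  amps <- runif(n_c + n_p, 0.8, 1.2)

  ids <- c(sprintf("C%03d", seq_len(n_c)),
           if (n_p > 0) sprintf("P%03d", seq_len(n_p)))
  labels <- c(rep(0L, n_c), rep(1L, n_p))
  severities <- c(rep(0, n_c), if (n_p > 0) 1 - reserve)

  subjects <- lapply(seq_along(ids), function(i) {
    set.seed(mix_seed(seed, 3L, i))
    s <- severities[i]
    clin <- list(
      ASMI = max(3, 6.49 - 0.41 * s + rnorm(1, 0, 0.18)),
      grip = max(8, 25.75 - 5.4 * s + rnorm(1, 0, 1.5)),
      TCS5 = max(4, 8.46 + 4.4 * s + rnorm(1, 0, 0.8)),
      MW6  = max(0.3, 1.17 - 0.32 * s + rnorm(1, 0, 0.07)),
      age  = max(60, round(69 + 2 * s + rnorm(1, 0, 6)))
    )
    subject_record(ids[i], labels[i], clinical = clin)
  })

  trials <- list()
  for (i in seq_along(ids)) {
    kind <- if (labels[i] == 1L) "patient" else "control"
    res_i <- if (labels[i] == 1L) 1 - severities[i] else 1
    for (pp in seq_along(profile$postures)) {
      for (tt in seq_len(profile$trials_per_posture)) {
        trials[[length(trials) + 1L]] <- simulate_trial(
          profile, kind, reserve = res_i,
          seed = mix_seed(seed, 4L, i, pp, tt), amp = amps[i],
          subject_id = ids[i], posture = profile$postures[pp],
          trial_index = tt)
      }
    }
  }
  cop_cohort(subjects, trials)
}
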