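# Shared fixtures and independent oracles, built in code at test time.

cop_channel_names <- c("COP-LX", "COP-LY", "COP-RX", "COP-RY",
                       "COP-CX", "COP-CY")

# tiny hand-built trial with deterministic content
toy_trial <- function(subject_id = "S1", posture = "ST", trial_index = 1,
                      T_ = 50, offset = 0) {
  ch <- lapply(seq_along(cop_channel_names), function(k)
    offset + sin(seq_len(T_) / 5 + k) + 0.01 * k * seq_len(T_) / T_)
  names(ch) <- cop_channel_names
  cop_trial(subject_id, posture, trial_index, ch)
}

# cohort of constant-channel controls: subject i has every channel constant
# at value[i] (useful for median oracles); constants break zscore, so only
# used for raw-container tests
toy_cohort <- function(n_controls = 3, n_patients = 1, posture = "ST",
                       T_ = 40, seed = 7) {
  set.seed(seed)
  subjects <- c(
    lapply(seq_len(n_controls), function(i)
      subject_record(sprintf("C%02d", i), 0,
                     clinical = list(ASMI = 6 + i / 10, grip = 25 - i))),
    lapply(seq_len(n_patients), function(i)
      subject_record(sprintf("P%02d", i), 1,
                     clinical = list(ASMI = 5.5, grip = 20)))
  )
  trials <- lapply(subjects, function(s) {
    ch <- lapply(seq_along(cop_channel_names), function(k)
      rnorm(T_, 0, 1) + 0.05 * k)
    names(ch) <- cop_channel_names
    cop_trial(s$subject_id, posture, 1, ch)
  })
  cop_cohort(subjects, trials)
}

# controls sharing one shape up to scale and offset: z-scoring collapses
# both, so every control's standardized series is identical and the
# template must reproduce it exactly
make_constant_cohort <- function(values, posture = "ST", T_ = 30) {
  subjects <- lapply(seq_along(values), function(i)
    subject_record(sprintf("C%02d", i), 0))
  trials <- lapply(seq_along(values), function(i) {
    base <- sin(seq_len(T_) / 3)
    ch <- lapply(1:6, function(k) values[i] * base + i)
    names(ch) <- cop_channel_names
    cop_trial(sprintf("C%02d", i), posture, 1, ch)
  })
  cop_cohort(subjects, trials)
}

# textbook unconstrained DTW by full dynamic programming (independent of the
# banded C++ implementation), with optional backtracked optimal path
dtw_oracle <- function(a, b, gamma = 1, return_path = FALSE) {
  n <- length(a); m <- length(b)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- abs(a[i] - b[j])^gamma
      D[i + 1, j + 1] <- cost + min(D[i, j + 1], D[i + 1, j], D[i, j])
    }
  }
  if (!return_path) return(D[n + 1, m + 1])
  # backtrack (prefer diagonal on ties)
  path <- list(c(n, m))
  i <- n; j <- m
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1 }
    else if (j == 1) { i <- i - 1 }
    else {
      opts <- c(D[i, j], D[i, j + 1], D[i + 1, j])  # diag, up, left
      k <- which.min(opts)
      if (k == 1) { i <- i - 1; j <- j - 1 }
      else if (k == 2) { i <- i - 1 }
      else { j <- j - 1 }
    }
    path[[length(path) + 1L]] <- c(i, j)
  }
  list(dist = D[n + 1, m + 1], path = do.call(rbind, rev(path)))
}

# small separable / null feature matrices for selection and CV tests
separable_features <- function(n_per_class = 15, p = 6, gap = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), ncol = p)
  y <- rep(c(0L, 1L), each = n_per_class)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + gap
  colnames(X) <- paste0("feat", seq_len(p))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(X = X, y = y)
}
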