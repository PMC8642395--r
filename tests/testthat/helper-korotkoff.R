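# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

rms <- function(x) sqrt(mean(x^2))

# A clean (noise-free) reference recording used across test files.
fixture_recording <- function() {
  if (is.null(.fixtures$rec)) {
    p <- sim_params(sbp_true = 120, dbp_true = 80, heart_rate = 75,
                    seed = 3L)
    .fixtures$rec <- simulate_recording(p)
  }
  .fixtures$rec
}

# Its preprocessing products (beats, stacks, labels).
fixture_preprocessed <- function() {
  if (is.null(.fixtures$pp))
    .fixtures$pp <- preprocess_recording(fixture_recording())
  .fixtures$pp
}

# A small labeled stack dataset (two clean recordings, all beats) for
# training sanity checks.
fixture_stack_dataset <- function() {
  if (is.null(.fixtures$ds)) {
    recs <- lapply(c(101L, 102L, 103L), function(s)
      simulate_recording(sim_params(sbp_true = 118, dbp_true = 78,
                                    heart_rate = 80, seed = s)))
    pps <- lapply(recs, preprocess_recording)
    .fixtures$ds <- list(
      x_train = c(pps[[1]]$stacks, pps[[2]]$stacks),
      y_train = c(pps[[1]]$labels, pps[[2]]$labels),
      x_val = pps[[3]]$stacks,
      y_val = pps[[3]]$labels)
  }
  .fixtures$ds
}

# Independent brute-force template-MSE oracle (direct double loop over the
# printed definition; kept free of the package's vectorized path).
oracle_profiles <- function(t, yhat, ceiling = 0.9) {
  N <- length(t)
  curve <- function(tt, ts, td) {
    min(max(min(tt - (ts - 1), -0.5 * (tt - (td + 1))), 0), 1)
  }
  yc <- pmin(yhat, ceiling)
  sbp <- numeric(N); dbp <- numeric(N)
  for (n in 1:N) {
    vs <- c(); vd <- c()
    for (np in -5:4) {
      i <- n + np
      if (i < 1 || i > N) next
      vs <- c(vs, (yc[i] - ceiling * curve(t[i], t[n], t[N]))^2)
      vd <- c(vd, (yc[i] - ceiling * curve(t[i], t[1], t[n]))^2)
    }
    sbp[n] <- mean(vs); dbp[n] <- mean(vd)
  }
  list(sbp = sbp, dbp = dbp)
}

# Envelope-threshold burst counter on a noiseless sound trace: a burst is
# a contiguous region where the K-band envelope exceeds the threshold.
count_bursts <- function(sound, fs, threshold_frac = 0.15) {
  env <- korotkoff:::ksound_envelope(sound, fs)
  thr <- threshold_frac * max(env)
  above <- env > thr
  r <- rle(above)
  sum(r$values & r$lengths > 0.02 * fs)
}
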