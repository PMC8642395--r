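test_that("cuff oscillation filter passes the pulse band and rejects the ramp", {
  fs <- 2560
  t <- (0:(20 * fs - 1)) / fs
  inband <- sin(2 * pi * 5 * t)
  out <- extract_cuff_oscillation(inband, fs)
  mid <- seq(5 * fs, 15 * fs)
  gain <- rms(out[mid]) / rms(inband[mid])
  expect_gt(20 * log10(gain), -3)              # 5 Hz preserved within 3 dB
  ramp <- 80 * sin(2 * pi * 0.1 * t)
  out2 <- extract_cuff_oscillation(ramp, fs)
  att <- 20 * log10(rms(out2[mid]) / rms(ramp[mid]))
  expect_lt(att, -20)                          # deflation-scale motion rejected
  expect_length(out, length(inband))
  expect_error(extract_cuff_oscillation(numeric(100), fs), "short")
})

test_that("the low-pass edge sits at the maximum pulse rate 400/60 Hz", {
  g <- korotkoff:::bp_zero_phase_gain(400 / 60, 4, 400 / 60, order = 1)
  expect_equal(g, 0.5)
  # gain drops monotonically above the edge
  f <- seq(400 / 60, 20, by = 0.1)
  gg <- korotkoff:::bp_zero_phase_gain(f, 4, 400 / 60, order = 1)
  expect_true(all(diff(gg) < 0))
})

test_that("zero-phase filtering does not shift a symmetric pulse peak", {
  fs <- 2560
  n <- 20 * fs
  x <- numeric(n)
  ic <- 10 * fs
  w <- round(0.125 * fs)
  x[(ic - w):(ic + w)] <- 0.5 * (1 + cos(pi * (-w:w) / w))
  out <- extract_cuff_oscillation(x + 100, fs)
  expect_lt(abs(which.max(out) - ic), 0.01 * fs)   # < 10 ms shift
})

test_that("beat peaks are recovered from a synthetic recording", {
  p <- sim_params(sbp_true = 150, dbp_true = 65, start_pressure = 155,
                  end_pressure = 60, deflation_rate = (155 - 60) / 60,
                  heart_rate = 60, seed = 5L)
  rec <- simulate_recording(p)
  osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
  beats <- detect_beat_peaks(osc, rec$cuff_pressure, rec$fs)
  truth <- rec$annotations$beat_times
  expect_lte(abs(length(beats$peak_times) - 60), 1)
  match_err <- vapply(truth, function(x)
    min(abs(x - beats$peak_times)), numeric(1))
  expect_true(all(match_err < 0.05))              # within 50 ms of truth
  expect_true(all(diff(beats$peak_times) >= 60 / 400))
})

test_that("a constant cuff trace yields zero peaks with a warning", {
  expect_warning(b <- detect_beat_peaks(rep(0, 5000), rep(100, 5000), 2560),
                 "no beat peaks")
  expect_length(b$peak_times, 0)
})

test_that("of two candidate peaks 0.1 s apart only the larger is kept", {
  fs <- 2560
  osc <- numeric(4 * fs)
  osc[fs] <- 1; osc[fs + round(0.1 * fs)] <- 0.8
  b <- detect_beat_peaks(osc, rep(100, length(osc)), fs)
  expect_length(b$peak_times, 1)
  expect_equal(b$peak_times, (fs - 1) / fs)
})

test_that("peak detection is invariant to a constant cuff offset", {
  rec <- fixture_recording()
  osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
  osc2 <- extract_cuff_oscillation(rec$cuff_pressure + 37.5, rec$fs)
  b1 <- detect_beat_peaks(osc, rec$cuff_pressure, rec$fs)
  b2 <- detect_beat_peaks(osc2, rec$cuff_pressure + 37.5, rec$fs)
  expect_equal(b1$peak_times, b2$peak_times)
  expect_equal(b2$peak_cuff_pressures, b1$peak_cuff_pressures + 37.5)
})

test_that("segments are 1024 samples, centered, zero-padded at edges", {
  fs <- 2560
  sound <- rnorm(10 * fs)
  seg <- extract_segment(sound, 5, fs)
  expect_length(seg, 1024)
  ic <- round(5 * fs) + 1
  expect_identical(seg, sound[(ic - 512):(ic + 511)])
  # peak 0.1 s from the start: left 0.1 s of the window is zero-padded
  seg2 <- extract_segment(sound, 0.1, fs)
  expect_length(seg2, 1024)
  n_pad <- 512 - round(0.1 * fs)
  expect_true(all(seg2[seq_len(n_pad)] == 0))
  expect_true(any(seg2[-seq_len(n_pad)] != 0))
})

test_that("the filter bank has 50 bands of 10 Hz from 25 to 525 Hz", {
  st <- bandpass_stack(rnorm(1024), 2560)
  expect_identical(dim(st), c(50L, 1024L))
  be <- attr(st, "band_edges")
  expect_equal(be[, "low"], 25 + 10 * (0:49))
  expect_equal(be[, "high"], 35 + 10 * (0:49))
  expect_equal(nrow(be), (515 - 25) / 10 + 1)
  expect_error(bandpass_stack(rnorm(1000), 2560), "1024")
})

test_that("a pure 100 Hz tone concentrates energy in the 95-105 Hz band", {
  seg <- sin(2 * pi * 100 * (0:1023) / 2560)
  st <- bandpass_stack(seg, 2560, normalize = FALSE)
  expect_equal(which.max(rowSums(st^2)), 8L)     # band 8 = [95, 105] Hz
})

test_that("an all-zero segment gives an all-zero stack", {
  st <- bandpass_stack(numeric(1024), 2560)
  expect_true(all(st == 0))
})

test_that("stack energy is bounded by the in-band segment energy", {
  set.seed(4)
  for (k in 1:5) {
    seg <- rnorm(1024)
    st <- bandpass_stack(seg, 2560, normalize = FALSE)
    X <- fft(seg)
    f <- pmin((0:1023) / 1024 * 2560, 2560 - (0:1023) / 1024 * 2560)
    inband <- sum(Mod(X[f >= 25 & f <= 525])^2) / 1024
    expect_lt(sum(st^2), inband * 1.1)
  }
})

test_that("filtering commutes with time reversal (zero phase)", {
  set.seed(5)
  seg <- rnorm(1024)
  a <- bandpass_stack(rev(seg), 2560, normalize = FALSE)
  b <- bandpass_stack(seg, 2560, normalize = FALSE)
  expect_equal(unclass(a), unclass(b)[, 1024:1], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("stacks are normalized by the raw segment RMS", {
  seg <- sin(2 * pi * 100 * (0:1023) / 2560) * 3
  st <- bandpass_stack(seg, 2560)
  expect_equal(attr(st, "segment_rms"), rms(seg))
  raw <- bandpass_stack(seg, 2560, normalize = FALSE)
  expect_equal(unclass(st), unclass(raw) / rms(seg), ignore_attr = TRUE)
})

test_that("preprocess_recording ties beats, stacks and labels together", {
  pp <- fixture_preprocessed()
  expect_length(pp$stacks, length(pp$beats$peak_times))
  expect_length(pp$labels, length(pp$beats$peak_times))
  expect_true(all(pp$labels >= 0 & pp$labels <= 1))
  expect_true(any(pp$labels == 1) && any(pp$labels == 0))
})
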