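test_that("simulation parameters are validated", {
  expect_error(sim_params(sbp_true = 120, dbp_true = 80,
                          start_pressure = 110), "ordering")
  expect_error(sim_params(dbp_true = 80, end_pressure = 90), "ordering")
  expect_error(sim_params(heart_rate = 30), "heart_rate")
  expect_error(sim_params(heart_rate = 200), "heart_rate")
  expect_error(sim_params(snr_db = NA), "snr_db")
  expect_error(sim_params(pulse_amplitude = 3.5), "below 3 mmHg")
})

test_that("ground truth is stored verbatim and traces are consistent", {
  p <- sim_params(sbp_true = 120, dbp_true = 80, start_pressure = 160,
                  end_pressure = 40, seed = 1L)
  rec <- simulate_recording(p)
  expect_identical(rec$annotations$sbp, 120)
  expect_identical(rec$annotations$dbp, 80)
  expect_equal(rec$annotations$t_sbp, (160 - 120) / 3)
  expect_length(rec$sound_pressure, length(rec$cuff_pressure))
  expect_identical(rec$fs, 2560)
  expect_true(all(rec$cuff_pressure >= 0))
  # deflation trend: smoothed cuff is non-increasing
  sm <- stats::filter(rec$cuff_pressure, rep(1 / 2560, 2560))
  expect_true(all(diff(sm[!is.na(sm)]) <= 1e-6))
})

test_that("identical seed gives bit-identical recordings", {
  p <- sim_params(seed = 42L, snr_db = 8)
  a <- simulate_recording(p)
  b <- simulate_recording(p)
  expect_identical(a$sound_pressure, b$sound_pressure)
  expect_identical(a$cuff_pressure, b$cuff_pressure)
})

test_that("burst count matches duration x heart rate when audible span covers the recording", {
  # window chosen so the audibility span covers essentially all beats
  p <- sim_params(sbp_true = 150.5, dbp_true = 65, start_pressure = 151,
                  end_pressure = 64, deflation_rate = (151 - 64) / 60,
                  heart_rate = 60, seed = 5L)
  rec <- simulate_recording(p)
  expect_lte(abs(count_bursts(rec$sound_pressure, rec$fs, 0.1) - 60), 1)
})

test_that("burst envelope is confined to the audibility window", {
  rec <- fixture_recording()
  ann <- rec$annotations
  p <- rec$params
  t <- (seq_along(rec$sound_pressure) - 1) / rec$fs
  before <- abs(rec$sound_pressure[t < ann$t_sbp - p$onset_ramp - 0.1])
  after <- abs(rec$sound_pressure[t > ann$t_dbp + p$offset_ramp + 0.1])
  expect_true(all(before == 0))
  expect_true(all(after == 0))
  inside <- abs(rec$sound_pressure[t > ann$t_sbp + 1 & t < ann$t_dbp - 1])
  expect_gt(max(inside), 0)
})

test_that("cuff oscillation is present at every beat and below 3 mmHg", {
  rec <- fixture_recording()
  osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
  idx <- round(rec$annotations$beat_times * rec$fs) + 1
  at_beats <- vapply(idx, function(i)
    max(abs(osc[max(1, i - 100):min(length(osc), i + 100)])), numeric(1))
  expect_true(all(at_beats > 0))
  expect_true(all(at_beats < 3))
})

test_that("auscultatory gap attenuates the beats following onset", {
  p <- sim_params(gap_probability = 1, seed = 9L)
  rec <- simulate_recording(p)
  amps <- rec$annotations$burst_amplitudes
  aud <- which(amps > 0)
  first <- aud[1]
  # 2nd-4th audible beats attenuated to at most 5% of full amplitude
  expect_true(all(amps[first + 1:3] <= 0.05 * max(amps) * (1 + 1e-9)))
})

test_that("noise injection closes the loop with the SNR estimator", {
  rec <- fixture_recording()
  for (target in c(8, -2.9)) {
    noisy <- inject_noise(rec, target, seed = 11L)
    expect_equal(estimate_snr(noisy), target, tolerance = 1)
  }
  expect_identical(inject_noise(rec, Inf), rec)
  bare <- rec; bare$annotations <- NULL
  expect_error(inject_noise(bare, 8), "annotations")
})

test_that("make_dataset is reproducible, respects ranges and splits disjointly", {
  rng <- list(sbp = c(100, 140), dbp = c(60, 90), heart_rate = c(55, 95),
              snr_db = c(Inf, Inf), gap_probability = 0)
  d1 <- make_dataset(10, ranges = rng, seed = 7L)
  d2 <- make_dataset(10, ranges = rng, seed = 7L)
  expect_identical(lapply(d1, `[[`, "sound_pressure"),
                   lapply(d2, `[[`, "sound_pressure"))
  sbps <- vapply(d1, function(r) r$annotations$sbp, numeric(1))
  expect_true(all(sbps >= 100 & sbps <= 140))
  splits <- vapply(d1, function(r) r$annotations$split, character(1))
  expect_setequal(unique(splits), c("train", "validation", "test"))
  expect_length(splits, 10)
  expect_error(make_dataset(3, ranges = list(sbp = NULL)), "ranges")
})

test_that("gap_probability = 1 attenuates early post-systolic beats in every recording", {
  rng <- list(sbp = c(110, 130), dbp = c(70, 85), heart_rate = c(60, 90),
              snr_db = c(Inf, Inf), gap_probability = 1)
  d <- make_dataset(4, ranges = rng, seed = 13L)
  for (rec in d) {
    amps <- rec$annotations$burst_amplitudes
    aud <- which(amps > 0)
    expect_true(all(amps[aud[1] + 1:3] <= 0.05 * max(amps) * (1 + 1e-9)))
  }
})
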