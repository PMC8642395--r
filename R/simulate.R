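#' Simulation parameters for a synthetic Korotkoff-cycle recording
#'
#' Defines one cuff-deflation measurement: a linear deflation from
#' `start_pressure` (above systolic) to `end_pressure` (below diastolic),
#' per-beat oscillometric pulses on the cuff channel, and one damped
#' Korotkoff-sound burst per beat on the sound channel whose envelope spans
#' the audibility window around the true systolic/diastolic pressures.
#'
#' @param sbp_true,dbp_true ground-truth systolic/diastolic pressure (mmHg).
#' @param start_pressure,end_pressure cuff pressure at the start/end of the
#'   deflation (mmHg); must bracket `sbp_true`/`dbp_true`.
#' @param deflation_rate deflation speed (mmHg/s); 3 mmHg/s is a typical
#'   clinical rate.
#' @param duration recording length (s); default `NULL` derives it from the
#'   pressure span and deflation rate. If longer, the cuff holds at
#'   `end_pressure`.
#' @param heart_rate beats per minute, within \[40, 180\].
#' @param ksound_band frequency band (Hz) carrying the burst energy.
#' @param burst_duration duration of each damped burst (s).
#' @param onset_ramp,offset_ramp seconds over which burst amplitude grows
#'   around the systolic point and decays around the diastolic point. The
#'   burst envelope is exactly zero before `t_SBP - onset_ramp` and after
#'   `t_DBP + offset_ramp`.
#' @param gap_probability probability that the recording contains an
#'   auscultatory gap (the 2nd-4th audible beats attenuated to
#'   near-inaudibility, x0.05).
#' @param snr_db target signal-to-noise ratio in dB as measured by
#'   [estimate_snr()]; `Inf` means no added noise.
#' @param pulse_amplitude peak oscillometric pulse amplitude (mmHg, < 3).
#' @param hr_jitter fractional standard deviation of beat-to-beat interval.
#' @param fs sampling rate (Hz).
#' @param seed integer master seed; identical parameters give bit-identical
#'   recordings.
#' @return a `sim_params` list.
#' @export
sim_params <- function(sbp_true = 120, dbp_true = 80,
                       start_pressure = sbp_true + 40,
                       end_pressure = max(dbp_true - 40, 5),
                       deflation_rate = 3, duration = NULL,
                       heart_rate = 75, ksound_band = c(25, 200),
                       burst_duration = 0.15,
                       onset_ramp = 0.5, offset_ramp = 1,
                       gap_probability = 0, snr_db = Inf,
                       pulse_amplitude = 2, hr_jitter = 0.02,
                       fs = 2560, seed = 1L) {
  p <- list(sbp_true = sbp_true, dbp_true = dbp_true,
            start_pressure = start_pressure, end_pressure = end_pressure,
            deflation_rate = deflation_rate, duration = duration,
            heart_rate = heart_rate, ksound_band = ksound_band,
            burst_duration = burst_duration, onset_ramp = onset_ramp,
            offset_ramp = offset_ramp, gap_probability = gap_probability,
            snr_db = snr_db, pulse_amplitude = pulse_amplitude,
            hr_jitter = hr_jitter, fs = fs, seed = as.integer(seed))
  validate_sim_params(p)
  if (is.null(p$duration))
    p$duration <- (start_pressure - end_pressure) / deflation_rate
  # round up to 0.1 s so the trace length is a multiple of 256 at 2560 Hz:
  # highly composite lengths keep the mixed-radix FFTs fast
  p$duration <- ceiling(p$duration * 10) / 10
  class(p) <- "sim_params"
  p
}

validate_sim_params <- function(p) {
  if (!(p$start_pressure > p$sbp_true && p$sbp_true > p$dbp_true &&
        p$dbp_true > p$end_pressure))
    stop("pressure ordering must satisfy start > SBP > DBP > end")
  if (p$heart_rate < 40 || p$heart_rate > 180)
    stop("heart_rate must lie in [40, 180] beats/min")
  if (is.na(p$snr_db)) stop("snr_db must be a number (or Inf for no noise)")
  if (p$deflation_rate <= 0) stop("deflation_rate must be positive")
  if (p$pulse_amplitude >= 3)
    stop("oscillometric pulse amplitude must stay below 3 mmHg")
  invisible(p)
}

new_recording <- function(cuff, sound, fs, annotations = NULL, params = NULL) {
  stopifnot(length(cuff) == length(sound))
  structure(list(cuff_pressure = cuff, sound_pressure = sound,
                 fs = fs, annotations = annotations, params = params),
            class = "ks_recording")
}

# Piecewise-linear audibility envelope of burst amplitude over the
# deflation: 0 before t_SBP - onset_ramp, 1 from t_SBP + onset_ramp to
# t_DBP - offset_ramp, 0 after t_DBP + offset_ramp.
audibility <- function(t, t_sbp, t_dbp, onset_ramp, offset_ramp) {
  up <- pmin(pmax((t - (t_sbp - onset_ramp)) / (2 * onset_ramp), 0), 1)
  down <- pmin(pmax(((t_dbp + offset_ramp) - t) / (2 * offset_ramp), 0), 1)
  pmin(up, down)
}

#' Simulate one Korotkoff-cycle recording
#'
#' Generates synchronized cuff-pressure and stethoscope sound traces with
#' exact ground-truth annotations, so every downstream stage (beat
#' detection, labeling, training, the decision rule, SNR estimation) can be
#' tested against known truth. The cuff trace is a linear deflation plus a
#' raised-cosine oscillometric pulse per beat whose amplitude follows a
#' bell curve over the deflation; the sound trace holds one damped
#' multi-sinusoid burst per beat, windowed by the audibility envelope.
#'
#' @param params a [sim_params()] object.
#' @return a `ks_recording` with elements `cuff_pressure` (mmHg),
#'   `sound_pressure` (Pa), `fs`, `annotations` (ground truth: `t_sbp`,
#'   `t_dbp`, `sbp`, `dbp`, `beat_times`, `burst_amplitudes`, `seed`) and
#'   `params`.
#' @export
simulate_recording <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration * p$fs)
    t <- (seq_len(n) - 1) / p$fs
    cuff <- pmax(p$start_pressure - p$deflation_rate * t, p$end_pressure)

    t_sbp <- (p$start_pressure - p$sbp_true) / p$deflation_rate
    t_dbp <- (p$start_pressure - p$dbp_true) / p$deflation_rate

    # beat train with mild RR jitter
    period <- 60 / p$heart_rate
    beats <- numeric(0)
    tb <- 0.4 * period
    while (tb < p$duration - 0.25) {
      beats <- c(beats, tb)
      tb <- tb + period * (1 + p$hr_jitter * rnorm(1))
    }

    # oscillometric pulses: raised-cosine bumps, bell-shaped amplitude
    map <- p$dbp_true + (p$sbp_true - p$dbp_true) / 3
    pw <- 0.25                                      # pulse width (s)
    amp <- p$pulse_amplitude *
      exp(-((p$start_pressure - p$deflation_rate * beats) - map)^2 / 35^2) +
      0.25
    for (k in seq_along(beats)) {
      i0 <- round((beats[k] - pw / 2) * p$fs) + 1
      ii <- i0:(i0 + round(pw * p$fs) - 1)
      keep <- ii >= 1 & ii <= n
      u <- (ii[keep] - i0) / (pw * p$fs)
      cuff[ii[keep]] <- cuff[ii[keep]] + amp[k] * 0.5 * (1 - cos(2 * pi * u))
    }

    # Korotkoff bursts: damped mixture of sinusoids in ksound_band
    sound <- numeric(n)
    aud <- audibility(beats, t_sbp, t_dbp, p$onset_ramp, p$offset_ramp)
    # auscultatory gap: attenuate 2nd-4th audible beats
    if (p$gap_probability > 0 && runif(1) < p$gap_probability) {
      aidx <- which(aud > 0)
      gap <- aidx[aidx >= aidx[1] + 1 & aidx <= aidx[1] + 3]
      aud[gap] <- aud[gap] * 0.05
    }
    nb <- round(p$burst_duration * p$fs)
    tau <- p$burst_duration / 3
    for (k in seq_along(beats)) {
      f3 <- runif(3, p$ksound_band[1], p$ksound_band[2])
      ph <- runif(3, 0, 2 * pi)
      w <- c(1, 0.6, 0.35)
      if (aud[k] <= 0) next
      i0 <- round((beats[k] - p$burst_duration / 3) * p$fs) + 1
      ii <- i0:(i0 + nb - 1)
      keep <- ii >= 1 & ii <= n
      tt <- (ii[keep] - i0) / p$fs
      burst <- (w[1] * sin(2 * pi * f3[1] * tt + ph[1]) +
                w[2] * sin(2 * pi * f3[2] * tt + ph[2]) +
                w[3] * sin(2 * pi * f3[3] * tt + ph[3])) *
        exp(-tt / tau) * (1 - exp(-tt / 0.004))
      sound[ii[keep]] <- sound[ii[keep]] + 0.2 * aud[k] * burst
    }

    ann <- list(t_sbp = t_sbp, t_dbp = t_dbp,
                sbp = p$sbp_true, dbp = p$dbp_true,
                beat_times = beats, burst_amplitudes = 0.2 * aud,
                seed = p$seed)
    rec <- new_recording(cuff, sound, p$fs, annotations = ann, params = p)
    if (is.finite(p$snr_db))
      rec <- inject_noise(rec, p$snr_db, seed = derive_seed(p$seed, 7L))
    rec
  })
}

#' Add calibrated white noise to a recording
#'
#' Adds zero-mean Gaussian noise to the sound channel, scaled so that the
#' signal-to-noise ratio of the returned recording, as measured by
#' [estimate_snr()], equals `snr_db` (closed loop, within the root-finding
#' tolerance, well inside 1 dB). The cuff channel is left untouched.
#'
#' @param rec a `ks_recording` with ground-truth annotations (`t_sbp`,
#'   `t_dbp`); the SNR definition needs them.
#' @param snr_db target SNR in dB; `Inf` returns the recording unchanged.
#' @param seed integer seed for the noise realization.
#' @return the noisy `ks_recording`; `annotations$snr_db` records the target.
#' @export
inject_noise <- function(rec, snr_db, seed = 1L) {
  stopifnot(inherits(rec, "ks_recording"))
  if (is.infinite(snr_db) && snr_db > 0) return(rec)
  ann <- rec$annotations
  if (is.null(ann) || is.null(ann$t_sbp) || is.null(ann$t_dbp))
    stop("inject_noise needs ground-truth annotations (t_sbp, t_dbp): ",
         "the SNR definition is undefined without them")
  noise <- with_seed(seed, rnorm(length(rec$sound_pressure)))
  # reference scale: RMS burst peak level of the clean signal
  ref <- max(rms(rec$sound_pressure), 1e-6)
  f <- function(log10_sigma) {
    s2 <- rec
    s2$sound_pressure <- rec$sound_pressure + 10^log10_sigma * noise
    estimate_snr(s2) - snr_db
  }
  lo <- log10(ref) - 5; hi <- log10(ref) + 4
  if (f(hi) > 0)
    stop("requested SNR ", snr_db, " dB is below the estimator floor ",
         "for this recording")
  if (f(lo) < 0)
    stop("requested SNR ", snr_db, " dB is above what calibration can reach")
  root <- uniroot(f, c(lo, hi), tol = 1e-4)$root
  rec$sound_pressure <- rec$sound_pressure + 10^root * noise
  rec$annotations$snr_db <- snr_db
  rec
}

#' Generate a seeded dataset of synthetic recordings
#'
#' Draws per-recording parameters independently from the given ranges and
#' assigns disjoint train/validation/test split labels per recording.
#'
#' @param n_recordings number of recordings (>= 1).
#' @param ranges named list of `c(min, max)` ranges for `sbp`, `dbp`,
#'   `heart_rate` and `snr_db` (use `c(Inf, Inf)` for clean recordings),
#'   plus scalar `gap_probability`.
#' @param seed master seed; per-recording sub-seeds are derived from it.
#' @param split train/validation/test sizes, as fractions summing to 1 or
#'   absolute counts summing to `n_recordings`.
#' @return list of `ks_recording`s; each has attribute-free
#'   `annotations$split` holding its split label.
#' @export
make_dataset <- function(n_recordings,
                         ranges = list(sbp = c(100, 140), dbp = c(60, 90),
                                       heart_rate = c(55, 95),
                                       snr_db = c(Inf, Inf),
                                       gap_probability = 0),
                         seed = 1L,
                         split = c(train = 0.7, validation = 0.15,
                                   test = 0.15)) {
  stopifnot(n_recordings >= 1)
  for (nm in c("sbp", "dbp", "heart_rate", "snr_db"))
    if (is.null(ranges[[nm]]) || length(ranges[[nm]]) != 2 ||
        any(is.na(ranges[[nm]])))
      stop("ranges$", nm, " must be a length-2 numeric range")
  gp <- if (is.null(ranges$gap_probability)) 0 else ranges$gap_probability
  draws <- with_seed(seed, {
    list(sbp = runif(n_recordings, ranges$sbp[1], ranges$sbp[2]),
         dbp = runif(n_recordings, ranges$dbp[1], ranges$dbp[2]),
         hr = runif(n_recordings, ranges$heart_rate[1], ranges$heart_rate[2]),
         snr = if (all(is.infinite(ranges$snr_db))) rep(Inf, n_recordings)
               else runif(n_recordings, ranges$snr_db[1], ranges$snr_db[2]))
  })
  if (sum(split) == n_recordings && all(split == round(split))) {
    n_tr <- split[1]; n_va <- split[2]     # absolute counts
  } else {
    n_tr <- round(split[1] * n_recordings)
    n_va <- round(split[2] * n_recordings)
  }
  labels <- rep(c("train", "validation", "test"),
                c(n_tr, n_va, n_recordings - n_tr - n_va))
  lapply(seq_len(n_recordings), function(i) {
    p <- sim_params(sbp_true = draws$sbp[i], dbp_true = draws$dbp[i],
                    heart_rate = draws$hr[i], snr_db = draws$snr[i],
                    gap_probability = gp,
                    seed = derive_seed(seed, i))
    rec <- simulate_recording(p)
    rec$annotations$split <- labels[i]
    rec
  })
}

#' @export
print.ks_recording <- function(x, ...) {
  n <- length(x$cuff_pressure)
  cat("Korotkoff recording:", round(n / x$fs, 1), "s at", x$fs, "Hz\n")
  cat("  cuff pressure:", round(max(x$cuff_pressure), 1), "->",
      round(min(x$cuff_pressure), 1), "mmHg\n")
  if (!is.null(x$annotations) && !is.null(x$annotations$sbp))
    cat("  ground truth: SBP", round(x$annotations$sbp, 1), "/ DBP",
        round(x$annotations$dbp, 1), "mmHg;",
        length(x$annotations$beat_times), "beats\n")
  invisible(x)
}

#' @export
plot.ks_recording <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  t <- (seq_along(x$cuff_pressure) - 1) / x$fs
  plot(t, x$cuff_pressure, type = "l", xlab = "time (s)",
       ylab = "cuff pressure (mmHg)", ...)
  plot(t, x$sound_pressure, type = "l", xlab = "time (s)",
       ylab = "sound pressure (Pa)", ...)
  if (!is.null(x$annotations))
    graphics::abline(v = c(x$annotations$t_sbp, x$annotations$t_dbp),
                     col = 2, lty = 2)
  invisible(x)
}
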