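#' Extract the cuff-pressure oscillation
#'
#' Band-passes the raw cuff trace to 4-6.67 Hz (the upper edge being the
#' maximum physiologic pulse of 400/min = 400/60 s), removing the slow
#' deflation ramp and leaving the per-beat oscillometric component. The
#' trace is linearly detrended and filtered zero-phase, so beat peak times
#' are not shifted and the output has the same length as the input.
#'
#' @param cuff raw cuff-pressure series (mmHg).
#' @param fs sampling rate (Hz); must exceed twice the 6.67 Hz upper edge.
#' @return filtered series, same length as `cuff`.
#' @export
extract_cuff_oscillation <- function(cuff, fs) {
  if (fs <= 2 * 400 / 60) stop("fs must exceed twice the 6.67 Hz cutoff")
  if (length(cuff) < fs) stop("cuff trace shorter than 1 s: too short to filter")
  n <- length(cuff)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), cuff)
  detr <- cuff - fit$fitted.values
  # gentle (order-1 prototype) edges: a sharper band this narrow rings for
  # several tenths of a second and produces spurious side-lobe maxima
  fft_bandpass(detr, fs, 4, 400 / 60, order = 1)
}

#' Detect beat peaks in the cuff oscillation
#'
#' Local-maximum search on the band-passed cuff oscillation with a minimum
#' separation of 60/400 s (maximum pulse 400/min) and a prominence rule:
#' a candidate is kept only if its height reaches 25% of the running
#' median of candidate peak heights, which rejects noise ripples while
#' keeping weak early beats. Each retained peak is paired with the raw
#' cuff pressure at its time.
#'
#' @param oscillation output of [extract_cuff_oscillation()].
#' @param cuff raw cuff-pressure series (same length).
#' @param fs sampling rate (Hz).
#' @return a `beat_peaks` object: `peak_times` (s, strictly increasing),
#'   `peak_cuff_pressures` (mmHg), `indices`.
#' @export
detect_beat_peaks <- function(oscillation, cuff, fs) {
  stopifnot(length(oscillation) == length(cuff))
  n <- length(oscillation)
  x <- oscillation
  cand <- which(x[-c(1, n)] > x[-c(n - 1, n)] &
                x[-c(1, n)] >= x[-c(1, 2)]) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand) == 0) {
    warning("no beat peaks found in cuff oscillation")
    return(structure(list(peak_times = numeric(0),
                          peak_cuff_pressures = numeric(0),
                          indices = integer(0)), class = "beat_peaks"))
  }
  # local dominance: filter ringing produces side-lobe maxima ~0.2 s from
  # the true peak at a fraction of its height; drop any candidate with a
  # much larger candidate nearby (shortest physiologic period is 0.33 s)
  h <- x[cand]
  tc <- (cand - 1) / fs
  dom <- vapply(seq_along(cand), function(i) {
    near <- abs(tc - tc[i]) <= 0.3
    h[i] >= max(h[near]) / 2.2
  }, logical(1))
  cand <- cand[dom]
  h <- x[cand]
  k <- min(15L, length(h) - (length(h) + 1) %% 2)  # odd window <= 15
  ref <- if (k >= 3) stats::runmed(h, k) else rep(stats::median(h), length(h))
  cand <- cand[h >= 0.25 * ref]
  # enforce 60/400 s minimum separation, keeping the larger peak
  min_sep <- round(60 / 400 * fs)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in ord)
    if (!any(abs(keep - i) < min_sep)) keep <- c(keep, i)
  keep <- sort(keep)
  structure(list(peak_times = (keep - 1) / fs,
                 peak_cuff_pressures = cuff[keep],
                 indices = keep), class = "beat_peaks")
}

#' @export
print.beat_peaks <- function(x, ...) {
  cat(length(x$peak_times), "beat peaks")
  if (length(x$peak_times))
    cat(";", round(min(x$peak_times), 2), "-",
        round(max(x$peak_times), 2), "s, cuff",
        round(max(x$peak_cuff_pressures), 1), "->",
        round(min(x$peak_cuff_pressures), 1), "mmHg")
  cat("\n")
  invisible(x)
}

#' Extract a 0.4 s sound segment centered at a beat peak
#'
#' The window is `[peak - 0.2 s, peak + 0.2 s)`, i.e. `round(0.4 * fs)`
#' samples (1024 at 2560 Hz). Peaks closer than 0.2 s to either end are
#' zero-padded rather than discarded, so the beat count is preserved for
#' the decision rule.
#'
#' @param sound sound-pressure series (Pa).
#' @param peak_time beat peak time (s).
#' @param fs sampling rate (Hz).
#' @return numeric vector of `round(0.4 * fs)` samples.
#' @export
extract_segment <- function(sound, peak_time, fs) {
  len <- round(0.4 * fs)
  ic <- round(peak_time * fs) + 1L
  ii <- seq(ic - len %/% 2, length.out = len)
  seg <- numeric(len)
  ok <- ii >= 1 & ii <= length(sound)
  seg[ok] <- sound[ii[ok]]
  seg
}

.bank_cache <- new.env(parent = emptyenv())

# 50-row matrix of zero-phase gains for the filter bank at (fs, n).
bank_gains <- function(fs, n) {
  key <- paste(fs, n)
  if (!is.null(.bank_cache[[key]])) return(.bank_cache[[key]])
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  lo <- 25 + 10 * (0:49)
  g <- vapply(seq_along(lo),
              function(k) bp_zero_phase_gain(f, lo[k], lo[k] + 10, order = 2),
              numeric(n))                       # n x 50
  .bank_cache[[key]] <- g
  g
}

#' Build the band-pass-filtered signal stack for one segment
#'
#' Filters the 0.4 s segment through 50 contiguous band-pass filters of
#' 10 Hz bandwidth, low cutoffs 25 to 515 Hz (high cutoffs 35 to 525 Hz),
#' and stacks the filtered waveforms into a 50 x 1024 image. The rows are
#' real-valued zero-phase filtered waveforms, not magnitudes, so phase
#' information is preserved. With `normalize = TRUE` (the default used for
#' network input) the stack is divided by the RMS of the raw segment; the
#' RMS is kept as attribute `segment_rms`.
#'
#' @param segment numeric vector of `round(0.4 * fs)` samples.
#' @param fs sampling rate (Hz).
#' @param normalize divide by the raw segment RMS (skipped for an all-zero
#'   segment, which yields an all-zero stack).
#' @return a `signal_stack`: 50 x 1024 matrix with attributes `band_edges`
#'   (50 x 2, Hz), `fs`, `segment_rms`.
#' @export
bandpass_stack <- function(segment, fs = 2560, normalize = TRUE) {
  n <- round(0.4 * fs)
  if (length(segment) != n)
    stop("segment must have ", n, " samples at fs = ", fs)
  g <- bank_gains(fs, n)                         # n x 50
  X <- fft(segment)
  filt <- Re(stats::mvfft(matrix(X, n, 50) * g, inverse = TRUE)) / n
  stack <- t(filt)                               # 50 x n
  srms <- rms(segment)
  if (normalize && srms > 0) stack <- stack / srms
  lo <- 25 + 10 * (0:49)
  structure(stack,
            band_edges = cbind(low = lo, high = lo + 10),
            fs = fs, segment_rms = srms, class = c("signal_stack", "matrix"))
}

#' Preprocess a recording into beats, labels and signal stacks
#'
#' Runs the full front end on one recording: cuff-oscillation extraction,
#' beat-peak detection, 0.4 s sound segmentation at each cuff peak, and
#' the 50-band stack for each segment. When ground-truth annotations are
#' present, per-beat probability labels from the human-response curve are
#' attached.
#'
#' @param rec a `ks_recording`.
#' @param normalize per-segment RMS normalization of the stacks.
#' @return list with `beats` (a `beat_peaks`), `stacks` (list of
#'   `signal_stack`), and `labels` (per-beat probabilities, or NULL).
#' @export
preprocess_recording <- function(rec, normalize = TRUE) {
  osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
  beats <- detect_beat_peaks(osc, rec$cuff_pressure, rec$fs)
  stacks <- lapply(beats$peak_times, function(pt)
    bandpass_stack(extract_segment(rec$sound_pressure, pt, rec$fs), rec$fs,
                   normalize = normalize))
  labels <- NULL
  ann <- rec$annotations
  if (!is.null(ann) && !is.null(ann$t_sbp))
    labels <- label_beats(beats, ann$t_sbp, ann$t_dbp)
  list(beats = beats, stacks = stacks, labels = labels)
}
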