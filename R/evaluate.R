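#' Estimate the signal-to-noise ratio of a recording
#'
#' SNR as defined for auscultatory recordings: the noise level is the RMS
#' of the sound signal before the systolic time (excluding the first
#' second, which may hold the inflation transient), and the signal level
#' is the RMS of the per-beat Korotkoff-sound peak amplitudes between the
#' systolic and diastolic times. Peaks are measured on the smoothed
#' amplitude envelope of the 25-200 Hz band (rectified band-passed signal,
#' 20 Hz zero-phase low-pass), at beats located from the cuff channel, so
#' the measurement stays meaningful down to strongly negative SNR. The
#' estimate is scale-invariant in the sound trace.
#'
#' @param rec a `ks_recording`.
#' @param t_sbp,t_dbp systolic/diastolic times (s); default from the
#'   recording's annotations.
#' @return SNR in dB: `20 log10(signal level / noise level)`.
#' @export
estimate_snr <- function(rec, t_sbp = NULL, t_dbp = NULL) {
  stopifnot(inherits(rec, "ks_recording"))
  ann <- rec$annotations
  if (is.null(t_sbp)) t_sbp <- ann$t_sbp
  if (is.null(t_dbp)) t_dbp <- ann$t_dbp
  if (is.null(t_sbp) || is.null(t_dbp))
    stop("estimate_snr needs t_sbp and t_dbp (annotations or arguments)")
  fs <- rec$fs
  if (t_sbp < 0.5) stop("empty pre-systolic region: cannot estimate noise")
  t0 <- if (t_sbp > 1.5) 1 else 0.25 * t_sbp
  pre <- rec$sound_pressure[(round(t0 * fs) + 1):round(t_sbp * fs)]
  noise_level <- rms(pre)
  if (noise_level == 0) return(Inf)

  beats <- if (!is.null(ann$beat_times)) ann$beat_times
           else {
             osc <- extract_cuff_oscillation(rec$cuff_pressure, fs)
             detect_beat_peaks(osc, rec$cuff_pressure, fs)$peak_times
           }
  beats <- beats[beats > t_sbp & beats < t_dbp]
  if (length(beats) == 0)
    stop("no beats between t_sbp and t_dbp: cannot estimate signal level")
  env <- ksound_envelope(rec$sound_pressure, fs)
  n <- length(env)
  peaks <- vapply(beats, function(tb) {
    ii <- max(1, round((tb - 0.15) * fs)):min(n, round((tb + 0.15) * fs))
    max(env[ii])
  }, numeric(1))
  20 * log10(rms(peaks) / noise_level)
}

#' Blood-pressure error statistics
#'
#' Errors are `predicted - reference` in mmHg. Reports, separately for the
#' systolic and diastolic pressures, the mean, the sample standard
#' deviation (n - 1 denominator) and the number of cases whose absolute
#' error exceeds 5 mmHg. When per-recording SNR values are supplied, a
#' second stratum restricted to recordings with SNR below the set's mean
#' is added.
#'
#' @param predicted list of `bp_result`s, or a data frame with columns
#'   `sbp`, `dbp`.
#' @param reference data frame (or list of lists) with columns `sbp`,
#'   `dbp`, same length.
#' @param snr optional per-recording SNR values (dB) for stratification.
#' @return a `bp_error_stats` data frame with columns `quantity`,
#'   `stratum`, `mean_error`, `sd_error`, `n_exceeding_5mmHg`, `n_total`.
#' @export
bp_error_stats <- function(predicted, reference, snr = NULL) {
  as_bp_df <- function(x) {
    if (is.data.frame(x)) return(x)
    data.frame(sbp = vapply(x, function(r) r$sbp, numeric(1)),
               dbp = vapply(x, function(r) r$dbp, numeric(1)))
  }
  p <- as_bp_df(predicted); r <- as_bp_df(reference)
  if (nrow(p) != nrow(r))
    stop("predicted and reference must have the same length")
  one <- function(err, stratum, quantity) {
    data.frame(quantity = quantity, stratum = stratum,
               mean_error = mean(err), sd_error = sd(err),
               n_exceeding_5mmHg = sum(abs(err) > 5), n_total = length(err))
  }
  es <- p$sbp - r$sbp; ed <- p$dbp - r$dbp
  out <- rbind(one(es, "all", "SBP"), one(ed, "all", "DBP"))
  if (!is.null(snr)) {
    stopifnot(length(snr) == nrow(p))
    low <- snr < mean(snr)
    if (any(low))
      out <- rbind(out, one(es[low], "low-SNR", "SBP"),
                   one(ed[low], "low-SNR", "DBP"))
  }
  class(out) <- c("bp_error_stats", "data.frame")
  out
}

#' @export
print.bp_error_stats <- function(x, ...) {
  cat("Blood-pressure errors (predicted - reference)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-3s [%7s]  %5.1f +/- %4.1f mmHg   >5 mmHg: %d / %d\n",
                x$quantity[i], x$stratum[i], x$mean_error[i], x$sd_error[i],
                x$n_exceeding_5mmHg[i], x$n_total[i]))
  invisible(x)
}
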