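#' Human-response probability label curve
#'
#' Piecewise-linear probability that a beat at time `t` is heard as an
#' audible Korotkoff sound, given the times `t_sbp` and `t_dbp` at which
#' the systolic and diastolic pressures were determined. It encodes that a
#' listener may respond up to one second late at the systolic onset and up
#' to one second early or late at the diastolic offset:
#' \deqn{y = 0} for `t < t_sbp - 1` or `t > t_dbp + 1`;
#' \deqn{y = t - (t_sbp - 1)} on `[t_sbp - 1, t_sbp]`;
#' \deqn{y = 1} for `t_sbp < t < t_dbp - 1`;
#' \deqn{y = -0.5 (t - (t_dbp + 1))} on `[t_dbp - 1, t_dbp + 1]`.
#'
#' The whole curve equals `min(onset ramp, offset ramp)` clamped to
#' \[0, 1\], which is also how the degenerate short-cycle case
#' `t_dbp - t_sbp < 1` (empty plateau) is defined: the pointwise minimum of
#' the two ramps, preserving continuity and bounds.
#'
#' @param t time or vector of times (s).
#' @param t_sbp,t_dbp systolic/diastolic determination times (s),
#'   `t_sbp < t_dbp`.
#' @return probability value(s) in \[0, 1\].
#' @export
label_curve <- function(t, t_sbp, t_dbp) {
  if (!(t_sbp < t_dbp)) stop("t_sbp must be earlier than t_dbp")
  label_curve_raw(t, t_sbp, t_dbp)
}

# Min-of-ramps form without the ordering check; the decision-rule
# templates pin one endpoint to t_1 or t_N, which may coincide with the
# candidate time at the series edge.
label_curve_raw <- function(t, t_sbp, t_dbp) {
  onset <- t - (t_sbp - 1)
  offset <- -0.5 * (t - (t_dbp + 1))
  pmin(pmax(pmin(onset, offset), 0), 1)
}

#' Assign human-response labels to detected beats
#'
#' Evaluates [label_curve()] at each beat peak time.
#'
#' @param peaks a `beat_peaks` object (non-empty).
#' @param t_sbp,t_dbp systolic/diastolic determination times (s).
#' @return numeric vector of per-beat probabilities.
#' @export
label_beats <- function(peaks, t_sbp, t_dbp) {
  stopifnot(inherits(peaks, "beat_peaks"))
  if (length(peaks$peak_times) == 0) stop("no beats to label")
  label_curve(peaks$peak_times, t_sbp, t_dbp)
}
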