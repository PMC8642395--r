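#' Ordered per-beat probability series
#'
#' Container for the decision rule: strictly increasing beat times, the
#' network's per-beat Korotkoff-sound probabilities, and the raw cuff
#' pressure at each beat.
#'
#' @param t beat times (s), strictly increasing.
#' @param yhat per-beat probabilities in \[0, 1\].
#' @param cuff cuff pressure (mmHg) at each beat, positive.
#' @return a `beat_series`.
#' @export
beat_series <- function(t, yhat, cuff) {
  stopifnot(length(t) == length(yhat), length(t) == length(cuff))
  if (any(diff(t) <= 0)) stop("beat times must be strictly increasing")
  if (any(cuff <= 0)) stop("cuff pressures must be positive")
  if (any(yhat < 0 | yhat > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(t = t, yhat = yhat, cuff = cuff, N = length(t)),
            class = "beat_series")
}

#' Clip probabilities at the decision ceiling
#'
#' Predicted probabilities exceeding the ceiling (0.9) are replaced by it;
#' the matching label-curve template is correspondingly scaled by the same
#' ceiling. Idempotent.
#'
#' @param yhat probabilities in \[0, 1\].
#' @param ceiling clipping value (0.9).
#' @return clipped probabilities.
#' @export
clip_probabilities <- function(yhat, ceiling = 0.9) pmin(yhat, ceiling)

# Shared window: ten consecutive template values around the candidate,
# n' = -5..4; indices outside 1..N are excluded and the mean is taken over
# the remaining terms. The template is the label curve scaled by the
# ceiling, evaluated at the actual beat times.
profile_mse <- function(series, ceiling, sbp_side) {
  N <- series$N
  if (N < 2) stop("need at least 2 beats for an MSE profile")
  yc <- clip_probabilities(series$yhat, ceiling)
  t <- series$t
  vapply(seq_len(N), function(n) {
    idx <- n + (-5:4)
    idx <- idx[idx >= 1 & idx <= N]
    tmpl <- if (sbp_side)
      ceiling * label_curve_raw(t[idx], t_sbp = t[n], t_dbp = t[N])
    else
      ceiling * label_curve_raw(t[idx], t_sbp = t[1], t_dbp = t[n])
    mean((yc[idx] - tmpl)^2)
  }, numeric(1))
}

#' Per-candidate MSE profile for the systolic decision
#'
#' For each candidate beat `n`, compares the clipped probabilities in the
#' ten-beat window around `n` with the onset part of the ceiling-scaled
#' label curve placed at `t_sbp = t_n` (with `t_dbp` pinned to `t_N` so it
#' cannot affect the value). The systolic time is the profile's argmin.
#'
#' @param series a [beat_series()].
#' @param ceiling clipping/scaling ceiling (0.9).
#' @return numeric vector of length `N` of per-candidate MSE values.
#' @export
sbp_mse_profile <- function(series, ceiling = 0.9)
  profile_mse(series, ceiling, sbp_side = TRUE)

#' Per-candidate MSE profile for the diastolic decision
#'
#' Mirror of [sbp_mse_profile()]: the template is the offset part of the
#' label curve placed at `t_dbp = t_n` (with `t_sbp` pinned to `t_1`).
#'
#' @inheritParams sbp_mse_profile
#' @return numeric vector of length `N`.
#' @export
dbp_mse_profile <- function(series, ceiling = 0.9)
  profile_mse(series, ceiling, sbp_side = FALSE)

#' Decide systolic and diastolic pressure from a probability series
#'
#' Template-matching decision rule: the systolic index minimizes the
#' systolic MSE profile and the diastolic index minimizes the diastolic
#' profile, subject to the systolic beat preceding the diastolic beat; on
#' conflict the pair minimizing the sum of the two profiles over all
#' ordered pairs is taken. Ties break toward the earlier beat (higher cuff
#' pressure) for the systolic point and the later beat for the diastolic
#' point. The cuff pressures at the selected beats are the reported
#' pressures.
#'
#' @param series a [beat_series()] with at least 4 beats.
#' @param ceiling probability ceiling (0.9).
#' @return a `bp_result`: `sbp`, `dbp` (mmHg), `n_sbp`, `n_dbp` (beat
#'   indices), `t_sbp`, `t_dbp` (s), the two MSE profiles, and `flags`
#'   (`degenerate` when the profiles are flat).
#' @export
decide_bp <- function(series, ceiling = 0.9) {
  stopifnot(inherits(series, "beat_series"))
  if (series$N < 4) stop("need at least 4 beats to decide blood pressure")
  ps <- sbp_mse_profile(series, ceiling)
  pd <- dbp_mse_profile(series, ceiling)
  degenerate <- (max(ps) - min(ps) < 1e-12) && (max(pd) - min(pd) < 1e-12)
  n_s <- which.min(ps)                                  # earliest on ties
  n_d <- max(which(pd == min(pd)))                      # latest on ties
  if (n_s >= n_d) {
    # joint constrained minimization over ordered pairs
    best <- Inf; n_s <- 1L; n_d <- 2L
    for (i in seq_len(series$N - 1)) {
      j <- which.min(pd[(i + 1):series$N]) + i
      v <- ps[i] + pd[j]
      if (v < best) { best <- v; n_s <- i; n_d <- j }
    }
  }
  structure(list(sbp = series$cuff[n_s], dbp = series$cuff[n_d],
                 n_sbp = n_s, n_dbp = n_d,
                 t_sbp = series$t[n_s], t_dbp = series$t[n_d],
                 mse_sbp_profile = ps, mse_dbp_profile = pd,
                 method = "proposed",
                 flags = list(degenerate = degenerate)),
            class = "bp_result")
}

#' @export
print.bp_result <- function(x, ...) {
  cat("Blood pressure decision (", x$method, " method)\n", sep = "")
  if (isTRUE(x$flags$undecidable)) {
    cat("  undecidable: no run of two consecutive K-sound calls\n")
    return(invisible(x))
  }
  cat(sprintf("  SBP %.1f mmHg (beat %d, t = %.2f s)\n",
              x$sbp, x$n_sbp, x$t_sbp))
  cat(sprintf("  DBP %.1f mmHg (beat %d, t = %.2f s)\n",
              x$dbp, x$n_dbp, x$t_dbp))
  if (isTRUE(x$flags$degenerate))
    cat("  warning: flat MSE profiles (degenerate input)\n")
  invisible(x)
}

#' @export
plot.bp_result <- function(x, ...) {
  if (is.null(x$mse_sbp_profile)) {
    warning("no MSE profiles to plot for this result")
    return(invisible(x))
  }
  n <- seq_along(x$mse_sbp_profile)
  graphics::matplot(n, cbind(x$mse_sbp_profile, x$mse_dbp_profile),
                    type = "l", lty = 1, col = c(2, 4), xlab = "beat index",
                    ylab = "template MSE", ...)
  graphics::abline(v = c(x$n_sbp, x$n_dbp), col = c(2, 4), lty = 3)
  graphics::legend("topright", c("systolic", "diastolic"),
                   col = c(2, 4), lty = 1, bty = "n")
  invisible(x)
}
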