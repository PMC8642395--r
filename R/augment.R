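#' Training-time augmentation configuration
#'
#' Three augmentations are applied to every training stack, in the fixed
#' order noise -> circular shift -> cutout, each with freshly drawn
#' parameters (zero noise and zero shift are inside the draw ranges, so
#' identity is reachable). Augmentation is never applied at prediction
#' time.
#'
#' @param noise_max_frac upper bound of the white-noise RMS as a fraction
#'   of the segment RMS (stacks are per-segment RMS normalized, so the
#'   reference RMS is 1 on the stack scale).
#' @param shift_max maximum circular time shift in seconds (0.0977 s = 250
#'   samples at 2560 Hz).
#' @param cutout_frac per-axis fraction of the input blanked by cutout
#'   (0.3 of 50 x 1024 gives a 15 x 307 region).
#' @param cutout_fill value written into the cutout region.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(noise_max_frac = 0.1, shift_max = 0.0977,
                                cutout_frac = 0.3, cutout_fill = 0.05) {
  stopifnot(noise_max_frac >= 0, noise_max_frac <= 1,
            cutout_frac >= 0, cutout_frac <= 1,
            shift_max >= 0, shift_max <= 0.2)
  structure(list(noise_max_frac = noise_max_frac, shift_max = shift_max,
                 cutout_frac = cutout_frac, cutout_fill = cutout_fill),
            class = "augmentation_config")
}

#' Add white noise to a signal stack
#'
#' Adds independent zero-mean Gaussian noise with RMS equal to
#' `u * segment RMS`, `u ~ Uniform(0, noise_max_frac)`. On the normalized
#' stack scale the segment RMS is 1. Draws use the current R RNG stream,
#' so results are reproducible under `set.seed()`.
#'
#' @param stack a `signal_stack` (or plain matrix).
#' @param cfg an [augmentation_config()].
#' @return the noisy stack.
#' @export
add_white_noise <- function(stack, cfg = augmentation_config()) {
  if (cfg$noise_max_frac == 0) return(stack)
  u <- runif(1, 0, cfg$noise_max_frac)
  stack + rnorm(length(stack), sd = u)
}

#' Circularly shift a signal stack along time
#'
#' Rotates all 50 rows by one common integer sample offset drawn uniformly
#' from `{-s_max, ..., s_max}` with `s_max = round(shift_max * fs)` (250
#' samples, 97.7 ms, at 2560 Hz). Values are conserved: the operation is a
#' pure column rotation.
#'
#' @inheritParams add_white_noise
#' @param shift optional fixed shift in samples (overrides the draw).
#' @return the shifted stack.
#' @export
circular_shift <- function(stack, cfg = augmentation_config(), shift = NULL) {
  fs <- attr(stack, "fs"); if (is.null(fs)) fs <- 2560
  smax <- round(cfg$shift_max * fs)
  s <- if (is.null(shift)) sample.int(2L * smax + 1L, 1L) - smax - 1L
       else as.integer(shift)
  if (s == 0) return(stack)
  nc <- ncol(stack)
  s <- ((s %% nc) + nc) %% nc
  stack[, c((nc - s + 1):nc, 1:(nc - s)), drop = FALSE]
}

#' Cutout: blank a random rectangular region of the stack
#'
#' Selects a rectangle of 30% of the input per axis (floored: 15 x 307 for
#' a 50 x 1024 stack), placed uniformly at random fully inside the stack,
#' and overwrites it with `cutout_fill` (0.05).
#'
#' @inheritParams add_white_noise
#' @return the stack with one region filled.
#' @export
cutout <- function(stack, cfg = augmentation_config()) {
  if (cfg$cutout_frac == 0) return(stack)
  h <- floor(cfg$cutout_frac * nrow(stack))
  w <- floor(cfg$cutout_frac * ncol(stack))
  r0 <- sample.int(nrow(stack) - h + 1L, 1L)
  c0 <- sample.int(ncol(stack) - w + 1L, 1L)
  stack[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- cfg$cutout_fill
  stack
}

#' Apply the full training augmentation chain
#'
#' Noise, then circular shift, then cutout, in that fixed order.
#'
#' @inheritParams add_white_noise
#' @return the augmented stack.
#' @export
augment_stack <- function(stack, cfg = augmentation_config()) {
  cutout(circular_shift(add_white_noise(stack, cfg), cfg), cfg)
}
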