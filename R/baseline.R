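# Baseline comparison method: binary K-sound classification on spectrogram
# input plus the consecutive-beat decision rule.

#' Extract the 1 s sound window around a beat for the baseline method
#'
#' @param sound sound-pressure series (Pa).
#' @param peak_time beat peak time (s).
#' @param fs sampling rate (Hz).
#' @return numeric vector of `fs` samples (zero-padded at the edges).
#' @export
extract_baseline_segment <- function(sound, peak_time, fs) {
  len <- round(fs)
  ic <- round(peak_time * fs) + 1L
  ii <- seq(ic - len %/% 2, length.out = len)
  seg <- numeric(len)
  ok <- ii >= 1 & ii <= length(sound)
  seg[ok] <- sound[ii[ok]]
  seg
}

#' Spectrogram input for the baseline classifier
#'
#' One second of sound is resampled to 2 kHz and converted to a 60 x 116
#' magnitude spectrogram: 60 ms Hann frames (16.7 Hz frequency
#' resolution), a 16-sample hop (approximately 87% overlap; the hop is
#' fixed and the frame sequence end-trimmed so the frame count is exactly
#' 116), the lowest 60 frequency bins retained, magnitude in dB re 1 Pa
#' with a -120 dB floor.
#'
#' @param sound numeric vector holding (at least) 1 s of sound around a
#'   beat; longer inputs are center-cropped, shorter ones zero-padded.
#' @param fs sampling rate of `sound` (Hz).
#' @return a `spectrogram_input`: 60 x 116 matrix (dB) with attribute
#'   `freq_resolution` (Hz).
#' @export
spectrogram_input <- function(sound, fs = 2560) {
  n1 <- round(fs)
  if (length(sound) > n1) {
    c0 <- (length(sound) - n1) %/% 2
    sound <- sound[(c0 + 1):(c0 + n1)]
  } else if (length(sound) < n1) {
    sound <- c(sound, numeric(n1 - length(sound)))
  }
  x <- if (fs != 2000) as.numeric(signal::resample(sound, 2000, fs))
       else sound
  x <- x[seq_len(min(length(x), 2000))]
  if (length(x) < 2000) x <- c(x, numeric(2000 - length(x)))
  frame_len <- 120L; hop <- 16L; n_frames <- 116L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(frame_len) / frame_len)
  frames <- vapply(seq_len(n_frames), function(k) {
    i0 <- (k - 1L) * hop
    x[(i0 + 1):(i0 + frame_len)] * w
  }, numeric(frame_len))
  X <- stats::mvfft(frames)[1:60, , drop = FALSE]
  amp <- abs(X) / sum(w)
  amp[-1, ] <- 2 * amp[-1, ]                    # one-sided amplitude
  db <- 20 * log10(pmax(amp, 1e-6))
  db <- pmax(db, -120)
  structure(db, freq_resolution = 2000 / frame_len,
            class = c("spectrogram_input", "matrix"))
}

# ---- small conv stack --------------------------------------------------

baseline_arch <- function() {
  list(in_h = 60, in_w = 116, channels = c(8, 16, 32))
}

#' Build the baseline spectrogram classifier
#'
#' A small convolutional stack on the 60 x 116 spectrogram: three 3 x 3
#' convolution layers (8, 16, 32 channels) each followed by a rectifier
#' applied before 2 x 2 max pooling, then concatenated global average and
#' global max pooling feeding a single sigmoid output.
#'
#' @param seed seed for weight initialization.
#' @return an untrained `baseline_model`.
#' @export
baseline_build_model <- function(seed = 1L) {
  arch <- baseline_arch()
  p <- with_seed(seed, {
    ch <- c(1, arch$channels)
    p <- list()
    for (l in 1:3) {
      p[[paste0("conv", l, ".w")]] <- he_init(ch[l + 1], ch[l] * 9)
      p[[paste0("conv", l, ".b")]] <- rep(0, ch[l + 1])
    }
    p[["fc.w"]] <- rnorm(2 * ch[4], sd = 1 / sqrt(2 * ch[4]))
    p[["fc.b"]] <- 0
    p
  })
  structure(list(arch = arch, params = p, history = NULL, trained = FALSE),
            class = "baseline_model")
}

add_channel_bias <- function(x, b, B) {
  d <- dim(x); hw <- d[1] * d[2]
  x + array(rep(rep(b, times = B), each = hw), d)
}

baseline_fwd <- function(p, arch, X) {
  B <- if (length(dim(X)) == 3) dim(X)[3] else 1L
  if (length(dim(X)) == 2) dim(X) <- c(dim(X), 1L)
  ch <- c(1, arch$channels)
  cache <- list(B = B, acts = list(), pools = list())
  # fixed input affine: dB values (-120..0) to roughly unit scale, keeping
  # absolute level information (the discriminative cue for K-sounds)
  x <- (X + 60) / 30
  for (l in 1:3) {
    cache$acts[[l]] <- x
    h <- conv2d_fwd(x, dim(x), p[[paste0("conv", l, ".w")]], B,
                    ch[l], ch[l + 1], 3L, 3L, 1L, 1L, 1L, 1L)
    h <- add_channel_bias(h, p[[paste0("conv", l, ".b")]], B)
    r <- relu_fwd(h)
    cache$pre <- c(cache$pre, list(h))
    mp <- maxpool_fwd(r, dim(r), 2L, 2L, 2L, 2L, 0L, 0L)
    cache$pools[[l]] <- list(idx = mp$idx, in_dim = dim(r))
    x <- mp$y
  }
  d <- dim(x); hw <- d[1] * d[2]; C <- ch[4]
  xm <- x; dim(xm) <- c(hw, d[3])
  # head: global average and global max pooling, concatenated
  amax <- apply(xm, 2, which.max)
  feat <- cbind(t(matrix(colMeans(xm), C, B)),
                t(matrix(xm[cbind(amax, seq_len(d[3]))], C, B)))
  logit <- as.numeric(feat %*% p[["fc.w"]]) + p[["fc.b"]]
  cache$feat <- feat; cache$last_dim <- d; cache$amax <- amax
  list(prob = stats::plogis(logit), cache = cache)
}

baseline_bwd <- function(p, arch, cache, dlogit) {
  B <- cache$B
  ch <- c(1, arch$channels)
  g <- list()
  g[["fc.w"]] <- as.numeric(t(cache$feat) %*% dlogit)
  g[["fc.b"]] <- sum(dlogit)
  d <- cache$last_dim; hw <- d[1] * d[2]; C <- ch[4]
  dfeat <- outer(dlogit, p[["fc.w"]])           # B x 2C
  davg <- dfeat[, seq_len(C), drop = FALSE]
  dmax <- dfeat[, C + seq_len(C), drop = FALSE]
  dxm <- matrix(rep(as.numeric(t(davg)), each = hw) / hw, hw, d[3])
  dxm[cbind(cache$amax, seq_len(d[3]))] <-
    dxm[cbind(cache$amax, seq_len(d[3]))] + as.numeric(t(dmax))
  dx <- dxm; dim(dx) <- d
  for (l in 3:1) {
    pl <- cache$pools[[l]]
    dr <- maxpool_bwd(dx, dim(dx), pl$idx, pl$in_dim[1], pl$in_dim[2])
    dh <- dr * (cache$pre[[l]] > 0)
    # channel bias gradient
    dd <- dim(dh); hw2 <- dd[1] * dd[2]
    dm <- dh; dim(dm) <- c(hw2, dd[3])
    g[[paste0("conv", l, ".b")]] <-
      as.numeric(rowsum(colSums(dm), rep(seq_len(ch[l + 1]), times = B)))
    cb <- conv2d_bwd(cache$acts[[l]], dim(cache$acts[[l]]),
                     p[[paste0("conv", l, ".w")]], dh,
                     B, ch[l], ch[l + 1], 3L, 3L, 1L, 1L, 1L, 1L)
    g[[paste0("conv", l, ".w")]] <- cb$dw
    dx <- cb$dx
  }
  g
}

#' Train the baseline classifier
#'
#' Binary cross-entropy on 0/1 labels (a beat is labeled 1 iff it lies
#' between the systolic and diastolic times). The model with the highest
#' validation accuracy (0.5 threshold) is kept; training stops after
#' `patience_epochs` epochs without improvement (default 100).
#'
#' @param dataset list with `x_train` (list of 60 x 116 spectrograms),
#'   `y_train` (0/1), `x_val`, `y_val`.
#' @param cfg a [train_config()].
#' @param model optional pre-built `baseline_model`.
#' @param verbose print one line per epoch.
#' @return the trained `baseline_model` with `history` and `val_accuracy`.
#' @export
baseline_train <- function(dataset, cfg = train_config(patience_epochs = 100),
                           model = NULL, verbose = FALSE) {
  if (length(dataset$x_train) == 0 || length(dataset$x_val) == 0)
    stop("dataset must contain non-empty train and validation splits")
  if (is.null(model))
    model <- baseline_build_model(seed = derive_seed(cfg$seed, 2L))
  arch <- model$arch
  p <- model$params
  opt <- adam_init(p)
  xval <- stacks_to_array(dataset$x_val)
  ntr <- length(dataset$y_train)
  hist <- data.frame(epoch = integer(0), train_bce = numeric(0),
                     val_accuracy = numeric(0))
  best <- list(acc = -Inf, params = p, epoch = 0L)
  wait <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(ntr)
      bce_sum <- 0; nb <- 0
      for (b0 in seq(1, ntr, by = cfg$batch_size)) {
        ii <- ord[b0:min(b0 + cfg$batch_size - 1, ntr)]
        X <- stacks_to_array(dataset$x_train[ii])
        y <- dataset$y_train[ii]
        fw <- baseline_fwd(p, arch, X)
        bce_sum <- bce_sum + bce_loss(y, fw$prob) * length(ii)
        nb <- nb + length(ii)
        g <- baseline_bwd(p, arch, fw$cache, (fw$prob - y) / length(ii))
        up <- adam_step(p, g, opt, cfg$learning_rate, cfg$weight_decay)
        p <- up$params; opt <- up$opt
      }
      vp <- baseline_fwd(p, arch, xval)$prob
      acc <- mean((vp > 0.5) == (dataset$y_val > 0.5))
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_bce = bce_sum / nb,
                                     val_accuracy = acc))
      if (verbose)
        message(sprintf("epoch %3d  train BCE %.4f  val acc %.3f",
                        epoch, bce_sum / nb, acc))
      if (acc > best$acc) {
        best <- list(acc = acc, params = p, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience_epochs) break
      }
    }
  })
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model$val_accuracy <- best$acc
  model$trained <- TRUE
  model
}

#' Classify beats as Korotkoff sounds (baseline)
#'
#' @param model a trained `baseline_model`.
#' @param spectrograms list of 60 x 116 `spectrogram_input`s (beat order),
#'   a single one, or a 3-d array.
#' @return integer vector of 0/1 calls (0.5 threshold on the sigmoid
#'   output).
#' @export
baseline_classify <- function(model, spectrograms) {
  stopifnot(inherits(model, "baseline_model"))
  X <- stacks_to_array(spectrograms)
  if (dim(X)[1] != model$arch$in_h || dim(X)[2] != model$arch$in_w)
    stop("spectrogram geometry must be ", model$arch$in_h, " x ",
         model$arch$in_w)
  n <- dim(X)[3]
  out <- numeric(n)
  for (b0 in seq(1, n, by = 64L)) {
    ii <- b0:min(b0 + 63L, n)
    out[ii] <- baseline_fwd(model$params, model$arch,
                            X[, , ii, drop = FALSE])$prob
  }
  as.integer(out > 0.5)
}

#' Consecutive-beat decision rule (baseline)
#'
#' The systolic pressure is the cuff pressure at the first beat of the
#' first run of at least two consecutive K-sound calls; the diastolic
#' pressure is the cuff pressure at the last beat of the last such run —
#' the moment after which beats no longer appear. With no run of two
#' consecutive calls the result is flagged undecidable. The rule's noise
#' sensitivity (a spurious pre-systolic call run shifts the systolic
#' decision) is intentional: it is the behavior the template-matching
#' rule is compared against.
#'
#' @param calls integer 0/1 per-beat K-sound calls.
#' @param series a [beat_series()] with matching beat count (its `yhat` is
#'   not used by this rule).
#' @return a `bp_result` with `method = "baseline"`.
#' @export
baseline_decide <- function(calls, series) {
  stopifnot(inherits(series, "beat_series"), length(calls) == series$N)
  if (series$N < 2) stop("need at least 2 beats")
  r <- rle(as.integer(calls))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values == 1L & r$lengths >= 2L)
  if (length(runs) == 0) {
    return(structure(list(sbp = NA_real_, dbp = NA_real_,
                          n_sbp = NA_integer_, n_dbp = NA_integer_,
                          t_sbp = NA_real_, t_dbp = NA_real_,
                          mse_sbp_profile = NULL, mse_dbp_profile = NULL,
                          method = "baseline",
                          flags = list(undecidable = TRUE)),
                     class = "bp_result"))
  }
  n_s <- starts[runs[1]]
  n_d <- ends[runs[length(runs)]]
  structure(list(sbp = series$cuff[n_s], dbp = series$cuff[n_d],
                 n_sbp = n_s, n_dbp = n_d,
                 t_sbp = series$t[n_s], t_dbp = series$t[n_d],
                 mse_sbp_profile = NULL, mse_dbp_profile = NULL,
                 method = "baseline", flags = list(undecidable = FALSE)),
            class = "bp_result")
}

#' Measure blood pressure from a recording with the baseline method
#'
#' @param model a trained `baseline_model`.
#' @param rec a `ks_recording`.
#' @return a `bp_result` with `method = "baseline"`.
#' @export
baseline_measure_bp <- function(model, rec) {
  osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
  beats <- detect_beat_peaks(osc, rec$cuff_pressure, rec$fs)
  specs <- lapply(beats$peak_times, function(pt)
    spectrogram_input(extract_baseline_segment(rec$sound_pressure, pt,
                                               rec$fs), rec$fs))
  calls <- baseline_classify(model, specs)
  series <- beat_series(beats$peak_times, rep(0.5, length(calls)),
                        beats$peak_cuff_pressures)
  baseline_decide(calls, series)
}
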