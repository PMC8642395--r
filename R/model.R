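#' Build the probability-output residual network
#'
#' Constructs the adapted 18-layer residual CNN: the standard four-stage,
#' two-block-per-stage residual layout with batch normalization, modified
#' for this task in three ways — the first convolution takes a single
#' 50 x 1024 band-pass-filtered signal stack (one channel; its time stride
#' is widened to 4 to match the 20:1 aspect ratio of the stack), the final
#' fully connected layer maps to a single output, and a sigmoid head
#' yields a probability in (0, 1). `width_scale` scales every channel
#' width, so narrow desk-scale variants train quickly on one CPU while
#' `width_scale = 1` reproduces the canonical channel widths
#' (64/128/256/512).
#'
#' @param width_scale channel width multiplier (> 0).
#' @param conv1_time_stride stride of the first convolution along time.
#' @param seed seed for weight initialization.
#' @return an untrained `ksbp_model`.
#' @export
build_model <- function(width_scale = 0.25, conv1_time_stride = 4,
                        seed = 1L) {
  stopifnot(width_scale > 0)
  arch <- resnet_arch(width_scale, conv1_time_stride = conv1_time_stride)
  init <- init_resnet(arch, seed = seed)
  structure(list(arch = arch, params = init$params, bn_state = init$state,
                 history = NULL, trained = FALSE, config = NULL,
                 seed = as.integer(seed)),
            class = "ksbp_model")
}

#' Number of trainable parameters of a model
#' @param model a `ksbp_model`.
#' @return integer count (convolutions, batch-norm affine terms, final
#'   fully connected layer).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "ksbp_model"))
  sum(vapply(model$params, length, numeric(1)))
}

#' Binary cross-entropy with fractional labels
#'
#' \deqn{L = -(1/N) \sum [ y_n \log \hat y_n + (1 - y_n) \log(1 - \hat y_n) ]}
#' Supports fractional labels from the human-response curve; predictions
#' are clamped away from 0 and 1.
#'
#' @param y true labels in \[0, 1\].
#' @param yhat predicted probabilities in \[0, 1\].
#' @return scalar loss.
#' @export
bce_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  stopifnot(all(y >= 0 & y <= 1), all(yhat >= 0 & yhat <= 1))
  eps <- 1e-12
  yh <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yh) + (1 - y) * log(1 - yh))
}

#' Mean squared error between labels and predictions
#'
#' The monitoring metric used for checkpoint selection and early stopping.
#'
#' @inheritParams bce_loss
#' @return scalar mean squared error.
#' @export
mse_monitor <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  mean((y - yhat)^2)
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param weight_decay decoupled weight decay on convolution and fully
#'   connected weights.
#' @param patience_epochs stop after this many epochs without improvement
#'   of the monitored validation metric (50 for the proposed method, 100
#'   for the baseline).
#' @param max_epochs hard cap so desk-scale runs always terminate.
#' @param seed seed controlling shuffling, augmentation draws and (when a
#'   model is built internally) initialization.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32,
                         weight_decay = 1e-5, patience_epochs = 50,
                         max_epochs = 500, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, weight_decay >= 0,
            patience_epochs >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

stacks_to_array <- function(stacks) {
  if (is.array(stacks) && length(dim(stacks)) == 3) return(stacks)
  if (is.matrix(stacks)) return(array(stacks, c(dim(stacks), 1)))
  array(unlist(stacks, use.names = FALSE),
        c(dim(stacks[[1]]), length(stacks)))
}

#' Train the probability-output network
#'
#' Minimizes binary cross-entropy with Adam while monitoring the
#' validation mean squared error; the returned model carries the
#' checkpoint with the smallest validation MSE seen, and training stops
#' early after `patience_epochs` epochs without improvement. Training-time
#' augmentation (white noise, circular shift, cutout) is applied to every
#' training stack and never at validation or prediction. Fully
#' reproducible under `cfg$seed`.
#'
#' @param dataset list with `x_train` (list of 50 x 1024 stacks),
#'   `y_train` (labels in \[0, 1\]), `x_val`, `y_val`.
#' @param cfg a [train_config()].
#' @param model optionally a pre-built `ksbp_model`; default builds one
#'   with `width_scale`.
#' @param width_scale passed to [build_model()] when `model` is NULL.
#' @param augment apply training-time augmentation.
#' @param aug_cfg an [augmentation_config()].
#' @param verbose print one line per epoch.
#' @return the trained `ksbp_model`, with `history` (per-epoch training
#'   BCE and validation MSE) and `best_epoch`.
#' @export
ks_train <- function(dataset, cfg = train_config(), model = NULL,
                     width_scale = 0.25, augment = TRUE,
                     aug_cfg = augmentation_config(), verbose = FALSE) {
  if (length(dataset$x_train) == 0 || length(dataset$x_val) == 0)
    stop("dataset must contain non-empty train and validation splits")
  stopifnot(length(dataset$x_train) == length(dataset$y_train),
            length(dataset$x_val) == length(dataset$y_val))
  if (is.null(model))
    model <- build_model(width_scale, seed = derive_seed(cfg$seed, 1L))
  arch <- model$arch
  p <- model$params; st <- model$bn_state
  opt <- adam_init(p)
  xval <- stacks_to_array(dataset$x_val)
  ntr <- length(dataset$y_train)
  hist <- data.frame(epoch = integer(0), train_bce = numeric(0),
                     val_mse = numeric(0))
  best <- list(mse = Inf, params = p, state = st, epoch = 0L)
  wait <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(ntr)
      bce_sum <- 0; nb <- 0
      for (b0 in seq(1, ntr, by = cfg$batch_size)) {
        ii <- ord[b0:min(b0 + cfg$batch_size - 1, ntr)]
        xs <- dataset$x_train[ii]
        if (augment) xs <- lapply(xs, augment_stack, cfg = aug_cfg)
        X <- stacks_to_array(xs)
        y <- dataset$y_train[ii]
        fw <- resnet_fwd(p, st, arch, X, training = TRUE)
        st <- fw$state
        bce_sum <- bce_sum + bce_loss(y, fw$prob) * length(ii)
        nb <- nb + length(ii)
        g <- resnet_bwd(p, arch, fw$cache, (fw$prob - y) / length(ii))
        up <- adam_step(p, g, opt, cfg$learning_rate, cfg$weight_decay)
        p <- up$params; opt <- up$opt
      }
      val_prob <- predict_core(p, st, arch, xval)
      vmse <- mse_monitor(dataset$y_val, val_prob)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_bce = bce_sum / nb,
                                     val_mse = vmse))
      if (verbose)
        message(sprintf("epoch %3d  train BCE %.4f  val MSE %.4f",
                        epoch, bce_sum / nb, vmse))
      if (vmse < best$mse - 1e-12) {
        best <- list(mse = vmse, params = p, state = st, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience_epochs) break
      }
    }
  })
  model$params <- best$params
  model$bn_state <- best$state
  model$history <- hist
  model$best_epoch <- best$epoch
  model$val_mse <- best$mse
  model$trained <- TRUE
  model$config <- cfg
  model
}

predict_core <- function(p, st, arch, X, batch_size = 64L) {
  n <- dim(X)[3]
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    ii <- b0:min(b0 + batch_size - 1, n)
    out[ii] <- resnet_fwd(p, st, arch, X[, , ii, drop = FALSE],
                          training = FALSE)$prob
  }
  out
}

#' Predict per-beat Korotkoff-sound probabilities
#'
#' Inference only: no augmentation is applied, and outputs follow the
#' order of the input stacks.
#'
#' @param model a trained (or untrained) `ksbp_model`.
#' @param stacks list of 50 x 1024 stacks (beat order), a single stack, or
#'   a 3-d array.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_beats <- function(model, stacks) {
  stopifnot(inherits(model, "ksbp_model"))
  X <- stacks_to_array(stacks)
  if (dim(X)[1] != model$arch$in_h || dim(X)[2] != model$arch$in_w)
    stop("stack geometry must be ", model$arch$in_h, " x ", model$arch$in_w)
  predict_core(model$params, model$bn_state, model$arch, X)
}

#' @export
predict.ksbp_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ks_recording")) return(measure_bp(object, newdata))
  predict_beats(object, newdata)
}

#' Measure blood pressure from a recording with a trained model
#'
#' Full inference pipeline on one recording: preprocessing (beat peaks,
#' segments, stacks), per-beat probability prediction, and the
#' template-matching decision rule.
#'
#' @param model a trained `ksbp_model`.
#' @param rec a `ks_recording`.
#' @param ceiling decision probability ceiling (0.9).
#' @return a `bp_result`.
#' @export
measure_bp <- function(model, rec, ceiling = 0.9) {
  pp <- preprocess_recording(rec)
  yhat <- predict_beats(model, pp$stacks)
  series <- beat_series(pp$beats$peak_times, yhat,
                        pp$beats$peak_cuff_pressures)
  decide_bp(series, ceiling = ceiling)
}

#' Random hyperparameter search
#'
#' Draws `n_sets` configurations — learning rate log-uniform in
#' `[1e-5, 1e-2]`, weight decay log-uniform in `[1e-6, 1e-3]`, batch size
#' a power of two in `[16, 128]` — trains each, and returns the model with
#' the smallest validation MSE.
#'
#' @param n_sets number of parameter sets (>= 1).
#' @param dataset as in [ks_train()].
#' @param seed master seed (sub-seeds per set are derived from it).
#' @param lr_range,wd_range ranges for the log-uniform draws.
#' @param ... further arguments to [ks_train()] (e.g. `width_scale`,
#'   `max_epochs` via `base_cfg`).
#' @param base_cfg template [train_config()] supplying patience and epoch
#'   caps.
#' @return best `ksbp_model`; `$search` holds the per-set table.
#' @export
random_search <- function(n_sets, dataset, seed = 1L,
                          lr_range = c(1e-5, 1e-2),
                          wd_range = c(1e-6, 1e-3),
                          base_cfg = train_config(), ...) {
  stopifnot(n_sets >= 1)
  draws <- with_seed(seed, {
    data.frame(
      learning_rate = 10^runif(n_sets, log10(lr_range[1]), log10(lr_range[2])),
      weight_decay = 10^runif(n_sets, log10(wd_range[1]), log10(wd_range[2])),
      batch_size = 2^sample(4:7, n_sets, replace = TRUE))
  })
  best <- NULL; best_mse <- Inf
  draws$val_mse <- NA_real_
  for (k in seq_len(n_sets)) {
    cfg <- train_config(learning_rate = draws$learning_rate[k],
                        batch_size = draws$batch_size[k],
                        weight_decay = draws$weight_decay[k],
                        patience_epochs = base_cfg$patience_epochs,
                        max_epochs = base_cfg$max_epochs,
                        seed = derive_seed(seed, k))
    m <- ks_train(dataset, cfg, ...)
    draws$val_mse[k] <- m$val_mse
    if (m$val_mse < best_mse) { best_mse <- m$val_mse; best <- m }
  }
  best$search <- draws
  best
}

#' @export
print.ksbp_model <- function(x, ...) {
  cat("Korotkoff-sound probability CNN (18-layer residual, width scale ",
      x$arch$width_scale, ")\n", sep = "")
  cat("  input 50 x 1024, single channel;", format(n_parameters(x),
      big.mark = ","), "parameters\n")
  if (x$trained)
    cat(sprintf("  trained: best epoch %d, validation MSE %.4f\n",
                x$best_epoch, x$val_mse))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.ksbp_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.ksbp_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_bce, h$val_mse), type = "l",
                    lty = 1, col = c(1, 2), xlab = "epoch", ylab = "loss",
                    ...)
  graphics::legend("topright", c("training BCE", "validation MSE"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
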