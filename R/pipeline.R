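#' End-to-end run configuration
#'
#' One serializable object that fully reproduces a run: simulation ranges,
#' split sizes, training hyperparameters, the decision ceiling and one
#' global seed from which every stage's sub-seed is derived.
#'
#' @param n_train,n_val,n_test recordings per split (disjoint).
#' @param ranges simulation parameter ranges, as in [make_dataset()].
#' @param beats_per_recording training beats sub-sampled per recording
#'   (stratified over the label strata: pre-systolic, onset/offset ramps,
#'   plateau).
#' @param width_scale channel width multiplier of the proposed model.
#' @param learning_rate,batch_size,weight_decay,max_epochs,patience
#'   training hyperparameters of the proposed model.
#' @param baseline_max_epochs,baseline_patience baseline training caps.
#' @param ceiling decision probability ceiling.
#' @param method "proposed", "baseline" or "both".
#' @param seed global seed.
#' @param out_dir optional directory for artifacts (results JSON, models,
#'   log); NULL keeps everything in memory.
#' @return a `run_config`.
#' @export
run_config <- function(n_train = 15, n_val = 5, n_test = 10,
                       ranges = list(sbp = c(100, 140), dbp = c(60, 90),
                                     heart_rate = c(55, 95),
                                     snr_db = c(0, 18),
                                     gap_probability = 0),
                       beats_per_recording = 8,
                       width_scale = 0.125, learning_rate = 1e-3,
                       batch_size = 32, weight_decay = 1e-5,
                       max_epochs = 12, patience = 5,
                       baseline_max_epochs = 15, baseline_patience = 6,
                       ceiling = 0.9, method = "both", seed = 1L,
                       out_dir = NULL) {
  stopifnot(n_train >= 1, n_val >= 1, n_test >= 1,
            method %in% c("proposed", "baseline", "both"))
  structure(as.list(environment()), class = "run_config")
}

# Stratified sub-sampling of training beats: always include the ramp
# beats (fractional labels) up to k/3, then balance plateau and outside.
sample_training_beats <- function(labels, k, seed) {
  with_seed(seed, {
    ramp <- which(labels > 0.02 & labels < 0.98)
    ones <- which(labels >= 0.98)
    zeros <- which(labels <= 0.02)
    take <- function(idx, m) if (length(idx) <= m) idx
            else sort(sample(idx, m))
    sel <- take(ramp, max(1, floor(k / 3)))
    rem <- k - length(sel)
    n1 <- min(length(ones), ceiling(rem / 2))
    sel <- c(sel, take(ones, n1))
    sel <- c(sel, take(zeros, k - length(sel)))
    sort(unique(sel))
  })
}

collect_split <- function(recs, beats_per_recording, seed,
                          need_baseline = TRUE) {
  stacks <- list(); specs <- list(); y <- numeric(0); yb <- integer(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    osc <- extract_cuff_oscillation(rec$cuff_pressure, rec$fs)
    beats <- detect_beat_peaks(osc, rec$cuff_pressure, rec$fs)
    if (length(beats$peak_times) < 4) next
    ann <- rec$annotations
    lab <- label_beats(beats, ann$t_sbp, ann$t_dbp)
    sel <- sample_training_beats(lab, beats_per_recording,
                                 derive_seed(seed, i))
    for (s in sel) {
      pt <- beats$peak_times[s]
      stacks[[length(stacks) + 1]] <-
        bandpass_stack(extract_segment(rec$sound_pressure, pt, rec$fs),
                       rec$fs)
      if (need_baseline)
        specs[[length(specs) + 1]] <-
          spectrogram_input(extract_baseline_segment(rec$sound_pressure,
                                                     pt, rec$fs), rec$fs)
    }
    y <- c(y, lab[sel])
    yb <- c(yb, as.integer(beats$peak_times[sel] >= ann$t_sbp &
                           beats$peak_times[sel] <= ann$t_dbp))
  }
  list(stacks = stacks, specs = specs, y = y, y_binary = yb)
}

#' Run the whole pipeline: simulate, preprocess, train, predict, evaluate
#'
#' Generates disjoint train/validation/test sets of synthetic recordings,
#' trains the proposed probability network (and the baseline classifier),
#' measures blood pressure on every test recording with the
#' template-matching decision rule (and the consecutive-beat baseline
#' rule), and returns error statistics per method. Every stage is seeded
#' from the configuration's global seed; rerunning with the same
#' configuration reproduces the results exactly.
#'
#' @param cfg a [run_config()].
#' @param verbose print stage progress.
#' @return list with `config`, `results` (per-recording data frame:
#'   reference and predicted pressures, SNR), `stats` (a
#'   `bp_error_stats` per method), `models`.
#' @export
run_end_to_end <- function(cfg = run_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(...)
  n_all <- cfg$n_train + cfg$n_val + cfg$n_test
  say("simulating ", n_all, " recordings")
  recs <- make_dataset(n_all, ranges = cfg$ranges,
                       seed = derive_seed(cfg$seed, 11L),
                       split = c(train = cfg$n_train, validation = cfg$n_val,
                                 test = cfg$n_test))
  splits <- vapply(recs, function(r) r$annotations$split, character(1))
  need_bl <- cfg$method %in% c("baseline", "both")
  need_prop <- cfg$method %in% c("proposed", "both")

  say("preprocessing training beats")
  tr <- collect_split(recs[splits == "train"], cfg$beats_per_recording,
                      derive_seed(cfg$seed, 21L), need_bl)
  va <- collect_split(recs[splits == "validation"], cfg$beats_per_recording,
                      derive_seed(cfg$seed, 22L), need_bl)

  model <- NULL; bl_model <- NULL
  if (need_prop) {
    say("training proposed model on ", length(tr$y), " beats")
    model <- ks_train(
      list(x_train = tr$stacks, y_train = tr$y,
           x_val = va$stacks, y_val = va$y),
      train_config(learning_rate = cfg$learning_rate,
                   batch_size = cfg$batch_size,
                   weight_decay = cfg$weight_decay,
                   patience_epochs = cfg$patience,
                   max_epochs = cfg$max_epochs,
                   seed = derive_seed(cfg$seed, 31L)),
      width_scale = cfg$width_scale, verbose = verbose)
  }
  if (need_bl) {
    say("training baseline model")
    bl_model <- baseline_train(
      list(x_train = tr$specs, y_train = tr$y_binary,
           x_val = va$specs, y_val = va$y_binary),
      train_config(learning_rate = cfg$learning_rate,
                   batch_size = cfg$batch_size,
                   weight_decay = cfg$weight_decay,
                   patience_epochs = cfg$baseline_patience,
                   max_epochs = cfg$baseline_max_epochs,
                   seed = derive_seed(cfg$seed, 32L)),
      verbose = verbose)
  }

  say("predicting test recordings")
  test_recs <- recs[splits == "test"]
  rows <- lapply(seq_along(test_recs), function(i) {
    rec <- test_recs[[i]]
    ann <- rec$annotations
    row <- data.frame(recording = i, sbp_ref = ann$sbp, dbp_ref = ann$dbp,
                      snr_db = estimate_snr(rec))
    if (need_prop) {
      bp <- measure_bp(model, rec, ceiling = cfg$ceiling)
      row$sbp_proposed <- bp$sbp; row$dbp_proposed <- bp$dbp
    }
    if (need_bl) {
      bp <- baseline_measure_bp(bl_model, rec)
      row$sbp_baseline <- bp$sbp; row$dbp_baseline <- bp$dbp
    }
    row
  })
  results <- do.call(rbind, rows)

  stats <- list()
  ref <- data.frame(sbp = results$sbp_ref, dbp = results$dbp_ref)
  if (need_prop)
    stats$proposed <- bp_error_stats(
      data.frame(sbp = results$sbp_proposed, dbp = results$dbp_proposed),
      ref, snr = results$snr_db)
  if (need_bl) {
    ok <- !is.na(results$sbp_baseline) & !is.na(results$dbp_baseline)
    stats$baseline <- bp_error_stats(
      data.frame(sbp = results$sbp_baseline,
                 dbp = results$dbp_baseline)[ok, , drop = FALSE],
      ref[ok, , drop = FALSE], snr = results$snr_db[ok])
  }

  out <- list(config = cfg, results = results, stats = stats,
              models = list(proposed = model, baseline = bl_model))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- cfg; cfg_json$out_dir <- NULL
    jsonlite::write_json(list(config = unclass(cfg_json),
                              results = results,
                              stats = lapply(stats, unclass)),
                         file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    saveRDS(out$models, file.path(cfg$out_dir, "models.rds"))
    writeLines(c(paste("run at", format(Sys.time())),
                 paste("seed", cfg$seed),
                 paste("R", getRversion()),
                 utils::capture.output(print(stats$proposed),
                                       print(stats$baseline))),
               file.path(cfg$out_dir, "run.log"))
  }
  out
}
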