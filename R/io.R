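#' Write a sound trace as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono). Sound pressure is written
#' in pascals without rescaling so that amplitudes survive a round trip.
#'
#' @param x numeric vector, sound samples (Pa).
#' @param path output file path.
#' @param fs sampling rate in Hz.
#' @export
write_wav <- function(x, path, fs) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  data_bytes <- 4L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a 32-bit float mono WAV file
#'
#' @param path WAV file written by [write_wav()] (or any float mono WAV).
#' @return list with `x` (samples) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  readChar(con, 4)                                         # "WAVE"
  fs <- NA_integer_; fmt <- NA_integer_; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 1, size = 2, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", sz - 8)
    } else if (id == "data") {
      if (!fmt %in% c(3L)) stop("only IEEE float WAV supported")
      x <- readBin(con, "double", sz / 4, size = 4, endian = "little")
      break
    } else {
      readBin(con, "raw", sz)
    }
  }
  list(x = x, fs = fs)
}

#' Write a recording to a directory (WAV + CSV + JSON sidecar)
#'
#' Produces `sound.wav` (float WAV, Pa), `cuff.csv` (columns `time`,
#' `cuff_pressure`) and `annotations.json` (sampling rate, ground truth and
#' simulation parameters when present).
#'
#' @param rec a `ks_recording`.
#' @param dir output directory (created if needed).
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "ks_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wav(rec$sound_pressure, file.path(dir, "sound.wav"), rec$fs)
  n <- length(rec$cuff_pressure)
  utils::write.csv(
    data.frame(time = (seq_len(n) - 1) / rec$fs,
               cuff_pressure = rec$cuff_pressure),
    file.path(dir, "cuff.csv"), row.names = FALSE)
  meta <- c(list(fs = rec$fs), rec$annotations)
  meta$params <- if (!is.null(rec$params)) unclass(rec$params)
  jsonlite::write_json(meta, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a recording directory written by [write_recording()]
#'
#' @param dir directory containing `sound.wav`, `cuff.csv` and optionally
#'   `annotations.json`.
#' @return a `ks_recording`.
#' @export
read_recording <- function(dir) {
  wav <- read_wav(file.path(dir, "sound.wav"))
  cuff <- utils::read.csv(file.path(dir, "cuff.csv"))
  ann <- NULL
  jp <- file.path(dir, "annotations.json")
  if (file.exists(jp)) {
    meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
    meta$fs <- NULL
    ann <- meta[setdiff(names(meta), "params")]
  }
  new_recording(cuff$cuff_pressure, wav$x, wav$fs, annotations = ann)
}
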