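# Domain types and readers/writers for signals and annotations.
#
# A SensorSignal is a plain list (class "sensor_signal") holding the voltage
# samples, the sampling rate fs, and subject/visit identity. Annotations are
# data frames (class "chew_segments") with one row per annotated segment.
# Annotation times are seconds; intervals are half-open [start_s, end_s):
# sample i (0-based) belongs to a segment iff start_s <= i/fs < end_s.

#' Construct a sensor signal
#'
#' Bundles a voltage time series with its sampling rate and identity. This is
#' the container every processing step in the package operates on.
#'
#' @param samples Numeric vector of voltage samples.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject_id,visit_id Identifiers (coerced to character).
#' @return An object of class `sensor_signal`: a list with elements
#'   `samples`, `fs`, `subject_id`, `visit_id`.
#' @examples
#' s <- sensor_signal(sin(2 * pi * 1.5 * seq(0, 10, by = 1e-3)), fs = 1000)
#' signal_duration(s)
#' @export
sensor_signal <- function(samples, fs, subject_id = "s1", visit_id = "v1") {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)")
  }
  if (anyNA(samples)) stop("`samples` must not contain NA")
  structure(
    list(samples = samples, fs = as.numeric(fs),
         subject_id = as.character(subject_id),
         visit_id = as.character(visit_id)),
    class = "sensor_signal"
  )
}

#' @export
print.sensor_signal <- function(x, ...) {
  cat(sprintf("<sensor_signal> subject=%s visit=%s fs=%g Hz n=%d (%.3f s)\n",
              x$subject_id, x$visit_id, x$fs, length(x$samples),
              signal_duration(x)))
  invisible(x)
}

#' Duration of a sensor signal in seconds
#'
#' @param signal A [sensor_signal()].
#' @return `length(samples) / fs`, exactly.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "sensor_signal"))
  length(signal$samples) / signal$fs
}

#' Construct a table of annotated chewing segments
#'
#' One row per annotated segment of a recording. Intake rows carry a
#' reference chew count `CNT(k)`; non-intake rows must have `chew_count` NA.
#' Intervals are half-open `[start_s, end_s)` and must not overlap within a
#' visit.
#'
#' @param subject_id,visit_id Identifiers, recycled to the number of rows.
#' @param start_s,end_s Segment bounds in seconds; `end_s > start_s >= 0`.
#' @param label `"intake"` or `"non-intake"`.
#' @param chew_count Non-negative integer reference chew count for intake
#'   rows, NA otherwise.
#' @return A data frame of class `chew_segments`, sorted by visit and
#'   `start_s`, with a `duration_s` column (`D(k) = end_s - start_s`).
#' @export
chew_segments <- function(subject_id, visit_id, start_s, end_s, label,
                          chew_count = NA) {
  df <- data.frame(
    subject_id = as.character(subject_id),
    visit_id = as.character(visit_id),
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    label = as.character(label),
    chew_count = suppressWarnings(as.numeric(chew_count)),
    stringsAsFactors = FALSE
  )
  validate_segments(df)
}

validate_segments <- function(df) {
  stopifnot(all(c("subject_id", "visit_id", "start_s", "end_s",
                  "label", "chew_count") %in% names(df)))
  if (any(!df$label %in% c("intake", "non-intake"))) {
    stop("segment labels must be 'intake' or 'non-intake'")
  }
  if (any(df$start_s < 0)) stop("segment start_s must be >= 0")
  if (any(df$end_s <= df$start_s)) {
    stop("segment end_s must be greater than start_s")
  }
  bad_cnt <- !is.na(df$chew_count) &
    (df$chew_count < 0 | df$chew_count != round(df$chew_count))
  if (any(bad_cnt)) stop("chew_count must be a non-negative integer")
  if (any(df$label == "non-intake" & !is.na(df$chew_count))) {
    stop("chew_count must be absent for non-intake segments")
  }
  df <- df[order(df$subject_id, df$visit_id, df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  # overlap check per visit on the sorted half-open intervals
  key <- paste(df$subject_id, df$visit_id, sep = "\r")
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    if (nrow(sub) > 1L &&
        any(sub$start_s[-1L] < sub$end_s[-nrow(sub)] - 1e-12)) {
      stop("overlapping annotation in visit ", sub$visit_id[1L])
    }
  }
  df$duration_s <- df$end_s - df$start_s
  class(df) <- c("chew_segments", "data.frame")
  df
}

#' Read segment annotations from CSV
#'
#' Expects a comma-separated UTF-8 file with header
#' `subject_id,visit_id,start_s,end_s,label,chew_count`; `chew_count` is
#' empty for non-intake rows. Rows are sorted by start time and checked for
#' overlap within each visit.
#'
#' @param path Path to the CSV file.
#' @return A `chew_segments` data frame (see [chew_segments()]).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       visit_id = "character"))
  validate_segments(df)
}

#' Write segment annotations to CSV
#'
#' Inverse of [read_annotations()]; round-trips up to float formatting.
#'
#' @param segments A `chew_segments` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(segments, path) {
  cols <- c("subject_id", "visit_id", "start_s", "end_s", "label",
            "chew_count")
  utils::write.csv(as.data.frame(segments)[, cols], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

# ---- WAV / raw binary I/O ---------------------------------------------------
# Minimal mono RIFF/WAV support (PCM16 and IEEE float32). Full-scale WAV
# amplitude [-1, 1] is mapped linearly onto a declared voltage range
# (default [0, 2] V, the acquisition range of the jaw sensor front-end).
# Counting is scale- and offset-invariant, so the mapping only affects
# display units.

#' Read a sensor recording from disk
#'
#' Accepts a mono WAV file (PCM16 or IEEE float32), or a raw little-endian
#' float32 file accompanied by a JSON sidecar `<path>.json` declaring at
#' least `fs`, and optionally `subject_id`, `visit_id`, `volt_range`.
#'
#' @param path Path to the `.wav` or raw `.f32`/binary file.
#' @param fs_override Optional sampling rate overriding the container's.
#' @param volt_range Length-2 numeric; WAV full scale `[-1, 1]` is mapped
#'   linearly onto this voltage range. Default `c(0, 2)` V.
#' @param subject_id,visit_id Identity used when the container carries none.
#' @return A [sensor_signal()] with samples in volts.
#' @export
read_signal <- function(path, fs_override = NULL, volt_range = c(0, 2),
                        subject_id = "s1", visit_id = "v1") {
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (grepl("\\.wav$", path, ignore.case = TRUE)) {
    w <- read_wav(path)
    fs <- if (!is.null(fs_override)) fs_override else w$fs
    volts <- (w$samples + 1) / 2 * (volt_range[2] - volt_range[1]) +
      volt_range[1]
    return(sensor_signal(volts, fs, subject_id, visit_id))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("raw input requires a JSON sidecar at ", sidecar)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs)) stop("sidecar must declare fs")
  fs <- if (!is.null(fs_override)) fs_override else meta$fs
  n <- file.size(path) / 4
  samples <- readBin(path, "numeric", n = n, size = 4, endian = "little")
  sensor_signal(samples, fs,
                subject_id = meta$subject_id %||% subject_id,
                visit_id = meta$visit_id %||% visit_id)
}

#' Write a sensor signal as a mono WAV file
#'
#' @param signal A [sensor_signal()].
#' @param path Output path.
#' @param volt_range Voltage range mapped to WAV full scale; must contain
#'   the sample range. Default `c(0, 2)` V.
#' @param format `"float32"` (lossless) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, volt_range = c(0, 2),
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(inherits(signal, "sensor_signal"))
  x <- (signal$samples - volt_range[1]) / (volt_range[2] - volt_range[1]) *
    2 - 1
  x <- pmin(pmax(x, -1), 1)
  fs <- as.integer(round(signal$fs))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per_sample <- bits %/% 8L
  data_size <- length(x) * bytes_per_sample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audio_format <- if (format == "pcm16") 1L else 3L
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes_per_sample), con, size = 4,
           endian = "little")
  writeBin(as.integer(bytes_per_sample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

# Parse a RIFF/WAV container; returns samples on [-1, 1] plus fs.
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", size = 2, endian = "little",
                              signed = FALSE)
      n_channels <- readBin(con, "integer", size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 2, endian = "little")
      bits <- readBin(con, "integer", size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", n = size - 16L)
      fmt <- list(audio_format = audio_format, n_channels = n_channels,
                  fs = fs, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$n_channels != 1L) stop("multi-channel WAV unsupported")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        raw16 <- readBin(con, "integer", n = size %/% 2L, size = 2,
                         endian = "little")
        samples <- raw16 / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n = size %/% 4L, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (need PCM16 or float32)")
      }
      return(list(samples = samples, fs = fmt$fs))
    } else {
      readBin(con, "raw", n = size + size %% 2L)
    }
  }
}

#' Write a sensor signal as raw float32 with a JSON sidecar
#'
#' Samples are stored as little-endian IEEE float32 volts; `<path>.json`
#' records `fs`, `subject_id` and `visit_id`.
#'
#' @inheritParams write_wav
#' @return `path`, invisibly.
#' @export
write_raw <- function(signal, path) {
  stopifnot(inherits(signal, "sensor_signal"))
  writeBin(signal$samples, path, size = 4, endian = "little")
  jsonlite::write_json(
    list(fs = signal$fs, subject_id = signal$subject_id,
         visit_id = signal$visit_id),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
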