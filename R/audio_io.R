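#' Audio clip container
#'
#' A multi-channel sampled waveform. Samples are stored as an
#' `n_channels x n_samples` numeric matrix of finite values; integer PCM input
#' is mapped to floats in \[-1, 1\].
#'
#' @param samples numeric vector (one channel) or `n_channels x n_samples`
#'   matrix
#' @param sample_rate sampling rate in Hz (positive integer)
#' @param source_id opaque identifier carried through the pipeline
#' @return an object of class `audio_clip`
#' @export
audio_clip <- function(samples, sample_rate, source_id = "") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), ncol(samples) >= 1L)
  if (!all(is.finite(samples)))
    stop_mealvoice("audio_clip samples must be finite", "mealvoice_value_error")
  sample_rate <- as.integer(sample_rate)
  stopifnot(sample_rate >= 1L)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         source_id = as.character(source_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip '%s': %d ch, %d samples @ %d Hz (%.3f s)>\n",
              x$source_id, n_channels(x), n_samples(x), x$sample_rate,
              clip_duration(x)))
  invisible(x)
}

#' @rdname audio_clip
#' @param clip an `audio_clip`
#' @export
n_channels <- function(clip) nrow(clip$samples)

#' @rdname audio_clip
#' @export
n_samples <- function(clip) ncol(clip$samples)

#' @rdname audio_clip
#' @export
clip_duration <- function(clip) n_samples(clip) / clip$sample_rate

## Peak normalization; silent signals pass through untouched.
peak_normalize <- function(x) {
  m <- max(abs(x))
  if (m > 0) x / m else x
}

#' Read a PCM WAV file
#'
#' Parses RIFF/WAVE with 16-bit integer PCM or 32-bit IEEE float samples.
#' Integer samples are scaled by 1/32768 into \[-1, 1\].
#'
#' @param path path to a WAV file
#' @return an [audio_clip] at the file's native rate and channel count
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop_mealvoice(sprintf("cannot read WAV file '%s': no such file", path),
                   "mealvoice_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(hdr, "RIFF"))
    stop_mealvoice(sprintf("'%s' is not a RIFF file", path), "mealvoice_io_error")
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_mealvoice(sprintf("'%s' is not a WAVE file", path), "mealvoice_io_error")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        audio_format = readBin(body[1:2], "integer", 1L, 2L, endian = "little"),
        channels     = readBin(body[3:4], "integer", 1L, 2L, endian = "little"),
        rate         = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(body[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_mealvoice(sprintf("'%s' is missing fmt/data chunks", path),
                   "mealvoice_io_error")
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2L,
                    signed = TRUE, endian = "little") / 32768
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "double", length(data_raw) / 4L, size = 4L,
                    endian = "little")
  } else {
    stop_mealvoice(sprintf(
      "'%s': unsupported WAV encoding (format %d, %d bits); need PCM16 or float32",
      path, fmt$audio_format, fmt$bits), "mealvoice_format_error")
  }
  ## samples are interleaved: frame-major, channel-minor
  samples <- matrix(vals, nrow = fmt$channels)
  audio_clip(samples, fmt$rate, source_id = basename(path))
}

#' Write an audio clip as a WAV file
#'
#' @param clip an [audio_clip]
#' @param path destination path
#' @param bits 16 (integer PCM, clamped to \[-1, 1\]) or 32 (IEEE float)
#' @return `path`, invisibly
#' @export
write_wav <- function(clip, path, bits = 16L) {
  stopifnot(inherits(clip, "audio_clip"), bits %in% c(16L, 32L))
  nch <- n_channels(clip)
  interleaved <- as.vector(clip$samples)  # column-major = frame-major
  bytes_per <- bits / 8L
  data_sz <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(if (bits == 16L) 1L else 3L), con, size = 2L, endian = "little")
  writeBin(as.integer(nch), con, size = 2L, endian = "little")
  writeBin(as.integer(clip$sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(clip$sample_rate * nch * bytes_per), con, size = 4L,
           endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(interleaved * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  } else {
    writeBin(interleaved, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Front-end signal conditioning
#'
#' Applies the contact-microphone front end: a zero-phase 4th-order Butterworth
#' high-pass (to remove blood-flow rumble below the cutoff), polyphase
#' resampling to the working rate, and peak normalization. Silent clips pass
#' through as silence.
#'
#' @param clip an [audio_clip]
#' @param cutoff_hz high-pass cutoff in Hz (default 100)
#' @param target_rate output sampling rate in Hz (default 16000); upsampling is
#'   refused
#' @return a conditioned [audio_clip] at `target_rate`
#' @export
preprocess <- function(clip, cutoff_hz = 100, target_rate = 16000) {
  stopifnot(inherits(clip, "audio_clip"))
  if (clip$sample_rate < 2 * cutoff_hz)
    stop_mealvoice("sample rate must be at least twice the high-pass cutoff",
                   "mealvoice_param_error")
  if (target_rate > clip$sample_rate)
    stop_mealvoice("no upsampling: target_rate exceeds the clip's rate",
                   "mealvoice_param_error")
  bf <- signal::butter(4, cutoff_hz / (clip$sample_rate / 2), type = "high")
  g <- gcd_int(as.integer(target_rate), clip$sample_rate)
  p <- as.integer(target_rate) %/% g
  q <- clip$sample_rate %/% g
  out <- t(apply(clip$samples, 1L, function(x) {
    y <- signal::filtfilt(bf, x)
    if (p != q) y <- signal::resample(y, p, q)
    y
  }))
  if (n_channels(clip) == 1L) out <- matrix(out, nrow = 1L)
  audio_clip(peak_normalize(out), target_rate, clip$source_id)
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Sum microphone channels into one signal
#'
#' Adds the channels sample-by-sample (raw summation, then one peak
#' normalization), the standard integration of the four contact-microphone
#' channels into a single model input. All-zero results skip renormalization.
#'
#' @param clip an [audio_clip] with `n_channels >= 1`
#' @return a mono [audio_clip] at the same rate
#' @export
sum_channels <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  s <- colSums(clip$samples)
  audio_clip(peak_normalize(s), clip$sample_rate, clip$source_id)
}
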