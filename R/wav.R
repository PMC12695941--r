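#' A single call recording
#'
#' Container for one vocalisation: the waveform, its sample rate, and the
#' labels that downstream analyses group by.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel;
#'   all values must lie in \[-1, 1\] and be finite.
#' @param sample_rate Sampling rate in Hz.
#' @param individual_id,species_id Character labels for the caller.
#' @param call_type `"meow"` or `"purr"`.
#' @return An object of class `call_recording`.
#' @export
call_recording <- function(samples, sample_rate, individual_id = NA_character_,
                           species_id = NA_character_, call_type = NA_character_) {
  if (length(samples) < 1L) stop("samples: must contain at least one sample")
  if (!is.numeric(samples)) stop("samples: must be numeric")
  if (any(!is.finite(samples))) stop("samples: NaN/Inf not allowed")
  if (max(abs(samples)) > 1 + 1e-9) stop("samples: amplitude must lie in [-1, 1]")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate: must be a single positive number")
  if (!is.na(call_type) && !call_type %in% c("meow", "purr"))
    stop("call_type: must be 'meow' or 'purr'")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 individual_id = as.character(individual_id),
                 species_id = as.character(species_id),
                 call_type = as.character(call_type)),
            class = "call_recording")
}

#' @export
print.call_recording <- function(x, ...) {
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  cat(sprintf("<call_recording> %s/%s %s: %.3f s, %g Hz, %d channel(s)\n",
              x$species_id, x$individual_id, x$call_type, n / x$sample_rate,
              x$sample_rate, ch))
  invisible(x)
}

#' Number of channels of a recording
#' @param recording A [call_recording()].
#' @return Integer channel count.
#' @export
n_channels <- function(recording) {
  if (is.matrix(recording$samples)) ncol(recording$samples) else 1L
}

# --- minimal RIFF/PCM WAV codec ---------------------------------------------
# No audio package ships with the analysis stack, so integer PCM (8/16/24-bit,
# mono or stereo) is decoded and encoded directly. Floating point and
# compressed encodings are rejected.

#' Read a PCM WAV file
#'
#' Decodes an integer PCM RIFF/WAVE file (8, 16 or 24 bits per sample, any
#' channel count up to 2) and rescales samples to \[-1, 1\].
#'
#' @param path Path to a WAV file.
#' @param individual_id,species_id,call_type Optional labels attached to the
#'   returned recording.
#' @return A [call_recording()]; stereo files yield a two-column sample matrix.
#' @export
load_wav <- function(path, individual_id = NA_character_,
                     species_id = NA_character_, call_type = NA_character_) {
  if (!file.exists(path)) stop("load_wav: file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("load_wav: not a WAV file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  raw4 <- function() rawToChar(readBin(con, "raw", 4L))
  if (raw4() != "RIFF") stop("load_wav: missing RIFF header: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # riff size
  if (raw4() != "WAVE") stop("load_wav: not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    chunk_id <- rawToChar(id)
    chunk_sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (chunk_id == "fmt ") {
      body <- readBin(con, "raw", chunk_sz)
      u16 <- function(i) sum(as.integer(body[i:(i + 1L)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(body[i:(i + 3L)]) * c(1, 256, 65536, 16777216))
      fmt <- list(audio_format = u16(1L), channels = u16(3L),
                  sample_rate = u32(5L), bits = u16(15L))
    } else if (chunk_id == "data") {
      data_raw <- readBin(con, "raw", chunk_sz)
    } else {
      readBin(con, "raw", chunk_sz + chunk_sz %% 2L)  # skip, chunks are padded to even
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("load_wav: missing fmt/data chunk: ", path)
  if (fmt$audio_format != 1L)
    stop("load_wav: unsupported encoding (only integer PCM): format tag ", fmt$audio_format)
  if (!fmt$bits %in% c(8L, 16L, 24L))
    stop("load_wav: unsupported bit depth: ", fmt$bits)
  if (fmt$channels < 1L || fmt$channels > 2L)
    stop("load_wav: unsupported channel count: ", fmt$channels)

  x <- switch(as.character(fmt$bits),
    "8" = (as.integer(data_raw) - 128) / 128,
    "16" = {
      v <- as.integer(data_raw)
      n <- length(v) %/% 2L
      val <- v[seq(1L, by = 2L, length.out = n)] +
             256L * v[seq(2L, by = 2L, length.out = n)]
      ifelse(val >= 32768L, val - 65536L, val) / 32768
    },
    "24" = {
      v <- as.integer(data_raw)
      n <- length(v) %/% 3L
      val <- v[seq(1L, by = 3L, length.out = n)] +
             256 * v[seq(2L, by = 3L, length.out = n)] +
             65536 * v[seq(3L, by = 3L, length.out = n)]
      ifelse(val >= 8388608, val - 16777216, val) / 8388608
    })
  if (fmt$channels == 2L)
    x <- matrix(x, ncol = 2L, byrow = TRUE)
  call_recording(x, fmt$sample_rate, individual_id, species_id, call_type)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' @param recording A [call_recording()] (mono vector or stereo matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path) {
  x <- recording$samples
  channels <- if (is.matrix(x)) ncol(x) else 1L
  if (is.matrix(x)) x <- as.vector(t(x))  # interleave
  pcm <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  sr <- as.integer(round(recording$sample_rate))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(c(1L, channels), con, size = 2L, endian = "little")
  writeBin(c(sr, sr * channels * 2L), con, size = 4L, endian = "little")
  writeBin(c(channels * 2L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

#' Mix a recording down to mono
#'
#' Stereo recordings become the per-sample mean of the two channels; mono
#' recordings are returned unchanged.
#'
#' @param recording A [call_recording()] with one or two channels.
#' @return A mono [call_recording()].
#' @export
to_mono <- function(recording) {
  x <- recording$samples
  if (!is.matrix(x)) return(recording)
  if (ncol(x) > 2L) stop("to_mono: more than 2 channels not supported")
  recording$samples <- rowMeans(x)
  recording
}
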