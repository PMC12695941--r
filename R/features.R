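# Per-call acoustic features: frame-averaged MFCCs, duration, spectral
# centroid, and an STFT spectrogram for QC.

#' Hertz to mel and back
#'
#' The mel scale is approximately linear below 1 kHz and logarithmic above:
#' m(f) = 2595 log10(1 + f/700).
#'
#' @param f Frequency in Hz (>= 0).
#' @param m Frequency in mel.
#' @return Frequency on the other scale.
#' @export
mel_scale <- function(f) {
  if (any(f < 0)) stop("mel_scale: frequency must be >= 0")
  2595 * log10(1 + f / 700)
}

#' @rdname mel_scale
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) stop("mel_to_hz: mel value must be >= 0")
  700 * (10^(m / 2595) - 1)
}

#' MFCC extraction configuration
#'
#' Defaults follow common speech-processing practice where the analysis leaves
#' a choice open: 50% frame hop, 26 triangular filters from 0 Hz to Nyquist,
#' coefficients 1-10 (the 0th, a loudness proxy, excluded), Hamming taper,
#' orthonormal DCT-II, no pre-emphasis. The window length is the one knob that
#' differs by call type: 30 ms for meows, 300 ms for purrs, matching the very
#' different time scales of the two calls.
#'
#' @param call_type `"meow"` or `"purr"`; sets the default window length.
#' @param window_length Frame length in seconds.
#' @param hop_fraction Hop as a fraction of the window, in (0, 1].
#' @param n_filters Number of mel filters.
#' @param n_coefficients Number of cepstral coefficients returned (default 10).
#' @param fmin,fmax Filterbank frequency limits in Hz (`fmax = NULL` means
#'   Nyquist at extraction time).
#' @param log_floor Floor added to filterbank energies, relative to the call's
#'   maximum energy, before the log (avoids -Inf on silent frames).
#' @param include_c0 Keep the 0th coefficient as the first value? (Breaks
#'   amplitude invariance; off by default.)
#' @return A `mfcc_config` list.
#' @export
mfcc_config <- function(call_type = c("meow", "purr"), window_length = NULL,
                        hop_fraction = 0.5, n_filters = 26L,
                        n_coefficients = 10L, fmin = 0, fmax = NULL,
                        log_floor = 1e-12, include_c0 = FALSE) {
  call_type <- match.arg(call_type)
  if (is.null(window_length))
    window_length <- if (call_type == "meow") 0.030 else 0.300
  if (hop_fraction <= 0 || hop_fraction > 1)
    stop("mfcc_config: hop_fraction must lie in (0, 1]")
  if (n_coefficients > n_filters)
    stop("mfcc_config: n_coefficients must not exceed n_filters")
  if (!is.null(fmax) && fmin >= fmax)
    stop("mfcc_config: fmin must be below fmax")
  if (log_floor <= 0) stop("mfcc_config: log_floor must be positive")
  structure(list(call_type = call_type, window_length = window_length,
                 hop_fraction = hop_fraction, n_filters = as.integer(n_filters),
                 n_coefficients = as.integer(n_coefficients),
                 fmin = fmin, fmax = fmax, log_floor = log_floor,
                 include_c0 = include_c0),
            class = "mfcc_config")
}

.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

# orthonormal DCT-II matrix, rows = coefficient order 0..(n_out-1)
.dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  m <- seq_len(n_in) - 1
  D <- sqrt(2 / n_in) * cos(pi * outer(k, m + 0.5) / n_in)
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

#' Mel filterbank matrix
#'
#' Triangular filters with centers equally spaced on the mel axis between
#' `fmin` and `fmax`; adjacent filters overlap (each filter's lower edge is the
#' previous center).
#'
#' @param config An [mfcc_config()].
#' @param n_fft FFT length used for the frame spectra.
#' @param sample_rate Sampling rate in Hz.
#' @return `n_filters x (n_fft/2 + 1)` weight matrix.
#' @export
mel_filterbank <- function(config, n_fft, sample_rate) {
  fmax <- if (is.null(config$fmax)) sample_rate / 2 else config$fmax
  if (fmax > sample_rate / 2) stop("mel_filterbank: fmax above Nyquist")
  edges_mel <- seq(mel_scale(config$fmin), mel_scale(fmax),
                   length.out = config$n_filters + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  center_bins <- round(edges_hz[2:(config$n_filters + 1L)] * n_fft / sample_rate)
  if (anyDuplicated(center_bins))
    stop("mel_filterbank: n_filters too large for this n_fft (duplicate center bins)")
  f_bins <- (0:(n_fft / 2)) * sample_rate / n_fft
  H <- matrix(0, config$n_filters, length(f_bins))
  for (i in seq_len(config$n_filters)) {
    lo <- edges_hz[i]; c0 <- edges_hz[i + 1L]; hi <- edges_hz[i + 2L]
    up <- (f_bins - lo) / (c0 - lo)
    down <- (hi - f_bins) / (hi - c0)
    H[i, ] <- pmax(0, pmin(up, down))
  }
  attr(H, "centers_hz") <- edges_hz[2:(config$n_filters + 1L)]
  H
}

# full-window frames (last partial frame dropped), Hamming-tapered,
# zero-padded to the next power of two
.frame_spectra <- function(x, win_len, hop) {
  n_frames <- floor((length(x) - win_len) / hop) + 1L
  n_fft <- 2^ceiling(log2(win_len))
  idx <- outer(seq_len(win_len), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = win_len) * .hamming(win_len)
  padded <- matrix(0, n_fft, n_frames)
  padded[seq_len(win_len), ] <- frames
  mag <- Mod(stats::mvfft(padded))[1:(n_fft / 2 + 1L), , drop = FALSE]
  list(mag = mag, n_fft = n_fft, n_frames = n_frames)
}

#' Frame-averaged MFCCs of one call
#'
#' The signal is divided into overlapping Hamming-tapered frames; each frame's
#' magnitude spectrum is passed through the mel filterbank, the filterbank
#' energies are floored and logged, and an orthonormal DCT-II yields the
#' cepstral coefficients, which are then averaged over all frames of the call.
#'
#' @param recording A mono [call_recording()].
#' @param config An [mfcc_config()].
#' @return Named numeric vector `mfcc1` ... `mfcc<n>` (plus `mfcc0` first if
#'   `include_c0`), with the frame count as attribute `n_frames`.
#' @export
mfcc_per_call <- function(recording, config) {
  x <- recording$samples
  if (is.matrix(x)) stop("mfcc_per_call: convert to mono first (to_mono)")
  sr <- recording$sample_rate
  win_len <- round(config$window_length * sr)
  if (length(x) < win_len)
    stop(sprintf(paste0("mfcc_per_call: recording (%d samples) shorter than one ",
                        "%g s window (%d samples); choose a shorter window_length"),
                 length(x), config$window_length, win_len))
  hop <- max(1L, round(win_len * config$hop_fraction))
  sp <- .frame_spectra(x, win_len, hop)
  H <- mel_filterbank(config, sp$n_fft, sr)
  E <- H %*% sp$mag                      # n_filters x n_frames
  top <- max(E)
  logE <- if (top > 0) log(E + config$log_floor * top)
          else matrix(log(.Machine$double.xmin), nrow(E), ncol(E))
  D <- .dct_matrix(config$n_coefficients + 1L, config$n_filters)
  cc <- D %*% logE                       # orders 0..n_coefficients
  keep <- if (config$include_c0) seq_len(config$n_coefficients + 1L) - 1L
          else seq_len(config$n_coefficients)
  out <- rowMeans(cc)[keep + 1L]
  names(out) <- paste0("mfcc", keep)
  attr(out, "n_frames") <- sp$n_frames
  out
}

#' Call duration in seconds
#' @param recording A [call_recording()].
#' @return Length divided by sample rate, in seconds.
#' @export
call_duration <- function(recording) {
  n <- if (is.matrix(recording$samples)) nrow(recording$samples)
       else length(recording$samples)
  if (n < 1L) stop("call_duration: empty recording")
  n / recording$sample_rate
}

#' Spectral centroid in Hz
#'
#' Magnitude-weighted mean frequency of the whole-call spectrum over positive
#' frequencies.
#'
#' @param recording A mono [call_recording()].
#' @return Centroid frequency in Hz.
#' @export
spectral_centroid <- function(recording) {
  x <- recording$samples
  if (is.matrix(x)) stop("spectral_centroid: convert to mono first (to_mono)")
  if (all(x == 0)) stop("spectral_centroid: all-zero signal, centroid undefined")
  # pad to a highly composite length: a large prime sample count would make
  # the mixed-radix FFT quadratically slow on minutes-long purrs
  n <- stats::nextn(length(x), c(2, 3, 5))
  mag <- Mod(stats::fft(c(x, rep(0, n - length(x)))))
  pos <- 2:(floor(n / 2) + 1L)
  f <- (pos - 1) * recording$sample_rate / n
  sum(f * mag[pos]) / sum(mag[pos])
}

#' Spectrogram parameters
#'
#' Defaults mirror the QC display settings used for these recordings:
#' 1024-point FFT, Hamming window, 87.5% overlap, 16-bit depth.
#'
#' @param n_fft FFT/window length (power of two).
#' @param window Taper name (only `"hamming"` supported).
#' @param overlap Fractional overlap in \[0, 1).
#' @param bit_depth Source bit depth recorded for reporting.
#' @return A `spectrogram_params` list.
#' @export
spectrogram_params <- function(n_fft = 1024L, window = "hamming",
                               overlap = 0.875, bit_depth = 16L) {
  if (overlap < 0 || overlap >= 1) stop("spectrogram_params: overlap must lie in [0, 1)")
  if (bitwAnd(as.integer(n_fft), as.integer(n_fft) - 1L) != 0L)
    stop("spectrogram_params: n_fft must be a power of two")
  if (window != "hamming") stop("spectrogram_params: only the Hamming window is supported")
  structure(list(n_fft = as.integer(n_fft), window = window, overlap = overlap,
                 bit_depth = as.integer(bit_depth)),
            class = "spectrogram_params")
}

#' STFT magnitude spectrogram
#'
#' @param recording A mono [call_recording()].
#' @param params A [spectrogram_params()].
#' @return Matrix (frequency bins x frames) of STFT magnitudes with attributes
#'   `freqs_hz`, `times_s`, `bin_width_hz` (sample_rate / n_fft) and `hop_s`
#'   (n_fft (1 - overlap) / sample_rate).
#' @export
call_spectrogram <- function(recording, params = spectrogram_params()) {
  x <- recording$samples
  if (is.matrix(x)) stop("call_spectrogram: convert to mono first (to_mono)")
  sr <- recording$sample_rate
  n_fft <- params$n_fft
  hop <- max(1L, round(n_fft * (1 - params$overlap)))
  if (length(x) < n_fft) stop("call_spectrogram: recording shorter than one window")
  sp <- .frame_spectra(x, n_fft, hop)
  S <- sp$mag
  attr(S, "freqs_hz") <- (0:(n_fft / 2)) * sr / n_fft
  attr(S, "times_s") <- ((seq_len(sp$n_frames) - 1L) * hop + n_fft / 2) / sr
  attr(S, "bin_width_hz") <- sr / n_fft
  attr(S, "hop_s") <- hop / sr
  S
}

#' Extract the per-call feature table from a cohort
#'
#' Computes duration, spectral centroid and frame-averaged MFCC1-10 for every
#' recording, using the 30 ms (meow) / 300 ms (purr) window configuration.
#'
#' @param cohort List of [call_recording()]s (mixed call types allowed; each
#'   call uses its own type's config).
#' @param meow_config,purr_config [mfcc_config()]s per call type.
#' @return A data.frame with columns `call_id, individual_id, species_id,
#'   call_type, duration_s, spectral_centroid_hz, mfcc1..mfcc10`.
#' @export
extract_features <- function(cohort,
                             meow_config = mfcc_config("meow"),
                             purr_config = mfcc_config("purr")) {
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- to_mono(cohort[[i]])
    cfg <- if (identical(rec$call_type, "purr")) purr_config else meow_config
    cc <- mfcc_per_call(rec, cfg)
    df <- data.frame(call_id = sprintf("call_%04d", i),
                     individual_id = rec$individual_id,
                     species_id = rec$species_id, call_type = rec$call_type,
                     duration_s = call_duration(rec),
                     spectral_centroid_hz = spectral_centroid(rec),
                     stringsAsFactors = FALSE)
    for (j in seq_along(cc)) df[[names(cc)[j]]] <- unname(cc[j])
    df
  })
  do.call(rbind, rows)
}

#' Write / read the feature table CSV
#'
#' The layout is one row per call with columns `call_id, individual_id,
#' species_id, call_type, duration_s, spectral_centroid_hz, mfcc1..mfcc10`.
#' The reader sniffs the delimiter (comma, semicolon or tab), accepts a
#' decimal comma with semicolon delimiters, and maps columns by fuzzy header
#' match (case/punctuation-insensitive; e.g. `"MFCC 1"`, `"duration"`), so
#' exports from other tools in the same layout load too.
#'
#' @param features Feature data.frame as from [extract_features()].
#' @param path CSV path.
#' @return `write_feature_csv`: `path` invisibly; `read_feature_csv`: the
#'   feature data.frame in canonical column naming.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header))),
              ";" = lengths(regmatches(header, gregexpr(";", header))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header))))
  sep <- names(which.max(counts))
  dec <- if (sep == ";") "," else "."
  df <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                          stringsAsFactors = FALSE, check.names = FALSE)
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  nm <- norm(names(df))
  pick <- function(keys) {
    hit <- which(nm %in% keys)
    if (length(hit)) hit[1L] else NA_integer_
  }
  mapping <- c(call_id = pick(c("callid", "call", "id")),
               individual_id = pick(c("individualid", "individual", "catid", "cat", "indid")),
               species_id = pick(c("speciesid", "species")),
               call_type = pick(c("calltype", "type", "vocalisation", "vocalization")),
               duration_s = pick(c("durations", "duration", "durs", "dur")),
               spectral_centroid_hz = pick(c("spectralcentroidhz", "spectralcentroid",
                                             "centroidhz", "centroid")))
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (canon in names(mapping)) {
    out[[canon]] <- if (!is.na(mapping[canon])) df[[mapping[canon]]] else NA
  }
  mfcc_idx <- regmatches(nm, regexec("^mfcc0*([0-9]+)$", nm))
  for (j in seq_along(mfcc_idx)) {
    if (length(mfcc_idx[[j]]) == 2L) {
      k <- as.integer(mfcc_idx[[j]][2L])
      out[[paste0("mfcc", k)]] <- df[[j]]
    }
  }
  if (!any(grepl("^mfcc[0-9]+$", names(out))))
    stop("read_feature_csv: no MFCC columns recognised in ", path)
  out
}

#' Names of the MFCC columns of a feature table
#' @param features Feature data.frame.
#' @return Character vector `mfcc1` ... sorted by coefficient order.
#' @export
mfcc_columns <- function(features) {
  nm <- grep("^mfcc[0-9]+$", names(features), value = TRUE)
  nm[order(as.integer(sub("mfcc", "", nm)))]
}
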