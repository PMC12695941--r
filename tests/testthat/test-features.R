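# independent MFCC oracle: plain-loop recomputation with its own triangle and
# DCT code, kept free of the package's vectorized implementation
oracle_mfcc <- function(x, sr, win_s, hop_frac, n_filters, n_coef) {
  win <- round(win_s * sr)
  hop <- round(win * hop_frac)
  n_fft <- 2^ceiling(log2(win))
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  n_frames <- floor((length(x) - win) / hop) + 1
  f_bins <- (0:(n_fft / 2)) * sr / n_fft
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  pts <- imel(seq(mel(0), mel(sr / 2), length.out = n_filters + 2))
  E <- matrix(0, n_filters, n_frames)
  for (t in seq_len(n_frames)) {
    seg <- x[((t - 1) * hop + 1):((t - 1) * hop + win)] * ham
    spec <- abs(fft(c(seg, rep(0, n_fft - win))))[1:(n_fft / 2 + 1)]
    for (i in seq_len(n_filters)) {
      acc <- 0
      for (b in seq_along(f_bins)) {
        f <- f_bins[b]
        w <- if (f >= pts[i] && f <= pts[i + 1]) (f - pts[i]) / (pts[i + 1] - pts[i])
             else if (f > pts[i + 1] && f <= pts[i + 2]) (pts[i + 2] - f) / (pts[i + 2] - pts[i + 1])
             else 0
        acc <- acc + w * spec[b]
      }
      E[i, t] <- acc
    }
  }
  logE <- log(E + 1e-12 * max(E))
  out <- numeric(n_coef)
  for (k in seq_len(n_coef)) {
    for (t in seq_len(n_frames)) {
      s <- 0
      for (m in seq_len(n_filters))
        s <- s + logE[m, t] * cos(pi * k * (m - 0.5) / n_filters)
      out[k] <- out[k] + sqrt(2 / n_filters) * s
    }
  }
  out / n_frames
}

test_that("mel scale matches its closed form and is invertible", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(1000), 1000, tolerance = 1e-3)  # within 0.1%
  # concave above 1 kHz: doubling frequency less than doubles the mel value,
  # and the quadrupled frequency stays well under 4x
  expect_lt(mel_scale(2000), 2 * mel_scale(1000))
  expect_lt(mel_scale(4000), 4 * mel_scale(1000))
  f <- c(0.5, 10, 123, 999, 1000, 4000, 20000)
  expect_equal(mel_to_hz(mel_scale(f)), f, tolerance = 1e-6)
  expect_error(mel_scale(-1), ">= 0")
  expect_true(all(diff(mel_scale(seq(0, 48000, by = 10))) > 0))
})

test_that("mel filterbank triangles are unimodal, ordered and gap-free", {
  cfg <- mfcc_config("meow")
  H <- mel_filterbank(cfg, 2048, 16000)
  expect_equal(dim(H), c(26L, 1025L))
  centers <- attr(H, "centers_hz")
  expect_true(all(diff(centers) > 0))
  # equal spacing on the mel axis
  expect_equal(diff(mel_scale(centers)), rep(diff(mel_scale(centers))[1], 25),
               tolerance = 1e-8)
  for (i in seq_len(nrow(H))) {
    w <- H[i, ]
    peak <- which.max(w)
    expect_true(all(diff(w[1:peak]) >= -1e-12))
    expect_true(all(diff(w[peak:length(w)]) <= 1e-12))
  }
  f_bins <- (0:1024) * 16000 / 2048
  covered <- f_bins > centers[1] & f_bins < centers[26]
  expect_true(all(colSums(H)[covered] > 0))
  expect_error(mel_filterbank(mfcc_config("meow", n_filters = 200), 256, 16000),
               "duplicate center bins")
})

test_that("frame count follows the window/hop arithmetic", {
  x <- sin(2 * pi * 300 * (0:(69120 - 1)) / 96000)
  rec <- call_recording(x, 96000)
  cc <- mfcc_per_call(rec, mfcc_config("meow"))  # 30 ms window, 50% hop
  expect_equal(attr(cc, "n_frames"), 47L)        # floor((69120-2880)/1440)+1
  expect_length(cc, 10L)
  expect_named(cc, paste0("mfcc", 1:10))
  short <- call_recording(x[1:100], 96000)
  expect_error(mfcc_per_call(short, mfcc_config("meow")), "shorter than one")
})

test_that("MFCC coefficients 1-10 are invariant to amplitude gain", {
  set.seed(21)
  rec <- synthesize_meow(default_meow_profile(), 16000)
  cfg <- mfcc_config("meow")
  ref <- mfcc_per_call(rec, cfg)
  for (gain in c(0.1, 0.37, 2, 10)) {
    scaled <- rec
    scaled$samples <- rec$samples * gain / max(1, gain)  # keep within [-1,1]
    scaled2 <- call_recording(rec$samples / 10 * gain, rec$sample_rate)
    got <- mfcc_per_call(scaled2, cfg)
    expect_lt(max(abs(got - ref)), 1e-8)
  }
  # with c0 included, gain is no longer invariant
  cfg0 <- mfcc_config("meow", include_c0 = TRUE)
  a <- mfcc_per_call(rec, cfg0)
  b <- mfcc_per_call(call_recording(rec$samples * 0.1, 16000), cfg0)
  expect_gt(abs(a[1] - b[1]), 1)
})

test_that("MFCCs agree with an independently coded reference", {
  sr <- 8000
  t <- (0:(sr * 0.3 - 1)) / sr
  chirp <- 0.8 * sin(2 * pi * (300 * t + 400 * t^2))  # fixed synthetic chirp
  rec <- call_recording(chirp, sr)
  cfg <- mfcc_config("meow", n_filters = 12, n_coefficients = 6)
  got <- mfcc_per_call(rec, cfg)
  want <- oracle_mfcc(chirp, sr, 0.030, 0.5, 12, 6)
  expect_equal(as.numeric(got), want, tolerance = 1e-8)
})

test_that("silent and near-silent input yields finite coefficients", {
  rec <- call_recording(rep(0, 4000), 8000)
  cc <- mfcc_per_call(rec, mfcc_config("meow"))
  expect_true(all(is.finite(cc)))
})

test_that("duration is sample count over sample rate", {
  expect_equal(call_duration(call_recording(numeric(69120) + 0.1, 96000)), 0.72)
  expect_equal(call_duration(call_recording(0.1, 96000)), 1 / 96000)
})

test_that("spectral centroid matches tones, mixtures and white noise", {
  sr <- 96000
  n <- sr / 2  # 0.5 s, integer cycles for both tones
  t <- (0:(n - 1)) / sr
  tone <- call_recording(0.9 * sin(2 * pi * 1000 * t), sr)
  expect_lt(abs(spectral_centroid(tone) - 1000), sr / n + 1e-9)
  mix <- call_recording(0.45 * sin(2 * pi * 200 * t) + 0.45 * sin(2 * pi * 1000 * t), sr)
  expect_equal(spectral_centroid(mix), 600, tolerance = 0.02)
  set.seed(33)
  noise <- call_recording(pmax(-1, pmin(1, rnorm(n, 0, 0.2))), sr)
  expect_equal(spectral_centroid(noise), 24000, tolerance = 0.05)
  expect_error(spectral_centroid(call_recording(rep(0, 100) + 0, 8000)), "all-zero")
})

test_that("spectrogram reports the documented resolution and handles silence", {
  sr <- 96000
  rec <- call_recording(sin(2 * pi * 500 * (0:9999) / sr), sr)
  S <- call_spectrogram(rec, spectrogram_params(n_fft = 1024, overlap = 0.875))
  expect_equal(attr(S, "bin_width_hz"), 93.75)        # printed as 94 Hz
  expect_equal(round(attr(S, "bin_width_hz")), 94)
  expect_equal(attr(S, "hop_s"), 128 / sr)            # 1.33 ms
  expect_equal(round(attr(S, "hop_s") * 1000, 2), 1.33)
  zero <- call_recording(rep(0, 5000) + 0, sr)
  expect_true(all(call_spectrogram(zero) == 0))
  expect_error(spectrogram_params(overlap = 1), "overlap")
  expect_error(spectrogram_params(n_fft = 1000), "power of two")
})

test_that("spectrogram magnitudes match signal::specgram", {
  sr <- 8000
  x <- sin(2 * pi * 440 * (0:7999) / sr)
  rec <- call_recording(x, sr)
  S <- call_spectrogram(rec, spectrogram_params(n_fft = 256, overlap = 0.5))
  ref <- signal::specgram(x, n = 256, Fs = sr, window = signal::hamming(256),
                          overlap = 128)
  # signal::specgram drops the Nyquist row; compare the shared bins
  keep <- seq_len(nrow(ref$S))
  expect_equal(ncol(S), ncol(ref$S))
  expect_equal(apply(S[keep, ], 2, which.max), apply(Mod(ref$S), 2, which.max))
  expect_equal(as.vector(S[keep, ]), as.vector(Mod(ref$S)), tolerance = 1e-6)
})

test_that("feature tables roundtrip through CSV, including foreign layouts", {
  ft <- desk_features(desk_meow_spec(n_individuals = 2, calls_per_individual = 2,
                                     seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_equal(back$duration_s, ft$duration_s)
  expect_equal(back$mfcc7, ft$mfcc7)
  expect_equal(mfcc_columns(back), paste0("mfcc", 1:10))

  # semicolon-delimited, decimal comma, fuzzy headers
  foreign <- withr::local_tempfile(fileext = ".csv")
  hdr <- c("Cat ID", "Species", "Call Type", "Duration", "Centroid",
           paste("MFCC", 1:10))
  rows <- apply(ft, 1, function(r) {
    vals <- c(r[["individual_id"]], r[["species_id"]], r[["call_type"]],
              sub("\\.", ",", r[["duration_s"]]), sub("\\.", ",", r[["spectral_centroid_hz"]]),
              sapply(paste0("mfcc", 1:10), function(k) sub("\\.", ",", r[[k]])))
    paste(vals, collapse = ";")
  })
  writeLines(c(paste(hdr, collapse = ";"), rows), foreign)
  got <- read_feature_csv(foreign)
  expect_equal(got$duration_s, ft$duration_s, tolerance = 1e-6)
  expect_equal(got$individual_id, ft$individual_id)
  expect_equal(got$mfcc3, ft$mfcc3, tolerance = 1e-6)
})

test_that("feature extraction is deterministic and complete for both types", {
  mft <- desk_features(desk_meow_spec(n_individuals = 2, calls_per_individual = 2, seed = 6))
  pft <- desk_features(desk_purr_spec(n_individuals = 2, calls_per_individual = 2, seed = 6))
  for (ft in list(mft, pft)) {
    expect_true(all(is.finite(as.matrix(ft[, mfcc_columns(ft)]))))
    expect_true(all(ft$duration_s > 0))
    expect_true(all(ft$spectral_centroid_hz > 0))
  }
  again <- desk_features(desk_meow_spec(n_individuals = 2, calls_per_individual = 2, seed = 6))
  expect_identical(mft, again)
})
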