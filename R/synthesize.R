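# Synthetic meow- and purr-like calls with known ground-truth individual
# structure. Meows: additive harmonic source shaped by formant resonances.
# Purrs: periodic damped-noise bursts through an individual resonator, with a
# slow alternating amplitude modulation emulating egressive/ingressive
# breathing phases.

# truncated-Gaussian draw; rejection first, clamped after 50 tries.
# sd <= 0 returns the clamped mean without consuming the RNG stream.
.rtnorm <- function(mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(min(hi, max(lo, mean)))
  for (i in 1:50) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(hi, max(lo, mean))
}

# call-type base parameters: the centre of each profile distribution and the
# between-individual spread at between_sd_scale = 1 / within-individual spread
# at within_sd_scale = 1. Centres mirror the field-reported ranges: meow F0
# 208-1000 Hz and mean duration 0.72 s (0.17-2.21 s); purr F0 25-30 Hz and
# mean duration 10.77 s (1.09-39.82 s).
.synth_base <- function(call_type) {
  switch(call_type,
    meow = list(
      f0_center = 600, f0_between_sd = 90, f0_range = c(150, 1200),
      formant_centers = c(1100, 2600), formant_between_sd = c(160, 260),
      formant_bandwidths = c(220, 350),
      duration_center = 0.72, duration_between_sd = 0.35,
      duration_range = c(0.17, 2.21),
      f0_jitter_sd_unit = 50, duration_sd_unit = 0.12,
      envelope_jitter_sd_unit = 100),
    purr = list(
      f0_center = 27, f0_between_sd = 2, f0_range = c(20, 40),
      burst_center = 300, burst_between_sd = 170,
      burst_bandwidth = 180, burst_bw_between_sd = 40,
      duration_center = 10.77, duration_between_sd = 6,
      duration_range = c(1.09, 39.82),
      duty_center = 0.35, duty_between_sd = 0.06,
      asym_center = 0.75, asym_between_sd = 0.08,
      resp_center = 1.0, resp_between_sd = 0.25,
      f0_jitter_sd_unit = 1.0, duration_sd_unit = 1.2,
      envelope_jitter_sd_unit = 45),
    stop("call_type: must be 'meow' or 'purr'"))
}

#' Specify a synthetic cohort
#'
#' Describes a set of individuals and calls to synthesize, with separate
#' controls for the spread of individual profile means (`between_sd_scale`)
#' and the per-call jitter around them (`within_sd_scale`). Both scales
#' multiply the call type's unit spreads, so 0 gives identical profiles /
#' identical calls and larger values give stronger individual signatures /
#' noisier calls respectively.
#'
#' @param n_individuals Number of individuals (>= 2).
#' @param calls_per_individual Calls synthesized per individual (>= 2).
#' @param call_type `"meow"` or `"purr"`.
#' @param between_sd_scale,within_sd_scale Non-negative variance scales.
#' @param sample_rate Sampling rate in Hz (default 96000, the rate the
#'   recordings this generator emulates were made at).
#' @param seed Integer seed; all randomness of [generate_cohort()] flows from it.
#' @param base Optional named list overriding entries of the call type's base
#'   parameter table (e.g. shorter `duration_center` for quick experiments).
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals, calls_per_individual,
                        call_type = c("meow", "purr"),
                        between_sd_scale = 1, within_sd_scale = 1,
                        sample_rate = 96000, seed = 1L, base = list()) {
  call_type <- match.arg(call_type)
  chk <- function(ok, field, msg) if (!ok) stop("cohort_spec: ", field, " ", msg)
  chk(is.numeric(n_individuals) && n_individuals >= 2, "n_individuals", "must be >= 2")
  chk(is.numeric(calls_per_individual) && calls_per_individual >= 2,
      "calls_per_individual", "must be >= 2")
  chk(is.numeric(between_sd_scale) && between_sd_scale >= 0,
      "between_sd_scale", "must be >= 0")
  chk(is.numeric(within_sd_scale) && within_sd_scale >= 0,
      "within_sd_scale", "must be >= 0")
  chk(is.numeric(sample_rate) && sample_rate > 0, "sample_rate", "must be > 0")
  b <- utils::modifyList(.synth_base(call_type), base)
  # highest synthesized frequency must stay below Nyquist
  top <- if (call_type == "meow") max(b$formant_centers) + 2 * max(b$formant_bandwidths)
         else b$burst_center + 4 * b$burst_bandwidth
  chk(sample_rate > 2 * top, "sample_rate",
      sprintf("must exceed twice the highest synthesized frequency (~%.0f Hz)", top))
  structure(list(n_individuals = as.integer(n_individuals),
                 calls_per_individual = as.integer(calls_per_individual),
                 call_type = call_type,
                 between_sd_scale = between_sd_scale,
                 within_sd_scale = within_sd_scale,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 base = b),
            class = "cohort_spec")
}

#' Construct an individual's vocal profile
#'
#' @param individual_id Label.
#' @param call_type `"meow"` or `"purr"`.
#' @param f0_mean Mean fundamental frequency (Hz); meows must lie in
#'   \[150, 1200\], purrs in \[20, 40\].
#' @param f0_jitter_sd Within-individual per-call F0 jitter (Hz).
#' @param duration_mean,duration_sd Call duration mean and per-call SD (s).
#' @param formant_centers,formant_bandwidths Meow resonances (Hz), strictly
#'   increasing centers.
#' @param burst_center,burst_bandwidth Purr pulse resonance (Hz).
#' @param pulse_duty_cycle Fraction of the purr pulse period occupied by the
#'   burst, in (0, 1).
#' @param envelope_asymmetry Amplitude ratio of the ingressive to the
#'   egressive breathing phase, in \[0, 1\] (1 = symmetric).
#' @param resp_rate Breathing alternation rate (Hz).
#' @param envelope_jitter_sd Within-individual per-call jitter of the spectral
#'   envelope (formant / burst centers), in Hz.
#' @return A validated `individual_profile` list.
#' @export
individual_profile <- function(individual_id, call_type, f0_mean, f0_jitter_sd = 0,
                               duration_mean, duration_sd = 0,
                               formant_centers = NULL, formant_bandwidths = NULL,
                               burst_center = NULL, burst_bandwidth = NULL,
                               pulse_duty_cycle = NULL, envelope_asymmetry = NULL,
                               resp_rate = 1, envelope_jitter_sd = 0) {
  chk <- function(ok, field, msg) if (!ok) stop("individual_profile: ", field, " ", msg)
  chk(call_type %in% c("meow", "purr"), "call_type", "must be 'meow' or 'purr'")
  chk(is.numeric(f0_mean) && f0_mean > 0, "f0_mean", "must be > 0")
  chk(is.numeric(duration_mean) && duration_mean > 0, "duration_mean", "must be > 0")
  if (call_type == "meow") {
    chk(f0_mean >= 150 && f0_mean <= 1200, "f0_mean", "must lie in [150, 1200] Hz for meows")
    chk(!is.null(formant_centers) && all(diff(formant_centers) > 0),
        "formant_centers", "must be strictly increasing")
    chk(length(formant_bandwidths) == length(formant_centers),
        "formant_bandwidths", "must match formant_centers in length")
  } else {
    chk(f0_mean >= 20 && f0_mean <= 40, "f0_mean", "must lie in [20, 40] Hz for purrs")
    chk(!is.null(pulse_duty_cycle) && pulse_duty_cycle > 0 && pulse_duty_cycle < 1,
        "pulse_duty_cycle", "must lie in (0, 1)")
    chk(!is.null(envelope_asymmetry) && envelope_asymmetry >= 0 && envelope_asymmetry <= 1,
        "envelope_asymmetry", "must lie in [0, 1]")
    chk(is.numeric(burst_center) && burst_center > 0, "burst_center", "must be > 0")
  }
  structure(list(individual_id = as.character(individual_id), call_type = call_type,
                 f0_mean = f0_mean, f0_jitter_sd = f0_jitter_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 formant_centers = formant_centers,
                 formant_bandwidths = formant_bandwidths,
                 burst_center = burst_center, burst_bandwidth = burst_bandwidth,
                 pulse_duty_cycle = pulse_duty_cycle,
                 envelope_asymmetry = envelope_asymmetry,
                 resp_rate = resp_rate, envelope_jitter_sd = envelope_jitter_sd),
            class = "individual_profile")
}

#' Draw individual profiles for a cohort
#'
#' Profile means are drawn around the call type's base values with spread
#' `between_sd_scale` times the unit between-individual spread, truncated to
#' the type's valid range. Consumes the current RNG stream; [generate_cohort()]
#' seeds it from `spec$seed` before calling this.
#'
#' @param spec A [cohort_spec()].
#' @return List of `spec$n_individuals` [individual_profile()] objects.
#' @export
sample_individual_profiles <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  b <- spec$base
  bt <- spec$between_sd_scale
  wt <- spec$within_sd_scale
  lapply(seq_len(spec$n_individuals), function(i) {
    id <- sprintf("ind%02d", i)
    f0 <- .rtnorm(b$f0_center, bt * b$f0_between_sd, b$f0_range[1], b$f0_range[2])
    dur <- .rtnorm(b$duration_center, bt * b$duration_between_sd,
                   b$duration_range[1], b$duration_range[2])
    if (spec$call_type == "meow") {
      fc <- mapply(function(c0, s) .rtnorm(c0, bt * s, lo = 200),
                   b$formant_centers, b$formant_between_sd)
      fc <- sort(fc)
      if (any(diff(fc) < 50)) fc <- fc[1] + (seq_along(fc) - 1) * max(diff(c(0, fc)), 300)
      individual_profile(id, "meow", f0_mean = f0,
                         f0_jitter_sd = wt * b$f0_jitter_sd_unit,
                         duration_mean = dur,
                         duration_sd = wt * b$duration_sd_unit,
                         formant_centers = fc,
                         formant_bandwidths = b$formant_bandwidths,
                         envelope_jitter_sd = wt * b$envelope_jitter_sd_unit)
    } else {
      individual_profile(id, "purr", f0_mean = f0,
                         f0_jitter_sd = wt * b$f0_jitter_sd_unit,
                         duration_mean = dur,
                         duration_sd = wt * b$duration_sd_unit,
                         burst_center = .rtnorm(b$burst_center, bt * b$burst_between_sd, lo = 80),
                         burst_bandwidth = .rtnorm(b$burst_bandwidth, bt * b$burst_bw_between_sd, lo = 40),
                         pulse_duty_cycle = .rtnorm(b$duty_center, bt * b$duty_between_sd, 0.05, 0.9),
                         envelope_asymmetry = .rtnorm(b$asym_center, bt * b$asym_between_sd, 0, 1),
                         resp_rate = .rtnorm(b$resp_center, bt * b$resp_between_sd, 0.5, 2),
                         envelope_jitter_sd = wt * b$envelope_jitter_sd_unit)
    }
  })
}

# sum-of-Lorentzians vocal tract gain with a flat base so the fundamental
# always survives between resonances
.resonance_gain <- function(f, centers, bandwidths, base = 0.12) {
  g <- rep(base, length(f))
  for (j in seq_along(centers)) {
    hw <- bandwidths[j] / 2
    g <- g + hw^2 / ((f - centers[j])^2 + hw^2)
  }
  g
}

#' Synthesize one meow-like call
#'
#' Additive harmonic source at the per-call F0 (profile mean plus Gaussian
#' jitter, truncated to \[150, 1200\] Hz), with a 1/k^2 source roll-off shaped
#' by Lorentzian resonances at the profile's formants, under a rise-then-fall
#' amplitude envelope (open-then-closing mouth). At least 5 harmonics below
#' Nyquist are required. Consumes the current RNG stream.
#'
#' @param profile An [individual_profile()] with `call_type = "meow"`.
#' @param sample_rate Sampling rate in Hz.
#' @return A [call_recording()], peak-normalized to 0.9.
#' @export
synthesize_meow <- function(profile, sample_rate = 96000) {
  if (profile$call_type != "meow") stop("synthesize_meow: profile is not a meow profile")
  nyq <- sample_rate / 2
  if (any(profile$formant_centers >= nyq))
    stop("synthesize_meow: formant center at or above Nyquist (", nyq, " Hz)")
  f0 <- .rtnorm(profile$f0_mean, profile$f0_jitter_sd, 150, 1200)
  dur <- .rtnorm(profile$duration_mean, profile$duration_sd, lo = 0.05)
  fc <- profile$formant_centers
  if (profile$envelope_jitter_sd > 0)
    fc <- fc + stats::rnorm(length(fc), 0, profile$envelope_jitter_sd)
  fc <- pmin(sort(fc), 0.9 * nyq)
  n <- round(dur * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  n_harm <- min(40L, floor(0.95 * nyq / f0))
  if (n_harm < 5L)
    stop("synthesize_meow: fewer than 5 harmonics fit below Nyquist; raise sample_rate")
  k <- seq_len(n_harm)
  amp <- .resonance_gain(k * f0, fc, profile$formant_bandwidths) / k^2
  wave <- numeric(n)
  for (i in k) wave <- wave + amp[i] * sin(2 * pi * i * f0 * t)
  tau <- t / dur
  env <- tau^0.9 * (1 - tau)^1.5
  wave <- wave * env
  wave <- 0.9 * wave / max(abs(wave))
  call_recording(wave, sample_rate, profile$individual_id, call_type = "meow")
}

#' Synthesize one purr-like call
#'
#' A low-frequency pulse train at the per-call F0 (truncated to \[20, 40\] Hz):
#' each pulse is a damped white-noise burst occupying `pulse_duty_cycle` of
#' the period, filtered by a two-pole resonator at the profile's
#' individual-specific burst center. A slow (`resp_rate` alternations per
#' second) smoothed square-wave amplitude modulation emulates the egressive /
#' ingressive breathing phases with amplitude ratio `envelope_asymmetry`.
#' Consumes the current RNG stream.
#'
#' @param profile An [individual_profile()] with `call_type = "purr"`.
#' @param sample_rate Sampling rate in Hz.
#' @return A [call_recording()], peak-normalized to 0.95.
#' @export
synthesize_purr <- function(profile, sample_rate = 96000) {
  if (profile$call_type != "purr") stop("synthesize_purr: profile is not a purr profile")
  duty <- profile$pulse_duty_cycle
  if (is.null(duty) || duty <= 0 || duty >= 1)
    stop("synthesize_purr: pulse_duty_cycle must lie in (0, 1)")
  f0 <- .rtnorm(profile$f0_mean, profile$f0_jitter_sd, 20, 40)
  dur <- .rtnorm(profile$duration_mean, profile$duration_sd, lo = 0.5)
  n <- round(dur * sample_rate)
  period <- round(sample_rate / f0)
  plen <- max(2L, round(duty * period))
  phase <- (seq_len(n) - 1) %% period
  gate <- ifelse(phase < plen, exp(-5 * phase / plen), 0)
  src <- stats::rnorm(n) * gate
  bc <- .rtnorm(profile$burst_center, profile$envelope_jitter_sd, lo = 60,
                hi = 0.4 * sample_rate)
  r <- exp(-pi * profile$burst_bandwidth / sample_rate)
  theta <- 2 * pi * bc / sample_rate
  y <- as.numeric(stats::filter(src, c(2 * r * cos(theta), -r^2), method = "recursive"))
  # egressive/ingressive alternation: smoothed square wave between 1 and asym
  asym <- profile$envelope_asymmetry
  s <- sin(2 * pi * profile$resp_rate / 2 * (seq_len(n) - 1) / sample_rate)
  gain <- asym + (1 - asym) * 0.5 * (1 + tanh(s / 0.08))
  y <- y * gain
  y <- 0.95 * y / max(abs(y))
  call_recording(y, sample_rate, profile$individual_id, call_type = "purr")
}

#' Generate a labelled synthetic cohort
#'
#' Seeds the RNG from `spec$seed`, draws the individual profiles first, then
#' synthesizes calls individual by individual (documented stream order), so
#' the whole cohort is reproducible from the spec alone.
#'
#' @param spec A [cohort_spec()].
#' @param species_id Species label attached to every recording.
#' @return A list of `n_individuals * calls_per_individual`
#'   [call_recording()]s, with the generating `spec` as attribute.
#' @export
generate_cohort <- function(spec, species_id = "synthetic") {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  set.seed(spec$seed)
  profiles <- sample_individual_profiles(spec)
  synth <- if (spec$call_type == "meow") synthesize_meow else synthesize_purr
  out <- vector("list", spec$n_individuals * spec$calls_per_individual)
  idx <- 1L
  for (p in profiles) {
    for (j in seq_len(spec$calls_per_individual)) {
      rec <- synth(p, spec$sample_rate)
      rec$species_id <- species_id
      out[[idx]] <- rec
      idx <- idx + 1L
    }
  }
  attr(out, "spec") <- spec
  attr(out, "profiles") <- profiles
  out
}

#' Generate a multi-species synthetic cohort
#'
#' Species differ by base shifts of F0, formants and duration (spread
#' `species_sd_scale`); individuals vary within species by `between_sd_scale`;
#' calls vary within individuals by `within_sd_scale`. One species (the
#' domestic-cat analogue) can be synthesized with its within-individual
#' variance multiplied by `within_multiplier`, emulating a more variable call.
#'
#' @param n_species Number of species.
#' @param individuals_per_species,calls_per_individual Cohort shape.
#' @param species_sd_scale Spread of species base parameters.
#' @param between_sd_scale,within_sd_scale As in [cohort_spec()].
#' @param variable_species Index of the species with inflated within-individual
#'   variance, or 0 for none.
#' @param within_multiplier Variance multiplier for `variable_species`.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @param base Optional base-table overrides (see [cohort_spec()]).
#' @return List of labelled [call_recording()]s (species `"species1"`, ...).
#' @export
generate_species_cohort <- function(n_species = 6, individuals_per_species = 4,
                                    calls_per_individual = 10,
                                    species_sd_scale = 1, between_sd_scale = 1,
                                    within_sd_scale = 1, variable_species = 1,
                                    within_multiplier = 3, sample_rate = 96000,
                                    seed = 1L, base = list()) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_species)) {
    b <- utils::modifyList(.synth_base("meow"), base)
    b$f0_center <- min(1100, max(250, b$f0_center + stats::rnorm(1, 0, 140 * species_sd_scale)))
    b$formant_centers <- sort(pmax(400, b$formant_centers +
      stats::rnorm(2, 0, c(220, 380) * species_sd_scale)))
    b$duration_center <- max(0.3, b$duration_center + stats::rnorm(1, 0, 0.18 * species_sd_scale))
    wt <- within_sd_scale * if (s == variable_species) within_multiplier else 1
    spec <- cohort_spec(individuals_per_species, calls_per_individual, "meow",
                        between_sd_scale = between_sd_scale, within_sd_scale = wt,
                        sample_rate = sample_rate, seed = 1L, base = b)
    profiles <- sample_individual_profiles(spec)
    for (p in profiles) {
      p$individual_id <- sprintf("sp%d_%s", s, p$individual_id)
      for (j in seq_len(calls_per_individual)) {
        rec <- synthesize_meow(p, sample_rate)
        rec$individual_id <- p$individual_id
        rec$species_id <- sprintf("species%d", s)
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  out
}

#' Write a cohort to WAV files plus a manifest
#'
#' One 16-bit PCM WAV per call, plus `manifest.csv` with columns
#' `file, individual_id, species_id, call_type, seed`.
#'
#' @param cohort A list of [call_recording()]s (e.g. from [generate_cohort()]).
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest (defaults to the cohort spec's).
#' @return The manifest as a data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NULL) {
  if (is.null(seed)) {
    spec <- attr(cohort, "spec")
    seed <- if (!is.null(spec)) spec$seed else NA_integer_
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort), function(i) {
    rec <- cohort[[i]]
    fn <- sprintf("call_%03d_%s_%s.wav", i, rec$individual_id, rec$call_type)
    write_wav(rec, file.path(dir, fn))
    data.frame(file = fn, individual_id = rec$individual_id,
               species_id = rec$species_id, call_type = rec$call_type,
               seed = seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
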