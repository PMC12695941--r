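Package: vocsig
Title: Individual Vocal Signatures in Cat Meows and Purrs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies how strongly cat vocalisations encode individual
    identity. Provides a source-filter synthesizer for meow-like (tonal,
    harmonic) and purr-like (low-frequency pulse train) calls with
    controllable between- and within-individual variance; per-call acoustic
    features (frame-averaged mel-frequency cepstral coefficients, duration,
    spectral centroid) from PCM WAV audio; stepwise discriminant function
    analysis with leave-one-out cross-validation, proportional priors and
    exact binomial tests against chance; Beecher's stereotypy index H_S and
    the derived number of encodable individuals; and within-group dispersion
    in discriminant signal space with one-way ANOVA, partial eta squared and
    post-hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    MASS,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
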