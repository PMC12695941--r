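# vocsig — individual vocal signatures in cat meows and purrs

`vocsig` quantifies how strongly a vocalisation encodes its caller's
identity, built around the two calls of the domestic cat: the tonal,
human-directed **meow** (F0 ≈ 208–1000 Hz) and the low-frequency pulsed
**purr** (F0 ≈ 25–30 Hz, produced on alternating egressive/ingressive
airstreams). It is aimed at bioacousticians who want a tested, reproducible
version of the standard individual-signature workflow, and at anyone who
needs a synthetic benchmark with known ground-truth caller identity.

The pipeline:

* **Synthesis** — `generate_cohort()` produces labelled meow-like
  (harmonic source + formant resonances) and purr-like (damped-noise pulse
  train + breathing-phase amplitude alternation) calls, with independently
  controllable between-individual and within-individual variance scales.
* **Features** — `extract_features()` reduces each call (synthetic or WAV)
  to duration, spectral centroid, and ten frame-averaged mel-frequency
  cepstral coefficients (30 ms windows for meows, 300 ms for purrs).
* **Discrimination** — `dfa()` fits a stepwise canonical discriminant
  function analysis (Wilks'-lambda selection, eigenvalues, explained
  variation, chi-squared); `classify_loocv()` estimates classification
  success by leave-one-out cross-validation with group-size priors and an
  exact binomial test against the chance level 100/g %.
* **Information** — `stereotypy()` applies Beecher's stereotypy index to the
  per-feature one-way ANOVA F statistics,

  H_s = log2 √((F + n̄ − 1)/n̄),

  sums the contributions to the total signature information H_S (bits per
  signal), and reports 2^H_S — the number of individuals the call type could
  encode.
* **Dispersion** — `dispersion()` measures within-group variability as the
  Euclidean distance of each call to its group centroid in discriminant
  signal space, with one-way ANOVA, partial η², and Tukey post-hoc
  contrasts (the domestic-vs-wild-cat comparison).
* **Orchestration** — `run_individual_signature_analysis()` and
  `run_species_comparison()` run the whole chain from a single seeded
  `run_config()`, with CSV report bundles and provenance.

## A worked example

An 8-individual × 15-call synthetic study per call type, with the
purr-analogue generated at three times the meow-analogue's
between-individual spread (the package's default study conditions), at
reduced sampling rates for speed:

```r
library(vocsig)
cfg <- run_config(
  input_mode = "synthetic", n_individuals = 8, calls_per_individual = 15,
  sample_rate = 16000, seed = 1,
  meow_base = list(duration_center = 0.5, duration_between_sd = 0.12,
                   duration_range = c(0.2, 1.0)),
  purr_base = list(duration_center = 2, duration_between_sd = 0.6,
                   duration_range = c(1, 4), duration_sd_unit = 0.3))
report <- run_individual_signature_analysis(cfg)
print(report)
```

```
meow: 120 calls / 8 individuals; LOOCV 50.0% (chance 12.50%, p <2e-16); H_S 3.63 bits (capacity 12.38)
purr: 120 calls / 8 individuals; LOOCV 84.2% (chance 12.50%, p <2e-16); H_S 18.86 bits (capacity 476173.68)
seed: 1  config: 374e15af
```

Both call types classify far above the 12.5 % chance level (exact binomial
p < 2e-16), and the purr-analogue — synthesized with the stronger
between-individual structure — shows both the higher cross-validated
accuracy and the larger information total, the ordering the pipeline is
designed to recover. The fitted model carries the usual DFA model-fit table:

```r
print(report$purr$model)
```

```
Discriminant function analysis
  8 groups, 120 calls, priors: proportional
  selected features: mfcc2, mfcc5, mfcc9, mfcc7, mfcc1, mfcc3, mfcc4
                            DF1    DF2    DF3   DF4  DF5  DF6 DF7
Eigenvalue               287.79  23.46   6.01  0.91  0.2 0.04   0
Explained variation [%]   90.40   7.40   1.90  0.30  0.1 0.00   0
Wilks' Lambda              0.00   0.00   0.06  0.42  0.8 0.96   1
Chi-squared             1303.01 671.28 314.80 97.70 25.3 4.83   0
```

Real data enter the same way: `run_config(input_mode = "wav_dir", ...)` for
a directory of WAVs plus a manifest, or `input_mode = "feature_csv"` for a
pre-extracted per-call feature table (one row per call: labels, duration,
spectral centroid, MFCC1–10; delimiter and decimal-comma variants are
sniffed automatically).

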