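---
title: "Quantifying individual vocal signatures in cat calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual vocal signatures in cat calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocsig)
```

## The question and the pipeline

Many animal vocalisations carry stable, caller-specific structure — an
*individual vocal signature*. Domestic cats offer a sharp test case because
their two familiar calls differ in almost everything: the **meow** is a tonal,
harmonically structured call (fundamental frequency roughly 208–1000 Hz,
typically under 2.5 s) used mostly toward humans, while the **purr** is a
continuous low-frequency pulse train (F0 25–30 Hz) produced on alternating
egressive and ingressive airstreams. `vocsig` implements the full analysis
chain needed to ask *which call type encodes more identity information*:

1. **Features** (`extract_features()`): each call is reduced to its duration,
   spectral centroid, and ten frame-averaged mel-frequency cepstral
   coefficients (MFCC1–10).
2. **Discrimination** (`dfa()`, `classify_loocv()`): a stepwise canonical
   discriminant function analysis classifies calls to individuals;
   leave-one-out cross-validation estimates the honest success rate, which an
   exact binomial test compares against the `chance_level()` of 100/g %.
3. **Information** (`stereotypy()`): Beecher's stereotypy index converts each
   feature's one-way ANOVA F (individual identity as the factor) into bits,
   $H_s = \log_2 \sqrt{(F + \bar n - 1)/\bar n}$, where $\bar n$ is the mean
   number of calls per individual; the per-feature contributions are summed
   and $2^{H_S}$ is the number of individuals the call type could encode.
4. **Dispersion** (`dispersion()`): within-group variability is measured as
   the Euclidean distance of each call to its group centroid in discriminant
   signal space, compared across groups by one-way ANOVA with partial
   $\eta^2$ and Tukey post-hoc contrasts — the tool used to ask whether one
   species' calls (the domestic cat's meows) are more variable than its
   relatives'.
5. **Synthesis** (`generate_cohort()`): because the original recordings are
   not redistributable, a source–filter synthesizer produces meow-like and
   purr-like cohorts with *known* ground-truth individual structure, so every
   stage above is testable end to end.

## The synthesizer: what it emulates and what it does not

The meow model is an additive harmonic source (per-call F0 drawn from the
individual's mean with Gaussian jitter, truncated to 150–1200 Hz; 1/k²
source roll-off) shaped by two Lorentzian formant resonances and a
rise-then-fall amplitude envelope mimicking the open-then-closing mouth. The
purr model is a pulse train at 20–40 Hz — each pulse a damped white-noise
burst through a two-pole resonator at an individual-specific center — with a
slow smoothed square-wave amplitude alternation emulating the
egressive/ingressive breathing phases (ratio `envelope_asymmetry`).

Individuality enters through the *profile*: each individual's F0, formant (or
burst) centers, and durations are drawn once around call-type base values,
with spread `between_sd_scale` times the unit spreads; each call then jitters
around its profile with spread `within_sd_scale` times the within-individual
units. Setting either scale to zero gives identical profiles or identical
calls, which the tests exploit.

**Calibration of the unit spreads (chosen once, as the package's default study
conditions).** The base values mirror the published descriptive statistics of
real meows and purrs (meow duration centred on 0.72 s within 0.17–2.21 s,
purr duration on 10.77 s within 1.09–39.82 s, 96 kHz sampling). The
between/within unit spreads were set so that an 8-individual, 15-call cohort
sits in the *realistic* separability regime rather than a trivially separable
one: the meow-analogue at unit between-spread cross-validates around 60–70 %
correct and the purr-analogue at three times the between-spread around
85–90 %, matching the regime observed in real recordings (64.4 % and 85.5 %
for the same design). The purr's spectral-envelope parameterization has no
published per-individual statistics, so it is validated purely through
recovery properties: cohorts generated with stronger between-individual
separation must yield higher cross-validated accuracy and higher $H_S$, and a
species synthesized with inflated within-individual variance must show the
largest signal-space dispersion. Total $H_S$ magnitudes under the 3:1
between-scale ratio exceed the real data's 2.65/4.47 bits — the prescribed
ratio implies a larger F-statistic gap than the recordings had — so only the
*ordering* of the two call types is treated as a recoverable quantity.

What the generator does **not** emulate: laryngeal production mechanics,
perceptual realism, background noise, microphone variation, or call
segmentation errors. Passing tests therefore demonstrate that the *pipeline*
recovers known structure, not that real cat calls behave like the model.

## Feature extraction choices

The analysis window is 30 ms for meows and 300 ms for purrs — roughly ten
periods of each call's fundamental — with a 50 % hop (a conventional default;
the hop is a config field so it is recorded with every run). The filterbank
has 26 triangular filters spanning 0 Hz to Nyquist on the mel axis
($m(f) = 2595\log_{10}(1+f/700)$); wide limits keep the purr's 25–30 Hz
fundamental region inside the first filters. No pre-emphasis is applied,
because pre-emphasis would suppress exactly that region. The 0th cepstral
coefficient (a loudness proxy) is excluded; "ten MFCCs" means orders 1–10,
and a `include_c0` flag makes the alternative testable. Filterbank energies
are floored at `1e-12` times the call's maximum energy before the log, so
silent frames cannot produce `-Inf`; because the floor is relative, the
coefficients are exactly invariant to amplitude gain. The DCT is the
orthonormal type-II, fixing the coefficient scale across implementations.
Frames are Hamming-tapered (the same taper as the QC spectrogram, whose
defaults — 1024-point FFT, 87.5 % overlap — reproduce the published display
resolution of 93.75 Hz per bin and 1.33 ms per hop); the last partial frame
is dropped rather than zero-padded.

These conventions (hop, filter count, frequency limits, c0 handling) are not
fixed by any published description of the original MATLAB routine, so exact
numerical agreement with the published supplementary feature table is not
guaranteed; all of them are explicit `mfcc_config()` fields.

## Discriminant analysis conventions

Variables first pass a tolerance screen (a feature is dropped while its
tolerance $1-R^2$ against the remaining features falls below 0.001), then
enter by the classical Wilks'-lambda stepwise rule with F-to-enter 3.84 and
F-to-remove 2.71 — the long-standing defaults of commercial DFA software,
since the original analysis names the software but not its thresholds. The
canonical solution is computed from the within/between SSCP pencil via a
Cholesky-whitened symmetric eigenproblem; coefficients are scaled to unit
pooled within-group score variance, with the sign convention that each
function's largest-magnitude coefficient is positive. For function $k$,
$\Lambda_k = \prod_{i\ge k} (1+\lambda_i)^{-1}$ and
$\chi^2_k = -(N-1-(p+g)/2)\ln\Lambda_k$.

Classification uses linear discriminant scores with the shared pooled
covariance (not quadratic), priors proportional to observed group sizes by
default (`"uniform"` by flag), and deterministic tie-breaking: larger prior
first, then group label order. Leave-one-out cross-validation refits the
group means and pooled covariance without the held-out call but keeps the
feature selection of the full fit — the behaviour of standard DFA software's
leave-one-out classification — while `nested = TRUE` re-runs screening and
selection inside every fold for sensitivity analysis. When no feature clears
F-to-enter, classification falls back to priors alone and the dispersion
stage falls back to the full-model space.

## Information index conventions

The per-feature F statistics come from one-way ANOVA with individual identity
as the single factor (with one factor, type II sums of squares equal type I;
"random factor" does not change the F ratio in this design, so a fixed-form
computation is used). $\bar n$ is a single pooled value — total calls over
individuals — for the whole data set, following the printed formula's usage;
it is computed from the data actually supplied rather than hard-coded.
Features with $F < 1$ (less between- than within-individual variance) would
contribute negative bits; such contributions are clipped to zero, since
information cannot be negative. Contributions are summed over the raw
coefficients without decorrelation; a PCA-decorrelated variant is available
behind `decorrelate = TRUE` but is off by default, matching the analysis this
package follows. No confidence intervals are attached to $H_S$.

## Dispersion conventions

Distances are measured to centroids recomputed from the projected calls (not
taken from the model), so the operation also works on held-out projections.
The default signal space uses *all* retained discriminant functions;
`n_functions = 2` reproduces the two-dimensional space of the published
figures. The published between-species dispersion ANOVA ($F_5 = 15.294$,
$\eta^2 = 0.24$) does not state which dimensionality it used, so that figure
is reported for comparison only, never asserted. Post-hoc contrasts are Tukey
HSD by default (the conventional companion of one-way ANOVA), with
Bonferroni-adjusted pairwise t tests by flag.

## Problem sizes used by the tests and the acceptance script

The test suite exercises the full audio pipeline at reduced sampling rates
(16 kHz meow-analogues, 8 kHz purr-analogues) and shortened durations
(≈0.5 s and ≈2 s), which keeps every property checkable in minutes while
leaving the variance structure — the quantity under test — at the default
study conditions. The statistical recovery properties use 8 × 15 cohorts
(the balanced study design) over 25–50 replicates, and the species-dispersion
recovery uses 6 species × 4 individuals × 12 calls with the variable species
at 3× within-individual variance and a halved between-individual spread (with
few individuals per species, individual sampling noise would otherwise
dominate the species-level dispersion contrast). The acceptance script runs
the generator at its full defaults (96 kHz, full durations).

## Known limitations

* The synthesizer's purr envelope is a minimal two-parameter model; real
  purrs have richer spectro-temporal structure (and occasional embedded tonal
  components) that MFCCs would pick up. Its noise bursts also keep more
  broadband energy than a real purr, so the synthetic purr's spectral
  centroid sits well above the few hundred hertz of real recordings; the
  centroid is reported descriptively and does not enter the MFCC-based
  discrimination.
* Exact reproduction of the published feature table would require the
  original MATLAB configuration (hop, filter count, limits), which is not
  public; agreement is therefore expected at the level of statistical
  conclusions, not coefficients.
* Stepwise selection on the full data before leave-one-out classification is
  mildly optimistic; the nested mode quantifies that optimism but is not the
  default, to match standard practice.
* $H_S$ sums correlated MFCC contributions; the decorrelated variant
  typically gives smaller totals.

## A worked desk-scale example

```{r example, eval = FALSE}
library(vocsig)
cfg <- run_config(input_mode = "synthetic", seed = 1)
report <- run_individual_signature_analysis(cfg)
print(report)
```
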