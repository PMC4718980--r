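---
title: "Modulation-spectrum metrics for voice pathology detection: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulation-spectrum metrics for voice pathology detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`msvoice` implements a modulation-spectrum (MS) analysis chain for sustained
vowels: six scalar metrics of the MS modulus, an equal-error-rate (EER)
threshold detector evaluated with speaker-grouped cross-validation, a staged
grid-search tuning protocol, a GMM ensemble over the metric vectors, and a
synthetic vowel generator that makes every stage testable. This vignette is
the package's own account of the underlying models, the tunable parameters,
the numerical choices made where the design was genuinely open, and what the
synthetic experiments do and do not establish.

## The modulation spectrum

A sustained vowel is quasi-periodic: energy sits at the fundamental and its
harmonics, and in a healthy phonation those carriers are nearly steady.
Pathological phonation perturbs the carriers cycle to cycle — period (jitter)
and amplitude (shimmer) fluctuations, additive turbulence noise, slow tremor
— which amplitude-modulates the subband envelopes. The MS represents exactly
this: `compute_modspec()` filters a frame with an sTFT filterbank, takes each
subband's envelope, and Fourier-analyzes the envelopes, giving a complex
matrix `E(f_a, f_m)` indexed by acoustic band center `f_a` and modulation
frequency `f_m`. Only the modulus `|E|` is used downstream.

Realization choices, all exposed through `modspec_config()`:

- **Filterbank**: an sTFT with a Hann window of `2*(n_acoustic_bands - 1)`
  samples, so the one-sided bin count equals the acoustic band count
  (default 128 bands, i.e. a 254-sample window, uniform centers
  `k * fs / 254`, ≈ 98 Hz apart at 25 kHz).
- **Demodulation**: the magnitude of the complex sTFT coefficient sequence
  per band — the standard incoherent realization of Hilbert-envelope
  demodulation for narrow bands. Coherent (carrier-tracking) demodulation is
  deliberately out of scope.
- **Envelope rate**: the sTFT hop (default 32 samples) sets the envelope
  sampling rate `fs/hop` = 781.25 Hz at 25 kHz, supporting modulation
  analysis to ±390 Hz, comfortably above the 220 Hz maximum the tuning
  protocol explores.
- **Modulation FFT**: each band's envelope is transformed with a 1024-point
  FFT and the columns reordered to a symmetric −/0/+ axis (bin spacing
  ≈ 0.76 Hz). With an even FFT length one −Nyquist bin is unpaired; the
  modulus symmetry `|E(f_a, f_m)| = |E(f_a, −f_m)|` holds for all paired
  bins because envelopes are real.
- **DC handling**: a 180 ms frame yields only ~133 envelope samples, far
  fewer than the 1024 FFT points. Transforming the raw zero-padded envelope
  would smear the large envelope mean across the ±7 bins nearest 0 Hz,
  burying genuine low-rate side bands under the DC skirt. The package
  therefore computes the 0 Hz bin exactly as the envelope sum and the
  remaining bins from the demeaned, zero-padded envelope. The 0 Hz column
  still carries the full central-band energy — a pure tone produces its
  global maximum there — while a 50 Hz AM tone shows its strongest off-0 Hz
  cells at ±50 Hz, as it must.
- **No envelope taper** before the modulation FFT (rectangular window): the
  simplest reproducible choice; with the mean handled exactly, rectangular
  leakage from genuine side bands is mild and symmetric.

One practical consequence of the filterbank geometry: AM side bands are
represented *within* a band only while the modulation rate stays inside the
analysis window's bandwidth (±2 bins ≈ ±200 Hz for the Hann main lobe).
Fast modulations approaching the band spacing are progressively resolved as
separate carriers instead. The calibration tests sweep rates 20–200 Hz,
which the default geometry represents correctly.

`restrict_modspec()` slices the matrix to an acoustic range
`[fa_low, fa_high]` and modulation range `|f_m| ≤ fm_high` (0 Hz always
kept); all band-restricted metrics are defined through it.

## The six metrics

All metrics consume the modulus; RALA uses linear units (as its definition
requires), the others the dB modulus `20·log10|E|` with a −120 dB floor for
zero cells (preventing infinite percentiles on silence-adjacent synthetic
frames).

- **MSH** (`msh()`): `Σ |cell − mean of its N×N neighbourhood|` on the dB
  matrix. The printed definition this follows omits the absolute value, but
  without it the sum telescopes toward zero for any matrix; the magnitude
  form is the standard homogeneity measure and is what makes the even/odd
  mask-size contrast meaningful. For even N the window anchored at `(i, j)`
  spans `i − N/2 + 1 .. i + N/2`, i.e. the anchor sits off-centre; this
  asymmetry is why even masks discriminate better and why the shipped mask
  is 6×6. Border windows are truncated to in-matrix cells.
  Whether the original study computed MSH on linear or dB modulus is not
  documented; dB is the package default (and a config switch), consistent
  with the image-homogeneity framing.
- **CIL** (`cil()`): the intersection of the increasing and decreasing
  cumulative histogram curves of the dB modulus — by construction the
  median, and implemented directly as such.
- **RALA** (`rala()`): `N_A / N_B` against the linear mean, with the `≥ / <`
  partition. An all-equal matrix (N_B = 0) is a degenerate spectrum and
  raises an error rather than returning infinity.
- **MSP25/75/95** (`msp()`): percentiles of the dB cells under the
  linear-interpolation-between-closest-ranks convention
  (`quantile(type = 7)`), shared with `cil()` so `msp(x, 50) == cil(x)`
  exactly. The verbal low/mid/high-level reading of the percentiles in the
  source literature is internally confusing; the plain p-th percentile is
  implemented.

`frame_metrics()` computes the MS once per frame and evaluates each metric on
its own restricted sub-matrix; `corpus_metrics()` maps this over a corpus
after peak normalization, yielding the tidy per-frame feature table the rest
of the package consumes. Because every metric is either a level ratio or is
computed after per-recording peak normalization, the whole table is invariant
to pre-normalization gain — asserted end-to-end in the tests.

## Detection and cross-validation

`eer_point()` learns a threshold on training scores: candidates are midpoints
between adjacent sorted unique scores plus ±∞; the candidate minimizing
`|FPR − FNR|` is chosen (finite samples rarely allow exact equality; ties go
to the lower threshold) and `(FPR + FNR)/2` reported as the EER. Orientation
— whether pathology scores high or low — is learned per training split by
comparing class mean *ranks* rather than means: a rank statistic keeps the
operating point invariant under any strictly monotone rescaling of a metric,
which raw means do not guarantee. Scores exactly at the threshold classify
as pathological (sensitivity-favouring tie rule).

`assign_speaker_folds()` assigns whole speakers to folds (stratified by class
and dealt round-robin after a seeded shuffle), so no speaker's frames ever
straddle a train/test split — the leakage assertion is re-checked on every
CV run. `cv_single_metric_efficiency()` reports per-fold efficiencies, their
mean and sample SD; decisions are per frame by default, or per recording
(mean frame score) via `level = "recording"` — which of the two the original
evaluation counted is not documented, so both are provided.

## The tuning protocol

`run_stage()`/`run_tuning()` implement the four-stage coordinate-wise
protocol: frame length (20–200 ms, 20 ms steps), MSH mask size (2–12),
modulation upper limit (20–220 Hz, 20 Hz steps), then acoustic margins
(lower 0–1000 Hz in 100 Hz steps; upper 1.2–12 kHz, 300 Hz steps at low
frequencies and wider above — the exact upper list is not fully printed in
the source material, so the default grid unions the step description with
every bound the selected ranges use). Each stage runs with the previous
selections frozen; stages that do not vary the frame length compute the
spectra once and re-restrict per candidate. `select_best_value()` encodes
the published selection logic: among candidates within 1 % absolute
efficiency of the maximum, prefer the smallest (shorter frames better
satisfy stationarity; smaller masks and limits are cheaper and less
corpus-specific). `cross_corpus_consensus()` is a reproducible stand-in for
the by-inspection choice of "generalist" ranges across two tuning corpora:
min-max normalize each corpus's efficiencies and take the candidate
maximizing the worse of the two. `tuned_defaults()` ships the selected
configuration (180 ms, 6×6, and the six per-metric ranges) exactly.

## GMM ensemble and feature associations

`fit_gmm_detector()` z-scores the features (parameters from the training rows
only — a conditioning step, not part of the original description) and fits
one diagonal-covariance GMM per class by EM with seeded k-means
initialization and a 1e-6 variance floor; decisions compare class
log-likelihoods with equal priors. The EM engine is deliberately small and
fully deterministic given the seed; a unit test cross-checks its attained
likelihood against `mclust` on a reference problem. `cv_gmm_efficiency()`
sweeps component counts (the study span is 4–64) under the same
speaker-grouped folds and adds a 95 % normal-approximation binomial
half-width on the pooled decision count — the confidence-interval
construction in the source tables is unstated, so this standard one is used
and labelled.

`correlation_matrix()` and `relative_mi_matrix()` quantify metric redundancy.
The relative mutual information estimator is a documented reconstruction:
equal-width binning over each metric's observed range (default 32 bins),
plug-in histogram MI, normalized by `log2(n_bins)`. Under this normalization
the diagonal is the normalized marginal entropy — below 1 for peaked
distributions — which reproduces the qualitative non-unit diagonal of the
published matrices; it is not claimed to be the original authors' estimator.

## The synthetic generator

`synth_vowel()` is an additive harmonic source — `n_harmonics` harmonics
with 1/k roll-off — with cycle-by-cycle Gaussian period perturbation
(jitter, % of period, clipped at ±3 SD), cycle gain perturbation (shimmer),
sinusoidal amplitude tremor, and white noise scaled to a target
harmonics-to-noise power ratio (defined pre-normalization; the synthesized
parts are kept as an attribute so tests can audit the power bookkeeping).
`make_corpus()` draws per-speaker parameters uniformly from class ranges:
the `strong` profile plants jitter 0–0.3 % / shimmer 0–1.5 % / HNR 25–35 dB
for normals against 1.5–4 % / 4–10 % / 5–15 dB for pathologicals (typical
normative vs clearly dysphonic perturbation magnitudes); `moderate` sits in
between; `null` draws both classes from the normal ranges. Field-wise range
overrides allow planting targeted effects, e.g. a 40–60 Hz tremor band that
only a modulation-limit sweep reaching 60 Hz can see.

What this emulates: labeled multi-speaker sustained-vowel corpora with
controllable, known perturbation differences at 25 kHz. What it does not:
glottal-flow waveforms and formant structure (a 1/k spectral envelope, not a
vocal tract), specific pathologies, recording-channel variability, or any
link between synthetic perturbation levels and clinical severity. Passing
tests therefore validate the *machinery* — spectra, metrics, thresholds,
folding, tuning, ensembles — not clinical performance, and the published
per-database efficiency figures are not reproduction targets here because
the clinical corpora are not redistributable.

## Problem sizes, determinism, degenerate inputs

The test-suite experiments use sizes chosen to exercise the statistics
honestly while staying desk-scale: the strong-effect corpus is 10 speakers
per class × 3 s (≈ 320 frames at 180 ms); null calibration averages 20 seeded
corpora of 10 speakers per class × 1 s (the null property is
duration-independent, so shorter recordings suffice); the planted-band sweep
uses 10 speakers per class × 2 s. The null-calibration band `[0.40, 0.60]`
is asserted on the across-seed mean per metric — the per-seed efficiency is
a single random draw whose spread is a property of corpus size, not of
correctness.

Everything stochastic flows from explicit integer seeds (corpus seed →
per-speaker seeds; CV seed → fold shuffle; GMM seed → per-fit k-means), so
corpora, plans, stage results and fitted detectors are bit-reproducible.
Degenerate inputs fail loudly with typed errors: all-zero signals
(normalization, metrics), frames shorter than a window, empty band
restrictions, all-equal spectra (RALA), single-class training splits,
zero-variance or constant features.

## Known limitations

- The sTFT filterbank parameters of the original analysis toolbox are not
  published; the window/hop here are documented configuration, and absolute
  metric values will differ from other MS implementations even though the
  qualitative behaviour (peak placement, symmetry, class separation) is
  calibrated by tests.
- Whether "1024 modulation bands" counts one- or two-sided bins is ambiguous
  in the source; two-sided is assumed (figures show negative modulation
  frequencies).
- The consensus rule and the MI normalization are explicit reconstructions
  of narrative procedures, and labelled as such above.
- Frame-level efficiency treats frames from one speaker as exchangeable
  test items; with few speakers per fold the per-fold SD understates
  speaker-level uncertainty.
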