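# msvoice

Modulation-spectrum metrics for voice pathology detection from sustained
vowels.

## The problem

Dysphonic voices disperse acoustic energy away from the harmonic structure a
healthy phonation maintains. The **modulation spectrum** (MS) makes this
visible: the signal is split into acoustic subbands with an sTFT filterbank,
each subband's Hilbert envelope is extracted, and the envelopes are Fourier
analyzed, producing a complex matrix `E(f_a, f_m)` over acoustic frequency
`f_a` (carrier) and modulation frequency `f_m` (envelope fluctuation rate). A
steady vowel concentrates `|E|` at the 0 Hz modulation column; perturbed
phonation (jitter, shimmer, noise, tremor) spreads it into side bands.

`msvoice` condenses `|E|` into six scalar metrics and wraps them in a full
detection workflow:

- **MSH** — modulation spectrum homogeneity,
  `MSH = Σ_a Σ_m | E(f_a,f_m) − Ē_{N×N}(f_a,f_m) |`, the summed absolute
  deviation of each dB cell from its N×N neighbourhood mean (higher = less
  homogeneous);
- **CIL** — cumulative intersection level, the intersection of the increasing
  and decreasing cumulative histogram curves of the dB modulus, i.e. its
  median;
- **RALA** — ratio of points above the linear average,
  `RALA = N_A / N_B` with `N_A = #{|E| ≥ mean|E|}`, `N_B = #{|E| < mean|E|}`;
- **MSP25 / MSP75 / MSP95** — percentiles of the dB modulus level
  distribution.

Around the metrics the package provides: speaker-grouped k-fold
cross-validation of an equal-error-rate (EER) threshold detector; the
four-stage coordinate-wise tuning protocol (frame length → MSH mask →
modulation upper limit → acoustic margins) with shipped tuned defaults; a
two-class diagonal-covariance GMM ensemble over the six-metric vectors with
Pearson/relative-mutual-information feature diagnostics; and a synthetic
sustained-vowel generator (jitter, shimmer, HNR, tremor) so everything is
testable without clinical corpora.

It is written for speech/voice researchers and for engineers evaluating
acoustic screening front-ends.

## Worked example

Generate a labeled synthetic corpus with a strong planted pathology effect,
compute per-frame metrics at the tuned defaults, and cross-validate each
metric and the GMM ensemble:

```r
library(msvoice)

corpus  <- make_corpus(corpus_spec(n_speakers_per_class = 10, duration_s = 3,
                                   effect = "strong", seed = 101))
metrics <- corpus_metrics(corpus)            # tuned_defaults() ranges, 180 ms frames
plan    <- assign_speaker_folds(corpus, k = 7, seed = 11)

purrr::map_dfr(c("msh","cil","rala","msp25","msp75","msp95"),
               \(m) glance(cv_single_metric_efficiency(metrics, m, plan)))
#>   metric mean_efficiency    sd level     k  seed
#> 1 msh              0.607 0.119 frame     7    11
#> 2 cil              1     0     frame     7    11
#> 3 rala             0.938 0.165 frame     7    11
#> 4 msp25            1     0     frame     7    11
#> 5 msp75            0.929 0.122 frame     7    11
#> 6 msp95            0.924 0.130 frame     7    11

cv_gmm_efficiency(metrics, plan, component_grid = c(4, 8, 16), seed = 19)
#>   n_components mean_efficiency    sd pooled_efficiency ci_halfwidth n_pooled
#> 1            4               1     0                 1            0      320
#> 2            8               1     0                 1            0      320
#> 3           16               1     0                 1            0      320
```

Each `mean_efficiency` is the average fraction of correctly classified frames
over the 7 speaker-grouped folds, classifying at the EER threshold learned on
the training folds (chance is 0.5). The dispersion metrics separate the
planted effect almost perfectly; MSH is the weakest on this synthetic
material, as its contrast cue depends on harmonic texture the simple additive
source only partly reproduces. The GMM ensemble matches the best single
metric. `autoplot()` methods exist for spectra, detection results, tuning
stages and association matrices, and `ms_cli()` (wrapper in
`inst/scripts/msvoice-cli.R`) exposes the same pipeline as `synth`,
`metrics`, `detect`, `tune`, `ensemble` and `assoc` subcommands.

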