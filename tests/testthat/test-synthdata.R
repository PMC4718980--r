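# Tone stimuli and the synthetic vowel/corpus generator.

test_that("pure tone has unit peak, sine RMS, and is deterministic", {
  tn <- pure_tone(1000, 1, 25000)
  expect_length(tn$samples, 25000)
  expect_equal(max(abs(tn$samples)), 1)
  expect_equal(sqrt(mean(tn$samples^2)), sqrt(0.5), tolerance = 1e-3)
  expect_identical(tn$samples, pure_tone(1000, 1, 25000)$samples)
  expect_error(pure_tone(13000, 1, 25000), class = "msvoice_error_aliasing")
})

test_that("AM tone matches the closed-form AM spectrum", {
  am <- am_tone(1000, 50, 0.5, 1, 25000)
  # depth 0 degenerates to the pure tone
  expect_identical(am_tone(1000, 50, 0, 1, 25000)$samples,
                   pure_tone(1000, 1, 25000)$samples)
  # carrier at 1000, sidebands at 950/1050 with amplitude ratio depth/2
  S <- Mod(fft(am$samples)) / length(am$samples)
  hz <- function(f) round(f * length(am$samples) / 25000) + 1
  expect_equal(S[hz(950)] / S[hz(1000)], 0.25, tolerance = 1e-6)
  expect_equal(S[hz(1050)] / S[hz(1000)], 0.25, tolerance = 1e-6)
  # no other spectral content
  keep <- c(hz(c(950, 1000, 1050)), length(am$samples) + 2 - hz(c(950, 1000, 1050)))
  expect_lt(max(S[-keep]), 1e-10 * max(S))
  # full-depth modulation pinches the envelope to ~0
  full <- am_tone(500, 25, 1, 1, 25000)
  env <- abs(full$samples)
  expect_lt(min(stats::filter(env, rep(1 / 25, 25), sides = 2), na.rm = TRUE), 0.05)
  expect_error(am_tone(1000, 50, 1.5, 1), class = "msvoice_error_parameter")
})

test_that("a clean vowel is periodic at 1/f0", {
  v <- synth_vowel(voice_params(f0 = 125, duration_s = 1), seed = 1)
  x <- v$samples
  lag <- 25000 / 125
  r <- cor(x[1:(length(x) - lag)], x[(lag + 1):length(x)])
  expect_gte(r, 0.99)
})

test_that("the HNR of the synthesized parts matches the request within 1 dB", {
  for (target in c(10, 20, 30)) {
    v <- synth_vowel(voice_params(f0 = 140, jitter_pct = 0.5, shimmer_pct = 2,
                                  hnr_db = target, duration_s = 1), seed = 5)
    parts <- attr(v, "components")
    measured <- 10 * log10(mean(parts$harmonic^2) / mean(parts$noise^2))
    expect_lt(abs(measured - target), 1)
    # the normalized output is the scaled sum of the parts
    total <- parts$harmonic + parts$noise
    expect_equal(v$samples, total / max(abs(total)), tolerance = 1e-12)
  }
})

test_that("vowel synthesis is deterministic and validates parameters", {
  p <- voice_params(f0 = 110, jitter_pct = 2, shimmer_pct = 5, hnr_db = 15,
                    duration_s = 0.5)
  expect_identical(synth_vowel(p, seed = 7)$samples,
                   synth_vowel(p, seed = 7)$samples)
  expect_false(identical(synth_vowel(p, seed = 7)$samples,
                         synth_vowel(p, seed = 8)$samples))
  expect_error(voice_params(f0 = -10), class = "msvoice_error_parameter")
  expect_error(voice_params(f0 = 200, n_harmonics = 80, fs = 25000),
               class = "msvoice_error_parameter")
})

test_that("jitter and noise break strict periodicity", {
  clean <- synth_vowel(voice_params(f0 = 125, duration_s = 0.5), seed = 2)
  rough <- synth_vowel(voice_params(f0 = 125, jitter_pct = 3, hnr_db = 10,
                                    duration_s = 0.5), seed = 2)
  acf_at <- function(x, lag) cor(x[1:(length(x) - lag)], x[(lag + 1):length(x)])
  expect_gt(acf_at(clean$samples, 200), acf_at(rough$samples, 200))
})

test_that("make_corpus produces a balanced, reproducible labeled corpus", {
  spec <- corpus_spec(n_speakers_per_class = 5, duration_s = 0.5,
                      effect = "strong", seed = 12)
  co <- make_corpus(spec)
  expect_equal(nrow(co), 10)
  expect_equal(sum(co$label == "normal"), 5)
  expect_equal(sum(co$label == "pathological"), 5)
  expect_equal(length(unique(co$speaker_id)), 10)
  co2 <- make_corpus(spec)
  expect_identical(purrr::map(co$recording, "samples"),
                   purrr::map(co2$recording, "samples"))
  # planted effect visible in the drawn parameters
  expect_gt(mean(co$jitter_pct[co$label == "pathological"]),
            mean(co$jitter_pct[co$label == "normal"]))
  expect_lt(mean(co$hnr_db[co$label == "pathological"]),
            mean(co$hnr_db[co$label == "normal"]))
  # all recordings satisfy the signal contract
  for (r in co$recording) {
    expect_true(all(is.finite(r$samples)))
    expect_equal(max(abs(r$samples)), 1)
    expect_equal(r$fs, 25000)
  }
})

test_that("a null-effect corpus draws both classes from the same ranges", {
  spec <- corpus_spec(n_speakers_per_class = 4, duration_s = 0.5,
                      effect = "null", seed = 3)
  expect_identical(spec$ranges$normal, spec$ranges$pathological)
  co <- make_corpus(spec)
  expect_true(all(co$jitter_pct <= 0.3))
})

test_that("parameter range overrides plant a custom effect", {
  spec <- corpus_spec(n_speakers_per_class = 3, duration_s = 0.5,
                      effect = "null", seed = 4,
                      pathological_params = list(tremor_rate_hz = c(40, 60),
                                                 tremor_extent_pct = c(20, 40)))
  co <- make_corpus(spec)
  path <- co[co$label == "pathological", ]
  expect_true(all(path$tremor_rate_hz >= 40 & path$tremor_rate_hz <= 60))
  expect_true(all(co$tremor_rate_hz[co$label == "normal"] == 0))
})

test_that("write_corpus emits WAVs and a loadable manifest", {
  dir <- withr::local_tempdir()
  co <- make_corpus(corpus_spec(n_speakers_per_class = 2, duration_s = 0.3,
                                effect = "strong", seed = 6))
  mpath <- write_corpus(co, dir)
  expect_true(file.exists(mpath))
  back <- load_corpus(mpath)
  expect_equal(nrow(back), 4)
  expect_setequal(back$speaker_id, co$speaker_id)
  # 16-bit quantization round trip
  expect_lt(max(abs(back$recording[[1]]$samples - co$recording[[1]]$samples)),
            1.1 / 32767)
})
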