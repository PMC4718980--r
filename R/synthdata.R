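# Synthetic stimuli and labeled sustained-vowel corpora. The generator exists
# so the detection/tuning machinery can be exercised end-to-end with planted,
# known effects; it validates machinery, not clinical performance.

#' Pure sinusoidal tone
#'
#' @param f Tone frequency in Hz (`0 < f < fs/2`).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return A peak-normalized [recording()].
#' @export
pure_tone <- function(f, duration_s = 1, fs = 25000) {
  am_tone(fc = f, fm = 1, depth = 0, duration_s = duration_s, fs = fs)
}

#' Amplitude-modulated tone
#'
#' `(1 + depth * cos(2 pi fm t)) * cos(2 pi fc t)`, peak-normalized. With
#' `depth = 0` this degenerates to [pure_tone()].
#'
#' @param fc Carrier frequency in Hz (`0 < fc < fs/2`).
#' @param fm Modulation rate in Hz (`0 < fm < fs/2`).
#' @param depth Modulation depth in `[0, 1]`.
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return A peak-normalized [recording()].
#' @export
am_tone <- function(fc, fm, depth, duration_s = 1, fs = 25000) {
  if (fc <= 0 || fc >= fs / 2) {
    ms_abort(sprintf("carrier %g Hz violates 0 < f < fs/2 = %g", fc, fs / 2),
             "aliasing")
  }
  if (fm <= 0 || fm >= fs / 2) {
    ms_abort(sprintf("modulation rate %g Hz violates 0 < f < fs/2", fm),
             "aliasing")
  }
  if (depth < 0 || depth > 1) ms_abort("depth must be in [0, 1]", "parameter")
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  x <- (1 + depth * cos(2 * pi * fm * t)) * cos(2 * pi * fc * t)
  normalize_recording(recording(x, fs, speaker_id = "tone", label = "unknown",
                                source_path = sprintf("am_tone(%g,%g,%g)", fc, fm, depth)))
}

#' Voice synthesis parameters
#'
#' Parameters of the additive harmonic voice model: `n_harmonics` harmonics of
#' `f0` with 1/k amplitude roll-off, cycle-to-cycle Gaussian period
#' perturbation (`jitter_pct`, % of the period, clipped at +-3 SD),
#' cycle-to-cycle Gaussian gain perturbation (`shimmer_pct`, %), slow
#' sinusoidal amplitude tremor (`tremor_rate_hz`, `tremor_extent_pct`), and
#' white noise scaled so the harmonic-to-noise power ratio equals `hnr_db`
#' (use `Inf` for a noise-free voice).
#'
#' @param f0 Fundamental frequency in Hz.
#' @param n_harmonics Harmonic count; `n_harmonics * f0` must stay below
#'   `fs / 2`.
#' @param jitter_pct,shimmer_pct Perturbation extents in percent (>= 0).
#' @param hnr_db Harmonics-to-noise ratio in dB.
#' @param tremor_rate_hz,tremor_extent_pct Amplitude-tremor rate (Hz) and
#'   extent (%).
#' @param duration_s Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return An object of class `voice_params`.
#' @export
voice_params <- function(f0 = 125, n_harmonics = 20, jitter_pct = 0,
                         shimmer_pct = 0, hnr_db = Inf, tremor_rate_hz = 0,
                         tremor_extent_pct = 0, duration_s = 3, fs = 25000) {
  p <- list(f0 = f0, n_harmonics = as.integer(n_harmonics),
            jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
            hnr_db = hnr_db, tremor_rate_hz = tremor_rate_hz,
            tremor_extent_pct = tremor_extent_pct,
            duration_s = duration_s, fs = fs)
  if (p$f0 <= 0 || p$duration_s <= 0 || p$fs <= 0 ||
      p$jitter_pct < 0 || p$shimmer_pct < 0 || p$tremor_extent_pct < 0 ||
      p$n_harmonics < 1 || p$n_harmonics * p$f0 >= p$fs / 2) {
    ms_abort("invalid voice synthesis parameters", "parameter")
  }
  structure(p, class = "voice_params")
}

#' Synthesize a sustained vowel
#'
#' Builds the harmonic source cycle by cycle (each cycle's period and gain
#' independently perturbed), applies tremor AM, then adds white noise scaled
#' to the requested HNR. The returned recording is peak-normalized and carries
#' the pre-normalization harmonic and noise parts in
#' `attr(x, "components")` for power bookkeeping.
#'
#' @param params A [voice_params()].
#' @param seed Integer seed; the signal is bit-reproducible given
#'   `params` + `seed`.
#' @param speaker_id,label Metadata for the returned recording.
#' @return A [recording()].
#' @export
synth_vowel <- function(params, seed = 1, speaker_id = "synth",
                        label = "unknown") {
  stopifnot(inherits(params, "voice_params"))
  n <- round(params$duration_s * params$fs)
  t <- (seq_len(n) - 1) / params$fs
  n_cycles <- ceiling(params$duration_s * params$f0 * 1.5) + 8

  withr::with_seed(seed, {
    zj <- pmax(-3, pmin(3, rnorm(n_cycles)))
    zs <- pmax(-3, pmin(3, rnorm(n_cycles)))
    periods <- (1 / params$f0) * (1 + params$jitter_pct / 100 * zj)
    periods <- pmax(periods, 0.2 / params$f0)
    gains <- pmax(1 + params$shimmer_pct / 100 * zs, 0.05)

    cyc <- findInterval(t, cumsum(c(0, periods)))       # cycle index per sample
    inst_f <- 1 / periods[cyc]
    phase <- cumsum(2 * pi * inst_f / params$fs)
    harm <- numeric(n)
    for (k in seq_len(params$n_harmonics)) {
      harm <- harm + sin(k * phase) / k
    }
    harm <- harm * gains[cyc]
    if (params$tremor_extent_pct > 0 && params$tremor_rate_hz > 0) {
      harm <- harm * (1 + params$tremor_extent_pct / 100 *
                        sin(2 * pi * params$tremor_rate_hz * t))
    }
    noise <- if (is.finite(params$hnr_db)) {
      rnorm(n, sd = sqrt(mean(harm^2) / 10^(params$hnr_db / 10)))
    } else {
      numeric(n)
    }
    rec <- normalize_recording(recording(
      harm + noise, params$fs, speaker_id = speaker_id, label = label,
      source_path = sprintf("synth_vowel(f0=%g,seed=%d)", params$f0, seed)))
    attr(rec, "components") <- list(harmonic = harm, noise = noise)
    rec
  })
}

# Default per-class parameter ranges (uniform draws) by effect size.
effect_ranges <- function(effect) {
  normal <- list(f0 = c(100, 220), jitter_pct = c(0, 0.3),
                 shimmer_pct = c(0, 1.5), hnr_db = c(25, 35),
                 tremor_rate_hz = c(0, 0), tremor_extent_pct = c(0, 0))
  pathological <- switch(effect,
    strong = list(f0 = c(100, 220), jitter_pct = c(1.5, 4),
                  shimmer_pct = c(4, 10), hnr_db = c(5, 15),
                  tremor_rate_hz = c(0, 0), tremor_extent_pct = c(0, 0)),
    moderate = list(f0 = c(100, 220), jitter_pct = c(0.5, 1.5),
                    shimmer_pct = c(1.5, 4), hnr_db = c(15, 25),
                    tremor_rate_hz = c(0, 0), tremor_extent_pct = c(0, 0)),
    null = normal
  )
  list(normal = normal, pathological = pathological)
}

#' Specification of a synthetic labeled corpus
#'
#' Describes a two-class corpus of synthetic sustained vowels: per-class
#' parameter ranges (uniform draws per speaker), speaker counts, recording
#' duration and a seed fixing the whole corpus bit-for-bit. The built-in
#' effect profiles plant class differences in jitter, shimmer and HNR:
#' `"strong"` (normal jitter 0-0.3 %, HNR 25-35 dB vs pathological jitter
#' 1.5-4 %, HNR 5-15 dB), `"moderate"` (intermediate), `"null"` (classes
#' identically distributed). `normal_params` / `pathological_params` entries
#' (named `c(lo, hi)` ranges) override the profile field-wise, e.g. to plant a
#' tremor band.
#'
#' @param n_speakers_per_class Speakers per class.
#' @param duration_s Recording duration per speaker in seconds.
#' @param fs Sampling rate in Hz.
#' @param effect `"strong"`, `"moderate"` or `"null"`.
#' @param seed Integer seed.
#' @param normal_params,pathological_params Named lists of `c(lo, hi)` range
#'   overrides.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_speakers_per_class = 10, duration_s = 3, fs = 25000,
                        effect = c("strong", "moderate", "null"), seed = 1,
                        normal_params = list(), pathological_params = list()) {
  effect <- match.arg(effect)
  if (n_speakers_per_class < 1 || duration_s <= 0 || fs <= 0) {
    ms_abort("invalid corpus specification", "parameter")
  }
  rng <- effect_ranges(effect)
  rng$normal[names(normal_params)] <- normal_params
  rng$pathological[names(pathological_params)] <- pathological_params
  for (cls in names(rng)) {
    for (f in names(rng[[cls]])) {
      v <- rng[[cls]][[f]]
      if (!is.numeric(v) || length(v) != 2 || v[1] > v[2]) {
        ms_abort(sprintf("range for %s$%s must be c(lo, hi)", cls, f), "parameter")
      }
    }
  }
  structure(
    list(n_speakers_per_class = as.integer(n_speakers_per_class),
         duration_s = duration_s, fs = fs, effect = effect,
         seed = as.integer(seed), ranges = rng),
    class = "corpus_spec"
  )
}

#' Generate a synthetic labeled corpus
#'
#' Draws one parameter set per speaker from the class ranges and synthesizes
#' one recording per speaker. Deterministic given the spec (per-speaker seeds
#' are derived from the corpus seed).
#'
#' @param spec A [corpus_spec()].
#' @return A corpus tibble: `speaker_id`, `recording_id`, `label`, the drawn
#'   synthesis parameters, and a `recording` list-column.
#' @export
make_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  draw_one <- function(cls, i) {
    sid <- sprintf("%s%02d", substr(cls, 1, 1), i)
    sseed <- ms_child_seed(spec$seed, i + ifelse(cls == "pathological", 5000, 0))
    rng <- spec$ranges[[cls]]
    pars <- withr::with_seed(sseed, {
      lapply(rng, function(v) runif(1, v[1], v[2]))
    })
    f0 <- pars$f0
    vp <- voice_params(
      f0 = f0,
      n_harmonics = min(30L, max(1L, floor(0.45 * spec$fs / f0))),
      jitter_pct = pars$jitter_pct, shimmer_pct = pars$shimmer_pct,
      hnr_db = pars$hnr_db, tremor_rate_hz = pars$tremor_rate_hz,
      tremor_extent_pct = pars$tremor_extent_pct,
      duration_s = spec$duration_s, fs = spec$fs
    )
    rec <- synth_vowel(vp, seed = ms_child_seed(sseed, 1), speaker_id = sid,
                       label = cls)
    tibble::tibble(
      speaker_id = sid, recording_id = paste0(sid, "_r1"), label = cls,
      f0 = f0, jitter_pct = pars$jitter_pct, shimmer_pct = pars$shimmer_pct,
      hnr_db = pars$hnr_db, tremor_rate_hz = pars$tremor_rate_hz,
      tremor_extent_pct = pars$tremor_extent_pct,
      recording = list(rec)
    )
  }
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(spec$n_speakers_per_class),
                   function(i) draw_one("normal", i)),
    purrr::map_dfr(seq_len(spec$n_speakers_per_class),
                   function(i) draw_one("pathological", i))
  )
}

#' Write a corpus to WAV files plus a manifest CSV
#'
#' @param corpus A corpus tibble from [make_corpus()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map2_chr(corpus$recording, corpus$recording_id, function(rec, rid) {
    p <- file.path(dir, paste0(rid, ".wav"))
    write_wav(rec$samples, rec$fs, p)
    p
  })
  manifest <- dplyr::mutate(
    dplyr::select(corpus, -"recording"), path = paths, .before = 1)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
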