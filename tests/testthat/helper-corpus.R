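# Shared synthetic fixtures, built once per test run and cached.

.ms_cache <- new.env(parent = emptyenv())

ms_cached <- function(key, expr) {
  if (is.null(.ms_cache[[key]])) assign(key, force(expr), envir = .ms_cache)
  .ms_cache[[key]]
}

# The strong-effect study corpus: 10 speakers per class, 3 s recordings.
strong_corpus <- function() {
  ms_cached("strong_corpus",
            make_corpus(corpus_spec(n_speakers_per_class = 10, duration_s = 3,
                                    effect = "strong", seed = 101)))
}

strong_metrics <- function() {
  ms_cached("strong_metrics", corpus_metrics(strong_corpus()))
}

strong_metrics_fullrange <- function() {
  ms_cached("strong_metrics_fullrange",
            corpus_metrics(strong_corpus(), tuned = NULL))
}

strong_plan <- function() {
  ms_cached("strong_plan", assign_speaker_folds(strong_corpus(), k = 7, seed = 11))
}

# Small quick corpus for structural tests.
small_corpus <- function() {
  ms_cached("small_corpus",
            make_corpus(corpus_spec(n_speakers_per_class = 4, duration_s = 1,
                                    effect = "strong", seed = 7)))
}

small_metrics <- function() {
  ms_cached("small_metrics", corpus_metrics(small_corpus()))
}

small_plan <- function() {
  ms_cached("small_plan", assign_speaker_folds(small_corpus(), k = 3, seed = 2))
}

# Write a stereo 16-bit WAV (the package writer is mono-only by design).
write_stereo_wav <- function(left, right, fs, path) {
  q <- function(x) as.integer(pmax(-32768, pmin(32767, round(x * 32767))))
  inter <- as.vector(rbind(q(left), q(right)))
  n_bytes <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  invisible(path)
}
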