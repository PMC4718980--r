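# Recording container, loading/resampling, normalization and framing.

#' Construct a voice recording object
#'
#' A `voice_rec` wraps a numeric sample vector together with its sampling rate
#' and corpus metadata (speaker id, class label, provenance path).
#'
#' @param samples Numeric vector of finite samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param speaker_id Opaque speaker identifier.
#' @param label One of `"normal"`, `"pathological"`, `"unknown"`.
#' @param source_path Provenance string (file of origin, or a synthesis tag).
#' @return An object of class `voice_rec`.
#' @export
recording <- function(samples, fs, speaker_id = "unknown", label = "unknown",
                      source_path = NA_character_) {
  if (!is.numeric(samples) || length(samples) == 0 || !all(is.finite(samples))) {
    ms_abort("recording samples must be a non-empty finite numeric vector", "format")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    ms_abort("fs must be a positive scalar", "format")
  }
  label <- match.arg(label, ms_labels)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         speaker_id = as.character(speaker_id), label = label,
         source_path = as.character(source_path)),
    class = "voice_rec"
  )
}

#' @export
print.voice_rec <- function(x, ...) {
  cat(sprintf("<voice_rec> %.3f s @ %g Hz | speaker %s | %s\n",
              length(x$samples) / x$fs, x$fs, x$speaker_id, x$label))
  invisible(x)
}

#' Load a mono WAV recording, resampling to a target rate
#'
#' Reads a mono PCM WAV file, converts it to floating point in `[-1, 1]` and,
#' when the file rate differs from `target_fs`, resamples it with a polyphase
#' FIR filter ([signal::resample()]).
#'
#' @param path Path to a mono WAV file.
#' @param target_fs Target sampling rate in Hz (default 25000, the rate the
#'   metric defaults were derived at).
#' @param speaker_id,label Metadata attached to the returned recording.
#' @return A [recording()] at `target_fs`.
#' @export
load_recording <- function(path, target_fs = 25000, speaker_id = "unknown",
                           label = "unknown") {
  wav <- read_wav(path)
  if (wav$n_channels != 1) {
    ms_abort(paste0("expected a mono file, got ", wav$n_channels,
                    " channels: ", path), "channel")
  }
  x <- wav$samples
  if (length(x) == 0) ms_abort(paste0("empty WAV file: ", path), "format")
  if (wav$fs != target_fs) {
    g <- gcd_int(round(target_fs), round(wav$fs))
    x <- as.numeric(signal::resample(x, round(target_fs) / g, round(wav$fs) / g))
    n_out <- round(length(wav$samples) * target_fs / wav$fs)
    x <- x[seq_len(min(n_out, length(x)))]
  }
  x <- pmax(-1, pmin(1, x))
  recording(x, target_fs, speaker_id = speaker_id, label = label,
            source_path = path)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Peak-normalize a recording
#'
#' Scales the waveform so its maximum absolute sample equals 1. Normalization
#' is a pure gain change; all level-ratio metrics downstream are invariant to
#' the pre-normalization gain.
#'
#' @param rec A [recording()].
#' @return The normalized recording.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "voice_rec"))
  peak <- max(abs(rec$samples))
  if (peak == 0) {
    ms_abort("cannot normalize an all-zero signal", "degenerate")
  }
  rec$samples <- rec$samples / peak
  rec
}

#' Segment a recording into fixed-length frames
#'
#' Cuts the signal into frames of `frame_length_ms` milliseconds advanced by
#' `hop_ms`; a trailing partial frame is discarded. The default hop equals the
#' frame length (non-overlapping frames).
#'
#' @param rec A [recording()].
#' @param frame_length_ms Frame length in milliseconds (>= 1).
#' @param hop_ms Hop between frame starts in milliseconds (default:
#'   `frame_length_ms`).
#' @return A `frame_set`: a list with `frames` (matrix, one column per frame),
#'   `frame_length_ms`, `hop_ms`, `fs`, and the parent metadata.
#' @export
frame_signal <- function(rec, frame_length_ms, hop_ms = frame_length_ms) {
  stopifnot(inherits(rec, "voice_rec"))
  if (frame_length_ms < 1 || hop_ms < 1) {
    ms_abort("frame_length_ms and hop_ms must be >= 1 ms", "format")
  }
  frame_len <- round(frame_length_ms * rec$fs / 1000)
  hop <- round(hop_ms * rec$fs / 1000)
  n <- length(rec$samples)
  if (n < frame_len) {
    ms_abort(sprintf("signal (%d samples) shorter than one %d-sample frame",
                     n, frame_len), "too_short")
  }
  n_frames <- floor((n - frame_len) / hop) + 1
  starts <- (seq_len(n_frames) - 1) * hop + 1
  idx <- outer(0:(frame_len - 1), starts, "+")
  structure(
    list(frames = matrix(rec$samples[idx], nrow = frame_len),
         frame_length_ms = frame_length_ms, hop_ms = hop_ms, fs = rec$fs,
         speaker_id = rec$speaker_id, label = rec$label,
         source_path = rec$source_path),
    class = "frame_set"
  )
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames of %g ms (hop %g ms) @ %g Hz\n",
              ncol(x$frames), x$frame_length_ms, x$hop_ms, x$fs))
  invisible(x)
}

#' Read a corpus manifest CSV
#'
#' A manifest lists one recording per row with columns `path`, `speaker_id`
#' and `label` (header required; extra columns are kept). Labels must be
#' `normal` or `pathological`.
#'
#' @param path Manifest CSV path.
#' @return A tibble with at least `path`, `speaker_id`, `label`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) ms_abort(paste0("manifest not found: ", path), "format")
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("path", "speaker_id", "label")
  if (!all(req %in% names(df))) {
    ms_abort(paste0("manifest must have columns: ", paste(req, collapse = ", ")),
             "format")
  }
  if (!all(df$label %in% c("normal", "pathological"))) {
    ms_abort("manifest labels must be 'normal' or 'pathological'", "format")
  }
  tibble::as_tibble(df)
}

#' Load every recording listed in a manifest
#'
#' @param manifest A manifest tibble from [read_manifest()] or a path to one.
#' @param target_fs Sampling rate all recordings are resampled to.
#' @return A corpus tibble: `speaker_id`, `recording_id`, `label` and a
#'   `recording` list-column of [recording()] objects.
#' @export
load_corpus <- function(manifest, target_fs = 25000) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  recs <- purrr::pmap(
    list(manifest$path, manifest$speaker_id, manifest$label),
    function(p, s, l) load_recording(p, target_fs, speaker_id = s, label = l)
  )
  tibble::tibble(
    speaker_id = as.character(manifest$speaker_id),
    recording_id = if ("recording_id" %in% names(manifest)) {
      as.character(manifest$recording_id)
    } else {
      tools::file_path_sans_ext(basename(manifest$path))
    },
    label = manifest$label,
    recording = recs
  )
}
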