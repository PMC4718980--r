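# The six scalar modulation-spectrum metrics: MSH, CIL, RALA, MSP25/75/95.

metric_names <- c("msh", "cil", "rala", "msp25", "msp75", "msp95")

#' Modulation spectrum homogeneity (MSH)
#'
#' Sums, over every cell of the dB modulus matrix, the absolute difference
#' between the cell and the mean of its N x N neighbourhood. Larger values
#' mean a less homogeneous spectrum; a constant matrix scores exactly 0.
#'
#' For even N the window anchored at cell (i, j) spans rows
#' `i - N/2 + 1 .. i + N/2` (and likewise columns), so the anchor sits just
#' above-left of the window centre; the asymmetry is what makes even masks
#' sensitive to local contrast. Windows are truncated at the matrix borders
#' and the mean taken over the in-matrix cells only.
#'
#' @param ms_db Numeric matrix of dB levels (see [modulus_db()]).
#' @param mask_n Mask side length N (>= 2; matrix must be at least N in each
#'   dimension).
#' @return The homogeneity sum (dB-difference units).
#' @export
msh <- function(ms_db, mask_n) {
  ms_db <- as.matrix(ms_db)
  if (mask_n < 2) ms_abort("mask_n must be >= 2", "precondition")
  if (nrow(ms_db) < mask_n || ncol(ms_db) < mask_n) {
    ms_abort(sprintf("matrix (%d x %d) smaller than the %d x %d mask",
                     nrow(ms_db), ncol(ms_db), mask_n, mask_n), "size")
  }
  nr <- nrow(ms_db); nc <- ncol(ms_db)
  lo <- -(ceiling(mask_n / 2) - 1L)  # window offset range [lo, hi]
  hi <- floor(mask_n / 2)

  # Integral image for O(1) truncated-window sums.
  S <- matrix(0, nr + 1, nc + 1)
  S[-1, -1] <- apply(apply(ms_db, 2, cumsum), 1, cumsum) |> t()

  r1 <- pmax(seq_len(nr) + lo, 1L); r2 <- pmin(seq_len(nr) + hi, nr)
  c1 <- pmax(seq_len(nc) + lo, 1L); c2 <- pmin(seq_len(nc) + hi, nc)
  sums <- S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sum(abs(ms_db - sums / counts))
}

#' Cumulative intersection level (CIL)
#'
#' The level at which the increasing and decreasing cumulative histogram
#' curves of the dB modulus intersect — the median of all dB cells, computed
#' directly as such.
#'
#' @param ms_db Numeric matrix of dB levels.
#' @return The median level in dB.
#' @export
cil <- function(ms_db) {
  if (length(ms_db) == 0) ms_abort("empty matrix", "size")
  median(as.numeric(ms_db))
}

#' Ratio of points above the linear average (RALA)
#'
#' Partitions the cells of the linear-unit modulus matrix against its mean:
#' `na` cells at or above the mean, `nb` below. The ratio `na / nb` grows when
#' spectral energy disperses away from the 0 Hz modulation band, as it does in
#' dysphonic voices.
#'
#' @param ms_linear Non-negative numeric matrix of modulus values.
#' @return An object of class `rala_breakdown`: list with `ratio`, `na`, `nb`,
#'   `nt`, `mean_modulus`.
#' @export
rala <- function(ms_linear) {
  x <- as.numeric(ms_linear)
  if (length(x) == 0) ms_abort("empty matrix", "size")
  m <- mean(x)
  na <- sum(x >= m)
  nb <- sum(x < m)
  if (nb == 0) {
    ms_abort("degenerate spectrum: all cells equal the mean (nb = 0)",
             "degenerate")
  }
  structure(
    list(ratio = na / nb, na = na, nb = nb, nt = length(x), mean_modulus = m),
    class = "rala_breakdown"
  )
}

#' @export
print.rala_breakdown <- function(x, ...) {
  cat(sprintf("<rala> ratio %.4f (na %d / nb %d of %d cells; mean %.4g)\n",
              x$ratio, x$na, x$nb, x$nt, x$mean_modulus))
  invisible(x)
}

#' Modulation spectrum level percentile (MSP)
#'
#' The p-th percentile of all dB cells, under the linear-interpolation-
#' between-closest-ranks convention (`stats::quantile()` type 7, shared with
#' [cil()] so that `msp(x, 50) == cil(x)` exactly).
#'
#' @param ms_db Numeric matrix of dB levels.
#' @param p Percentile in (0, 100); the metric set uses 25, 75 and 95.
#' @return The level in dB.
#' @export
msp <- function(ms_db, p) {
  if (length(ms_db) == 0) ms_abort("empty matrix", "size")
  if (p <= 0 || p >= 100) ms_abort("p must be in (0, 100)", "precondition")
  unname(quantile(as.numeric(ms_db), p / 100, type = 7))
}

# Compute one metric from a modulus matrix (linear units) already restricted.
metric_from_modulus <- function(absE, metric, mask_n, floor_db) {
  switch(metric,
    rala = rala(absE)$ratio,
    msh = msh(modulus_db(absE, floor_db), mask_n),
    cil = cil(modulus_db(absE, floor_db)),
    msp25 = msp(modulus_db(absE, floor_db), 25),
    msp75 = msp(modulus_db(absE, floor_db), 75),
    msp95 = msp(modulus_db(absE, floor_db), 95),
    ms_abort(paste0("unknown metric: ", metric), "precondition")
  )
}

# Restrict a modulus matrix by index against stored axes (cheap re-restriction
# used by frame_metrics and the tuning stages).
restrict_modulus <- function(absE, fa, fm, fa_low, fa_high, fm_high) {
  rows <- which(fa >= fa_low & fa <= fa_high)
  cols <- which(abs(fm) <= fm_high | fm == 0)
  if (length(rows) == 0 || length(cols) == 0) {
    ms_abort("no band centers fall in the requested range", "empty_selection")
  }
  absE[rows, cols, drop = FALSE]
}

#' Compute all six metrics for one frame
#'
#' Computes the modulation spectrum once, then evaluates each metric on its
#' own band-restricted sub-matrix: RALA on the linear modulus, MSH/CIL/MSP on
#' the dB modulus. With `tuned = NULL` every metric uses the full acoustic and
#' modulation range.
#'
#' @param frame Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param config A [modspec_config()].
#' @param tuned A [tuned_config()] giving per-metric ranges and the MSH mask
#'   (default [tuned_defaults()]); `NULL` for full-range metrics.
#' @return A one-row tibble with columns `msh`, `cil`, `rala`, `msp25`,
#'   `msp75`, `msp95`.
#' @export
frame_metrics <- function(frame, fs, config = modspec_config(),
                          tuned = tuned_defaults()) {
  if (all(frame == 0)) {
    ms_abort("all-zero frame yields a degenerate spectrum", "degenerate")
  }
  ms <- compute_modspec(frame, fs, config)
  absE <- Mod(ms$E)
  mask_n <- if (is.null(tuned)) 6L else tuned$msh_mask_n
  vals <- lapply(metric_names, function(mname) {
    sub <- if (is.null(tuned)) {
      absE
    } else {
      r <- tuned$ranges[tuned$ranges$metric == mname, ]
      restrict_modulus(absE, ms$fa_centers, ms$fm_centers,
                       r$fa_low, r$fa_high, r$fm_high)
    }
    tryCatch(
      metric_from_modulus(sub, mname, mask_n, config$floor_db),
      msvoice_error = function(e) {
        ms_abort(paste0("metric '", mname, "': ", conditionMessage(e)),
                 "degenerate")
      }
    )
  })
  names(vals) <- metric_names
  tibble::as_tibble(vals)
}

#' Per-frame metric table for a corpus
#'
#' Normalizes each recording, segments it into frames of the tuned frame
#' length, and computes the six metrics per frame.
#'
#' @param corpus A corpus tibble (`speaker_id`, `recording_id`, `label`,
#'   `recording` list-column) as produced by [make_corpus()] or
#'   [load_corpus()], or a manifest CSV path.
#' @param config A [modspec_config()].
#' @param tuned A [tuned_config()] (default [tuned_defaults()]); `NULL` for
#'   full-range metrics at the config frame length.
#' @param hop_ms Frame hop in ms (default: the frame length, non-overlapping).
#' @return A tibble with one row per frame: `recording_id`, `speaker_id`,
#'   `label`, `frame_index` and the six metric columns.
#' @export
corpus_metrics <- function(corpus, config = modspec_config(),
                           tuned = tuned_defaults(), hop_ms = NULL) {
  if (is.character(corpus)) corpus <- load_corpus(corpus)
  frame_ms <- if (is.null(tuned)) config$frame_length_ms else tuned$frame_length_ms
  if (is.null(hop_ms)) hop_ms <- frame_ms
  purrr::pmap_dfr(
    list(corpus$recording, corpus$recording_id, corpus$speaker_id, corpus$label),
    function(rec, rid, sid, lab) {
      fr <- frame_signal(normalize_recording(rec), frame_ms, hop_ms)
      purrr::map_dfr(seq_len(ncol(fr$frames)), function(i) {
        dplyr::bind_cols(
          tibble::tibble(recording_id = rid, speaker_id = sid, label = lab,
                         frame_index = i),
          frame_metrics(fr$frames[, i], rec$fs, config, tuned)
        )
      })
    }
  )
}
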