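# Modulation spectrum: sTFT filterbank -> subband Hilbert envelopes ->
# modulation FFT, giving a complex matrix E(f_a, f_m).

#' Modulation-spectrum configuration
#'
#' Defaults follow the basic configuration the metrics were developed with:
#' 128 uniform acoustic bands, 1024 modulation bands (two-sided), Hilbert
#' envelope demodulation, 180 ms analysis frames. The sTFT filterbank uses a
#' Hann window of `2 * (n_acoustic_bands - 1)` samples so the one-sided bin
#' count equals the acoustic band count, and a hop of `stft_hop_samples`
#' samples; the envelope sampling rate `fs / stft_hop_samples` must exceed
#' twice the highest modulation frequency of interest (781.25 Hz at the
#' defaults for fs = 25 kHz, i.e. modulation content up to ~390 Hz).
#'
#' @param n_acoustic_bands Number of uniform acoustic bands (>= 2).
#' @param n_mod_bands Two-sided modulation FFT length (>= 2).
#' @param stft_hop_samples sTFT hop in samples.
#' @param frame_length_ms Default analysis frame length in milliseconds.
#' @param demodulation Only `"hilbert_envelope"` is supported: the subband
#'   envelope is the magnitude of the complex sTFT coefficient sequence, the
#'   standard incoherent realization of Hilbert-envelope demodulation for
#'   narrow bands.
#' @param floor_db Level floor applied when converting modulus to dB.
#' @return An object of class `ms_config`.
#' @export
modspec_config <- function(n_acoustic_bands = 128, n_mod_bands = 1024,
                           stft_hop_samples = 32, frame_length_ms = 180,
                           demodulation = "hilbert_envelope", floor_db = -120) {
  demodulation <- match.arg(demodulation, "hilbert_envelope")
  if (n_acoustic_bands < 2 || n_mod_bands < 2) {
    ms_abort("need at least 2 acoustic and 2 modulation bands", "format")
  }
  if (floor_db >= 0) ms_abort("floor_db must be negative", "format")
  structure(
    list(n_acoustic_bands = as.integer(n_acoustic_bands),
         n_mod_bands = as.integer(n_mod_bands),
         stft_hop_samples = as.integer(stft_hop_samples),
         frame_length_ms = frame_length_ms,
         demodulation = demodulation,
         floor_db = floor_db),
    class = "ms_config"
  )
}

#' Compute the modulation spectrum of one frame
#'
#' The frame is analyzed with an sTFT filterbank (Hann window of
#' `2*(n_acoustic_bands-1)` samples, hop `stft_hop_samples`); the magnitude of
#' each band's coefficient sequence is its Hilbert envelope; each envelope is
#' transformed with an `n_mod_bands`-point FFT to give the modulation
#' dimension. The 0 Hz modulation bin is computed exactly as the envelope sum,
#' and the remaining bins from the demeaned, zero-padded envelope, so the
#' central modulation band carries the full envelope mean energy without
#' leaking its spectral skirt into neighbouring bins (the envelope sequence is
#' much shorter than the FFT length at the default hop).
#'
#' The modulation axis is two-sided and ordered negative to positive with 0 at
#' the centre; for an even FFT length the single -Nyquist bin is unpaired.
#' `|E(f_a, f_m)| == |E(f_a, -f_m)|` for all paired bins because envelopes are
#' real.
#'
#' @param frame Numeric sample vector (one analysis frame).
#' @param fs Sampling rate in Hz.
#' @param config A [modspec_config()].
#' @return An object of class `ms_modspec` with elements `E` (complex matrix,
#'   acoustic bands x modulation bands), `fa_centers`, `fm_centers`, `fs`,
#'   `env_fs` and `config`.
#' @export
compute_modspec <- function(frame, fs, config = modspec_config()) {
  stopifnot(is.numeric(frame), fs > 0, inherits(config, "ms_config"))
  nac <- config$n_acoustic_bands
  nmod <- config$n_mod_bands
  hop <- config$stft_hop_samples
  win <- 2L * (nac - 1L)
  if (length(frame) < win) {
    ms_abort(sprintf("frame (%d samples) shorter than the %d-sample sTFT window",
                     length(frame), win), "too_short")
  }

  starts <- seq(1L, length(frame) - win + 1L, by = hop)
  idx <- outer(0:(win - 1L), starts, "+")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))
  X <- mvfft(matrix(frame[idx], nrow = win) * w)
  env <- Mod(X[seq_len(nac), , drop = FALSE])   # acoustic bands x time

  n_env <- ncol(env)
  if (n_env > nmod) env <- env[, seq_len(nmod), drop = FALSE]
  n_env <- ncol(env)
  mu <- rowMeans(env)
  padded <- matrix(0, nrow = nmod, ncol = nac)
  padded[seq_len(n_env), ] <- t(env - mu)
  E <- mvfft(padded)                            # modulation bins x acoustic bands
  E[1, ] <- complex(real = mu * n_env)          # exact 0 Hz (envelope sum)
  E <- t(E)

  # Reorder columns to a symmetric -/0/+ modulation axis.
  half <- nmod %/% 2L
  ord <- c((half + 1L):nmod, 1L:half)
  E <- E[, ord, drop = FALSE]
  env_fs <- fs / hop
  fm <- ((-half):(half - 1L)) * env_fs / nmod
  fa <- (0:(nac - 1L)) * fs / win

  structure(
    list(E = E, fa_centers = fa, fm_centers = fm, fs = fs, env_fs = env_fs,
         config = config),
    class = "ms_modspec"
  )
}

#' Restrict a modulation spectrum to frequency ranges
#'
#' Keeps acoustic bands with `fa_low <= f_a <= fa_high` and modulation bands
#' with `|f_m| <= fm_high`. Both modulation signs are retained and the 0 Hz
#' column is always kept.
#'
#' @param ms An `ms_modspec`.
#' @param fa_low,fa_high Acoustic range in Hz (`fa_low < fa_high`).
#' @param fm_high Upper modulation frequency in Hz (> 0).
#' @return The restricted `ms_modspec`.
#' @export
restrict_modspec <- function(ms, fa_low, fa_high, fm_high) {
  stopifnot(inherits(ms, "ms_modspec"))
  if (!(fa_low < fa_high)) ms_abort("fa_low must be < fa_high", "precondition")
  if (!(fm_high > 0)) ms_abort("fm_high must be > 0", "precondition")
  rows <- which(ms$fa_centers >= fa_low & ms$fa_centers <= fa_high)
  cols <- which(abs(ms$fm_centers) <= fm_high | ms$fm_centers == 0)
  if (length(rows) == 0 || length(cols) == 0) {
    ms_abort("no band centers fall in the requested range", "empty_selection")
  }
  ms$E <- ms$E[rows, cols, drop = FALSE]
  ms$fa_centers <- ms$fa_centers[rows]
  ms$fm_centers <- ms$fm_centers[cols]
  ms
}

#' Modulation-spectrum modulus in dB
#'
#' `20 * log10(|E|)` with levels clamped below at `floor_db`; zero cells map
#' to the floor. Total on any input.
#'
#' @param ms An `ms_modspec`, or a non-negative numeric matrix of modulus
#'   values.
#' @param floor_db Negative dB floor (default -120).
#' @return A numeric matrix of dB levels.
#' @export
modulus_db <- function(ms, floor_db = -120) {
  if (floor_db >= 0) ms_abort("floor_db must be negative", "precondition")
  A <- if (inherits(ms, "ms_modspec")) Mod(ms$E) else as.matrix(ms)
  out <- matrix(floor_db, nrow(A), ncol(A))
  pos <- A > 0
  out[pos] <- pmax(20 * log10(A[pos]), floor_db)
  dimnames(out) <- dimnames(A)
  out
}

#' @export
print.ms_modspec <- function(x, ...) {
  cat(sprintf(
    "<ms_modspec> %d acoustic x %d modulation bands | fa %.0f..%.0f Hz | fm %+.1f..%+.1f Hz\n",
    nrow(x$E), ncol(x$E), min(x$fa_centers), max(x$fa_centers),
    min(x$fm_centers), max(x$fm_centers)))
  invisible(x)
}

#' Tidy a modulation spectrum into a long tibble
#'
#' @param x An `ms_modspec`.
#' @param ... Unused.
#' @return A tibble with columns `fa`, `fm`, `modulus`, `level_db`.
#' @export
tidy.ms_modspec <- function(x, ...) {
  A <- Mod(x$E)
  tibble::tibble(
    fa = rep(x$fa_centers, times = ncol(A)),
    fm = rep(x$fm_centers, each = nrow(A)),
    modulus = as.vector(A),
    level_db = as.vector(modulus_db(A, x$config$floor_db))
  )
}

#' Heatmap of a modulation spectrum
#'
#' @param object An `ms_modspec`.
#' @param fm_limit Optional absolute modulation-frequency display limit (Hz).
#' @param ... Unused.
#' @return A ggplot object (dB modulus over the modulation/acoustic plane).
#' @export
autoplot.ms_modspec <- function(object, fm_limit = NULL, ...) {
  df <- tidy.ms_modspec(object)
  if (!is.null(fm_limit)) df <- dplyr::filter(df, abs(.data$fm) <= fm_limit)
  ggplot2::ggplot(df, ggplot2::aes(.data$fm, .data$fa, fill = .data$level_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|E| (dB)") +
    ggplot2::labs(x = "modulation frequency (Hz)", y = "acoustic frequency (Hz)") +
    ggplot2::theme_minimal()
}
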