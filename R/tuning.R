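# Four-stage coordinate-wise tuning: frame length -> MSH mask -> modulation
# upper limit -> acoustic margins; plus cross-corpus consensus and the shipped
# tuned defaults.

#' Tuned metric configuration
#'
#' Bundles the analysis frame length, the MSH mask size, and per-metric
#' modulation/acoustic restriction ranges.
#'
#' @param frame_length_ms Analysis frame length in ms.
#' @param msh_mask_n MSH mask side length.
#' @param ranges A tibble with columns `metric`, `fm_high`, `fa_low`,
#'   `fa_high` covering all six metrics.
#' @return An object of class `tuned_config`.
#' @export
tuned_config <- function(frame_length_ms, msh_mask_n, ranges) {
  stopifnot(all(c("metric", "fm_high", "fa_low", "fa_high") %in% names(ranges)))
  if (!setequal(ranges$metric, metric_names)) {
    ms_abort("ranges must cover exactly the six metrics", "precondition")
  }
  if (any(ranges$fa_low >= ranges$fa_high) || any(ranges$fm_high <= 0)) {
    ms_abort("invalid per-metric ranges", "precondition")
  }
  structure(
    list(frame_length_ms = frame_length_ms, msh_mask_n = as.integer(msh_mask_n),
         ranges = tibble::as_tibble(ranges)),
    class = "tuned_config"
  )
}

#' @export
print.tuned_config <- function(x, ...) {
  cat(sprintf("<tuned_config> frame %g ms, MSH mask %d x %d\n",
              x$frame_length_ms, x$msh_mask_n, x$msh_mask_n))
  print(x$ranges)
  invisible(x)
}

#' Shipped tuned defaults
#'
#' The configuration selected by the published tuning study: 180 ms frames,
#' 6 x 6 MSH mask, and per-metric modulation upper limits / acoustic ranges
#' MSH (80 Hz, 200-9000 Hz), CIL (80 Hz, 0-2000 Hz), RALA (200 Hz,
#' 800-6000 Hz), MSP25 (80 Hz, 0-1800 Hz), MSP75 (200 Hz, 0-2000 Hz),
#' MSP95 (200 Hz, 0-9000 Hz).
#'
#' @return A [tuned_config()].
#' @export
tuned_defaults <- function() {
  tuned_config(
    frame_length_ms = 180, msh_mask_n = 6,
    ranges = tibble::tibble(
      metric  = c("msh", "cil", "rala", "msp25", "msp75", "msp95"),
      fm_high = c(80, 80, 200, 80, 200, 200),
      fa_low  = c(200, 0, 800, 0, 0, 0),
      fa_high = c(9000, 2000, 6000, 1800, 2000, 9000)
    )
  )
}

#' Default tuning grids
#'
#' The candidate grids of the four tuning stages: frame lengths 20-200 ms in
#' 20 ms steps; MSH mask sizes 2-12; modulation upper limits 20-220 Hz in
#' 20 Hz steps; acoustic lower limits 0-1000 Hz in 100 Hz steps and upper
#' limits spanning 1.2-12 kHz (300 Hz steps at low frequencies, wider steps
#' above, including every bound the selected ranges use).
#'
#' @return A named list: `frame_length`, `mask_size`, `mod_upper`,
#'   `acoustic_low`, `acoustic_high`, and `acoustic_range` (a tibble crossing
#'   the lower and upper candidates with `fa_low < fa_high`).
#' @export
default_grids <- function() {
  lows <- seq(0, 1000, by = 100)
  highs <- c(1200, 1500, 1800, 2000, 2500, 3000, 4000, 5000, 6000, 8000, 9000, 12000)
  list(
    frame_length = seq(20, 200, by = 20),
    mask_size = 2:12,
    mod_upper = seq(20, 220, by = 20),
    acoustic_low = lows,
    acoustic_high = highs,
    acoustic_range = dplyr::filter(
      tidyr::crossing(fa_low = lows, fa_high = highs), .data$fa_low < .data$fa_high)
  )
}

# Replace one metric's restriction inside a tuned config.
set_metric_range <- function(tuned, metric, fm_high = NULL, fa_low = NULL,
                             fa_high = NULL) {
  i <- which(tuned$ranges$metric == metric)
  if (!is.null(fm_high)) tuned$ranges$fm_high[i] <- fm_high
  if (!is.null(fa_low)) tuned$ranges$fa_low[i] <- fa_low
  if (!is.null(fa_high)) tuned$ranges$fa_high[i] <- fa_high
  tuned
}

# Cache of per-frame modulus matrices for one corpus at one frame length, so
# range/mask stages re-restrict instead of recomputing spectra.
corpus_modulus_cache <- function(corpus, frame_ms, config) {
  purrr::pmap_dfr(
    list(corpus$recording, corpus$recording_id, corpus$speaker_id, corpus$label),
    function(rec, rid, sid, lab) {
      fr <- frame_signal(normalize_recording(rec), frame_ms)
      purrr::map_dfr(seq_len(ncol(fr$frames)), function(i) {
        m <- compute_modspec(fr$frames[, i], rec$fs, config)
        tibble::tibble(recording_id = rid, speaker_id = sid, label = lab,
                       frame_index = i, absE = list(Mod(m$E)),
                       fa = list(m$fa_centers), fm = list(m$fm_centers))
      })
    }
  )
}

cache_metric_scores <- function(cache, metric, fm_high, fa_low, fa_high,
                                mask_n, floor_db) {
  score <- purrr::pmap_dbl(list(cache$absE, cache$fa, cache$fm),
    function(A, fa, fm) {
      metric_from_modulus(restrict_modulus(A, fa, fm, fa_low, fa_high, fm_high),
                          metric, mask_n, floor_db)
    })
  dplyr::mutate(dplyr::select(cache, "recording_id", "speaker_id", "label",
                              "frame_index"), score = score)
}

#' Run one tuning stage over a candidate grid
#'
#' Varies one degree of freedom (frame length, MSH mask size, modulation upper
#' limit, or the acoustic range) while the others stay fixed at the values in
#' `fixed`, and records the cross-validated efficiency of `metric` at every
#' candidate. For the three stages with a fixed frame length the modulation
#' spectra are computed once and re-restricted per candidate.
#'
#' @param corpus A corpus tibble ([make_corpus()] / [load_corpus()]).
#' @param metric Metric name (`mask_size` stage applies to `"msh"` only).
#' @param stage One of `"frame_length"`, `"mask_size"`, `"mod_upper"`,
#'   `"acoustic_range"`.
#' @param grid Candidate values: a numeric vector for the scalar stages, or a
#'   tibble with `fa_low`, `fa_high` for `"acoustic_range"`. Defaults to the
#'   stage's [default_grids()] entry.
#' @param fixed A [tuned_config()] supplying the non-varied variables.
#' @param plan A [assign_speaker_folds()] plan for the corpus speakers.
#' @param level Decision level, see [cv_single_metric_efficiency()].
#' @param config A [modspec_config()].
#' @return An `ms_stage` tibble: one row per candidate with `mean_efficiency`
#'   and `sd` (scalar stages have a `value` column; the acoustic stage keeps
#'   `fa_low`/`fa_high`).
#' @export
run_stage <- function(corpus, metric,
                      stage = c("frame_length", "mask_size", "mod_upper",
                                "acoustic_range"),
                      grid = NULL, fixed = tuned_defaults(), plan,
                      level = "frame", config = modspec_config()) {
  stage <- match.arg(stage)
  if (is.null(grid)) {
    grid <- default_grids()[[if (stage == "acoustic_range") "acoustic_range" else
      switch(stage, frame_length = "frame_length", mask_size = "mask_size",
             mod_upper = "mod_upper")]]
  }
  if (stage == "mask_size" && metric != "msh") {
    ms_abort("the mask_size stage only applies to msh", "precondition")
  }
  r <- fixed$ranges[fixed$ranges$metric == metric, ]

  eval_scores <- function(scores) {
    glance.ms_detection(cv_single_metric_efficiency(scores, "score", plan, level))
  }

  if (stage == "frame_length") {
    if (length(grid) == 0) ms_abort("empty grid", "size")
    res <- purrr::map_dfr(grid, function(v) {
      cache <- corpus_modulus_cache(corpus, v, config)
      sc <- cache_metric_scores(cache, metric, r$fm_high, r$fa_low, r$fa_high,
                                fixed$msh_mask_n, config$floor_db)
      g <- eval_scores(sc)
      tibble::tibble(value = v, mean_efficiency = g$mean_efficiency, sd = g$sd)
    })
  } else {
    cache <- corpus_modulus_cache(corpus, fixed$frame_length_ms, config)
    if (stage == "acoustic_range") {
      if (nrow(grid) == 0) ms_abort("empty grid", "size")
      res <- purrr::pmap_dfr(grid, function(fa_low, fa_high) {
        sc <- cache_metric_scores(cache, metric, r$fm_high, fa_low, fa_high,
                                  fixed$msh_mask_n, config$floor_db)
        g <- eval_scores(sc)
        tibble::tibble(fa_low = fa_low, fa_high = fa_high,
                       mean_efficiency = g$mean_efficiency, sd = g$sd)
      })
    } else {
      if (length(grid) == 0) ms_abort("empty grid", "size")
      res <- purrr::map_dfr(grid, function(v) {
        sc <- if (stage == "mod_upper") {
          cache_metric_scores(cache, metric, v, r$fa_low, r$fa_high,
                              fixed$msh_mask_n, config$floor_db)
        } else { # mask_size
          cache_metric_scores(cache, metric, r$fm_high, r$fa_low, r$fa_high,
                              v, config$floor_db)
        }
        g <- eval_scores(sc)
        tibble::tibble(value = v, mean_efficiency = g$mean_efficiency, sd = g$sd)
      })
    }
  }
  structure(res, class = c("ms_stage", class(res)), stage = stage,
            metric = metric, level = level)
}

#' Select the best grid value from a stage result
#'
#' Among candidates whose mean efficiency lies within `tolerance` of the
#' stage maximum, returns the preferred extreme — e.g. the shortest frame
#' within 1 % of the best, favouring the stationarity assumption.
#'
#' @param result An `ms_stage` (or tibble with `value` or `fa_low`/`fa_high`
#'   plus `mean_efficiency`).
#' @param tolerance Absolute efficiency tolerance (default 0.01).
#' @param prefer `"smallest"` or `"largest"` (acoustic ranges are ordered
#'   lexicographically by `(fa_low, fa_high)`).
#' @return The chosen scalar value, or a one-row tibble for acoustic ranges.
#' @export
select_best_value <- function(result, tolerance = 0.01,
                              prefer = c("smallest", "largest")) {
  prefer <- match.arg(prefer)
  if (nrow(result) == 0) ms_abort("empty stage result", "size")
  keep <- result$mean_efficiency >= max(result$mean_efficiency) - tolerance
  cand <- result[keep, ]
  if ("value" %in% names(cand)) {
    v <- sort(cand$value)
    if (prefer == "smallest") v[1] else v[length(v)]
  } else {
    cand <- dplyr::arrange(cand, .data$fa_low, .data$fa_high)
    cand[if (prefer == "smallest") 1 else nrow(cand),
         c("fa_low", "fa_high"), drop = FALSE]
  }
}

#' Cross-corpus consensus value
#'
#' Reconciles the same tuning stage run on two corpora: each corpus's
#' efficiencies are min-max normalized and the candidate maximizing the
#' worse of the two normalized efficiencies is chosen (a reproducible
#' stand-in for picking ranges that behave well in both databases), with ties
#' broken toward the preferred extreme.
#'
#' @param results_a,results_b `ms_stage` results over the same grid.
#' @param prefer Tie-break direction, as in [select_best_value()].
#' @return The chosen scalar value (or one-row tibble for acoustic ranges).
#' @export
cross_corpus_consensus <- function(results_a, results_b,
                                   prefer = c("smallest", "largest")) {
  prefer <- match.arg(prefer)
  key <- function(d) {
    if ("value" %in% names(d)) d$value else paste(d$fa_low, d$fa_high)
  }
  if (nrow(results_a) != nrow(results_b) ||
      !identical(key(results_a), key(results_b))) {
    ms_abort("stage results do not share the same grid", "grid")
  }
  norm <- function(e) if (max(e) > min(e)) (e - min(e)) / (max(e) - min(e)) else rep(1, length(e))
  score <- pmin(norm(results_a$mean_efficiency), norm(results_b$mean_efficiency))
  best <- which(score == max(score))
  if ("value" %in% names(results_a)) {
    v <- sort(results_a$value[best])
    if (prefer == "smallest") v[1] else v[length(v)]
  } else {
    cand <- dplyr::arrange(results_a[best, ], .data$fa_low, .data$fa_high)
    cand[if (prefer == "smallest") 1 else nrow(cand),
         c("fa_low", "fa_high"), drop = FALSE]
  }
}

#' Run the full four-stage tuning protocol for one metric
#'
#' Coordinate-wise optimization in the fixed stage order: frame length, then
#' MSH mask size (msh only), then the modulation upper limit, then the
#' acoustic margins; each stage runs with the previous stages' selections
#' frozen.
#'
#' @inheritParams run_stage
#' @param grids A [default_grids()]-shaped list.
#' @param start Starting [tuned_config()].
#' @param tolerance Selection tolerance, see [select_best_value()].
#' @return An `ms_tuning` list: `config` (the tuned config for `metric`) and
#'   `stages` (named list of `ms_stage` results).
#' @export
run_tuning <- function(corpus, metric, plan, grids = default_grids(),
                       start = tuned_defaults(), tolerance = 0.01,
                       level = "frame", config = modspec_config()) {
  fixed <- start
  stages <- list()

  s1 <- run_stage(corpus, metric, "frame_length", grids$frame_length, fixed,
                  plan, level, config)
  fixed$frame_length_ms <- select_best_value(s1, tolerance, "smallest")
  stages$frame_length <- s1

  if (metric == "msh") {
    s2 <- run_stage(corpus, metric, "mask_size", grids$mask_size, fixed, plan,
                    level, config)
    fixed$msh_mask_n <- as.integer(select_best_value(s2, tolerance, "smallest"))
    stages$mask_size <- s2
  }

  s3 <- run_stage(corpus, metric, "mod_upper", grids$mod_upper, fixed, plan,
                  level, config)
  fixed <- set_metric_range(fixed, metric,
                            fm_high = select_best_value(s3, tolerance, "smallest"))
  stages$mod_upper <- s3

  s4 <- run_stage(corpus, metric, "acoustic_range", grids$acoustic_range,
                  fixed, plan, level, config)
  best4 <- select_best_value(s4, tolerance, "smallest")
  fixed <- set_metric_range(fixed, metric, fa_low = best4$fa_low,
                            fa_high = best4$fa_high)
  stages$acoustic_range <- s4

  structure(list(config = fixed, stages = stages, metric = metric),
            class = "ms_tuning")
}

#' Efficiency-vs-candidate plot for a tuning stage
#'
#' @param object An `ms_stage`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_stage <- function(object, ...) {
  if (!"value" %in% names(object)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(.data$fa_high, .data$mean_efficiency,
                                           colour = factor(.data$fa_low))) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "acoustic upper limit (Hz)", y = "mean CV efficiency",
                      colour = "fa_low (Hz)") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$value, .data$mean_efficiency)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_efficiency - .data$sd,
                                      ymax = .data$mean_efficiency + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = attr(object, "stage"), y = "mean CV efficiency") +
    ggplot2::theme_minimal()
}

#' Write / read a tuned configuration as YAML
#'
#' @param tuned A [tuned_config()].
#' @param path File path.
#' @return `path` invisibly; `read_tuned_config()` returns a [tuned_config()].
#' @export
write_tuned_config <- function(tuned, path) {
  yaml::write_yaml(list(
    frame_length_ms = tuned$frame_length_ms,
    msh_mask_n = tuned$msh_mask_n,
    ranges = lapply(split(tuned$ranges, tuned$ranges$metric), function(r) {
      list(fm_high = r$fm_high, fa_low = r$fa_low, fa_high = r$fa_high)
    })
  ), path)
  invisible(path)
}

#' @rdname write_tuned_config
#' @export
read_tuned_config <- function(path) {
  y <- yaml::read_yaml(path)
  ranges <- purrr::imap_dfr(y$ranges, function(r, m) {
    tibble::tibble(metric = m, fm_high = r$fm_high, fa_low = r$fa_low,
                   fa_high = r$fa_high)
  })
  tuned_config(y$frame_length_ms, y$msh_mask_n, ranges)
}
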