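# Single-metric EER-threshold detection with speaker-grouped k-fold CV.

#' Assign speakers to cross-validation folds
#'
#' Every frame of a speaker must land in the same fold, so folds are assigned
#' at the speaker level: within each class, speakers are shuffled by the seed
#' and dealt round-robin over the k folds (class-stratified so small corpora
#' cannot produce single-class training sets).
#'
#' @param speakers A tibble with columns `speaker_id` and `label` (one row per
#'   speaker), or a corpus/metric tibble from which the distinct pairs are
#'   taken.
#' @param k Number of folds (default 7).
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `fold_plan`: tibble `speaker_id`, `label`, `fold` (0..k-1), with
#'   attributes `k` and `seed`.
#' @export
assign_speaker_folds <- function(speakers, k = 7, seed = 1) {
  spk <- dplyr::distinct(speakers, .data$speaker_id, .data$label)
  if (any(duplicated(spk$speaker_id))) {
    ms_abort("a speaker appears with more than one label", "precondition")
  }
  if (nrow(spk) < k) {
    ms_abort(sprintf("%d speakers cannot fill %d folds", nrow(spk), k), "size")
  }
  counts <- table(spk$label)
  if (any(counts < k)) {
    ms_abort(sprintf("every class needs >= k = %d speakers for stratification", k),
             "size")
  }
  plan <- withr::with_seed(seed, {
    purrr::map_dfr(split(spk, spk$label), function(d) {
      d <- d[sample.int(nrow(d)), ]
      d$fold <- (seq_len(nrow(d)) - 1L) %% as.integer(k)
      d
    })
  })
  plan <- dplyr::arrange(plan, .data$speaker_id)
  structure(plan, class = c("fold_plan", class(plan)), k = as.integer(k),
            seed = as.integer(seed))
}

#' Learn the EER operating point from labeled training scores
#'
#' Orientation is learned from the training data: the pathological class is
#' taken as the "high" class when its mean rank is at least the normal class's
#' mean rank (a rank statistic, so the learned operating point is invariant
#' under strictly monotone score transforms). Candidate thresholds are the midpoints
#' between adjacent sorted unique scores plus the two infinities; the
#' threshold minimizing `|FPR - FNR|` is chosen (ties broken toward the lower
#' threshold) and the EER reported as `(FPR + FNR) / 2` there.
#'
#' @param train A tibble with columns `score` (finite numeric) and `label`
#'   (`normal` / `pathological`).
#' @return An `eer_op`: list with `threshold` (in original score units),
#'   `eer`, `orientation` (`"pathological_high"` or `"pathological_low"`).
#' @export
eer_point <- function(train) {
  if (!all(c("normal", "pathological") %in% train$label)) {
    ms_abort("training scores must contain both classes", "class")
  }
  if (!all(is.finite(train$score))) {
    ms_abort("scores must be finite", "precondition")
  }
  sp <- train$score[train$label == "pathological"]
  sn <- train$score[train$label == "normal"]
  rk <- rank(train$score)
  orientation <- if (mean(rk[train$label == "pathological"]) >=
                     mean(rk[train$label == "normal"])) {
    "pathological_high"
  } else {
    "pathological_low"
  }
  flip <- if (orientation == "pathological_high") 1 else -1
  sp_o <- sort(flip * sp)
  sn_o <- sort(flip * sn)

  u <- sort(unique(c(sp_o, sn_o)))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  # decision: pathological iff oriented score >= threshold
  fpr <- (length(sn_o) - findInterval(cand, sn_o)) / length(sn_o)
  fnr <- findInterval(cand, sp_o) / length(sp_o)
  i <- which.min(abs(fpr - fnr))   # first minimum = lowest threshold
  structure(
    list(threshold = flip * cand[i], eer = (fpr[i] + fnr[i]) / 2,
         orientation = orientation),
    class = "eer_op"
  )
}

#' @export
print.eer_op <- function(x, ...) {
  cat(sprintf("<eer_op> threshold %.6g (%s), EER %.3f\n",
              x$threshold, x$orientation, x$eer))
  invisible(x)
}

# Oriented decision rule shared by efficiency_at and predictions: scores
# exactly at the threshold classify as pathological (sensitivity-favoring tie
# rule).
eer_classify <- function(scores, op) {
  if (op$orientation == "pathological_high") {
    ifelse(scores >= op$threshold, "pathological", "normal")
  } else {
    ifelse(scores <= op$threshold, "pathological", "normal")
  }
}

#' Classification efficiency at an operating point
#'
#' @param test A tibble with columns `score` and `label`.
#' @param op An [eer_point()] result.
#' @return Fraction of correct classifications in `[0, 1]`.
#' @export
efficiency_at <- function(test, op) {
  if (nrow(test) == 0) ms_abort("empty test set", "size")
  mean(eer_classify(test$score, op) == test$label)
}

#' Speaker-grouped cross-validated efficiency of one metric
#'
#' For each fold, the EER operating point is learned on all other folds and
#' applied to the held-out fold; no speaker ever appears on both sides of a
#' split (asserted on every run). At `level = "recording"` frame scores are
#' first averaged per recording and decisions made per recording.
#'
#' @param data A metric table from [corpus_metrics()] (or any tibble with
#'   `speaker_id`, `recording_id`, `label` and the metric column).
#' @param metric Name of the score column (one of `"msh"`, `"cil"`, `"rala"`,
#'   `"msp25"`, `"msp75"`, `"msp95"`, or any numeric column).
#' @param plan A [assign_speaker_folds()] plan covering every speaker in
#'   `data`.
#' @param level `"frame"` (default) or `"recording"`.
#' @return An `ms_detection` object; see [tidy.ms_detection()] and
#'   [glance.ms_detection()].
#' @export
cv_single_metric_efficiency <- function(data, metric, plan,
                                        level = c("frame", "recording")) {
  level <- match.arg(level)
  if (!metric %in% names(data)) {
    ms_abort(paste0("no such metric column: ", metric), "precondition")
  }
  scores <- tibble::tibble(
    speaker_id = as.character(data$speaker_id),
    recording_id = as.character(data$recording_id),
    label = data$label,
    score = data[[metric]]
  )
  if (level == "recording") {
    scores <- dplyr::summarise(
      dplyr::group_by(scores, .data$speaker_id, .data$recording_id, .data$label),
      score = mean(.data$score), .groups = "drop")
  }
  missing <- setdiff(unique(scores$speaker_id), plan$speaker_id)
  if (length(missing) > 0) {
    ms_abort(paste0("speakers absent from the fold plan: ",
                    paste(missing, collapse = ", ")), "precondition")
  }
  scores <- dplyr::left_join(scores, dplyr::select(plan, "speaker_id", "fold"),
                             by = "speaker_id")
  folds <- sort(unique(scores$fold))
  per_fold <- purrr::map_dfr(folds, function(f) {
    train <- scores[scores$fold != f, ]
    test <- scores[scores$fold == f, ]
    stopifnot(length(intersect(train$speaker_id, test$speaker_id)) == 0)
    if (length(unique(train$label)) < 2) {
      ms_abort(sprintf("training folds for fold %d contain a single class", f),
               "class")
    }
    op <- eer_point(train)
    tibble::tibble(fold = f, efficiency = efficiency_at(test, op),
                   n = nrow(test), train_eer = op$eer)
  })
  structure(
    list(per_fold = per_fold,
         mean_efficiency = mean(per_fold$efficiency),
         sd = sd(per_fold$efficiency),
         metric = metric, level = level, k = attr(plan, "k"),
         seed = attr(plan, "seed")),
    class = "ms_detection"
  )
}

#' @export
print.ms_detection <- function(x, ...) {
  cat(sprintf("<ms_detection> %s @ %s level: efficiency %.3f +- %.3f (k = %d)\n",
              x$metric, x$level, x$mean_efficiency, x$sd, x$k))
  invisible(x)
}

#' Per-fold efficiencies of a detection result
#'
#' @param x An `ms_detection`.
#' @param ... Unused.
#' @return A tibble with `fold`, `efficiency`, `n`, `train_eer`.
#' @export
tidy.ms_detection <- function(x, ...) x$per_fold

#' One-row summary of a detection result
#'
#' @param x An `ms_detection`.
#' @param ... Unused.
#' @return A tibble with `metric`, `mean_efficiency`, `sd`, `level`, `k`,
#'   `seed`.
#' @export
glance.ms_detection <- function(x, ...) {
  tibble::tibble(metric = x$metric, mean_efficiency = x$mean_efficiency,
                 sd = x$sd, level = x$level, k = x$k, seed = x$seed)
}

#' Per-fold efficiency plot
#'
#' @param object An `ms_detection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_detection <- function(object, ...) {
  df <- tidy.ms_detection(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold), .data$efficiency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_efficiency, linetype = 2) +
    ggplot2::labs(x = "fold", y = "efficiency",
                  title = sprintf("%s (%s level)", object$metric, object$level)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
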