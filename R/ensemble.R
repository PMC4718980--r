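# GMM ensemble detection over the six-metric feature vectors, and the
# feature-association diagnostics (Pearson correlation, relative mutual
# information).

#' GMM detector specification
#'
#' @param n_components Number of Gaussian components per class (the study
#'   grid spans 4-64).
#' @param seed Integer seed for the k-means initialization.
#' @param var_floor Variance floor applied to every diagonal covariance entry.
#' @return An object of class `gmm_spec`.
#' @export
gmm_spec <- function(n_components = 4, seed = 1, var_floor = 1e-6) {
  if (n_components < 1) ms_abort("n_components must be >= 1", "precondition")
  structure(list(n_components = as.integer(n_components),
                 seed = as.integer(seed), var_floor = var_floor),
            class = "gmm_spec")
}

# Diagonal-covariance GMM fitted by EM with seeded k-means initialization.
gmm_em <- function(X, G, seed, var_floor = 1e-6, max_iter = 200, tol = 1e-8) {
  n <- nrow(X); d <- ncol(X)
  if (G == 1) {
    mu <- matrix(colMeans(X), 1, d)
    v <- matrix(pmax(apply(X, 2, function(c) mean((c - mean(c))^2)), var_floor), 1, d)
    return(list(w = 1, mu = mu, var = v, loglik = sum(gmm_logdens(
      list(w = 1, mu = mu, var = v), X))))
  }
  km <- withr::with_seed(seed, kmeans(X, centers = G, nstart = 5, iter.max = 50))
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(G)))) / n
  w <- pmax(w, 1e-8); w <- w / sum(w)
  mu <- km$centers
  v <- matrix(0, G, d)
  for (g in seq_len(G)) {
    rows <- X[km$cluster == g, , drop = FALSE]
    v[g, ] <- if (nrow(rows) > 1) apply(rows, 2, function(c) mean((c - mean(c))^2)) else 1
  }
  v <- pmax(v, var_floor)

  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # E step: log responsibilities
    lp <- sapply(seq_len(G), function(g) {
      log(w[g]) + colSums(dnorm(t(X), mu[g, ], sqrt(v[g, ]), log = TRUE))
    })
    if (G == 1) lp <- matrix(lp, ncol = 1)
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(lse)
    r <- exp(lp - lse)
    # M step
    nk <- colSums(r)
    w <- pmax(nk / n, 1e-8); w <- w / sum(w)
    mu <- crossprod(r, X) / nk
    for (g in seq_len(G)) {
      diff2 <- sweep(X, 2, mu[g, ])^2
      v[g, ] <- pmax(colSums(r[, g] * diff2) / nk[g], var_floor)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(w = w, mu = mu, var = v, loglik = ll)
}

# Per-row log density of a diagonal GMM.
gmm_logdens <- function(model, X) {
  G <- length(model$w)
  lp <- sapply(seq_len(G), function(g) {
    log(model$w[g]) +
      colSums(dnorm(t(X), model$mu[g, ], sqrt(model$var[g, ]), log = TRUE))
  })
  if (G == 1) lp <- matrix(lp, ncol = 1)
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Fit a two-class GMM detector
#'
#' Standardizes the metric columns (parameters learned on the training rows
#' only) and fits one diagonal-covariance GMM per class by EM with seeded
#' k-means initialization and a variance floor. Decisions compare the class
#' log-likelihoods (equal priors).
#'
#' @param train A feature table: tibble with `label` and the metric columns.
#' @param spec A [gmm_spec()].
#' @param cols Feature column names (default: the six metrics).
#' @return An object of class `ms_gmm_detector`.
#' @export
fit_gmm_detector <- function(train, spec = gmm_spec(), cols = metric_names) {
  if (!all(cols %in% names(train))) {
    ms_abort("missing feature columns in training table", "precondition")
  }
  if (!all(c("normal", "pathological") %in% train$label)) {
    ms_abort("training table must contain both classes", "class")
  }
  X <- as.matrix(train[, cols])
  if (any(!is.finite(X))) ms_abort("non-finite feature values", "precondition")
  for (cls in c("normal", "pathological")) {
    if (sum(train$label == cls) < spec$n_components) {
      ms_abort(sprintf("class '%s' has fewer rows (%d) than components (%d)",
                       cls, sum(train$label == cls), spec$n_components), "size")
    }
  }
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  models <- lapply(c(normal = "normal", pathological = "pathological"),
    function(cls) {
      gmm_em(Z[train$label == cls, , drop = FALSE], spec$n_components,
             seed = ms_child_seed(spec$seed, if (cls == "normal") 11 else 13),
             var_floor = spec$var_floor)
    })
  structure(list(models = models, center = center, scale = scale, cols = cols,
                 spec = spec),
            class = "ms_gmm_detector")
}

#' @export
print.ms_gmm_detector <- function(x, ...) {
  cat(sprintf("<ms_gmm_detector> %d components/class, %d features\n",
              x$spec$n_components, length(x$cols)))
  invisible(x)
}

#' Predict with a GMM detector
#'
#' @param object An [fit_gmm_detector()] result.
#' @param newdata A feature table with the detector's feature columns.
#' @param type `"class"` for labels, `"score"` for the pathological-minus-
#'   normal log-likelihood difference.
#' @param ... Unused.
#' @return A character vector of labels or a numeric score vector.
#' @export
predict.ms_gmm_detector <- function(object, newdata, type = c("class", "score"),
                                    ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, object$cols])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  score <- gmm_logdens(object$models$pathological, Z) -
    gmm_logdens(object$models$normal, Z)
  if (type == "score") score else ifelse(score >= 0, "pathological", "normal")
}

#' Speaker-grouped CV efficiency of the GMM ensemble
#'
#' For each component count in the grid, runs speaker-grouped k-fold
#' cross-validation of the two-class GMM detector over the metric columns and
#' reports the mean per-fold efficiency, its SD, and a 95 % binomial
#' (normal-approximation) confidence half-width on the pooled decision count.
#'
#' @param features A feature table from [corpus_metrics()].
#' @param plan A [assign_speaker_folds()] plan.
#' @param component_grid Component counts to evaluate (default
#'   `c(4, 8, 16, 32, 64)` within the study's 4-64 span).
#' @param seed Base seed for the per-fit initializations.
#' @param cols Feature column names.
#' @return An `ms_gmm_cv` tibble: `n_components`, `mean_efficiency`, `sd`,
#'   `ci_halfwidth`, `pooled_efficiency`, `n_pooled`; per-fold detail in
#'   `attr(x, "per_fold")`.
#' @export
cv_gmm_efficiency <- function(features, plan, component_grid = c(4, 8, 16, 32, 64),
                              seed = 1, cols = metric_names) {
  features <- dplyr::left_join(features,
                               dplyr::select(plan, "speaker_id", "fold"),
                               by = "speaker_id")
  if (any(is.na(features$fold))) {
    ms_abort("speakers absent from the fold plan", "precondition")
  }
  folds <- sort(unique(features$fold))
  per_fold <- list()
  res <- purrr::map_dfr(component_grid, function(G) {
    fold_rows <- purrr::map_dfr(folds, function(f) {
      train <- features[features$fold != f, ]
      test <- features[features$fold == f, ]
      stopifnot(length(intersect(train$speaker_id, test$speaker_id)) == 0)
      det <- fit_gmm_detector(train, gmm_spec(
        G, seed = ms_child_seed(seed, 97 * G + f)), cols = cols)
      pred <- predict(det, test)
      tibble::tibble(n_components = G, fold = f,
                     efficiency = mean(pred == test$label),
                     n_correct = sum(pred == test$label), n = nrow(test))
    })
    per_fold[[as.character(G)]] <<- fold_rows
    p <- sum(fold_rows$n_correct) / sum(fold_rows$n)
    tibble::tibble(
      n_components = G,
      mean_efficiency = mean(fold_rows$efficiency),
      sd = sd(fold_rows$efficiency),
      pooled_efficiency = p,
      ci_halfwidth = 1.96 * sqrt(p * (1 - p) / sum(fold_rows$n)),
      n_pooled = sum(fold_rows$n)
    )
  })
  structure(res, class = c("ms_gmm_cv", class(res)),
            per_fold = dplyr::bind_rows(per_fold), seed = seed,
            k = attr(plan, "k"))
}

#' Pairwise Pearson correlation of the metric columns
#'
#' @param features A feature table.
#' @param cols Feature column names (default: the six metrics).
#' @return A list with `pearson` (6 x 6 correlation matrix) and `p_values`
#'   (two-sided test p-values; diagonal `NA`).
#' @export
correlation_matrix <- function(features, cols = metric_names) {
  X <- as.matrix(features[, cols])
  if (nrow(X) < 3) ms_abort("need at least 3 rows", "size")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    ms_abort(paste0("zero-variance feature: ",
                    paste(cols[sds == 0], collapse = ", ")), "degenerate")
  }
  r <- cor(X)
  p <- matrix(NA_real_, ncol(X), ncol(X), dimnames = dimnames(r))
  for (i in seq_len(ncol(X) - 1)) {
    for (j in (i + 1):ncol(X)) {
      p[i, j] <- p[j, i] <- cor.test(X[, i], X[, j])$p.value
    }
  }
  list(pearson = r, p_values = p)
}

#' Relative mutual information matrix of the metric columns
#'
#' Each column is discretized into `n_bins` equal-width bins over its observed
#' range; pairwise mutual information is estimated by the plug-in histogram
#' estimator and normalized by `log2(n_bins)`, so the diagonal equals the
#' normalized marginal entropy (1 only for a bin-uniform variable).
#'
#' @param features A feature table.
#' @param n_bins Number of bins (default 32).
#' @param cols Feature column names.
#' @return The 6 x 6 symmetric relative-MI matrix.
#' @export
relative_mi_matrix <- function(features, n_bins = 32, cols = metric_names) {
  X <- as.matrix(features[, cols])
  if (n_bins < 2) ms_abort("n_bins must be >= 2", "precondition")
  if (nrow(X) < n_bins) ms_abort("need at least n_bins rows", "size")
  rngs <- apply(X, 2, range)
  if (any(rngs[1, ] == rngs[2, ])) {
    ms_abort("constant feature column", "degenerate")
  }
  B <- sapply(seq_len(ncol(X)), function(j) {
    pmin(floor((X[, j] - rngs[1, j]) / (rngs[2, j] - rngs[1, j]) * n_bins) + 1L,
         n_bins)
  })
  d <- ncol(X)
  out <- matrix(0, d, d, dimnames = list(cols, cols))
  for (i in seq_len(d)) {
    for (j in i:d) {
      joint <- table(B[, i], B[, j]) / nrow(X)
      px <- rowSums(joint); py <- colSums(joint)
      nz <- joint > 0
      mi <- sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
      out[i, j] <- out[j, i] <- mi / log2(n_bins)
    }
  }
  out
}

#' Feature-association matrices
#'
#' Convenience wrapper computing both [correlation_matrix()] and
#' [relative_mi_matrix()].
#'
#' @inheritParams relative_mi_matrix
#' @return An `ms_assoc` object: list with `pearson`, `p_values`,
#'   `relative_mi`, `n_bins`.
#' @export
association_matrices <- function(features, n_bins = 32, cols = metric_names) {
  cm <- correlation_matrix(features, cols)
  structure(
    list(pearson = cm$pearson, p_values = cm$p_values,
         relative_mi = relative_mi_matrix(features, n_bins, cols),
         n_bins = n_bins),
    class = "ms_assoc"
  )
}

#' Long-format association table
#'
#' @param x An `ms_assoc`.
#' @param ... Unused.
#' @return A tibble with `metric_a`, `metric_b`, `pearson`, `p_value`,
#'   `relative_mi`.
#' @export
tidy.ms_assoc <- function(x, ...) {
  nm <- rownames(x$pearson)
  tibble::tibble(
    metric_a = rep(nm, times = length(nm)),
    metric_b = rep(nm, each = length(nm)),
    pearson = as.vector(x$pearson),
    p_value = as.vector(x$p_values),
    relative_mi = as.vector(x$relative_mi)
  )
}

#' Association heatmaps
#'
#' @param object An `ms_assoc`.
#' @param ... Unused.
#' @return A ggplot object with correlation and relative-MI panels.
#' @export
autoplot.ms_assoc <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy.ms_assoc(object),
                            c("pearson", "relative_mi"),
                            names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$metric_a, .data$metric_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       size = 3) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
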