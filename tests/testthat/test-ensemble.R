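# GMM ensemble detector and feature-association matrices.

gauss_features <- function(n, sep, seed, d = 6) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * d), n, d), matrix(rnorm(n * d, sep), n, d))
    tbl <- tibble::as_tibble(as.data.frame(X))
    names(tbl) <- c("msh", "cil", "rala", "msp25", "msp75", "msp95")
    tbl$label <- rep(c("normal", "pathological"), each = n)
    tbl$speaker_id <- c(rep(sprintf("n%02d", 1:10), length.out = n),
                        rep(sprintf("p%02d", 1:10), length.out = n))
    tbl$recording_id <- sprintf("r%04d", seq_len(2 * n))
    tbl
  })
}

test_that("well-separated clouds are fit almost perfectly", {
  tbl <- gauss_features(150, sep = 6, seed = 1)
  det <- fit_gmm_detector(tbl, gmm_spec(4, seed = 5))
  pred <- predict(det, tbl)
  expect_gte(mean(pred == tbl$label), 0.99)
  # deterministic given seed
  det2 <- fit_gmm_detector(tbl, gmm_spec(4, seed = 5))
  expect_identical(predict(det2, tbl), pred)
  expect_identical(det$models, det2$models)
  # score orientation: pathological rows get positive log-likelihood ratio
  sc <- predict(det, tbl, type = "score")
  expect_gt(mean(sc[tbl$label == "pathological"]), 0)
  expect_lt(mean(sc[tbl$label == "normal"]), 0)
  expect_error(fit_gmm_detector(tbl[c(1:10, 151:160), ], gmm_spec(32)),
               class = "msvoice_error_size")
})

test_that("the EM engine agrees with mclust on the attained likelihood", {
  skip_if_not_installed("mclust")
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 4), 100, 2))
  })
  fit <- msvoice:::gmm_em(X, 2, seed = 1)
  mc <- mclust::densityMclust(X, G = 2, modelNames = "VVI", verbose = FALSE,
                              plot = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("label-independent features score near chance in CV", {
  effs <- vapply(1:20, function(s) {
    tbl <- gauss_features(50, sep = 0, seed = 500 + s)
    plan <- assign_speaker_folds(tbl, k = 5, seed = s)
    min(cv_gmm_efficiency(tbl, plan, component_grid = 2,
                          seed = s)$mean_efficiency)
  }, numeric(1))
  expect_gt(mean(effs), 0.4)
  expect_lt(mean(effs), 0.6)
})

test_that("cv_gmm_efficiency reports the binomial confidence half-width", {
  tbl <- gauss_features(100, sep = 3, seed = 9)
  plan <- assign_speaker_folds(tbl, k = 5, seed = 4)
  res <- cv_gmm_efficiency(tbl, plan, component_grid = c(4, 8), seed = 11)
  expect_equal(nrow(res), 2)
  expect_equal(res$n_components, c(4, 8))
  p <- res$pooled_efficiency
  expect_equal(res$ci_halfwidth, 1.96 * sqrt(p * (1 - p) / res$n_pooled))
  # closed-form instance
  expect_equal(1.96 * sqrt(0.723 * 0.277 / 200),
               1.96 * sqrt(0.723 * (1 - 0.723) / 200))
  pf <- attr(res, "per_fold")
  expect_equal(sort(unique(pf$fold)), 0:4)
})

test_that("correlation matrix matches the direct formula and is PSD", {
  tbl <- gauss_features(200, sep = 1, seed = 21)
  cm <- correlation_matrix(tbl)
  expect_equal(diag(cm$pearson), rep(1, 6), ignore_attr = TRUE)
  expect_equal(cm$pearson, t(cm$pearson))
  # textbook covariance / sigma sigma oracle for one pair
  x <- tbl$msh; y <- tbl$cil
  r_oracle <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(cm$pearson["msh", "cil"], r_oracle)
  # a feature and its negation correlate at -1
  tbl2 <- dplyr::mutate(tbl, cil = -msh)
  expect_equal(correlation_matrix(tbl2)$pearson["msh", "cil"], -1)
  expect_gt(min(eigen(cm$pearson, symmetric = TRUE)$values), -1e-10)
  expect_error(correlation_matrix(dplyr::mutate(tbl, rala = 1)),
               class = "msvoice_error_degenerate")
})

test_that("relative MI: self-information diagonal, symmetry, bounds", {
  nb <- 8
  # bin-uniform variable has normalized self-information exactly 1
  u <- rep(seq(0.5 / nb, 1 - 0.5 / nb, length.out = nb), each = 50)
  tbl <- tibble::tibble(msh = u, cil = u, rala = u + 1, msp25 = u * 2,
                        msp75 = rev(u), msp95 = u)
  mi <- relative_mi_matrix(tbl, n_bins = nb)
  expect_equal(mi["msh", "msh"], 1)
  # diagonal equals plug-in entropy / log2(n_bins) for a non-uniform column
  withr::with_seed(17, {
    x <- rbeta(600, 0.5, 3)
    tblx <- tibble::tibble(msh = x, cil = x, rala = x, msp25 = x,
                           msp75 = x, msp95 = x)
  })
  mx <- relative_mi_matrix(tblx, n_bins = nb)
  bins <- pmin(floor((x - min(x)) / (max(x) - min(x)) * nb) + 1, nb)
  expect_equal(mx["msh", "msh"], oracle_entropy_bits(bins) / log2(nb))
  expect_lt(mx["msh", "msh"], 1)
  # symmetry and the MI <= min marginal entropy bound
  tblm <- gauss_features(300, sep = 0.5, seed = 33)
  m2 <- relative_mi_matrix(tblm, n_bins = 8)
  expect_equal(m2, t(m2))
  for (i in 1:6) for (j in 1:6) {
    expect_lte(m2[i, j], min(m2[i, i], m2[j, j]) + 1e-12)
    expect_gte(m2[i, j], 0)
  }
  expect_error(relative_mi_matrix(dplyr::mutate(tblm, msh = 2), n_bins = 8),
               class = "msvoice_error_degenerate")
})

test_that("independent uniforms give near-zero off-diagonal relative MI", {
  withr::with_seed(8, {
    X <- matrix(runif(20000 * 6), ncol = 6)
  })
  tbl <- tibble::as_tibble(as.data.frame(X))
  names(tbl) <- c("msh", "cil", "rala", "msp25", "msp75", "msp95")
  mi <- relative_mi_matrix(tbl, n_bins = 16)
  off <- mi[upper.tri(mi)]
  expect_lt(max(off), 0.05)
  expect_gt(min(diag(mi)), 0.99)   # uniform marginals
})

test_that("association wrapper ties both matrices together", {
  tbl <- gauss_features(150, sep = 1, seed = 55)
  a <- association_matrices(tbl, n_bins = 8)
  expect_s3_class(a, "ms_assoc")
  expect_equal(a$pearson, correlation_matrix(tbl)$pearson)
  expect_equal(a$relative_mi, relative_mi_matrix(tbl, 8))
  td <- tidy(a)
  expect_equal(nrow(td), 36)
  expect_s3_class(ggplot2::autoplot(a), "ggplot")
})
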