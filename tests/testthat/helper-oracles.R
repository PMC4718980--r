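# Independent oracles: deliberately naive implementations used only to
# cross-check the package's vectorized code.

# Truncated-window homogeneity by explicit double loop.
oracle_msh <- function(m, n) {
  lo <- -(ceiling(n / 2) - 1)
  hi <- floor(n / 2)
  total <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      rr <- max(1, i + lo):min(nrow(m), i + hi)
      cc <- max(1, j + lo):min(ncol(m), j + hi)
      total <- total + abs(m[i, j] - mean(m[rr, cc]))
    }
  }
  total
}

# Cell-by-cell counting for the above/below-average partition.
oracle_rala <- function(m) {
  mu <- mean(m)
  na <- 0; nb <- 0
  for (v in as.numeric(m)) {
    if (v >= mu) na <- na + 1 else nb <- nb + 1
  }
  na / nb
}

# Percentile by sorting + linear interpolation between closest ranks.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100
  lo <- floor(h)
  if (lo + 1 >= length(x)) return(x[length(x)])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Exhaustive threshold sweep for the EER operating point, mirroring the
# documented orientation and tie rules with direct mean() comparisons.
oracle_eer <- function(scores, labels) {
  sp <- scores[labels == "pathological"]
  sn <- scores[labels == "normal"]
  rk <- rank(scores)
  flip <- if (mean(rk[labels == "pathological"]) >= mean(rk[labels == "normal"])) 1 else -1
  s <- flip * scores
  u <- sort(unique(s))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    fpr <- mean(flip * sn >= t)
    fnr <- mean(flip * sp < t)
    if (is.null(best) || abs(fpr - fnr) < best$gap - 1e-15) {
      best <- list(gap = abs(fpr - fnr), eer = (fpr + fnr) / 2,
                   threshold = flip * t)
    }
  }
  best
}

# Plug-in entropy (bits) of a discretized vector.
oracle_entropy_bits <- function(bins) {
  p <- table(bins) / length(bins)
  -sum(p * log2(p))
}
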