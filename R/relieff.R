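#' Relief-F feature weighting for multi-class data
#'
#' Scores each feature by contrasting its value differences between nearest
#' same-class neighbors (hits) and nearest other-class neighbors (misses).
#' For every instance R (all `m` instances are used), the `k` nearest hits
#' and, for each other class `c'`, the `k` nearest misses are found by
#' Manhattan distance on min-max-normalized features; weights are updated
#' as
#' `W[f] <- W[f] - sum_hits diff(f)/(m k)
#'        + sum_{c'} P(c')/(1 - P(class(R))) sum_miss diff(f)/(m k)`
#' with `diff(f, a, b) = |a - b| / range(f)`.  Because of the range
#' normalization the weights are invariant to affine rescaling of any
#' feature.  Zero-range (constant) features get weight 0 with a diagnostic.
#' Neighbor ties break by instance order (stable).
#'
#' @param features instances x features numeric matrix.
#' @param labels Per-instance class labels.
#' @param k_neighbors Number of nearest hits/misses per class (default 10).
#' @param n_keep Optional number of top-ranked features to report in
#'   `selected`.
#' @return A `relieff_result` list: `weights` (named per feature),
#'   `ranking` (feature indices, best first; ties by column order),
#'   `selected` (first `n_keep` of the ranking, if requested),
#'   `k_neighbors`.
#' @export
relieff_rank <- function(features, labels, k_neighbors = 10L,
                         n_keep = NULL) {
  X <- as.matrix(features)
  y <- factor(labels)
  m <- nrow(X)
  stopifnot(m == length(y), k_neighbors >= 1L)
  counts <- table(y)
  if (any(counts < k_neighbors + 1L))
    stop("need at least k_neighbors + 1 instances per class")
  rng <- apply(X, 2, function(v) diff(range(v)))
  zero <- rng <= 0
  if (any(zero))
    message("relieff_rank: ", sum(zero),
            " zero-range feature(s) received weight 0")
  rng_safe <- ifelse(zero, 1, rng)
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng_safe, "/")
  Xn[, zero] <- 0
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  prior <- counts / m
  k <- k_neighbors
  W <- numeric(ncol(X))
  classes <- levels(y)
  for (i in seq_len(m)) {
    ci <- as.character(y[i])
    for (cl in classes) {
      pool <- which(y == cl & seq_len(m) != i)
      nb <- pool[order(D[i, pool])][seq_len(k)]
      dsum <- colSums(abs(Xn[nb, , drop = FALSE] -
                          rep(Xn[i, ], each = length(nb))))
      if (cl == ci) {
        W <- W - dsum / (m * k)
      } else {
        W <- W + (prior[[cl]] / (1 - prior[[ci]])) * dsum / (m * k)
      }
    }
  }
  W[zero] <- 0
  names(W) <- colnames(X) %||% paste0("f", seq_along(W))
  ranking <- order(-W, seq_along(W))
  structure(list(weights = W, ranking = ranking,
                 selected = if (!is.null(n_keep))
                   ranking[seq_len(min(n_keep, length(W)))],
                 k_neighbors = k), class = "relieff_result")
}
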