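# Independent brute-force oracles used to validate the package's
# implementations.  Everything here is deliberately written as plain,
# slow enumeration, sharing no code with R/.

random_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A + t(A)
}

oracle_degree <- function(A) {
  vapply(seq_len(nrow(A)), function(i) sum(A[i, ] != 0), numeric(1))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] != 0) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# Floyd-Warshall distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A != 0, 1, Inf); diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# shortest-path counts sigma[s, t] by dynamic programming over distance
oracle_path_counts <- function(A, D) {
  n <- nrow(A)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (t in which(D[s, ] == d)) {
        preds <- which(A[, t] != 0 & D[s, ] == d - 1)
        sigma[s, t] <- sum(sigma[s, preds])
      }
    }
  }
  sigma
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  if (n < 3) return(numeric(n))
  D <- oracle_distances(A)
  sigma <- oracle_path_counts(A, D)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == t || s == v || t == v || s > t) next
      if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
      # paths through v: d(s,v) + d(v,t) == d(s,t)
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    bc[v] <- tot
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_eigenvector <- function(A) {
  n <- nrow(A)
  if (sum(A) == 0) return(numeric(n))
  D <- oracle_distances(A)
  # components from the distance matrix
  comp <- integer(n); cid <- 0
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1
    comp[is.finite(D[s, ])] <- cid
  }
  lcc <- which(comp == which.max(tabulate(comp)))
  if (length(lcc) < 2) return(numeric(n))
  # power iteration on A + I: same principal eigenvector, but the spectral
  # shift prevents oscillation on bipartite components
  S <- A[lcc, lcc, drop = FALSE] + diag(length(lcc))
  v <- rep(1 / sqrt(length(lcc)), length(lcc))
  for (it in 1:10000) {
    v2 <- S %*% v
    nv <- sqrt(sum(v2^2))
    if (nv == 0) break
    v2 <- v2 / nv
    if (max(abs(v2 - v)) < 1e-13) { v <- v2; break }
    v <- v2
  }
  out <- numeric(n)
  out[lcc] <- abs(v)
  out / sqrt(sum(out^2))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    D <- oracle_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / D; diag(inv) <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# one-way ANOVA from explicit sums of squares
oracle_anova_F <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# plain-loop Relief-F (all instances, k nearest hits / per-class misses,
# Manhattan distance on min-max normalized features)
oracle_relieff <- function(X, y, k) {
  X <- as.matrix(X); y <- factor(y)
  m <- nrow(X); p <- ncol(X)
  rng <- apply(X, 2, function(v) max(v) - min(v))
  rngs <- ifelse(rng == 0, 1, rng)
  Xn <- X
  for (f in seq_len(p)) Xn[, f] <- (X[, f] - min(X[, f])) / rngs[f]
  Xn[, rng == 0] <- 0
  W <- numeric(p)
  prior <- table(y) / m
  for (i in seq_len(m)) {
    d <- numeric(m)
    for (j in seq_len(m)) d[j] <- sum(abs(Xn[i, ] - Xn[j, ]))
    for (cl in levels(y)) {
      pool <- setdiff(which(y == cl), i)
      nb <- pool[order(d[pool])][seq_len(k)]
      for (f in seq_len(p)) {
        s <- sum(abs(Xn[i, f] - Xn[nb, f]))
        if (cl == as.character(y[i])) {
          W[f] <- W[f] - s / (m * k)
        } else {
          W[f] <- W[f] +
            (prior[[cl]] / (1 - prior[[as.character(y[i])]])) * s / (m * k)
        }
      }
    }
  }
  W[rng == 0] <- 0
  W
}

# small fast paradigm for pipeline-level tests
tiny_config <- function(seed = 1L, ...) {
  paradigm_config(n_colors = 2L, n_reps = 2L, n_sessions = 1L,
                  eeg_rate_hz = 250, seed = seed, ...)
}

quiet_truth <- function(...) {
  ground_truth(noise = list(eeg_background_uV = 0, eeg_alpha_uV = 0,
                            eeg_white_uV = 0, blink_rate_hz = 0,
                            blink_amp_uV = 0, fnirs_mayer = 0,
                            fnirs_cardiac = 0, fnirs_drift = 0,
                            fnirs_white = 0),
               network_gain_eeg = 0, network_gain_fnirs = 0, ...)
}
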