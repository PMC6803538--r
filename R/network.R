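#' Functional connectivity network from a channels x time window
#'
#' Pairwise Pearson correlations between channels, normalized to Fisher
#' Z-values (`atanh`, with `|r|` clipped at `1 - 1e-7`), zero diagonal.
#' A binary graph is derived by proportional thresholding: the strongest
#' `density` fraction of `|Z|` edges is retained (ties broken by `|Z|`
#' descending, then node-pair lexicographic order, so thresholding is
#' stable).  Constant channels produce undefined correlations; their edges
#' are set to 0 with a diagnostic.
#'
#' @param window channels x time matrix (>= 3 samples), typically the
#'   0-3.5 s observation segment of one trial.
#' @param density Fraction of edges retained in the binary graph
#'   (default 0.3).
#' @param node_ids Optional channel names.
#' @param modality Label stored with the network.
#' @return A `connectivity_network` list: `weights` (Fisher-Z matrix),
#'   `binary` (adjacency), `density`, `node_ids`, `modality`.
#' @export
connectivity <- function(window, density = 0.3, node_ids = NULL,
                         modality = "EEG") {
  stopifnot(is.matrix(window), ncol(window) >= 3L, density >= 0, density <= 1)
  n <- nrow(window)
  sds <- apply(window, 1, stats::sd)
  const <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(t(window)))
  if (length(const)) {
    message("connectivity: constant channel(s) ",
            paste(const, collapse = ", "), "; their edges set to 0")
    r[const, ] <- 0; r[, const] <- 0
  }
  r[is.na(r)] <- 0
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- 0
  binary <- .proportional_threshold(z, density)
  structure(list(weights = z, binary = binary, density = density,
                 node_ids = node_ids %||% as.character(seq_len(n)),
                 modality = modality),
            class = "connectivity_network")
}

.proportional_threshold <- function(z, density) {
  n <- nrow(z)
  A <- matrix(0L, n, n)
  if (n < 2L) return(A)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  w <- abs(z[upper.tri(z)])
  m <- round(density * nrow(ut))
  if (m > 0L) {
    ord <- order(-w, ut[, 1], ut[, 2])
    keep <- ord[seq_len(min(m, length(ord)))]
    A[ut[keep, , drop = FALSE]] <- 1L
    A <- A + t(A)
  }
  A
}

.check_adjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  A <- (A != 0) * 1L
  diag(A) <- 0L
  if (!isTRUE(all.equal(A, t(A)))) stop("adjacency must be symmetric")
  A
}

#' Nodal degree
#'
#' Number of neighbors of each node.
#'
#' @param A Binary adjacency matrix (simple undirected graph).
#' @return Integer vector of degrees.
#' @export
node_degree <- function(A) {
  A <- .check_adjacency(A)
  as.integer(rowSums(A))
}

#' Nodal clustering coefficient
#'
#' Fraction of realized links among each node's neighbors,
#' `2 T(i) / (k_i (k_i - 1))` with `T(i)` the number of triangles through
#' node i; defined 0 for degree < 2.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
node_clustering <- function(A) {
  A <- .check_adjacency(A)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

# level-synchronous BFS from source s: list(dist, sigma = shortest-path
# counts, levels = nodes grouped by distance)
.bfs_counts <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n); d[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  levels <- list(s)
  frontier <- replace(logical(n), s, TRUE)
  lev <- 0L
  repeat {
    cnt <- as.vector(A %*% (sigma * frontier))
    newf <- cnt > 0 & is.infinite(d)
    if (!any(newf)) break
    lev <- lev + 1L
    d[newf] <- lev
    sigma[newf] <- cnt[newf]
    levels[[lev + 1L]] <- which(newf)
    frontier <- newf
  }
  list(dist = d, sigma = sigma, levels = levels)
}

#' Nodal betweenness centrality
#'
#' Fraction of shortest paths between other node pairs passing through each
#' node, normalized by `(n - 1)(n - 2) / 2`; pairs in different components
#' contribute nothing.  Computed with Brandes' dependency accumulation.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric vector of normalized betweenness values.
#' @export
node_betweenness <- function(A) {
  A <- .check_adjacency(A)
  n <- nrow(A)
  if (n < 3L) return(numeric(n))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    b <- .bfs_counts(A, s)
    delta <- numeric(n)
    for (lv in rev(seq_along(b$levels))) {
      if (lv == 1L) break
      w <- b$levels[[lv]]
      vec <- numeric(n)
      vec[w] <- (1 + delta[w]) / b$sigma[w]
      contrib <- as.vector(A %*% vec)
      v <- b$levels[[lv - 1L]]
      delta[v] <- delta[v] + b$sigma[v] * contrib[v]
    }
    delta[s] <- 0
    bc <- bc + delta
  }
  bc / 2 / ((n - 1) * (n - 2) / 2)
}

# connected component labels via BFS
.components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    reach <- is.finite(.bfs_counts(A, s)$dist)
    comp[reach] <- cid
  }
  comp
}

#' Nodal eigenvector centrality
#'
#' Entries of the principal eigenvector of the adjacency matrix restricted
#' to the largest connected component (ties broken toward the component
#' containing the lowest-index node), nonnegative and normalized to unit
#' Euclidean norm; nodes outside that component score 0.  A graph with no
#' edges scores 0 everywhere.
#'
#' @param A Binary adjacency matrix (nonempty).
#' @return Numeric vector of centralities.
#' @export
node_eigenvector <- function(A) {
  A <- .check_adjacency(A)
  n <- nrow(A)
  if (n == 0L) stop("empty graph")
  if (sum(A) == 0) return(numeric(n))
  comp <- .components(A)
  sizes <- tabulate(comp)
  lcc <- which(comp == which.max(sizes))
  if (length(lcc) < 2L) return(numeric(n))
  ev <- eigen(A[lcc, lcc], symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- abs(v)  # Perron vector is sign-definite; fix orientation
  v <- v / sqrt(sum(v^2))
  out <- numeric(n)
  out[lcc] <- v
  out
}

# all-pairs shortest-path distances of a small graph via boolean powers
.distances_small <- function(S) {
  m <- nrow(S)
  D <- matrix(Inf, m, m); diag(D) <- 0
  reach <- diag(m) > 0
  Sb <- S > 0
  d <- 0L
  repeat {
    d <- d + 1L
    newreach <- (reach %*% Sb) > 0 | reach
    new <- newreach & !reach
    if (!any(new)) break
    D[new] <- d
    reach <- newreach
  }
  D
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbors:
#' the mean over ordered neighbor pairs of the inverse shortest-path length
#' within that subgraph (unreachable pairs contribute 0); defined 0 for
#' degree < 2.  Measures how well a node's neighbors communicate when the
#' node is removed.
#'
#' @param A Binary adjacency matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
node_local_efficiency <- function(A) {
  A <- .check_adjacency(A)
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) next
    D <- .distances_small(A[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    out[i] <- sum(inv) / (length(nb) * (length(nb) - 1))
  }
  out
}

#' All five nodal metrics of a connectivity network
#'
#' Concatenates degree, clustering coefficient, betweenness centrality,
#' eigenvector centrality and local efficiency of every node, in that fixed
#' metric-major order (all degrees, then all clusterings, ...).
#'
#' @param network A `connectivity_network` (or a bare adjacency matrix).
#' @return Named numeric vector of length `5 * n_nodes`
#'   (`<metric>.<node>`).
#' @export
nodal_features <- function(network) {
  A <- if (inherits(network, "connectivity_network")) network$binary
       else network
  ids <- if (inherits(network, "connectivity_network")) network$node_ids
         else as.character(seq_len(nrow(A)))
  vals <- c(degree = node_degree(A), clustering = node_clustering(A),
            betweenness = node_betweenness(A),
            eigenvector = node_eigenvector(A),
            local_efficiency = node_local_efficiency(A))
  names(vals) <- paste(rep(c("degree", "clustering", "betweenness",
                             "eigenvector", "local_efficiency"),
                           each = length(ids)), ids, sep = ".")
  vals
}

#' Per-trial nodal feature table
#'
#' Builds one connectivity network per trial from the configured analysis
#' window (default the 0-3.5 s observation period) and stacks the five
#' nodal metrics into a trials x (channels x 5) feature matrix.
#'
#' @param epochs An `epoch_set`.
#' @param window_s Analysis window (default `c(0, 3.5)`).
#' @param density Binary-graph density (default 0.3).
#' @return A `feature_table` list: `features` (trials x 5n matrix),
#'   `labels`, `modality`, `density`, `window_s`.
#' @export
trial_feature_table <- function(epochs, window_s = c(0, 3.5), density = 0.3) {
  stopifnot(inherits(epochs, "epoch_set"))
  t <- epoch_times(epochs)
  idx <- which(t >= window_s[1] - 1e-9 & t <= window_s[2] + 1e-9)
  if (length(idx) < 3L) stop("analysis window has fewer than 3 samples")
  n_trials <- dim(epochs$data)[1]
  feats <- NULL
  for (i in seq_len(n_trials)) {
    net <- connectivity(epochs$data[i, , idx], density = density,
                        node_ids = epochs$channel_names,
                        modality = epochs$modality)
    v <- nodal_features(net)
    if (is.null(feats))
      feats <- matrix(NA_real_, n_trials, length(v),
                      dimnames = list(NULL, names(v)))
    feats[i, ] <- v
  }
  structure(list(features = feats, labels = epochs$labels,
                 modality = epochs$modality, density = density,
                 window_s = window_s),
            class = "feature_table")
}

#' Grand-averaged connectivity network per condition
#'
#' Network of the condition grand-average waveforms over the analysis
#' window (the visualization-style network, complementing the per-trial
#' networks used for classification).
#'
#' @param epochs An `epoch_set`.
#' @param window_s Analysis window (default `c(0, 3.5)`).
#' @param density Binary-graph density (default 0.3).
#' @return Named list of `connectivity_network`, one per condition.
#' @export
grand_average_networks <- function(epochs, window_s = c(0, 3.5),
                                   density = 0.3) {
  ga <- grand_average(epochs)
  t <- attr(ga, "times_s")
  idx <- which(t >= window_s[1] - 1e-9 & t <= window_s[2] + 1e-9)
  out <- lapply(seq_len(dim(ga)[1]), function(ci)
    connectivity(ga[ci, , idx], density = density,
                 node_ids = epochs$channel_names,
                 modality = epochs$modality))
  names(out) <- dimnames(ga)[[1]]
  out
}
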