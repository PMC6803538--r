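test_that("connectivity builds clipped Fisher-Z weights and a stable binary graph", {
  set.seed(11)
  x <- matrix(rnorm(5 * 200), 5, 200)
  x[2, ] <- x[1, ]  # duplicated channel -> r = 1, clipped
  net <- connectivity(x, density = 0.4)
  expect_equal(net$weights[1, 2], atanh(1 - 1e-7))
  expect_true(isSymmetric(net$weights))
  expect_equal(diag(net$weights), rep(0, 5))
  expect_equal(sum(net$binary) / 2, round(0.4 * choose(5, 2)))
  expect_true(all(net$binary %in% 0:1))
  # Fisher Z closed form and oddness
  expect_equal(atanh(0.9), 1.4722, tolerance = 1e-4)
  expect_equal(atanh(-0.37), -atanh(0.37))
  # constant channel edges zeroed with diagnostic
  x[3, ] <- 2
  expect_message(net2 <- connectivity(x, density = 0.3), "constant")
  expect_equal(max(abs(net2$weights[3, ])), 0)
})

test_that("independent channels decorrelate as the window grows", {
  set.seed(12)
  mean_absr <- sapply(c(50, 500, 5000), function(T) {
    x <- matrix(rnorm(6 * T), 6, T)
    w <- connectivity(x, density = 0.3)$weights
    mean(abs(tanh(w[upper.tri(w)])))
  })
  expect_true(all(diff(mean_absr) < 0))
  expect_lt(mean_absr[3], 0.03)
})

test_that("nodal metrics match closed-form values on canonical graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(node_degree(tri), c(2L, 2L, 2L))
  expect_equal(node_clustering(tri), rep(1, 3))
  expect_equal(node_local_efficiency(tri), rep(1, 3))
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 3] <- 1
  path3 <- path3 + t(path3)
  expect_equal(node_degree(path3), c(1L, 2L, 1L))
  expect_equal(node_betweenness(path3), c(0, 1, 0))
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  expect_equal(node_clustering(star)[1], 0)
  expect_equal(node_local_efficiency(star)[1], 0)
  # star S_4: center / leaf eigenvector ratio is sqrt(3)
  ev <- node_eigenvector(star)
  expect_equal(ev[1] / ev[2], sqrt(3), tolerance = 1e-10)
  # complete graph: eigenvector 1/sqrt(n), betweenness 0, clustering 1
  K5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(node_eigenvector(K5), rep(1 / sqrt(5), 5), tolerance = 1e-10)
  expect_equal(node_betweenness(K5), rep(0, 5))
  expect_equal(node_clustering(K5), rep(1, 5))
  # empty graph: everything zero
  E4 <- matrix(0, 4, 4)
  ftE <- nodal_features(E4)
  expect_equal(unname(ftE), rep(0, 20))
})

test_that("all five metrics agree with brute-force enumeration on random graphs", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    A <- random_graph(n, p = runif(1, 0.2, 0.8))
    expect_equal(node_degree(A), oracle_degree(A))
    expect_equal(node_clustering(A), oracle_clustering(A), tolerance = 1e-10)
    expect_equal(node_betweenness(A), oracle_betweenness(A),
                 tolerance = 1e-10)
    expect_equal(node_eigenvector(A), oracle_eigenvector(A),
                 tolerance = 1e-8)
    expect_equal(node_local_efficiency(A), oracle_local_efficiency(A),
                 tolerance = 1e-10)
  }
})

test_that("metrics agree with igraph on larger random graphs", {
  skip_if_not_installed("igraph")
  set.seed(14)
  for (i in 1:5) {
    A <- random_graph(30, p = 0.2)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(node_degree(A), unname(igraph::degree(g)))
    expect_equal(node_betweenness(A),
                 unname(igraph::betweenness(g, normalized = TRUE)),
                 tolerance = 1e-10)
    cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    # igraph reports NaN->0 handling via isolates; degree-1 nodes give 0 here
    expect_equal(node_clustering(A), unname(cl), tolerance = 1e-10)
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(15)
  A <- random_graph(7, 0.5)
  perm <- sample(7)
  P <- A[perm, perm]
  for (f in list(node_degree, node_clustering, node_betweenness,
                 node_eigenvector, node_local_efficiency)) {
    expect_equal(f(P), f(A)[perm], tolerance = 1e-9)
  }
})

test_that("feature tables stack metrics in the documented order", {
  set.seed(16)
  dat <- array(rnorm(4 * 6 * 80), c(4, 6, 80))
  ep <- epoch_set(dat, 20, 0, rep(c("Sd", "Sm"), 2), "EEG")
  ft <- trial_feature_table(ep, window_s = c(0, 3.5), density = 0.3)
  expect_equal(dim(ft$features), c(4, 30))
  expect_false(anyNA(ft$features))
  # columns equal the single-network metric vectors per trial
  t <- epoch_times(ep); idx <- which(t >= 0 & t <= 3.5)
  net1 <- connectivity(dat[1, , idx], density = 0.3)
  expect_equal(unname(ft$features[1, ]), unname(nodal_features(net1)))
  expect_match(colnames(ft$features)[1], "^degree\\.")
  expect_match(colnames(ft$features)[30], "^local_efficiency\\.")
})

test_that("planted condition structure makes networks more similar within condition", {
  cfg <- tiny_config()
  sch <- build_schedule(cfg)
  tr <- ground_truth()
  e <- generate_eeg(sch, tr, seed = 21)
  ep <- epoch_extract(e$eeg, cfg$eeg_rate_hz, sch, c(-0.7, 3.5),
                      modality = "EEG")
  t <- epoch_times(ep); idx <- which(t >= 0 & t <= 3.5)
  W <- sapply(seq_len(nrow(sch)), function(i) {
    w <- connectivity(ep$data[i, , idx])$weights
    w[upper.tri(w)]
  })
  cw <- cor(W)
  lab <- as.character(ep$labels)
  same <- outer(lab, lab, "=="); diag(same) <- NA
  expect_gt(mean(cw[same & !is.na(same)]), mean(cw[!same & !is.na(same)]))
})
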