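test_that("node strengths match row sums and the published backward matrix", {
  wb <- build_weighted_hvg(toy_series(), "backward")
  d <- weighted_degrees(wb)
  # node 6 touches nodes 3 and 5: printed cells 0.927 + 0.510
  expect_equal(d[6], 0.927 + 0.510, tolerance = 2e-3)
  expect_equal(d, strength_oracle(wb$weights))
  # average strength: every printed off-diagonal cell counted twice over 6 nodes
  printed <- vapply(toy_wb_cells, `[`, numeric(1), 3)
  printed <- c(printed, round(backward_weight(7, 4, 1), 3))  # cell (1,2)
  expect_equal(average_weighted_degree(wb), 2 * sum(printed) / 6,
               tolerance = 5e-3)
  set.seed(4)
  w <- random_weight_matrix(10)
  expect_equal(weighted_degrees(w), strength_oracle(w))
})

test_that("strengths agree with igraph on a random weighted graph", {
  skip_if_not_installed("igraph")
  set.seed(8)
  w <- random_weight_matrix(15, density = 0.4)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(weighted_degrees(w),
               unname(igraph::strength(g)), tolerance = 1e-12)
})

test_that("degree deviation is the sample standard deviation of strengths", {
  # equal strengths: a path of equal weights has deviation 0 only for
  # interior-equal cases, so use a cycle-free two-node graph
  w2 <- matrix(c(0, 0.7, 0.7, 0), 2)
  expect_equal(degree_deviation(w2), 0)
  wb <- build_weighted_hvg(toy_series(), "backward")
  d <- strength_oracle(wb$weights)
  expect_equal(degree_deviation(wb), sqrt(sum((d - mean(d))^2) / (6 - 1)))
})

test_that("closed forms: uniform path strengths and degree average", {
  # path of N nodes, every adjacent weight c: total weight 2c(N-1)/N on average
  n <- 9; cw <- 0.42
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- cw
  expect_equal(average_weighted_degree(w), 2 * cw * (n - 1) / n)
})

test_that("all four statistics equal their triple-loop oracles on random graphs", {
  set.seed(123)
  for (trial in 1:50) {
    n <- sample(3:12, 1)
    w <- random_weight_matrix(n, density = runif(1, 0.3, 0.9))
    expect_equal(weighted_degrees(w), strength_oracle(w))
    expect_equal(average_weighted_degree(w), mean(strength_oracle(w)))
    expect_equal(degree_deviation(w), sd(strength_oracle(w)))
    ci_ref <- clustering_oracle(w)
    cl <- weighted_clustering(w)
    expect_equal(cl$per_node, ci_ref, tolerance = 1e-12)
    expect_equal(cl$network, mean(ci_ref))
    if (sum(ci_ref) > 0) {
      expect_equal(clustering_entropy(w), entropy_oracle(ci_ref))
    }
  }
})

test_that("clustering ratio is invariant to ordered-pair double counting", {
  # counting each ordered neighbour pair (j,k) and (k,j) multiplies both the
  # triangle sum and the normalizer by two; the oracle counts unordered
  # pairs once, the implementation sums ordered products, and they agree
  set.seed(5)
  w <- random_weight_matrix(8)
  expect_equal(weighted_clustering(w)$per_node, clustering_oracle(w))
})

test_that("clustering takes its textbook values on canonical graphs", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  cl <- weighted_clustering(tri)
  expect_equal(cl$per_node, rep(1, 3))
  expect_equal(cl$network, 1)
  path <- matrix(0, 5, 5)
  for (i in 1:4) path[i, i + 1] <- path[i + 1, i] <- runif(1)
  expect_equal(weighted_clustering(path)$network, 0)
  expect_warning(e <- clustering_entropy(path), "no triangles")
  expect_equal(e, 0)
})

test_that("clustering entropy of a uniform distribution is log n", {
  for (n in c(4, 7, 11)) {
    w <- matrix(0.5, n, n); diag(w) <- 0  # complete graph: all C_i equal
    expect_equal(clustering_entropy(w), log(n))
    expect_equal(clustering_entropy(w, log_base = 2), log2(n))
  }
  # single clustered node: degenerate distribution, zero entropy
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- w[1, 3] <- w[3, 1] <- w[2, 3] <- w[3, 2] <- 1
  ci <- weighted_clustering(w)$per_node
  expect_true(sum(ci > 0) >= 1)
  one_hot <- c(1, rep(0, 4))
  expect_equal(entropy_oracle(one_hot), 0)
})

test_that("weight scaling acts linearly on degrees and clustering, not entropy", {
  set.seed(6)
  w <- random_weight_matrix(10, 0.6)
  for (lam in c(0.2, 3, 17)) {
    expect_equal(average_weighted_degree(lam * w),
                 lam * average_weighted_degree(w))
    expect_equal(degree_deviation(lam * w), lam * degree_deviation(w))
    expect_equal(weighted_clustering(lam * w)$network,
                 lam * weighted_clustering(w)$network)
    expect_equal(clustering_entropy(lam * w), clustering_entropy(w))
  }
})

test_that("forward/backward fusion is an elementwise sum of feature vectors", {
  both <- extract_network_features(toy_series(), fuse = FALSE,
                                   shift_min = FALSE)
  fused <- extract_network_features(toy_series(), fuse = TRUE,
                                    shift_min = FALSE)
  expect_equal(fused, both$forward + both$backward)
  # against the oracles on the actual weight matrices
  wf <- build_weighted_hvg(toy_series(), "forward")$weights
  wb <- build_weighted_hvg(toy_series(), "backward")$weights
  expect_equal(fused[["avg_weighted_degree"]],
               mean(strength_oracle(wf)) + mean(strength_oracle(wb)))
  expect_equal(fused[["weighted_clustering"]],
               mean(clustering_oracle(wf)) + mean(clustering_oracle(wb)))
  expect_equal(fused[["clustering_entropy"]],
               entropy_oracle(clustering_oracle(wf)) +
                 entropy_oracle(clustering_oracle(wb)))
})

test_that("a zero segment yields zero features through the warning path", {
  suppressWarnings(f <- extract_network_features(rep(0, 6), shift_min = FALSE))
  expect_equal(unname(f), rep(0, 4))
  # one warning per direction: forward and backward graph are both flat
  w <- capture_warnings(extract_network_features(rep(0, 6),
                                                 shift_min = FALSE))
  expect_length(w, 2)
  expect_match(w, "no triangles", all = TRUE)
})
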