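test_that("proportional thresholding keeps exactly the strongest edges", {
  W <- random_weighted_graph(5, p_edge = 1, seed = 3)
  out <- threshold_proportional(W, 0.3)
  expect_equal(sum(out[upper.tri(out)] != 0), 3)
  kept <- sort(out[upper.tri(out)][out[upper.tri(out)] != 0], decreasing = TRUE)
  expect_equal(kept, sort(W[upper.tri(W)], decreasing = TRUE)[1:3])
  expect_identical(out, oracle_threshold(W, 0.3))
  # full density on an all-positive graph is the identity
  expect_equal(threshold_proportional(W, 1), W)
  expect_error(threshold_proportional(W, 0), "density")
  expect_error(threshold_proportional(W, 1.2), "density")
})

test_that("thresholding breaks weight ties deterministically", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[1, 3] <- W[2, 4] <- 0.5   # tied weights at the cut
  W[3, 4] <- 0.9
  W <- W + t(W)
  out1 <- threshold_proportional(W, 2 / 6)
  out2 <- threshold_proportional(W, 2 / 6)
  expect_identical(out1, out2)
  expect_identical(out1, oracle_threshold(W, 2 / 6))
  expect_equal(sum(out1[upper.tri(out1)] != 0), 2)
  expect_equal(out1[3, 4], 0.9)
  expect_equal(out1[1, 2], 0.5)  # lexicographically first among the ties
})

test_that("weighted clustering matches clique, star, and hand-computed cases", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_weighted(tri)$ci, rep(1, 3))
  expect_equal(clustering_weighted(tri)$C, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- 0.8; star <- star + t(star)
  expect_equal(clustering_weighted(star)$C, 0)
  # weighted triangle (1.0, 0.5, 0.5) with a pendant node hanging off node 3
  W <- fixture_graphs()$tri_pendant
  got <- clustering_weighted(W)
  exp_c1 <- (1.0 * 0.5 * 0.5)^(1 / 3)        # after scaling by max weight 1
  expect_equal(got$ci[1], exp_c1)
  expect_equal(got$ci[2], exp_c1)
  expect_equal(got$ci[4], 0)                 # pendant, degree 1
  expect_equal(got$ci, oracle_clustering(W)$ci, tolerance = 1e-12)
  expect_error(clustering_weighted(-tri), "nonnegative")
})

test_that("characteristic path length matches hand counts and scales as 1/w", {
  g <- fixture_graphs()
  expect_equal(as.numeric(characteristic_path_length(g$path3)), 4 / 3)
  W <- random_weighted_graph(7, seed = 5)
  L1 <- as.numeric(characteristic_path_length(W))
  expect_equal(as.numeric(characteristic_path_length(2 * W)), L1 / 2)
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no edges")
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  for (W in fixture_graphs()) {
    if (all(W == 0)) next
    expect_equal(clustering_weighted(W)$ci, oracle_clustering(W)$ci,
                 tolerance = 1e-10)
    expect_equal(as.numeric(characteristic_path_length(W)),
                 oracle_path_length(W), tolerance = 1e-10)
  }
})

test_that("null ensembles preserve degree sequence and weight multiset", {
  W <- threshold_proportional(random_weighted_graph(20, 0.6, seed = 9), 0.3)
  nulls <- null_ensemble(W, k = 20, seed = 4)
  deg0 <- sort(colSums(W > 0))
  w0 <- sort(W[upper.tri(W)][W[upper.tri(W)] != 0])
  for (M in nulls$graphs) {
    expect_identical(sort(colSums(M > 0)), deg0)
    expect_equal(sort(M[upper.tri(M)][M[upper.tri(M)] != 0]), w0)
  }
  # determinism given the seed
  nulls2 <- null_ensemble(W, k = 20, seed = 4)
  expect_identical(nulls$graphs, nulls2$graphs)
})

test_that("an Erdos-Renyi graph is its own null in expectation", {
  W <- wmtopo:::with_seed(21, {
    A <- (matrix(stats::runif(40 * 40), 40) < 0.3) * 1
    A[lower.tri(A, diag = TRUE)] <- 0
    A[A == 1] <- stats::runif(sum(A == 1), 0.5, 1)
    A + t(A)
  })
  nulls <- null_ensemble(W, k = 50, seed = 8)
  C_src <- clustering_weighted(W)$C
  C_null <- mean(vapply(nulls$graphs, function(M) clustering_weighted(M)$C,
                        numeric(1)))
  expect_lt(abs(C_null - C_src) / C_src, 0.15)
})

test_that("complete graphs fall back to weight-permuted nulls with a warning", {
  W <- random_weighted_graph(5, p_edge = 1, seed = 2)
  expect_warning(nulls <- null_ensemble(W, k = 3, seed = 1), "complete")
  for (M in nulls$graphs)
    expect_identical((M > 0), (W > 0))
})

test_that("self-normalization gives gamma = lambda = sigma = 1", {
  W <- threshold_proportional(random_weighted_graph(12, 0.7, seed = 6), 0.4)
  self <- structure(list(graphs = list(W), k = 1, seed = 0),
                    class = "null_ensemble")
  gt <- small_world_indices(W, self)
  expect_equal(gt$gamma, 1)
  expect_equal(gt$lambda, 1)
  expect_equal(gt$sigma, 1)
})

test_that("lattice-like graphs show excess clustering over their nulls", {
  gt_net <- ground_truth_network(60, neighbors = 4, rewire_p = 0.05, seed = 3)
  W <- gt_net$adjacency
  nulls <- null_ensemble(W, k = 20, seed = 5)
  gt <- small_world_indices(W, nulls)
  expect_gt(gt$gamma, 1.5)
  expect_gt(gt$sigma, 1)
})

test_that("metric curves use the full grid and satisfy the sigma identity", {
  expect_length(default_densities(), 21)
  W <- random_weighted_graph(30, 0.8, seed = 11)
  mc <- metric_curves(W, densities = seq(0.2, 0.5, by = 0.1), k_null = 5,
                      seed = 2)
  expect_equal(mc$curve$sigma, mc$curve$gamma / mc$curve$lambda,
               tolerance = 1e-10)
  expect_true(all(is.finite(as.matrix(mc$curve))))
  expect_equal(dim(mc$regional), c(30, 4))
  # identical seed reproduces the curves exactly
  mc2 <- metric_curves(W, densities = seq(0.2, 0.5, by = 0.1), k_null = 5,
                       seed = 2)
  expect_identical(mc$curve, mc2$curve)
})

test_that("path length is non-increasing as density grows", {
  for (s in 1:5) {
    W <- random_weighted_graph(12, p_edge = 0.9, seed = 30 + s)
    L <- vapply(c(0.2, 0.3, 0.4, 0.5),
                function(d) as.numeric(
                  characteristic_path_length(threshold_proportional(W, d))),
                numeric(1))
    expect_true(all(diff(L) <= 1e-12))
  }
})

test_that("negative-weight policies are applied before thresholding", {
  W <- random_weighted_graph(10, 0.9, seed = 40)
  W[1, 2] <- W[2, 1] <- -0.9
  mc_zero <- metric_curves(W, densities = 0.3, k_null = 5, seed = 1,
                           negative_policy = "zero")
  mc_abs <- metric_curves(W, densities = 0.3, k_null = 5, seed = 1,
                          negative_policy = "abs")
  expect_true(all(is.finite(as.matrix(mc_zero$curve))))
  # under "abs" the strong negative edge can enter the thresholded graph
  expect_false(identical(mc_zero$curve$C, mc_abs$curve$C))
})
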