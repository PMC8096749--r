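test_that("sparsity thresholding keeps the K strongest edges with a fixed rounding rule", {
  set.seed(1)
  W <- random_weight_matrix(90, density = 1)
  expect_identical(threshold_by_sparsity(W, 1)$K, 4005L)
  # round-half-even: 0.10 * 4005 = 400.5 -> 400
  expect_identical(threshold_by_sparsity(W, 0.10)$K, 400L)
  A <- threshold_by_sparsity(W, 0.10)$adjacency
  kept <- A[upper.tri(A)]
  expect_identical(sum(kept > 0), 400L)
  expect_gte(min(kept[kept > 0]), max(W[upper.tri(W)][A[upper.tri(A)] == 0]))
  expect_error(threshold_by_sparsity(W, 0), "sparsity")
  expect_error(threshold_by_sparsity(W, 1.2), "sparsity")
})

test_that("ties in weight are broken by ascending node-index pair", {
  W <- matrix(0, 4, 4)
  W[upper.tri(W)] <- 0.5  # all six edges tie
  W <- W + t(W)
  A <- threshold_by_sparsity(W, 1 / 3)$adjacency  # keep 2 of 6
  expect_identical(which(A[upper.tri(A)] > 0), c(1L, 2L))  # (1,2), (1,3)
})

test_that("thresholding commutes with node relabelling", {
  set.seed(2)
  W <- random_weight_matrix(12, density = 1)
  perm <- sample(12)
  A1 <- threshold_by_sparsity(W, 0.3)$adjacency
  A2 <- threshold_by_sparsity(W[perm, perm], 0.3)$adjacency
  expect_equal(A2, A1[perm, perm], ignore_attr = TRUE)
})

test_that("binary clustering reproduces hand-counted toy values", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(clustering_coefficient(K5, "binary")$mean, 1)
  tp <- toy_triangle_pendant()
  cc <- clustering_coefficient(tp, "binary")
  expect_equal(cc$nodal, c(1 / 3, 1, 1, 0))
  expect_equal(cc$mean, 7 / 12)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star, "binary")$mean, 0)
})

test_that("path metrics reproduce enumerated toy values", {
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  pe <- path_length_and_efficiency(P3, "binary")
  expect_equal(pe$Lp, 4 / 3)
  expect_equal(pe$Eglob, (1 + 1 + 0.5) / 3)
  expect_equal(pe$nodal_efficiency[2], 1)
  iso <- matrix(0, 2, 2)
  expect_equal(path_length_and_efficiency(iso)$Eglob, 0)
  # weighted and binary agree when all weights are 1
  set.seed(3)
  A <- (random_weight_matrix(8) > 0) + 0
  expect_equal(path_length_and_efficiency(A, "weighted"),
               path_length_and_efficiency(A, "binary"))
})

test_that("local efficiency: complete graph 1, star 0, toy matches oracle", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(local_efficiency(K4, "binary")$mean, 1)
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star, "binary")$mean, 0)
  tp <- toy_triangle_pendant()
  expect_equal(local_efficiency(tp, "binary")$nodal,
               oracle_local_efficiency(tp, "binary")$nodal,
               tolerance = 1e-12)
})

test_that("betweenness reproduces enumerated toy values", {
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(nodal_betweenness(P3, "binary"), c(0, 1, 0))
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(nodal_betweenness(star, "binary"), c(3, 0, 0, 0))
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(nodal_betweenness(K4, "binary"), rep(0, 4))
})

test_that("nodal degree counts edges (binary) and sums weights (strength)", {
  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(nodal_degree(P3, "binary"), c(1, 2, 1))
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_equal(nodal_degree(K6, "binary"), rep(5, 6))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 0.3; W[2, 3] <- W[3, 2] <- 0.4
  expect_equal(nodal_degree(W, "weighted"), c(0.3, 0.7, 0.4))
  iso <- rbind(cbind(K6, 0), 0)
  expect_equal(nodal_degree(iso, "binary")[7], 0)
})

test_that("weighted metrics match brute-force oracles on random graphs", {
  set.seed(4)
  for (i in 1:12) {
    W <- random_weight_matrix(8, density = 0.6)
    expect_equal(clustering_coefficient(W)$nodal, oracle_cp_weighted(W)$nodal,
                 tolerance = 1e-9)
    pe <- path_length_and_efficiency(W)
    or <- oracle_path_metrics(W)
    expect_equal(pe$Lp, or$Lp, tolerance = 1e-9)
    expect_equal(pe$Eglob, or$Eglob, tolerance = 1e-9)
    expect_equal(pe$nodal_efficiency, or$nodal_efficiency, tolerance = 1e-9)
    expect_equal(local_efficiency(W)$nodal, oracle_local_efficiency(W)$nodal,
                 tolerance = 1e-9)
    expect_equal(nodal_betweenness(W), oracle_betweenness(W),
                 tolerance = 1e-7)
  }
})

test_that("metric values are invariant under node relabelling", {
  set.seed(5)
  W <- random_weight_matrix(10, density = 0.5)
  perm <- sample(10)
  Wp <- W[perm, perm]
  expect_equal(clustering_coefficient(Wp)$nodal,
               clustering_coefficient(W)$nodal[perm], ignore_attr = TRUE)
  expect_equal(path_length_and_efficiency(Wp)$Lp,
               path_length_and_efficiency(W)$Lp)
  expect_equal(nodal_betweenness(Wp), nodal_betweenness(W)[perm],
               ignore_attr = TRUE)
  expect_equal(local_efficiency(Wp)$mean, local_efficiency(W)$mean)
})

test_that("rewired nulls preserve counts, degrees and the weight multiset", {
  set.seed(6)
  W <- threshold_by_sparsity(random_weight_matrix(30, 1), 0.2)$adjacency
  for (i in 1:10) {
    A <- rewire_network(W)
    expect_identical(rowSums(A > 0), rowSums(W > 0))
    expect_identical(sum(A > 0), sum(W > 0))
    expect_equal(sort(A[upper.tri(A) & A > 0]),
                 sort(W[upper.tri(W) & W > 0]), tolerance = 0)
    expect_equal(A, t(A))
  }
  expect_error(rewire_network(matrix(0, 4, 4)), "too few edges")
})

test_that("null references and rewiring are reproducible under a seed", {
  set.seed(7)
  W <- threshold_by_sparsity(random_weight_matrix(30, 1), 0.2)$adjacency
  r1 <- random_reference(W, n_null = 10, seed = 42)
  r2 <- random_reference(W, n_null = 10, seed = 42)
  expect_identical(r1, r2)
  set.seed(9); A1 <- rewire_network(W)
  set.seed(9); A2 <- rewire_network(W)
  expect_identical(A1, A2)
})

test_that("small-world indices are elementwise ratios", {
  sw <- small_world_indices(c(0.5, 0.6), c(2, 3), c(0.5, 0.3), c(2, 3))
  expect_equal(sw$gamma, c(1, 2))
  expect_equal(sw$lambda, c(1, 1))
  expect_equal(sw$sigma, c(1, 2))
})

test_that("AUC implements the trapezoidal rule and is linear", {
  s <- seq(0.10, 0.34, by = 0.01)
  expect_equal(metric_auc(rep(3, length(s)), s), 0.24 * 3)
  ramp <- seq(0, 1, length.out = length(s))
  expect_equal(metric_auc(ramp, s), 0.12)
  expect_error(metric_auc(1, 0.1), "at least two")
  set.seed(8)
  f <- runif(length(s)); g <- runif(length(s))
  expect_equal(metric_auc(2 * f + 5 * g, s),
               2 * metric_auc(f, s) + 5 * metric_auc(g, s),
               tolerance = 1e-12)
})

test_that("degree criterion alone forces the sparsity floor to 0.11 for 90 nodes", {
  set.seed(10)
  nets <- list(random_weight_matrix(90, 1))
  sel <- select_sparsity_range(nets, candidates = seq(0.05, 0.50, 0.01),
                               sigma_min = 0)
  # mean degree 2*round(S*4005)/90 must exceed 2*ln(90) = 8.9998;
  # S = 0.10 gives 8.89, S = 0.11 gives 9.8
  expect_equal(sel$S_lo, 0.11)
  expect_equal(sel$S_hi, 0.50)
  expect_error(select_sparsity_range(nets, candidates = 0.01,
                                     sigma_min = 0),
               "no admissible")
  expect_error(select_sparsity_range(list(), sigma_min = 0), "at least one")
})

test_that("hub scores flag exactly the top 10% per metric with index tie-breaks", {
  m <- matrix(0, 90, 3, dimnames = list(NULL, c("betweenness", "degree",
                                                "efficiency")))
  m[1:9, 1] <- 9:1          # distinct top block for metric 1
  m[5:20, 2] <- 2           # ties spanning the rank-9 cutoff
  m[1, 3] <- 1
  hs <- hub_scores(m)
  expect_identical(colSums(as.matrix(hs[, c("betweenness", "degree",
                                            "efficiency")])),
                   c(betweenness = 9, degree = 9, efficiency = 9))
  # metric 2 ties: first 9 of nodes 5..20 by index, i.e. 5..13
  expect_identical(which(hs$degree == 1), 5:13)
  expect_identical(hs$hub_score[5], 3L)  # node 5 top in all three
  expect_true(hs$is_hub[5])
})

test_that("metric curves stack globals and nodals over the sparsity grid", {
  net <- build_network(toy_subject(n_regions = 20, n_vox = 50, seed = 11))
  mc <- network_metrics(net, sparsities = c(0.2, 0.3, 0.4), n_null = 5,
                        seed = 1)
  expect_identical(dim(mc$global), c(7L, 3L))
  expect_true(all(is.finite(mc$global)))
  expect_identical(dim(mc$nodal$degree), c(20L, 3L))
  expect_true(all(unlist(mc$nodal) >= 0))
  au <- curves_auc(mc)
  expect_length(au$global, 7L)
  expect_identical(dim(au$nodal), c(20L, 3L))
  # gamma = Cp/Cp_random etc. are consistent at each sparsity by
  # construction; sigma = gamma/lambda exactly
  expect_equal(mc$global["sigma", ],
               mc$global["gamma", ] / mc$global["lambda", ])
})
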