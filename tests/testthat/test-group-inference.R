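test_that("permutation test: constants give p = 1; shifts give small p; seeded reruns agree", {
  expect_equal(permutation_test(rep(2, 10), rep(2, 12), n_perm = 200,
                                seed = 1)$p, 1)
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20, 1.5)
  r <- permutation_test(a, b, n_perm = 2000, seed = 3)
  expect_lt(r$p, 0.01)
  expect_equal(r$diff, mean(a) - mean(b))
  expect_identical(permutation_test(a, b, n_perm = 500, seed = 9),
                   permutation_test(a, b, n_perm = 500, seed = 9))
  expect_error(permutation_test(1, rnorm(5)), "at least 2")
})

test_that("Cohen's d: worked example, null identity, antisymmetry", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(4)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
})

test_that("BH step-up: worked example, all-null case, brute-force agreement", {
  r <- fdr_correct(c(0.01, 0.02, 0.04, 0.5), q = 0.05)
  expect_identical(r$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_false(any(fdr_correct(rep(1, 20))$significant))
  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    got <- fdr_correct(p, 0.05)$significant
    expect_identical(got, oracle_bh_reject(p, 0.05))
    # FDR never rejects more than naive 0.05 thresholding
    expect_lte(sum(got), sum(p <= 0.05))
  }
})

test_that("partial correlation matches brute-force residualization and limits", {
  set.seed(6)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  Z <- data.frame(age = rnorm(30), gender = rbinom(30, 1, .5),
                  education = rnorm(30))
  pc <- partial_correlation(x, y, Z)
  expect_equal(pc$r, oracle_partial_cor(x, y, Z), tolerance = 1e-10)
  expect_identical(pc$df, 30L - 3L - 2L)
  # six-subject worked set against the oracle
  x6 <- c(1, 3, 2, 5, 4, 6); y6 <- c(2, 1, 4, 3, 6, 5)
  Z6 <- data.frame(c1 = c(1, 1, 2, 2, 3, 3))
  expect_equal(partial_correlation(x6, y6, Z6)$r,
               oracle_partial_cor(x6, y6, Z6), tolerance = 1e-10)
  # covariates orthogonal to x and y leave plain Pearson r unchanged
  xc <- x - mean(x); yc <- y - mean(y)
  zo <- stats::lm.fit(cbind(1, xc, yc), rnorm(30))$residuals
  expect_equal(partial_correlation(x, y, data.frame(z = zo))$r,
               cor(x, y), tolerance = 1e-10)
  expect_equal(partial_correlation(x, x, Z)$r, 1, tolerance = 1e-12)
  expect_error(partial_correlation(x, y, cbind(Z, age2 = Z$age * 2)),
               "rank deficient")
  expect_error(partial_correlation(rnorm(4), rnorm(4),
                                   data.frame(a = rnorm(4), b = rnorm(4))),
               "need n >")
})

make_edge_cohort <- function(n, base, delta_edges = NULL, delta = 0,
                             nodes = 20, sd = 0.05) {
  lapply(seq_len(n), function(i) {
    W <- base + matrix(rnorm(nodes^2, 0, sd), nodes)
    W <- (W + t(W)) / 2
    if (!is.null(delta_edges)) {
      for (e in seq_len(nrow(delta_edges))) {
        a <- delta_edges[e, 1]; b <- delta_edges[e, 2]
        W[a, b] <- W[a, b] - delta
        W[b, a] <- W[a, b]
      }
    }
    diag(W) <- 0
    W
  })
}

test_that("NBS finds a planted weakened chain and reports edge counts as sizes", {
  set.seed(7)
  nodes <- 20
  base <- matrix(0.5, nodes, nodes)
  chain <- cbind(1:3, 2:4)  # edges 1-2, 2-3, 3-4
  a <- make_edge_cohort(15, base, nodes = nodes)
  b <- make_edge_cohort(15, base, chain, delta = 0.2, nodes = nodes)
  # primary threshold 0.01 keeps the suprathreshold noise graph
  # subcritical (mean degree 0.01 * 19 << 1), so the planted component
  # stands out against the permutation null
  r <- nbs(a, b, primary_p = 0.01, n_perm = 500,
           direction = "decreased", seed = 8)
  top <- which.min(r$p_values)
  expect_lt(r$p_values[top], 0.05)
  got <- paste(r$components[[top]]$node_i, r$components[[top]]$node_j)
  expect_true(all(c("R1 R2", "R2 R3", "R3 R4") %in% got))
  # size counts connections (3 planted edges, at most a couple of
  # noise attachments), not the 4+ nodes spanned
  expect_identical(r$sizes[top], nrow(r$components[[top]]))
  expect_lte(r$sizes[top], 6L)
  # the increased direction must not flag the weakened chain
  ri <- nbs(a, b, primary_p = 0.01, n_perm = 200,
            direction = "increased", seed = 9)
  expect_true(!length(ri$sizes) || min(ri$p_values) > 0.05)
  # determinism
  r2 <- nbs(a, b, primary_p = 0.01, n_perm = 500,
            direction = "decreased", seed = 8)
  expect_identical(r$p_values, r2$p_values)
})

test_that("NBS on exchangeable groups yields no significant component", {
  set.seed(10)
  base <- matrix(0.5, 15, 15)
  a <- make_edge_cohort(12, base, nodes = 15)
  b <- make_edge_cohort(12, base, nodes = 15)
  r <- nbs(a, b, n_perm = 300, direction = "decreased", seed = 11)
  expect_true(!length(r$p_values) || min(r$p_values) > 0.05)
  expect_error(nbs(a[1], b, n_perm = 10), "at least 2")
})

test_that("compare_groups reports 7 global and 270 nodal tests with FDR flags", {
  set.seed(12)
  mk <- function(n) {
    gl <- matrix(rnorm(n * 7), n,
                 dimnames = list(NULL, c("Cp", "Lp", "Eglob", "Eloc",
                                         "gamma", "lambda", "sigma")))
    nd <- array(rnorm(n * 90 * 3),
                dim = c(n, 90, 3),
                dimnames = list(NULL, aal90_labels(),
                                c("betweenness", "degree", "efficiency")))
    list(global = gl, nodal = nd)
  }
  cmp <- compare_groups(mk(8), mk(8), n_perm = 99, seed = 13)
  expect_identical(nrow(cmp$global), 7L)
  expect_identical(nrow(cmp$nodal), 270L)
  expect_true(all(cmp$nodal$p > 0 & cmp$nodal$p <= 1))
  # per-metric FDR: flags match a direct BH pass within each metric
  for (m in unique(cmp$nodal$metric)) {
    i <- cmp$nodal$metric == m
    expect_identical(cmp$nodal$significant[i],
                     oracle_bh_reject(cmp$nodal$p[i], 0.05))
  }
  expect_identical(sort(cmp$altered_regions),
                   sort(unique(cmp$nodal$region[cmp$nodal$significant])))
})
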