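make_gaussian_features <- function(n_per_class, d, delta, seed) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * d), 2 * n_per_class, d)
  y <- rep(c("control", "patient"), each = n_per_class)
  x[y == "patient", seq_len(min(10, d))] <-
    x[y == "patient", seq_len(min(10, d))] + delta
  list(x = x, y = factor(y))
}

test_that("feature sets have the documented shapes and reject bad input", {
  co <- simulate_cohort(simulation_design(n_per_group = 2,
                                          voxels_per_region = 40,
                                          seed = 1))
  nets <- cohort_networks(co)
  fs <- feature_set(co$meta$group, networks = nets, kind = "matrix")
  expect_identical(dim(fs$x), c(4L, 4005L))
  expect_length(fs$region_map, 4005L)
  expect_true(all(lengths(fs$region_map) == 2L))
  au <- cohort_aucs(nets, n_null = 0)
  fs2 <- feature_set(co$meta$group,
                     aucs = list(global = au$global[, 1:4],
                                 nodal = au$nodal),
                     kind = "metrics")
  expect_identical(ncol(fs2$x), 4L + 270L)
  expect_identical(lengths(fs2$region_map)[1:4], rep(0L, 4))
  expect_error(feature_set(rep("a", 4), networks = nets, kind = "matrix"),
               "binary")
})

test_that("well-separated classes are classified almost perfectly", {
  g <- make_gaussian_features(20, 20, delta = 5, seed = 2)
  r <- nested_cv_svm(g$x, g$y, seed = 3)
  expect_gte(r$balanced_accuracy, 0.95)
  # balanced accuracy identity holds per fold, exactly
  expect_equal(r$folds$balanced_accuracy,
               (r$folds$sensitivity + r$folds$specificity) / 2)
})

test_that("fold assignment is stratified and seed-reproducible", {
  g <- make_gaussian_features(15, 10, delta = 1, seed = 4)
  r1 <- nested_cv_svm(g$x, g$y, seed = 5)
  r2 <- nested_cv_svm(g$x, g$y, seed = 5)
  expect_identical(r1$fold_assignment, r2$fold_assignment)
  expect_identical(r1$balanced_accuracy, r2$balanced_accuracy)
  tab <- table(r1$fold_assignment, g$y)
  expect_true(all(tab == 3))  # 15 per class over 5 folds
  expect_error(nested_cv_svm(g$x[c(1:2, 16:17), ], g$y[c(1:2, 16:17)]),
               "at least 5")
  expect_error(nested_cv_svm(g$x[1:6, ], g$y[1:6]), "two classes")
})

test_that("label-shuffled data scores near chance", {
  g <- make_gaussian_features(20, 20, delta = 5, seed = 6)
  set.seed(7)
  bas <- vapply(1:5, function(i)
    nested_cv_svm(g$x, sample(g$y))$balanced_accuracy, 0)
  expect_gt(mean(bas), 0.3)
  expect_lt(mean(bas), 0.7)
})

test_that("hyperparameter selection does not leak held-out information", {
  # pure high-dimensional noise: any leakage of test folds into scaling
  # or C selection would lift accuracy above chance
  set.seed(8)
  bas <- vapply(1:5, function(i) {
    x <- matrix(rnorm(40 * 500), 40)
    y <- factor(rep(c("a", "b"), 20))
    nested_cv_svm(x, y)$balanced_accuracy
  }, 0)
  expect_gt(mean(bas), 0.3)
  expect_lt(mean(bas), 0.7)
})

test_that("permutation significance: separable data at the floor, smoke mode works", {
  g <- make_gaussian_features(10, 15, delta = 5, seed = 9)
  r <- permutation_significance(g$x, g$y, n_perm = 10, seed = 10)
  expect_equal(r$permutation_p, 1 / 11)  # soft floor at 1/(n_perm+1)
  expect_length(r$perm_accuracies, 10L)
  r2 <- permutation_significance(g$x, g$y, n_perm = 10, add_one = TRUE,
                                 seed = 10)
  expect_equal(r2$permutation_p, 1 / 11)
})

test_that("region ranking recovers a planted informative region", {
  set.seed(11)
  n <- 15
  # metrics-kind features: only region 7's nodal features separate groups
  gl <- matrix(rnorm(2 * n * 7), 2 * n,
               dimnames = list(NULL, c("Cp", "Lp", "Eglob", "Eloc",
                                       "gamma", "lambda", "sigma")))
  nd <- array(rnorm(2 * n * 90 * 3), dim = c(2 * n, 90, 3),
              dimnames = list(NULL, aal90_labels(),
                              c("betweenness", "degree", "efficiency")))
  y <- rep(c("control", "patient"), each = n)
  nd[y == "patient", 7, ] <- nd[y == "patient", 7, ] + 4
  fs <- feature_set(y, aucs = list(global = gl, nodal = nd),
                    kind = "metrics")
  r <- nested_cv_svm(fs, seed = 12)
  rc <- region_contributions(r)
  expect_identical(nrow(rc), 20L)
  expect_identical(rc$region[1], aal90_labels()[7])
  expect_identical(rc$abbreviation[1], aal90_abbrev()[7])
  expect_error(region_contributions(r, k = 95), "exceeds")
})

test_that("degenerate all-zero weights are flagged", {
  fs <- structure(list(x = matrix(0, 4, 3), y = factor(c("a", "a", "b", "b")),
                       kind = "metrics",
                       region_map = list(1L, 2L, 3L),
                       node_labels = paste0("R", 1:3)),
                  class = "feature_set")
  fake <- structure(list(mean_abs_weight = c(0, 0, 0), features = fs),
                    class = "morph_svm")
  expect_warning(rc <- region_contributions(fake, k = 2), "degenerate")
  expect_true(attr(rc, "degenerate"))
})
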