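# ---- feature assembly ------------------------------------------------

#' Assemble a feature set for classification
#'
#' `"matrix"` features are the 4005 upper-triangle edge weights of each
#' subject's network; `"metrics"` features concatenate the 7 global AUC
#' values and the 3 x 90 nodal AUC values. A feature-to-region incidence
#' map is attached so SVM weights can be aggregated per region.
#'
#' @param networks list of `morph_network`s (for `kind = "matrix"`).
#' @param aucs a [cohort_aucs()]-shaped list (for `kind = "metrics"`).
#' @param labels factor or character vector of binary class labels.
#' @param kind `"matrix"` or `"metrics"`.
#' @return object of class `feature_set`: list with `x` (subjects x
#'   features), `y` (factor), `kind`, and `region_map` (list: per
#'   feature, the region indices it touches; global metrics map to
#'   none).
#' @export
feature_set <- function(labels, networks = NULL, aucs = NULL,
                        kind = c("matrix", "metrics")) {
  kind <- match.arg(kind)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must be binary")
  if (kind == "matrix") {
    stopifnot(!is.null(networks))
    W1 <- as_weight_matrix(networks[[1]])
    n <- nrow(W1)
    ut <- upper.tri(W1)
    pairs <- which(ut, arr.ind = TRUE)
    x <- t(vapply(networks, function(m) as_weight_matrix(m)[ut],
                  numeric(sum(ut))))
    colnames(x) <- paste0("e_", pairs[, 1], "_", pairs[, 2])
    region_map <- lapply(seq_len(nrow(pairs)), function(i)
      as.integer(pairs[i, ]))
    labels_n <- rownames(W1) %||% paste0("R", seq_len(n))
  } else {
    stopifnot(!is.null(aucs))
    gl <- aucs$global
    nd <- aucs$nodal
    n <- dim(nd)[2]
    x <- cbind(gl,
               do.call(cbind, lapply(dimnames(nd)[[3]], function(m) {
                 v <- nd[, , m]
                 colnames(v) <- paste0(m, "_", seq_len(n))
                 v
               })))
    region_map <- c(rep(list(integer()), ncol(gl)),
                    lapply(rep(seq_len(n), length(dimnames(nd)[[3]])),
                           identity))
    labels_n <- dimnames(nd)[[2]]
  }
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(list(x = as.matrix(x), y = y, kind = kind,
                 region_map = region_map, node_labels = labels_n),
            class = "feature_set")
}

# stratified k-fold assignment: within each class, shuffle then deal
# round-robin
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    i <- which(y == lev)
    fold[i[sample.int(length(i))]] <- rep_len(seq_len(k), length(i))
  }
  fold
}

# train-fold standardization; constant features get sd 1 so they stay
# inert rather than producing NaN
scale_params <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
apply_scale <- function(x, sp) sweep(sweep(x, 2, sp$mu), 2, sp$sd, "/")

fit_linear_svm <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
}

svm_weights <- function(fit) {
  as.numeric(t(fit$coefs) %*% fit$SV)
}

# The linear-SVM dual depends on the data only through the Gram matrix,
# so each training fold can be replaced by a Cholesky factor Z of its
# (jittered) Gram matrix: fitting on rows of Z reproduces the
# high-dimensional fit exactly while costing O(n^2) per model instead
# of O(n^2 d). Held-out rows are mapped into the same inner-product
# space via z_te = K_te,tr Z^-T.
gram_factor <- function(xtr) {
  K <- tcrossprod(xtr)
  eps <- 1e-8 * mean(diag(K)) + 1e-12
  Z <- t(chol(K + diag(eps, nrow(K))))
  Z
}
gram_embed <- function(xte, xtr, Z) {
  t(forwardsolve(Z, t(tcrossprod(xte, xtr))))
}

# sensitivity/specificity with the second factor level as "positive"
fold_rates <- function(truth, pred) {
  pos <- levels(truth)[2]; neg <- levels(truth)[1]
  sens <- mean(pred[truth == pos] == pos)
  spec <- mean(pred[truth == neg] == neg)
  c(sensitivity = sens, specificity = spec,
    balanced_accuracy = (sens + spec) / 2)
}

# ---- nested cross-validation ----------------------------------------

#' Linear-SVM classification with nested stratified cross-validation
#'
#' Five-fold stratified outer cross-validation; within each outer
#' training fold, features are z-scored (training statistics only) and
#' the soft-margin parameter C is chosen by an inner stratified
#' cross-validated grid search over `10^-3 .. 10^4`; a linear SVM with
#' the selected C is then fit on the training fold and evaluated on the
#' held-out fold. Reported sensitivity, specificity and balanced
#' accuracy (= their mean) are fold averages. The second factor level of
#' the labels is treated as the positive class.
#'
#' @param features a [feature_set()], or a plain numeric matrix (then
#'   `labels` must be given).
#' @param labels labels when `features` is a bare matrix.
#' @param C_grid candidate costs (default `10^(-3:4)`).
#' @param outer_k,inner_k fold counts (default 5 / 5).
#' @param seed optional RNG seed (controls fold assignment).
#' @return object of class `morph_svm`: fold-mean `balanced_accuracy`,
#'   `sensitivity`, `specificity`; per-fold table `folds`;
#'   `mean_abs_weight` per feature; `fold_assignment`.
#' @export
nested_cv_svm <- function(features, labels = NULL, C_grid = 10^(-3:4),
                          outer_k = 5L, inner_k = 5L, seed = NULL) {
  if (!inherits(features, "feature_set")) {
    features <- structure(list(x = as.matrix(features),
                               y = factor(labels), kind = "raw",
                               region_map = NULL, node_labels = NULL),
                          class = "feature_set")
  }
  x <- features$x; y <- features$y
  if (!length(C_grid)) stop("C grid must be non-empty")
  if (nlevels(droplevels(y)) != 2L)
    stop("labels must contain exactly two classes")
  if (min(table(y)) < outer_k)
    stop("need at least ", outer_k, " subjects per class")
  if (!is.null(seed)) set.seed(seed)
  fold <- stratified_folds(y, outer_k)
  per_fold <- matrix(NA_real_, outer_k, 3,
                     dimnames = list(NULL, c("sensitivity", "specificity",
                                             "balanced_accuracy")))
  best_C <- numeric(outer_k)
  wsum <- numeric(ncol(x))
  for (f in seq_len(outer_k)) {
    tr <- fold != f; te <- !tr
    sp <- scale_params(x[tr, , drop = FALSE])
    xtr <- apply_scale(x[tr, , drop = FALSE], sp)
    xte <- apply_scale(x[te, , drop = FALSE], sp)
    ytr <- droplevels(y[tr])
    Z <- gram_factor(xtr)
    zte <- gram_embed(xte, xtr, Z)
    ik <- min(inner_k, min(table(ytr)))  # every inner fold non-empty
    inner <- stratified_folds(ytr, ik)
    cv_ba <- vapply(C_grid, function(C) {
      mean(vapply(seq_len(ik), function(g) {
        it <- inner != g
        fit <- fit_linear_svm(Z[it, , drop = FALSE], ytr[it], C)
        fold_rates(ytr[!it],
                   predict(fit, Z[!it, , drop = FALSE]))[["balanced_accuracy"]]
      }, 0))
    }, 0)
    C <- C_grid[which.max(cv_ba)]  # ties resolve to the smallest C
    best_C[f] <- C
    fit <- fit_linear_svm(Z, ytr, C)
    per_fold[f, ] <- fold_rates(y[te], predict(fit, zte))
    # dual coefficients transfer to the original feature space
    wsum <- wsum + abs(as.numeric(t(fit$coefs) %*%
                                    xtr[fit$index, , drop = FALSE]))
  }
  res <- colMeans(per_fold)
  structure(list(balanced_accuracy = unname(res["balanced_accuracy"]),
                 sensitivity = unname(res["sensitivity"]),
                 specificity = unname(res["specificity"]),
                 folds = as.data.frame(per_fold),
                 best_C = best_C,
                 mean_abs_weight = wsum / outer_k,
                 fold_assignment = fold,
                 features = features),
            class = "morph_svm")
}

#' @export
print.morph_svm <- function(x, ...) {
  cat("Linear SVM, nested stratified cross-validation\n")
  cat(sprintf("  balanced accuracy %.1f%% (sensitivity %.1f%%, specificity %.1f%%)\n",
              100 * x$balanced_accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  cat("  selected C per fold:", format(x$best_C, trim = TRUE), "\n")
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d label permutations)\n",
                x$permutation_p, x$n_perm))
  invisible(x)
}

#' Permutation significance of a classification accuracy
#'
#' Repeats the full nested cross-validation with randomly permuted
#' labels. The default estimator divides the number of permutations
#' whose balanced accuracy exceeds the real one by `n_perm`, with a soft
#' floor of `1/(n_perm + 1)`; `add_one = TRUE` uses
#' `(1 + #{perm >= real}) / (n_perm + 1)` instead.
#'
#' @inheritParams nested_cv_svm
#' @param n_perm label permutations (default 1000; small values are
#'   fine for smoke testing).
#' @param add_one use the add-one estimator.
#' @return the real-label `morph_svm` result with `permutation_p`,
#'   `n_perm` and `perm_accuracies` attached.
#' @export
permutation_significance <- function(features, labels = NULL,
                                     n_perm = 1000L, add_one = FALSE,
                                     C_grid = 10^(-3:4), outer_k = 5L,
                                     inner_k = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  real <- nested_cv_svm(features, labels, C_grid = C_grid,
                        outer_k = outer_k, inner_k = inner_k)
  fs <- real$features
  perm_ba <- vapply(seq_len(n_perm), function(i) {
    fp <- fs
    fp$y <- fs$y[sample.int(length(fs$y))]
    nested_cv_svm(fp, C_grid = C_grid, outer_k = outer_k,
                  inner_k = inner_k)$balanced_accuracy
  }, 0)
  p <- if (add_one) {
    (1 + sum(perm_ba >= real$balanced_accuracy)) / (n_perm + 1)
  } else {
    max(sum(perm_ba > real$balanced_accuracy) / n_perm, 1 / (n_perm + 1))
  }
  real$permutation_p <- p
  real$n_perm <- as.integer(n_perm)
  real$perm_accuracies <- perm_ba
  real
}

#' Region contributions to the classifier
#'
#' Ranks brain regions by the fold-averaged absolute SVM weights. For
#' metric features each nodal feature maps to its region (global
#' features carry no region); for matrix features the mean absolute
#' weights of all edges incident to a region are summed.
#'
#' @param result a `morph_svm` trained on a [feature_set()].
#' @param k number of regions reported (default 20, at most the number
#'   of nodes).
#' @return data.frame with `rank`, `region`, `abbreviation` (when the
#'   nodes are the AAL-90 set) and `score`; carries attribute
#'   `degenerate = TRUE` when all weights are zero.
#' @export
region_contributions <- function(result, k = 20L) {
  stopifnot(inherits(result, "morph_svm"))
  fs <- result$features
  if (is.null(fs$region_map))
    stop("result was not trained on a feature_set with a region map")
  n <- length(fs$node_labels)
  if (k > n) stop("k exceeds the number of regions")
  w <- result$mean_abs_weight
  score <- numeric(n)
  for (i in seq_along(w)) {
    r <- fs$region_map[[i]]
    if (length(r)) score[r] <- score[r] + w[i]
  }
  degenerate <- all(w == 0)
  if (degenerate)
    warning("all SVM weights are zero; ranking is degenerate")
  ord <- order(-score, seq_len(n))[seq_len(k)]
  out <- data.frame(rank = seq_len(k), region = fs$node_labels[ord],
                    score = score[ord], stringsAsFactors = FALSE)
  if (identical(fs$node_labels, aal90_labels()))
    out$abbreviation <- aal90_abbrev()[ord]
  attr(out, "degenerate") <- degenerate
  out
}
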