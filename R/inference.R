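# ---- permutation test and effect size -------------------------------

#' Two-sample permutation test on a difference of means
#'
#' Statistic: `mean(a) - mean(b)`. Two-tailed p with add-one
#' correction: `(1 + #{permuted |diff| >= observed |diff|}) / (n_perm + 1)`,
#' from seeded random label shuffles, so p is never exactly 0.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param n_perm number of label permutations (default 5000).
#' @param seed optional RNG seed.
#' @return list with `diff` (observed difference) and `p`.
#' @export
permutation_test <- function(a, b, n_perm = 5000L, seed = NULL) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  na <- length(a)
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  tot <- sum(pooled)
  exceed <- 0L
  thr <- abs(obs) - 1e-12
  for (i in seq_len(n_perm)) {
    ia <- sample.int(length(pooled), na)
    sa <- sum(pooled[ia])
    d <- sa / na - (tot - sa) / (length(pooled) - na)
    if (abs(d) >= thr) exceed <- exceed + 1L
  }
  list(diff = obs, p = (1 + exceed) / (n_perm + 1))
}

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' @param a,b numeric vectors.
#' @return `(mean(a) - mean(b)) / pooled SD`.
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))  # -1
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control at level `q`; returns adjusted values and
#' significance flags.
#'
#' @param p_values numeric vector of p-values.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` and `significant` (logical).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  adj <- p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= q)
}

# ---- partial correlation --------------------------------------------

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares regression on the covariates (with intercept); p-value
#' from the t distribution with `n - n_covariates - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of covariates (may have zero
#'   columns, giving the plain Pearson correlation).
#' @return list with `r`, `p`, `df` and `covariates` (names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    Z <- matrix(1, n, 1)
    k <- 0L
    cn <- character()
  } else {
    covariates <- as.matrix(as.data.frame(covariates))
    Z <- cbind(1, covariates)
    k <- ncol(covariates)
    cn <- colnames(covariates)
    if (qr(Z)$rank < ncol(Z)) stop("covariates are rank deficient")
  }
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant after covariate adjustment; correlation undefined")
  r <- cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, p = p, df = df, covariates = cn)
}

# ---- network-based statistic ----------------------------------------

# vectorized pooled-variance two-sample t statistics over edge columns
edge_t_stats <- function(X, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  Xa <- X[idx_a, , drop = FALSE]; Xb <- X[idx_b, , drop = FALSE]
  ma <- colMeans(Xa); mb <- colMeans(Xb)
  va <- (colSums(Xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(Xb^2) - nb * mb^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[se == 0] <- 0
  tt
}

# connected components of a set of suprathreshold edges; returns a list
# of integer edge-index vectors and the max component size (edge count)
edge_components <- function(edge_idx, pairs, n_nodes) {
  if (!length(edge_idx))
    return(list(components = list(), max_size = 0L))
  g <- igraph::graph_from_edgelist(pairs[edge_idx, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[pairs[edge_idx, 1]]
  comps <- split(edge_idx, comp_of_edge)
  sizes <- lengths(comps)
  list(components = unname(comps), max_size = max(sizes))
}

#' Network-based statistic (NBS)
#'
#' Localizes altered connections between two groups of weighted
#' networks. Per edge, a pooled-variance two-sample t-test in the stated
#' direction is thresholded at the one-tailed `primary_p` critical
#' value; connected components of the suprathreshold edges are measured
#' by their number of connections; their family-wise-corrected p-values
#' come from the permutation null distribution of the maximal component
#' size: `p = #{permutations with max component >= N} / n_perm`.
#'
#' @param mats_a,mats_b lists of symmetric weight matrices (e.g.
#'   `morph_network$weights`), one per subject.
#' @param primary_p one-tailed edge-level threshold (default 0.05).
#' @param n_perm label permutations (default 5000).
#' @param direction `"decreased"` tests group b < group a,
#'   `"increased"` tests group b > group a.
#' @param seed optional RNG seed.
#' @return object of class `nbs_result`: list with `direction`,
#'   `components` (list of data.frames: node_i, node_j, t), `sizes`,
#'   `p_values` (corrected), `primary_threshold`, `null_max`.
#' @export
nbs <- function(mats_a, mats_b, primary_p = 0.05, n_perm = 5000L,
                direction = c("decreased", "increased"), seed = NULL) {
  direction <- match.arg(direction)
  if (length(mats_a) < 2L || length(mats_b) < 2L)
    stop("each group needs at least 2 subjects")
  if (!is.null(seed)) set.seed(seed)
  get_w <- function(m) as_weight_matrix(m)
  n_nodes <- nrow(get_w(mats_a[[1]]))
  labels <- rownames(get_w(mats_a[[1]])) %||% paste0("R", seq_len(n_nodes))
  ut <- upper.tri(matrix(0, n_nodes, n_nodes))
  pairs <- which(ut, arr.ind = TRUE)
  X <- t(vapply(c(mats_a, mats_b), function(m) get_w(m)[ut],
                numeric(sum(ut))))
  na <- length(mats_a); nb <- length(mats_b); nt <- na + nb
  # decreased: b < a  <=>  t = (mean_a - mean_b)/se large positive
  sgn <- if (direction == "decreased") 1 else -1
  df <- nt - 2L
  t_crit <- qt(1 - primary_p, df)

  t_obs <- sgn * edge_t_stats(X, seq_len(na), na + seq_len(nb))
  obs <- edge_components(which(t_obs > t_crit), pairs, n_nodes)

  null_max <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    ia <- sample.int(nt, na)
    tp <- sgn * edge_t_stats(X, ia, setdiff(seq_len(nt), ia))
    null_max[b] <- edge_components(which(tp > t_crit), pairs,
                                   n_nodes)$max_size
  }
  sizes <- lengths(obs$components)
  p_vals <- vapply(sizes, function(N) sum(null_max >= N) / n_perm, 0)
  comps <- lapply(obs$components, function(ei)
    data.frame(node_i = labels[pairs[ei, 1]],
               node_j = labels[pairs[ei, 2]],
               t = abs(t_obs[ei]),
               stringsAsFactors = FALSE))
  structure(list(direction = direction, components = comps,
                 sizes = as.integer(sizes), p_values = p_vals,
                 primary_threshold = primary_p, t_critical = t_crit,
                 null_max = null_max),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, alpha = 0.05, ...) {
  cat(sprintf("NBS (%s direction), edge threshold p < %.3g, %d permutations\n",
              x$direction, x$primary_threshold, length(x$null_max)))
  if (!length(x$sizes)) {
    cat("  no suprathreshold components\n")
    return(invisible(x))
  }
  ord <- order(x$p_values, -x$sizes)
  for (i in ord) {
    cat(sprintf("  component of %d connection(s), corrected p = %.4f%s\n",
                x$sizes[i], x$p_values[i],
                if (x$p_values[i] < alpha) " *" else ""))
  }
  invisible(x)
}

# ---- cohort-level comparison report ---------------------------------

#' Compare groups on global and nodal AUC metrics
#'
#' Applies the permutation test and Cohen's d to the 7 global AUC
#' metrics and to the 3 x n_node nodal AUC metrics; nodal p-values get
#' Benjamini-Hochberg correction within each metric (or pooled, if
#' `fdr_scope = "pooled"`). A region is flagged "altered" when
#' significant in at least one of the three nodal metrics after FDR.
#'
#' @param aucs_a,aucs_b per-group AUC summaries: lists with `global`
#'   (subjects x 7 matrix) and `nodal` (subjects x n_node x 3 array) —
#'   the shape produced by [cohort_aucs()].
#' @param n_perm permutations per test (default 5000).
#' @param seed optional RNG seed.
#' @param q FDR level.
#' @param fdr_scope `"per_metric"` (default) or `"pooled"` (all 270
#'   nodal tests together).
#' @return object of class `group_comparison`: list with data.frames
#'   `global` (metric, diff, p, d) and `nodal` (region, metric, diff, p,
#'   q, significant, d), plus `altered_regions`.
#' @export
compare_groups <- function(aucs_a, aucs_b, n_perm = 5000L, seed = NULL,
                           q = 0.05,
                           fdr_scope = c("per_metric", "pooled")) {
  fdr_scope <- match.arg(fdr_scope)
  if (!is.null(seed)) set.seed(seed)
  gm <- colnames(aucs_a$global)
  global <- do.call(rbind, lapply(seq_along(gm), function(j) {
    a <- aucs_a$global[, j]; b <- aucs_b$global[, j]
    pt_ <- permutation_test(a, b, n_perm = n_perm)
    data.frame(metric = gm[j], diff = pt_$diff, p = pt_$p,
               d = cohens_d(a, b), stringsAsFactors = FALSE)
  }))

  nm <- dimnames(aucs_a$nodal)[[3]]
  regions <- dimnames(aucs_a$nodal)[[2]]
  nodal <- do.call(rbind, lapply(nm, function(m) {
    do.call(rbind, lapply(seq_along(regions), function(r) {
      a <- aucs_a$nodal[, r, m]; b <- aucs_b$nodal[, r, m]
      pt_ <- permutation_test(a, b, n_perm = n_perm)
      data.frame(region = regions[r], metric = m, diff = pt_$diff,
                 p = pt_$p, d = cohens_d(a, b), stringsAsFactors = FALSE)
    }))
  }))
  if (fdr_scope == "per_metric") {
    nodal$q <- NA_real_
    for (m in nm) {
      i <- nodal$metric == m
      nodal$q[i] <- fdr_correct(nodal$p[i], q)$adjusted
    }
  } else {
    nodal$q <- fdr_correct(nodal$p, q)$adjusted
  }
  nodal$significant <- nodal$q <= q
  altered <- sort(unique(nodal$region[nodal$significant]))
  structure(list(global = global, nodal = nodal,
                 altered_regions = altered, q = q, n_perm = n_perm),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison (%d permutations per test)\n", x$n_perm))
  cat("Global AUC metrics:\n")
  g <- x$global; g$diff <- round(g$diff, 4)
  g$p <- round(g$p, 4); g$d <- round(g$d, 3)
  print(g, row.names = FALSE)
  ns <- sum(x$nodal$significant)
  cat(sprintf("Nodal tests: %d of %d significant after FDR (q <= %.2f)\n",
              ns, nrow(x$nodal), x$q))
  if (length(x$altered_regions))
    cat("Altered regions:", paste(x$altered_regions, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.group_comparison <- function(object, ...) {
  sig <- object$nodal[object$nodal$significant, ]
  sig <- sig[order(sig$q), ]
  list(global = object$global, significant_nodal = sig,
       altered_regions = object$altered_regions)
}
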