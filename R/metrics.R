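# ---- thresholding ---------------------------------------------------

#' Threshold a weighted network at a given sparsity
#'
#' Retains the `K = round(S * n(n-1)/2)` strongest off-diagonal edges
#' (round-half-even, R's default rounding), keeping their weights. Ties
#' in weight are broken deterministically by ascending node-index pair.
#'
#' @param net a `morph_network`, or a symmetric weight matrix.
#' @param S sparsity: fraction of possible edges retained, in (0, 1].
#' @return an object of class `thresholded_graph`: list with
#'   `sparsity`, `K`, and `adjacency` (symmetric weighted matrix).
#' @examples
#' W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- 0
#' threshold_by_sparsity(W, 0.5)$K  # round(0.5 * 10) = 5
#' @export
threshold_by_sparsity <- function(net, S) {
  W <- as_weight_matrix(net)
  if (!is.numeric(S) || length(S) != 1L || S <= 0 || S > 1)
    stop("sparsity S must lie in (0, 1]")
  n <- nrow(W)
  idx <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[upper.tri(W)]
  K <- round(S * nrow(idx))
  A <- matrix(0, n, n, dimnames = dimnames(W))
  if (K > 0) {
    keep <- order(-w, idx[, 1], idx[, 2])[seq_len(K)]
    ii <- idx[keep, , drop = FALSE]
    A[ii] <- w[keep]
    A[ii[, c(2, 1), drop = FALSE]] <- w[keep]
  }
  structure(list(sparsity = S, K = as.integer(K), adjacency = A),
            class = "thresholded_graph")
}

as_weight_matrix <- function(x) {
  if (inherits(x, "morph_network")) x <- x$weights
  if (inherits(x, "thresholded_graph")) x <- x$adjacency
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("weight matrix must be square")
  if (max(abs(x - t(x))) > 1e-8) stop("weight matrix must be symmetric")
  diag(x) <- 0
  x
}

as_igraph <- function(x) {
  W <- as_weight_matrix(x)
  el <- edge_list(W)
  g <- if (nrow(el$pairs)) {
    igraph::graph_from_edgelist(el$pairs, directed = FALSE)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  g <- igraph::add_vertices(g, nrow(W) - igraph::vcount(g))
  igraph::E(g)$weight <- el$w
  g
}

# upper-triangle edge list of the positive entries
edge_list <- function(W) {
  keep <- W > 0 & upper.tri(W)
  pairs <- which(keep, arr.ind = TRUE)
  list(pairs = pairs, w = W[keep])
}

# edge lengths for path-based metrics: reciprocal weight (similarity ->
# distance); binary mode treats every retained edge as length 1
edge_lengths <- function(g, mode) {
  w <- igraph::E(g)$weight
  if (identical(mode, "binary")) rep(1, length(w)) else 1 / w
}

# ---- clustering -----------------------------------------------------

#' Clustering coefficient (binary formula or Onnela weighted variant)
#'
#' Binary mode implements \eqn{C_p = (1/n) \sum_i 2 t_i / (k_i (k_i - 1))}
#' with \eqn{t_i} the number of triangles around node i and \eqn{k_i} its
#' degree; nodes with fewer than two neighbours contribute 0. Weighted
#' mode is the Onnela generalization: \eqn{t_i} is replaced by the sum of
#' geometric means of triangle edge weights, after scaling weights by
#' their maximum.
#'
#' @param g a `thresholded_graph`, `morph_network`, or symmetric matrix.
#' @param mode `"weighted"` (default) or `"binary"`.
#' @return list with `nodal` (per-node coefficients) and `mean` (Cp).
#' @export
clustering_coefficient <- function(g, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(g)
  A <- (W > 0) + 0
  k <- rowSums(A)
  if (mode == "binary") {
    t2 <- diag(A %*% A %*% A)  # 2 * triangles * ... = 2 t_i
  } else {
    mw <- max(W)
    W13 <- if (mw > 0) (W / mw)^(1 / 3) else W
    t2 <- diag(W13 %*% W13 %*% W13)
  }
  nodal <- ifelse(k < 2, 0, t2 / (k * (k - 1)))
  list(nodal = as.numeric(nodal), mean = mean(nodal))
}

# ---- paths and efficiencies -----------------------------------------

#' Characteristic path length, global efficiency, nodal efficiency
#'
#' Shortest paths use Dijkstra on reciprocal-weight edge lengths
#' (binary mode: unit lengths). `Lp` averages distances over connected
#' ordered pairs; disconnected pairs are excluded from `Lp` and
#' contribute 0 to the efficiencies.
#'
#' @inheritParams clustering_coefficient
#' @return list with `Lp`, `Eglob` and `nodal_efficiency` (length-n).
#' @export
path_length_and_efficiency <- function(g, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(g)
  n <- nrow(W)
  if (n == 0L) stop("empty graph")
  ig <- as_igraph(W)
  d <- igraph::distances(ig, weights = edge_lengths(ig, mode),
                         algorithm = "dijkstra")
  diag(d) <- Inf                      # drop self-pairs
  finite <- is.finite(d)
  Lp <- if (any(finite)) mean(d[finite]) else NA_real_
  inv <- ifelse(finite, 1 / d, 0)
  Eglob <- if (n > 1) sum(inv) / (n * (n - 1)) else 0
  nodal <- if (n > 1) rowSums(inv) / (n - 1) else 0
  list(Lp = Lp, Eglob = Eglob, nodal_efficiency = as.numeric(nodal))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbourhood
#' subgraph (the node itself removed); nodes with fewer than two
#' neighbours contribute 0.
#'
#' @inheritParams clustering_coefficient
#' @return list with `nodal` and `mean` (Eloc).
#' @export
local_efficiency <- function(g, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(g)
  n <- nrow(W)
  el <- edge_list(W)
  nodal <- .local_efficiency_cpp(el$pairs[, 1], el$pairs[, 2], el$w,
                                 n, identical(mode, "weighted"))
  list(nodal = as.numeric(nodal), mean = mean(nodal))
}

#' Nodal betweenness centrality
#'
#' Brandes shortest-path betweenness on reciprocal-weight edge lengths,
#' unnormalized.
#'
#' @inheritParams clustering_coefficient
#' @return numeric vector of per-node betweenness values.
#' @export
nodal_betweenness <- function(g, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  ig <- as_igraph(g)
  as.numeric(igraph::betweenness(ig, weights = edge_lengths(ig, mode),
                                 normalized = FALSE))
}

#' Nodal degree / strength
#'
#' @inheritParams clustering_coefficient
#' @return numeric vector: binary mode counts retained incident edges;
#'   weighted mode sums their weights (strength).
#' @export
nodal_degree <- function(g, mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(g)
  if (mode == "binary") rowSums(W > 0) else rowSums(W)
}

# ---- random references ----------------------------------------------

#' Degree-preserving rewired null network
#'
#' Rewires the topology with Maslov-Sneppen double-edge swaps
#' (`nswap_factor * |E|` attempted swaps); each accepted swap exchanges
#' edge endpoints and the weights travel with their edges. Node count,
#' edge count, degree sequence and the multiset of edge weights are
#' preserved exactly. Driven by R's RNG, so `set.seed()` makes it
#' reproducible.
#'
#' @inheritParams clustering_coefficient
#' @param nswap_factor attempted swaps per edge (default 10).
#' @return a symmetric weighted adjacency matrix.
#' @export
rewire_network <- function(g, nswap_factor = 10) {
  W <- as_weight_matrix(g)
  el <- edge_list(W)
  m <- length(el$w)
  if (m < 2L) stop("too few edges to rewire")
  rw <- .ms_swap_cpp(el$pairs[, 1], el$pairs[, 2], el$w, nrow(W),
                     as.integer(nswap_factor * m))
  A <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  A[cbind(rw$i, rw$j)] <- rw$w
  A[cbind(rw$j, rw$i)] <- rw$w
  A
}

#' Null-model reference values for small-world normalization
#'
#' Averages Cp and Lp over `n_null` degree-preserving rewired networks
#' (see [rewire_network()]).
#'
#' @inheritParams clustering_coefficient
#' @param n_null number of null networks (default 100).
#' @param seed optional RNG seed.
#' @param nswap_factor attempted swaps per edge.
#' @return list with `Cp_random` and `Lp_random` (null means).
#' @export
random_reference <- function(g, n_null = 100L, seed = NULL,
                             mode = c("weighted", "binary"),
                             nswap_factor = 10) {
  mode <- match.arg(mode)
  if (n_null < 1L) stop("n_null must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  W <- as_weight_matrix(g)
  el <- edge_list(W)
  if (length(el$w) < 2L) stop("too few edges to rewire")
  st <- .null_reference_cpp(el$pairs[, 1], el$pairs[, 2], el$w,
                            nrow(W), as.integer(n_null),
                            as.integer(nswap_factor * length(el$w)),
                            identical(mode, "weighted"))
  list(Cp_random = st[1], Lp_random = st[2])
}

#' Small-world indices
#'
#' Elementwise normalized clustering `gamma = Cp / Cp_random`,
#' normalized path length `lambda = Lp / Lp_random`, and small-worldness
#' `sigma = gamma / lambda`.
#'
#' @param Cp,Lp observed values (scalars or curves).
#' @param Cp_random,Lp_random null-model references.
#' @return list with `gamma`, `lambda`, `sigma`.
#' @export
small_world_indices <- function(Cp, Lp, Cp_random, Lp_random) {
  gamma <- Cp / Cp_random
  lambda <- Lp / Lp_random
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}

# ---- curves over sparsities -----------------------------------------

#' Graph metrics across a sparsity range
#'
#' Thresholds a network at each sparsity and computes the seven global
#' metrics (Cp, Lp, Eglob, Eloc, gamma, lambda, sigma) and the three
#' nodal metrics (betweenness, degree, efficiency). gamma/lambda/sigma
#' use `n_null` degree-preserving rewired references per sparsity; set
#' `n_null = 0` to skip them (they are then NA).
#'
#' @param net a `morph_network` or weight matrix.
#' @param sparsities sparsity grid (default 0.10-0.34, step 0.01).
#' @param mode `"weighted"` (default) or `"binary"`.
#' @param n_null null networks per sparsity (default 100).
#' @param seed optional RNG seed for the null ensemble.
#' @return object of class `metric_curves`: list with `sparsities`,
#'   `global` (7 x n_sparsity matrix) and `nodal` (list of three
#'   n_node x n_sparsity matrices).
#' @export
network_metrics <- function(net, sparsities = seq(0.10, 0.34, by = 0.01),
                            mode = c("weighted", "binary"),
                            n_null = 100L, seed = NULL) {
  mode <- match.arg(mode)
  W <- as_weight_matrix(net)
  if (!is.null(seed)) set.seed(seed)
  nS <- length(sparsities)
  n <- nrow(W)
  gl <- matrix(NA_real_, 7, nS,
               dimnames = list(c("Cp", "Lp", "Eglob", "Eloc",
                                 "gamma", "lambda", "sigma"), NULL))
  nodal <- list(betweenness = matrix(0, n, nS, dimnames = list(rownames(W), NULL)),
                degree      = matrix(0, n, nS, dimnames = list(rownames(W), NULL)),
                efficiency  = matrix(0, n, nS, dimnames = list(rownames(W), NULL)))
  for (s in seq_len(nS)) {
    tg <- threshold_by_sparsity(W, sparsities[s])
    cc <- clustering_coefficient(tg, mode = mode)
    pe <- path_length_and_efficiency(tg, mode = mode)
    le <- local_efficiency(tg, mode = mode)
    gl["Cp", s] <- cc$mean
    gl["Lp", s] <- pe$Lp
    gl["Eglob", s] <- pe$Eglob
    gl["Eloc", s] <- le$mean
    nodal$betweenness[, s] <- nodal_betweenness(tg, mode = mode)
    nodal$degree[, s] <- nodal_degree(tg, mode = mode)
    nodal$efficiency[, s] <- pe$nodal_efficiency
    if (n_null > 0) {
      rr <- random_reference(tg, n_null = n_null, mode = mode)
      sw <- small_world_indices(cc$mean, pe$Lp, rr$Cp_random, rr$Lp_random)
      gl["gamma", s] <- sw$gamma
      gl["lambda", s] <- sw$lambda
      gl["sigma", s] <- sw$sigma
    }
  }
  structure(list(sparsities = sparsities, global = gl, nodal = nodal,
                 mode = mode),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat(sprintf("Graph-metric curves over %d sparsities [%.2f, %.2f] (%s mode)\n",
              length(x$sparsities), min(x$sparsities), max(x$sparsities),
              x$mode))
  print(round(x$global[, c(1, ncol(x$global))], 3))
  invisible(x)
}

#' @export
plot.metric_curves <- function(x, metrics = rownames(x$global), ...) {
  metrics <- intersect(metrics, rownames(x$global))
  old <- graphics::par(mfrow = c(ceiling(length(metrics) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    graphics::plot(x$sparsities, x$global[m, ], type = "b", pch = 16,
                   xlab = "sparsity", ylab = m, main = m, ...)
  }
  invisible(x)
}

# ---- AUC, sparsity selection, hubs ----------------------------------

#' Area under a metric curve over the sparsity window
#'
#' Trapezoidal integral of a metric-versus-sparsity curve; the standard
#' threshold-free summary scalar.
#'
#' @param values metric values, one per sparsity.
#' @param sparsities strictly increasing sparsity grid (>= 2 points).
#' @return scalar AUC.
#' @examples
#' metric_auc(rep(2, 25), seq(0.10, 0.34, 0.01))  # 0.24 * 2
#' @export
metric_auc <- function(values, sparsities) {
  if (length(values) != length(sparsities) || length(values) < 2L)
    stop("AUC needs at least two curve points")
  h <- diff(sparsities)
  sum(h * (head(values, -1) + values[-1]) / 2)
}

#' AUC summaries of a `metric_curves` object
#' @param curves a [network_metrics()] result.
#' @return list with `global` (named length-7 vector) and `nodal`
#'   (n_node x 3 matrix with columns betweenness, degree, efficiency).
#' @export
curves_auc <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  s <- curves$sparsities
  global <- apply(curves$global, 1, metric_auc, sparsities = s)
  nodal <- sapply(curves$nodal, function(m)
    apply(m, 1, metric_auc, sparsities = s))
  list(global = global, nodal = nodal)
}

#' Select an admissible sparsity range
#'
#' Finds the smallest and largest sparsity on the candidate grid such
#' that, for every subject, (a) the mean nodal degree of the thresholded
#' network exceeds `2 * ln(n)` and (b) small-worldness sigma exceeds
#' `sigma_min`. The mean binary degree of a sparsity-thresholded n-node
#' network is `2 * round(S * n(n-1)/2) / n`, so criterion (a) is closed
#' form; criterion (b) requires null references per subject (skip it
#' with `sigma_min = 0`).
#'
#' @param networks list of `morph_network`s (or weight matrices).
#' @param candidates candidate sparsity grid.
#' @param degree_rule mean-degree lower bound; default `2 * log(n)`
#'   (natural log).
#' @param sigma_min small-worldness lower bound (default 1.1).
#' @param n_null,seed,mode passed to the sigma computation.
#' @return list with `S_lo`, `S_hi`, and the admissible grid values.
#' @export
select_sparsity_range <- function(networks,
                                  candidates = seq(0.05, 0.50, by = 0.01),
                                  degree_rule = NULL, sigma_min = 1.1,
                                  n_null = 100L, seed = NULL,
                                  mode = "weighted") {
  if (!length(networks)) stop("need at least one subject network")
  n <- nrow(as_weight_matrix(networks[[1]]))
  if (is.null(degree_rule)) degree_rule <- 2 * log(n)
  M <- n * (n - 1) / 2
  deg_ok <- (2 * round(candidates * M) / n) > degree_rule
  ok <- deg_ok
  if (sigma_min > 0) {
    if (!is.null(seed)) set.seed(seed)
    for (s in which(deg_ok)) {
      for (net in networks) {
        tg <- threshold_by_sparsity(net, candidates[s])
        cc <- clustering_coefficient(tg, mode = mode)$mean
        lp <- path_length_and_efficiency(tg, mode = mode)$Lp
        rr <- random_reference(tg, n_null = n_null, mode = mode)
        sig <- small_world_indices(cc, lp, rr$Cp_random, rr$Lp_random)$sigma
        if (!is.finite(sig) || sig <= sigma_min) { ok[s] <- FALSE; break }
      }
    }
  }
  if (!any(ok)) stop("no admissible sparsity on the candidate grid")
  list(S_lo = min(candidates[ok]), S_hi = max(candidates[ok]),
       admissible = candidates[ok])
}

#' Hub scores from group-mean nodal AUC values
#'
#' For each of the three nodal metrics, flags the top 10% of nodes
#' (9 of 90); a node's hub score (0-3) counts the metrics in which it is
#' flagged. Ties at the cutoff rank are broken by ascending node index.
#'
#' @param nodal_aucs n_node x 3 matrix of group-mean nodal AUC values
#'   (columns betweenness, degree, efficiency).
#' @param top_frac fraction of nodes flagged per metric (default 0.10).
#' @param hub_min minimum hub score for the `is_hub` flag (default 2).
#' @param labels optional node labels.
#' @return data.frame with per-metric flags, `hub_score` and `is_hub`.
#' @export
hub_scores <- function(nodal_aucs, top_frac = 0.10, hub_min = 2L,
                       labels = rownames(nodal_aucs)) {
  nodal_aucs <- as.matrix(nodal_aucs)
  n <- nrow(nodal_aucs)
  k <- max(1L, round(top_frac * n))
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  flags <- apply(nodal_aucs, 2, function(v) {
    top <- order(-v, seq_len(n))[seq_len(k)]
    seq_len(n) %in% top
  })
  score <- rowSums(flags)
  out <- data.frame(region = labels, flags + 0,
                    hub_score = as.integer(score),
                    is_hub = score >= hub_min,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
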