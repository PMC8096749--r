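# Independent brute-force oracles. These deliberately avoid every code
# path used by the package: divergences by naive elementwise loops,
# distances by Floyd-Warshall, triangles by triple loops, betweenness
# by path counting on the Floyd-Warshall tableau.

oracle_kls <- function(p, q, eps = 1e-10) {
  p <- pmax(p, eps); p <- p / sum(p)
  q <- pmax(q, eps); q <- q / sum(q)
  d <- 0
  for (i in seq_along(p)) {
    d <- d + p[i] * log(p[i] / q[i]) + q[i] * log(q[i] / p[i])
  }
  exp(-d)
}

# all-pairs shortest path lengths by Floyd-Warshall; edge length 1/w
# (binary: 1)
oracle_fw <- function(W, mode = "weighted") {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0)
      D[i, j] <- if (mode == "binary") 1 else 1 / W[i, j]
  }
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_path_metrics <- function(W, mode = "weighted") {
  n <- nrow(W)
  D <- oracle_fw(W, mode)
  diag(D) <- Inf
  fin <- is.finite(D)
  Lp <- if (any(fin)) mean(D[fin]) else NA_real_
  inv <- ifelse(fin, 1 / D, 0)
  list(Lp = Lp,
       Eglob = sum(inv) / (n * (n - 1)),
       nodal_efficiency = rowSums(inv) / (n - 1))
}

# binary clustering by explicit triangle counting
oracle_cp_binary <- function(W) {
  A <- (W > 0) + 0
  n <- nrow(A)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    t <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && A[i, j] > 0 && A[i, h] > 0 && A[j, h] > 0) t <- t + 1
    }
    nodal[i] <- 2 * t / (k * (k - 1))
  }
  list(nodal = nodal, mean = mean(nodal))
}

# Onnela weighted clustering by explicit triple loops
oracle_cp_weighted <- function(W) {
  n <- nrow(W)
  mw <- max(W)
  S <- if (mw > 0) (W / mw)^(1 / 3) else W
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ] > 0)
    if (k < 2) next
    t <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && W[i, j] > 0 && W[i, h] > 0 && W[j, h] > 0)
        t <- t + S[i, j] * S[i, h] * S[j, h]
    }
    nodal[i] <- 2 * t / (k * (k - 1))
  }
  list(nodal = nodal, mean = mean(nodal))
}

oracle_local_efficiency <- function(W, mode = "weighted") {
  n <- nrow(W)
  nodal <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    nodal[i] <- oracle_path_metrics(W[nb, nb, drop = FALSE], mode)$Eglob
  }
  list(nodal = nodal, mean = mean(nodal))
}

# betweenness via Floyd-Warshall with shortest-path counting; sums
# dependencies over unordered pairs (matching undirected convention)
oracle_betweenness <- function(W, mode = "weighted", tol = 1e-9) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)  # number of shortest paths
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) {
      D[i, j] <- if (mode == "binary") 1 else 1 / W[i, j]
      S[i, j] <- 1
    }
  }
  diag(D) <- 0; diag(S) <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || i == k || j == k) next
    alt <- D[i, k] + D[k, j]
    if (alt < D[i, j] - tol) {
      D[i, j] <- alt
      S[i, j] <- S[i, k] * S[k, j]
    } else if (is.finite(alt) && abs(alt - D[i, j]) <= tol) {
      S[i, j] <- S[i, j] + S[i, k] * S[k, j]
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v) next
    if (is.finite(D[s, t]) && S[s, t] > 0 &&
        abs(D[s, v] + D[v, t] - D[s, t]) <= tol) {
      b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  b
}

# brute-force Benjamini-Hochberg step-up from the definition
oracle_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# partial correlation by explicit projection-matrix residualization
oracle_partial_cor <- function(x, y, Z) {
  Zm <- cbind(1, as.matrix(Z))
  H <- Zm %*% solve(t(Zm) %*% Zm) %*% t(Zm)
  rx <- x - H %*% x
  ry <- y - H %*% y
  as.numeric(cor(rx, ry))
}

# ---- shared fixtures -------------------------------------------------

# triangle {1,2,3} plus a pendant node 4 attached to node 1
toy_triangle_pendant <- function() {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  W[1, 4] <- W[4, 1] <- 1
  W
}

# random symmetric weight matrix with positive weights
random_weight_matrix <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  m <- sum(ut)
  w <- ifelse(runif(m) < density, runif(m, 0.1, 1), 0)
  W[ut] <- w
  W + t(W)
}

# small synthetic subject: list of region value bags
toy_subject <- function(n_regions = 6, n_vox = 60, seed = 1) {
  set.seed(seed)
  list(subject_id = "toy",
       region_values = lapply(seq_len(n_regions), function(r)
         abs(rnorm(n_vox, mean = 0.3 + 0.05 * r, sd = 0.1))),
       region_labels = paste0("R", seq_len(n_regions)))
}

floor_rand_profile <- function(n) {
  p <- runif(n)
  p / sum(p)
}
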