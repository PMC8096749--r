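#' Kernel density estimate as a discrete probability profile
#'
#' Estimates a Gaussian-kernel density for a bag of voxel values,
#' evaluated on an equally spaced grid and renormalized to a discrete
#' probability mass vector (probabilities sum to 1). The discrete-mass
#' convention matches the summation form of the divergence formulas used
#' for network construction.
#'
#' @param values numeric vector of voxel values (at least 2 distinct).
#' @param grid equally spaced evaluation grid; if `NULL`, a grid of `n`
#'   points spanning the data padded by `3 * bandwidth` is used.
#' @param n number of grid points when `grid` is `NULL` (default `2^7`).
#' @param bw bandwidth; defaults to Silverman's rule of thumb
#'   ([stats::bw.nrd0()]).
#' @param region_label optional label carried in the result.
#' @return an object of class `density_profile`: list with `grid`,
#'   `probabilities`, `bandwidth`, `region_label`.
#' @examples
#' p <- estimate_density(rnorm(500), n = 128)
#' sum(p$probabilities)  # 1
#' @export
estimate_density <- function(values, grid = NULL, n = 128L, bw = NULL,
                             region_label = NA_character_) {
  values <- as.numeric(values)
  if (length(unique(values)) < 2L)
    stop("degenerate sample: need at least 2 distinct values (bandwidth would be 0)",
         if (!is.na(region_label)) paste0(" in region ", region_label))
  if (is.null(bw)) bw <- bw.nrd0(values)
  if (!is.finite(bw) || bw <= 0)
    stop("degenerate sample: bandwidth is not positive",
         if (!is.na(region_label)) paste0(" in region ", region_label))
  if (is.null(grid)) {
    lo <- min(values) - 3 * bw
    hi <- max(values) + 3 * bw
    grid <- seq(lo, hi, length.out = n)
  } else {
    n <- length(grid)
  }
  d <- density(values, bw = bw, kernel = "gaussian",
               from = grid[1], to = grid[n], n = n)
  p <- d$y / sum(d$y)
  structure(list(region_label = region_label, grid = grid,
                 probabilities = p, bandwidth = bw),
            class = "density_profile")
}

# accept a density_profile or a bare probability vector
profile_probs <- function(x) {
  if (inherits(x, "density_profile")) x$probabilities else as.numeric(x)
}

check_shared_grid <- function(P, Q) {
  if (inherits(P, "density_profile") && inherits(Q, "density_profile") &&
      !isTRUE(all.equal(P$grid, Q$grid)))
    stop("density profiles are not on a shared grid")
  p <- profile_probs(P); q <- profile_probs(Q)
  if (length(p) != length(q))
    stop("density profiles are not on a shared grid")
  list(p = p, q = q)
}

# floor discrete masses to avoid infinite divergences, then renormalize
floor_probs <- function(p, eps = 1e-10) {
  p <- pmax(p, eps)
  p / sum(p)
}

#' Kullback-Leibler divergence between discrete probability profiles
#'
#' `kl_divergence` is the directed divergence
#' \eqn{D(P\|Q) = \sum_i P_i \log(P_i / Q_i)} (natural log);
#' `symmetric_kl` is the sum of the two directed divergences; `kls` maps
#' the symmetric divergence to a similarity
#' \eqn{\mathrm{KLS} = e^{-D(P,Q)}} in \[0, 1\], equal to 1 exactly when
#' the two distributions are identical. Masses are floored at `1e-10`
#' (then renormalized) before taking logs, so profiles with disjoint
#' support give a large finite divergence and a KLS near 0.
#'
#' @param P,Q `density_profile` objects on a shared grid, or bare
#'   probability vectors of equal length.
#' @return a non-negative scalar (`kl_divergence`, `symmetric_kl`) or a
#'   similarity in \[0, 1\] (`kls`).
#' @examples
#' kl_divergence(c(.5, .5), c(.9, .1))  # 0.5108256
#' symmetric_kl(c(.5, .5), c(.9, .1))   # 0.8788898
#' kls(c(.5, .5), c(.9, .1))            # 0.4152439
#' @export
kl_divergence <- function(P, Q) {
  pq <- check_shared_grid(P, Q)
  p <- floor_probs(pq$p); q <- floor_probs(pq$q)
  sum(p * (log(p) - log(q)))
}

#' @rdname kl_divergence
#' @export
symmetric_kl <- function(P, Q) {
  pq <- check_shared_grid(P, Q)
  p <- floor_probs(pq$p); q <- floor_probs(pq$q)
  sum((p - q) * (log(p) - log(q)))
}

#' @rdname kl_divergence
#' @export
kls <- function(P, Q) {
  min(1, exp(-symmetric_kl(P, Q)))
}

# subject-common evaluation grid: spans the pooled regional values,
# padded by 3x the largest regional bandwidth so all profiles share
# support
common_grid <- function(region_values, n = 128L) {
  bws <- vapply(region_values, function(v) {
    if (length(unique(v)) < 2L) return(NA_real_)
    bw.nrd0(v)
  }, 0)
  if (anyNA(bws))
    stop("degenerate region (all values identical): ",
         paste(which(is.na(bws)), collapse = ", "))
  pooled <- range(unlist(region_values, use.names = FALSE))
  pad <- 3 * max(bws)
  list(grid = seq(pooled[1] - pad, pooled[2] + pad, length.out = n),
       bandwidths = bws)
}

#' Build a subject's KLS morphological network
#'
#' Estimates one density profile per region on a subject-common grid,
#' then fills the 90 x 90 (more generally R x R) symmetric matrix of
#' pairwise KLS similarities. The diagonal is set to 0 by convention.
#'
#' @param subject a list with `region_values` (list of numeric vectors),
#'   and optionally `subject_id` and `region_labels` — the shape
#'   returned by [simulate_cohort()] and [extract_regional_values()].
#' @param n_grid grid resolution (default `2^7 = 128` sample points).
#' @return an object of class `morph_network`: list with `subject_id`,
#'   `weights` (symmetric matrix, zero diagonal, entries in \[0, 1\])
#'   and `node_labels`.
#' @examples
#' co <- simulate_cohort(simulation_design(n_per_group = 1,
#'                                         voxels_per_region = 60))
#' net <- build_network(co$subjects[[1]])
#' range(net$weights[upper.tri(net$weights)])
#' @export
build_network <- function(subject, n_grid = 128L) {
  rv <- subject$region_values
  R <- length(rv)
  cg <- tryCatch(common_grid(rv, n = n_grid), error = function(e)
    stop("cannot build network for subject ",
         subject$subject_id %||% "?", ": ", conditionMessage(e),
         call. = FALSE))
  P <- matrix(0, R, n_grid)
  for (r in seq_len(R)) {
    prof <- estimate_density(rv[[r]], grid = cg$grid,
                             bw = cg$bandwidths[r],
                             region_label = as.character(r))
    P[r, ] <- floor_probs(prof$probabilities)
  }
  L <- log(P)
  # sum_i (P_j - P_k)(log P_j - log P_k) expands to four cross terms,
  # all expressible with one matrix product
  d1 <- rowSums(P * L)
  PLt <- P %*% t(L)
  D <- outer(d1, d1, `+`) - PLt - t(PLt)
  W <- exp(-pmax(D, 0))
  W <- (W + t(W)) / 2
  diag(W) <- 0
  labels <- subject$region_labels %||%
    (if (R == 90L) aal90_labels() else paste0("R", seq_len(R)))
  dimnames(W) <- list(labels, labels)
  structure(list(subject_id = subject$subject_id %||% NA_character_,
                 weights = W, node_labels = labels),
            class = "morph_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.morph_network <- function(x, ...) {
  w <- x$weights[upper.tri(x$weights)]
  cat(sprintf("KLS morphological network: %s\n", x$subject_id))
  cat(sprintf("  %d nodes, %d weighted edges; weights in [%.3f, %.3f], median %.3f\n",
              nrow(x$weights), length(w), min(w), max(w),
              stats::median(w)))
  invisible(x)
}

#' Write / read a network as a TSV edge matrix
#' @param net a `morph_network`.
#' @param path file path.
#' @return `read_network_tsv` returns a `morph_network`.
#' @export
write_network_tsv <- function(net, path) {
  write.table(net$weights, path, sep = "\t", quote = FALSE,
              col.names = NA)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  structure(list(subject_id = sub("[.][^.]*$", "", basename(path)),
                 weights = m, node_labels = rownames(m)),
            class = "morph_network")
}
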