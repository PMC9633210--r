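#' SNF configuration
#'
#' Hyperparameters of similarity network fusion: the number of nearest
#' neighbours `k_neighbors`, the kernel bandwidth multiplier `sigma`, and
#' the number of cross-diffusion iterations `t_iterations` (defaults 14,
#' 0.3 and 27).
#'
#' @param k_neighbors neighbourhood size K.
#' @param sigma bandwidth hyperparameter of the scaled-exponential kernel.
#' @param t_iterations number of fusion iterations T.
#' @param correlation `"pearson"` (default) or `"spearman"` for the sample
#'   distance.
#' @return a list of class `snf_config`.
#' @export
snf_config <- function(k_neighbors = 14L, sigma = 0.3, t_iterations = 27L,
                       correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (t_iterations < 1) stop("t_iterations must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors), sigma = sigma,
                 t_iterations = as.integer(t_iterations),
                 correlation = correlation),
            class = "snf_config")
}

#' Centered PCA scores
#'
#' Principal component scores of the (column-centered) matrix, components
#' ordered by decreasing explained variance. `n_components` is clamped to
#' the matrix rank bound min(n_samples - 1, n_features) with a warning.
#'
#' @param x numeric matrix or `omics_matrix`, samples x features.
#' @param n_components number of components to keep.
#' @return numeric matrix of scores (samples x components) with an
#'   `explained_variance` attribute.
#' @export
pca_reduce <- function(x, n_components) {
  v <- if (inherits(x, "omics_matrix")) as_bare_matrix(x) else x
  if (all(apply(v, 2, stats::sd) == 0))
    stop("constant matrix: PCA undefined")
  rank_bound <- min(nrow(v) - 1L, ncol(v))
  if (n_components > rank_bound) {
    warning(sprintf("n_components clamped from %d to rank bound %d",
                    n_components, rank_bound))
    n_components <- rank_bound
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(v)
  attr(scores, "explained_variance") <- pc$sdev^2
  scores
}

# correlation-based sample distance: 1 - cor between sample rows
sample_cor_distance <- function(v, method) {
  if (any(apply(v, 1, stats::sd) == 0)) {
    bad <- rownames(v)[apply(v, 1, stats::sd) == 0]
    stop(sprintf("zero-variance sample(s): %s",
                 paste(utils::head(bad, 3), collapse = ", ")))
  }
  d <- 1 - stats::cor(t(v), method = method)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Sample affinity matrix for SNF
#'
#' Sample-sample distances are 1 - correlation between sample profiles;
#' affinities use the locally scaled exponential kernel of the original
#' SNF method: W_ij = dnorm(d_ij; 0, sigma * eps_ij), where eps_ij is the
#' mean of (i) the average distance from i to its K nearest neighbours,
#' (ii) the same for j, and (iii) d_ij.
#'
#' @param x an `omics_matrix` (samples x features) or numeric matrix.
#' @param config an [snf_config()].
#' @return symmetric nonnegative affinity matrix with sample dimnames.
#' @export
snf_affinity <- function(x, config = snf_config()) {
  v <- if (inherits(x, "omics_matrix")) as_bare_matrix(x) else x
  if (nrow(v) < config$k_neighbors + 2)
    stop("need at least k_neighbors + 2 samples")
  d <- sample_cor_distance(v, config$correlation)
  n <- nrow(d)
  k <- config$k_neighbors
  mean_knn <- vapply(seq_len(n), function(i) {
    di <- sort(d[i, -i])
    mean(di[seq_len(min(k, length(di)))])
  }, numeric(1))
  eps <- (outer(mean_knn, mean_knn, "+") + d) / 3
  eps[eps <= 0] <- .Machine$double.eps
  w <- stats::dnorm(d, mean = 0, sd = config$sigma * eps)
  w <- (w + t(w)) / 2
  dimnames(w) <- dimnames(d)
  w
}

# full-kernel transition matrix with the stabilizing 1/2 identity trick:
# off-diagonal mass sums to 1/2 per row, diagonal is 1/2
snf_full_kernel <- function(w) {
  p <- w
  diag(p) <- 0
  rs <- rowSums(p)
  rs[rs == 0] <- 1
  p <- p / (2 * rs)
  diag(p) <- 0.5
  p
}

# sparse K-nearest-neighbour kernel: rows renormalized over the K nearest
snf_knn_kernel <- function(w, k) {
  n <- nrow(w)
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    ord <- order(w[i, -i], decreasing = TRUE)
    nbr <- setdiff(seq_len(n), i)[ord][seq_len(min(k, n - 1))]
    s[i, nbr] <- w[i, nbr] / sum(w[i, nbr])
  }
  s
}

#' Fuse affinity matrices by similarity network fusion
#'
#' Iterative cross-diffusion: each view's full kernel is updated through
#' its K-nearest-neighbour kernel applied to the average of the other
#' views' kernels, for `t_iterations` rounds; the fused network is the
#' average of the final views, symmetrized, with the stabilizing identity
#' added. With a single input matrix the procedure reduces to diffusing
#' that matrix against itself.
#'
#' @param affinities list of affinity matrices with identical sample
#'   order (from [snf_affinity()]).
#' @param config an [snf_config()].
#' @return fused symmetric nonnegative matrix.
#' @export
snf_fuse <- function(affinities, config = snf_config()) {
  if (!length(affinities)) stop("need at least one affinity matrix")
  dims <- vapply(affinities, function(a) dim(a), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("affinity matrices differ in shape")
  m <- length(affinities)
  p <- lapply(affinities, snf_full_kernel)
  s <- lapply(affinities, snf_knn_kernel, k = config$k_neighbors)
  for (it in seq_len(config$t_iterations)) {
    p_new <- vector("list", m)
    for (v in seq_len(m)) {
      others <- if (m > 1) Reduce(`+`, p[-v]) / (m - 1) else p[[v]]
      q <- s[[v]] %*% others %*% t(s[[v]])
      q <- (q + t(q)) / 2
      # renormalize with the identity trick to keep iterations stable
      p_new[[v]] <- snf_full_kernel(q)
    }
    p <- p_new
  }
  fused <- Reduce(`+`, p) / m
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(affinities[[1]])
  fused
}

#' Spectral clustering of a fused affinity matrix
#'
#' Normalized-Laplacian spectral clustering (Ng-Jordan-Weiss): take the
#' eigenvectors for the smallest eigenvalues of L = I - D^-1/2 W D^-1/2,
#' row-normalize, and k-means them. With `n_clusters = NULL` the cluster
#' number is chosen by the largest eigengap over candidates 2..6.
#'
#' @param fused symmetric nonnegative affinity matrix.
#' @param n_clusters number of clusters, or `NULL` for eigengap selection.
#' @param k_candidates candidate cluster numbers for the eigengap rule.
#' @param seed RNG seed for the embedded k-means.
#' @return integer labels named by sample, with attributes `eigenvalues`
#'   and `chosen_k`.
#' @export
spectral_cluster <- function(fused, n_clusters = NULL, k_candidates = 2:6,
                             seed = 1L) {
  if (max(abs(fused - t(fused))) > 1e-8)
    stop("fused matrix must be symmetric")
  if (min(fused) < -1e-12) stop("fused matrix must be nonnegative")
  n <- nrow(fused)
  dg <- rowSums(fused)
  if (any(dg <= 0)) stop("isolated sample with zero affinity")
  dinv <- 1 / sqrt(dg)
  lap <- diag(n) - fused * tcrossprod(dinv)
  ei <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  lambda <- rev(ei$values)            # ascending
  vecs <- ei$vectors[, rev(seq_len(n)), drop = FALSE]
  if (is.null(n_clusters)) {
    cand <- k_candidates[k_candidates < n]
    gaps <- lambda[cand + 1] - lambda[cand]
    n_clusters <- cand[which.max(gaps)]
  }
  emb <- vecs[, seq_len(n_clusters), drop = FALSE]
  nrm <- sqrt(rowSums(emb^2))
  nrm[nrm == 0] <- 1
  emb <- emb / nrm
  labels <- kmeans_cluster(emb, n_clusters, seed = seed)
  names(labels) <- rownames(fused)
  attr(labels, "eigenvalues") <- lambda
  attr(labels, "chosen_k") <- n_clusters
  labels
}
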