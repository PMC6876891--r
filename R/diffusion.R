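# Anisotropic diffusion map over cells: Gaussian kernel on a symmetrised
# kNN graph, alpha-normalisation, row-stochastic transition matrix P with
# stationary distribution mu, and the discrete backward Kolmogorov operator
# L = (P - I)/epsilon. With alpha = 1/2, L converges (as n grows and epsilon
# shrinks) to grad(log r) . grad + Laplacian regardless of the sampling
# density r, which is exactly the generator needed by the birth-death model.

#' Gaussian diffusion kernel
#'
#' \eqn{K_\epsilon(x,y) = (4\pi\epsilon)^{-m/2} \exp(-\|x-y\|^2 / 4\epsilon)}.
#'
#' @param x,y numeric vectors of length `m`.
#' @param epsilon kernel width, positive.
#' @param m dimension (defaults to `length(x)`).
#' @return kernel value in `(0, (4*pi*epsilon)^(-m/2)]`.
#' @export
gaussian_kernel <- function(x, y, epsilon, m = length(x)) {
  if (epsilon <= 0) stop("epsilon must be positive")
  (4 * pi * epsilon)^(-m / 2) * exp(-sum((x - y)^2) / (4 * epsilon))
}

.kernel_from_dist2 <- function(d2, epsilon, m) {
  (4 * pi * epsilon)^(-m / 2) * exp(-d2 / (4 * epsilon))
}

#' Median-distance kernel bandwidth
#'
#' Sets the kernel width from the data: the bandwidth `2 * epsilon` is the
#' median of all pairwise Euclidean distances, i.e.
#' `epsilon = median(dist) / 2`.
#'
#' @param embedding an `ldd_embedding` or coordinate matrix.
#' @return scalar `epsilon`.
#' @export
median_bandwidth <- function(embedding) {
  coords <- .embedding_coords(embedding)
  if (nrow(coords) < 2) stop("need at least two cells")
  eps <- median(dist(coords)) / 2
  if (eps <= 0) stop("all points identical: median pairwise distance is zero")
  eps
}

#' Symmetrised kNN kernel weight matrix
#'
#' Connects `i` and `j` when either is among the other's `k` nearest
#' neighbours (`"or"` rule; `"and"` requires both), weighting retained edges
#' by [gaussian_kernel()]. Self-loops carry the kernel's diagonal value.
#'
#' @param embedding an `ldd_embedding` or coordinate matrix.
#' @param k number of nearest neighbours, `1 <= k < n`.
#' @param epsilon kernel width.
#' @param symmetrization `"or"` (default) or `"and"`.
#' @return symmetric `n x n` weight matrix.
#' @export
build_knn_graph <- function(embedding, k, epsilon,
                            symmetrization = c("or", "and")) {
  symmetrization <- match.arg(symmetrization)
  coords <- .embedding_coords(embedding)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n")
  d2 <- as.matrix(dist(coords))^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ])
    ord <- ord[ord != i]
    adj[i, ord[seq_len(k)]] <- TRUE
  }
  adj <- if (symmetrization == "or") adj | t(adj) else adj & t(adj)
  diag(adj) <- TRUE
  W <- .kernel_from_dist2(d2, epsilon, ncol(coords)) * adj
  dimnames(W) <- list(rownames(coords), rownames(coords))
  W
}

#' Anisotropic transition matrix and stationary distribution
#'
#' Applies the alpha-normalisation to a symmetric kernel weight matrix:
#' `q_i = sum_j W_ij`, `K_ij = W_ij / (q_i^alpha q_j^alpha)`,
#' `d_i = sum_j K_ij`, `P_ij = K_ij / d_i` and `mu_i = d_i / sum(d)`.
#' Because the normalised kernel stays symmetric, the chain is reversible and
#' `mu` is its stationary distribution.
#'
#' @param W symmetric non-negative weight matrix with no all-zero row.
#' @param alpha normalisation exponent (default `1/2`, the value for which
#'   the backward operator limit holds).
#' @return list with row-stochastic `P` and stationary `mu`.
#' @export
anisotropic_transition <- function(W, alpha = 0.5) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  q <- rowSums(W)
  if (any(q <= 0)) {
    stop("isolated cell(s) with zero kernel weight: ",
         paste(utils::head(rownames(W)[q <= 0], 5), collapse = ", "),
         "; increase k")
  }
  qa <- q^alpha
  K <- W / outer(qa, qa)
  d <- rowSums(K)
  P <- K / d
  mu <- d / sum(d)
  list(P = P, mu = mu)
}

#' Discrete backward Kolmogorov operator
#'
#' `L = (P - I) / epsilon`. Rows sum to zero and off-diagonals are
#' non-negative, so constants lie in the null space.
#'
#' @param P row-stochastic matrix.
#' @param epsilon kernel width used to build `P`.
#' @return matrix `L` of the same dimension.
#' @export
backward_operator <- function(P, epsilon) {
  stopifnot(epsilon > 0)
  (P - diag(nrow(P))) / epsilon
}

#' Equilibrium (diffusion) potential
#'
#' `U_i = -D log p(x_i)` with `p` a Gaussian kernel density estimate whose
#' bandwidth is tied to the diffusion-map kernel width. `U` captures the
#' component of the landscape generated by diffusion alone (wells at density
#' modes); it is distinct from the advection potential solved by
#' [solve_potential()].
#'
#' @param embedding an `ldd_embedding` or coordinate matrix.
#' @param D noise amplitude (`U` is proportional to it).
#' @param epsilon kernel width; defaults to [median_bandwidth()].
#' @return numeric vector of per-cell potentials.
#' @export
equilibrium_potential <- function(embedding, D = 1, epsilon = NULL) {
  if (D <= 0) stop("D must be positive")
  coords <- .embedding_coords(embedding)
  if (is.null(epsilon)) epsilon <- median_bandwidth(coords)
  d2 <- as.matrix(dist(coords))^2
  p_hat <- rowMeans(.kernel_from_dist2(d2, epsilon, ncol(coords)))
  -D * log(p_hat)
}

# Connected components of a non-negative adjacency by breadth-first search.
.graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      nb <- which(A[i, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Cell-level diffusion model
#'
#' Convenience wrapper building the full cell-level model: median bandwidth,
#' symmetrised kNN kernel graph, anisotropic transition matrix, stationary
#' distribution and backward operator.
#'
#' @inheritParams build_knn_graph
#' @inheritParams anisotropic_transition
#' @param epsilon kernel width, or `NULL` for [median_bandwidth()].
#' @return An `ldd_diffusion` list: `P`, `mu`, `W`, `L`, `epsilon`, `alpha`,
#'   `knn_k`.
#' @export
diffusion_model <- function(embedding, knn_k = 15, alpha = 0.5,
                            epsilon = NULL, symmetrization = c("or", "and")) {
  symmetrization <- match.arg(symmetrization)
  coords <- .embedding_coords(embedding)
  knn_k <- min(knn_k, nrow(coords) - 1)
  if (is.null(epsilon)) epsilon <- median_bandwidth(coords)
  W <- build_knn_graph(coords, knn_k, epsilon, symmetrization)
  if (max(.graph_components(W)) > 1) {
    stop("kNN graph is disconnected; increase knn_k")
  }
  tm <- anisotropic_transition(W, alpha)
  structure(list(P = tm$P, mu = tm$mu, W = W,
                 L = backward_operator(tm$P, epsilon),
                 epsilon = epsilon, alpha = alpha, knn_k = knn_k),
            class = "ldd_diffusion")
}
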