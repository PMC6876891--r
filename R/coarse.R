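# Coarse-graining of the cell-level Markov chain over k-means clusters:
# cluster transition matrix (size- and mu-weighted double sum over member
# cells), its backward operator, and the symmetric cluster weight matrix used
# to lay out differentiation paths.

#' Cluster cells in the embedding
#'
#' k-means with a fixed seed and multiple restarts. Cluster indices are
#' relabelled in order of descending size so labels are stable across runs.
#'
#' @param embedding an `ldd_embedding` or coordinate matrix.
#' @param K number of clusters, `2 <= K <= n`.
#' @param seed integer seed.
#' @param nstart number of k-means restarts.
#' @return integer vector of cluster labels in `1..K`, named by cell id.
#' @export
cluster_cells <- function(embedding, K, seed = 1, nstart = 10) {
  coords <- .embedding_coords(embedding)
  n <- nrow(coords)
  if (K < 2 || K > n) stop("K must satisfy 2 <= K <= n")
  if (nrow(unique(coords)) < K) stop("K exceeds the number of distinct points")
  km <- withr::with_seed(seed,
    kmeans(coords, centers = K, nstart = nstart, iter.max = 200))
  labels <- km$cluster
  sizes <- tabulate(labels, K)
  remap <- integer(K)
  remap[order(-sizes, seq_len(K))] <- seq_len(K)
  labels <- remap[labels]
  names(labels) <- rownames(coords)
  labels
}

.cluster_indicator <- function(labels, K = max(labels)) {
  if (!all(seq_len(K) %in% labels)) {
    stop("empty cluster(s): ", paste(setdiff(seq_len(K), labels), collapse = ", "))
  }
  M <- matrix(0, length(labels), K)
  M[cbind(seq_along(labels), labels)] <- 1
  M
}

#' Coarse-grained cluster transition matrix
#'
#' Aggregates the cell-level chain over clusters:
#' \deqn{\hat p_{st} = \frac{\hat\mu_t}{n_s n_t}
#'   \sum_{i \in \Omega_s} \sum_{j \in \Omega_t} p_{ij},}
#' with \eqn{\hat\mu_t} the stationary mass of cluster `t`. At finite sample
#' size the raw matrix is not exactly row-stochastic, so the row-normalised
#' version (whose backward operator annihilates constants, as the potential
#' solve requires) is returned alongside it.
#'
#' @param P cell-level row-stochastic matrix.
#' @param mu cell-level stationary distribution.
#' @param labels integer cluster labels in `1..K` covering every cell.
#' @return list with `mu_hat`, `n_s`, `P_hat_raw` and row-normalised `P_hat`.
#' @export
coarse_transition <- function(P, mu, labels) {
  K <- max(labels)
  M <- .cluster_indicator(labels, K)
  n_s <- colSums(M)
  mu_hat <- drop(crossprod(M, mu))
  S <- crossprod(M, P %*% M)                       # sum_{i in s, j in t} p_ij
  P_hat_raw <- sweep(S / outer(n_s, n_s), 2, mu_hat, `*`)
  P_hat <- P_hat_raw / rowSums(P_hat_raw)
  list(mu_hat = mu_hat, n_s = n_s, P_hat_raw = P_hat_raw, P_hat = P_hat)
}

#' Coarse-grained backward operator
#'
#' `L_hat = (P_hat - I) / epsilon`, the cluster-level analogue of
#' [backward_operator()].
#'
#' @param P_hat row-stochastic cluster transition matrix.
#' @param epsilon kernel width.
#' @return `K x K` operator with zero row sums.
#' @export
coarse_backward <- function(P_hat, epsilon) {
  backward_operator(P_hat, epsilon)
}

#' Cluster weight matrix
#'
#' \eqn{\tilde p_{st} = \sum_{i \in \Omega_s}\sum_{j \in \Omega_t} \mu_i p_{ij}}:
#' the stationary edge mass exchanged between clusters. Symmetric for the
#' reversible cell-level chain, with total mass one; its non-zero
#' off-diagonal entries are the candidate differentiation paths.
#'
#' @inheritParams coarse_transition
#' @return symmetric `K x K` matrix summing to 1.
#' @export
cluster_weight_matrix <- function(P, mu, labels) {
  K <- max(labels)
  M <- .cluster_indicator(labels, K)
  crossprod(M, (mu * P) %*% M)
}
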