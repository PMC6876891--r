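# Per-cluster birth-death net-flow rates estimated from the sample
# coordinates alone. By the divergence theorem, the average net creation rate
# over a cluster equals -D times the integral of the Laplacian of the
# cluster's conditional density, which decomposes into per-axis boundary
# derivatives of one-dimensional marginal kernel density estimates. A
# post-processing step then restores the global steady-state constraint
# sum_s n_s * R_s = 0 exactly.

.kde_derivative <- function(x0, samples, bandwidth) {
  z <- (x0 - samples) / bandwidth
  -sum(z * dnorm(z)) / (length(samples) * bandwidth^2)
}

#' Boundary derivatives of a one-dimensional kernel density estimate
#'
#' Fits a Gaussian KDE to `samples` and returns its derivative at the two
#' interval endpoints.
#'
#' @param samples numeric vector, at least one value.
#' @param a,b interval endpoints (default: sample range).
#' @param bandwidth positive KDE bandwidth.
#' @return named numeric vector `c(at_a = , at_b = )`.
#' @export
marginal_boundary_derivatives <- function(samples, a = min(samples),
                                          b = max(samples), bandwidth) {
  if (length(samples) < 1) stop("need at least one sample")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (a > b) stop("interval endpoints must satisfy a <= b")
  c(at_a = .kde_derivative(a, samples, bandwidth),
    at_b = .kde_derivative(b, samples, bandwidth))
}

.silverman_bw <- function(x) {
  bw <- tryCatch(bw.nrd0(x), error = function(e) 0)
  if (!is.finite(bw) || bw <= 0) bw <- max(sd(x), 1e-8)
  bw
}

#' Per-cluster net-flow rates
#'
#' For each cluster and each embedding axis, fits a marginal Gaussian KDE to
#' the cluster's coordinates (Silverman bandwidth) and sums the boundary
#' derivatives over its support interval:
#' \deqn{\hat R_s = -D \sum_j \left[\partial_x r_s^{(j)}(b_s^{(j)}) -
#'   \partial_x r_s^{(j)}(a_s^{(j)})\right].}
#' Positive rates flag source (birth) regions, negative rates sink (death)
#' regions. Clusters with two or fewer cells get a zero rate with a warning.
#'
#' @param embedding an `ldd_embedding` or coordinate matrix.
#' @param labels integer cluster labels in `1..K`.
#' @param D noise amplitude; only rescales the rates (and hence the
#'   potential) uniformly, so the default 1 is fine for ordering cells.
#' @param pad optional support padding, in bandwidths, applied to each
#'   interval endpoint (default 0: the support is the sample range).
#' @param bw_adjust multiplier on the Silverman bandwidth. Values above 1
#'   oversmooth the marginal KDEs, which markedly reduces the variance of the
#'   boundary-derivative estimate for cluster-sized samples while preserving
#'   the curvature contrast between concentrated (source-like) and dispersed
#'   (sink-like) clusters.
#' @return list with `R_hat` (length-K), `intervals` (K x m x 2 array),
#'   `bandwidths` (K x m) and `D`.
#' @export
cluster_netflow <- function(embedding, labels, D = 1, pad = 0,
                            bw_adjust = 3) {
  if (D <= 0) stop("D must be positive")
  coords <- .embedding_coords(embedding)
  K <- max(labels)
  m <- ncol(coords)
  if (!all(seq_len(K) %in% labels)) stop("empty cluster(s)")
  R_hat <- numeric(K)
  intervals <- array(NA_real_, c(K, m, 2),
                     dimnames = list(NULL, colnames(coords), c("a", "b")))
  bandwidths <- matrix(NA_real_, K, m)
  for (s in seq_len(K)) {
    rows <- which(labels == s)
    if (length(rows) <= 2) {
      warning(sprintf("cluster %d has %d cell(s); net-flow set to 0", s,
                      length(rows)))
      R_hat[s] <- 0
      next
    }
    acc <- 0
    for (j in seq_len(m)) {
      xs <- coords[rows, j]
      h <- bw_adjust * .silverman_bw(xs)
      a <- min(xs) - pad * h
      b <- max(xs) + pad * h
      dv <- marginal_boundary_derivatives(xs, a, b, h)
      acc <- acc + (dv[["at_b"]] - dv[["at_a"]])
      intervals[s, j, ] <- c(a, b)
      bandwidths[s, j] <- h
    }
    R_hat[s] <- -D * acc
  }
  list(R_hat = R_hat, intervals = intervals, bandwidths = bandwidths, D = D)
}

#' Enforce the steady-state constraint on net-flow rates
#'
#' Births must balance deaths over the whole population:
#' `sum_s n_s * R_s = 0`. Finite samples break this, so the size-weighted
#' mean rate is subtracted:
#' \deqn{\tilde R_s = \hat R_s - \sum_t n_t \hat R_t / N.}
#'
#' @param R_hat length-K vector of raw rates.
#' @param n_s length-K vector of cluster sizes.
#' @return length-K vector `R_tilde` satisfying the constraint to round-off.
#' @export
postprocess_netflow <- function(R_hat, n_s) {
  stopifnot(length(R_hat) == length(n_s))
  N <- sum(n_s)
  if (N == 0) stop("no cells (N = 0)")
  R_hat - sum(n_s * R_hat) / N
}
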