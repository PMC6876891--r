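# Cluster potential, pseudo-time, directed differentiation paths, the
# illustrative landscape surface, and the evaluation statistics.

#' Solve for the cluster differentiation potential
#'
#' The cluster potential satisfies the discrete Poisson problem
#' `(P_hat - I) V_hat = -R_tilde * epsilon`. The left-hand matrix is
#' singular (constants are in its null space), so the minimum-norm
#' least-squares solution is taken via the Moore-Penrose pseudo-inverse:
#' \deqn{\hat V = -(\hat P - I)^\dagger \tilde R \epsilon.}
#' High potential marks pluripotent (source) clusters, low potential
#' differentiated (sink) clusters.
#'
#' @param P_hat row-stochastic `K x K` cluster transition matrix.
#' @param R_tilde length-K post-processed net-flow rates.
#' @param epsilon kernel width.
#' @return length-K potential vector.
#' @export
solve_potential <- function(P_hat, R_tilde, epsilon) {
  stopifnot(all(is.finite(P_hat)), all(is.finite(R_tilde)), epsilon > 0)
  A <- P_hat - diag(nrow(P_hat))
  V <- -drop(MASS::ginv(A) %*% (R_tilde * epsilon))
  if (!all(is.finite(V))) stop("potential solve produced non-finite values")
  V
}

#' Per-cell pseudo-time from the cluster potential
#'
#' Pseudo-time is the additive inverse of the potential of the cell's
#' cluster: `pseudotime_i = -V_hat[label_i]`. The root (highest-potential)
#' cluster therefore has the smallest pseudo-time and differentiated cells
#' the largest, so correlation with true developmental time is expected to
#' be positive.
#'
#' @param V_hat length-K cluster potential.
#' @param labels integer cluster labels.
#' @return numeric vector of per-cell pseudo-times (named like `labels`).
#' @export
assign_pseudotime <- function(V_hat, labels) {
  stopifnot(all(labels >= 1), all(labels <= length(V_hat)))
  pt <- -V_hat[labels]
  names(pt) <- names(labels)
  pt
}

#' Directed differentiation paths between clusters
#'
#' Candidate (undirected) paths are the off-diagonal entries of the cluster
#' weight matrix above `threshold`; each is oriented from its higher- to its
#' lower-potential endpoint. Ties in potential are oriented from the larger
#' to the smaller cluster with a warning. The root is the cluster of maximal
#' potential; if thresholding disconnects the graph, a warning reports
#' per-component roots.
#'
#' @param P_tilde symmetric cluster weight matrix.
#' @param V_hat cluster potential.
#' @param threshold minimum retained weight; default 10% of the largest
#'   off-diagonal entry, which on the benchmark geometries cleanly separates
#'   genuine neighbour links from residual cross-branch weights.
#' @param n_s optional cluster sizes (used only to break potential ties).
#' @return list with `edges` (tibble: `from`, `to`, `weight`), `root`, and
#'   `component` (per-cluster component index of the retained graph).
#' @export
build_paths <- function(P_tilde, V_hat, threshold = NULL, n_s = NULL) {
  K <- nrow(P_tilde)
  stopifnot(K == length(V_hat))
  off <- P_tilde
  diag(off) <- 0
  if (is.null(threshold)) threshold <- 0.1 * max(off)
  if (threshold < 0) stop("threshold must be non-negative")
  from <- integer(0); to <- integer(0); weight <- numeric(0)
  for (s in seq_len(K - 1)) {
    for (t in seq(s + 1, K)) {
      w <- off[s, t]
      if (w <= threshold) next
      hi <- s; lo <- t
      if (V_hat[t] > V_hat[s]) { hi <- t; lo <- s }
      if (V_hat[t] == V_hat[s]) {
        warning(sprintf("potential tie between clusters %d and %d; orienting by size", s, t))
        if (!is.null(n_s) && n_s[t] > n_s[s]) { hi <- t; lo <- s }
      }
      from <- c(from, hi); to <- c(to, lo); weight <- c(weight, w)
    }
  }
  A <- matrix(0, K, K)
  if (length(from)) A[cbind(from, to)] <- A[cbind(to, from)] <- 1
  comp <- .graph_components(A)
  if (max(comp) > 1) {
    roots <- vapply(seq_len(max(comp)),
                    function(cc) which(comp == cc)[which.max(V_hat[comp == cc])],
                    integer(1))
    warning("path graph is disconnected after thresholding; per-component roots: ",
            paste(roots, collapse = ", "))
  }
  list(edges = tibble::tibble(from = from, to = to, weight = weight),
       root = which.max(V_hat), component = comp)
}

#' Illustrative landscape surface
#'
#' Evaluates the plotting surface
#' \deqn{f(x,y) = \frac1N \sum_i -\exp\!\big(-\big((x-x_i)^2+(y-y_i)^2\big)
#'   / (\sigma/\tilde p_i)^2\big), \qquad V(x,y) = a f(x,y) + b g(x,y),}
#' where \eqn{\tilde p_i} is the weight-matrix diagonal of cell `i`'s
#' cluster and `g` is a plane least-squares-fitted to the cells' potential
#' values - a simple monotone surrogate for the potential trend across the
#' plane. `a`, `b` and `sigma` are display parameters.
#'
#' @param coords_2d cells x 2 coordinate matrix.
#' @param labels integer cluster labels.
#' @param P_tilde cluster weight matrix.
#' @param V_hat cluster potential.
#' @param sigma kernel width of the surface bumps.
#' @param a,b mixing coefficients of the bump term and the trend plane.
#' @param grid_n grid resolution per axis.
#' @param expand fractional margin added around the data range.
#' @param cap optional upper cap; grid values above it are set to `NA`.
#' @return tibble with columns `x`, `y`, `f`, `g`, `V`.
#' @export
landscape_surface <- function(coords_2d, labels, P_tilde, V_hat,
                              sigma = NULL, a = 1, b = 1, grid_n = 80,
                              expand = 0.1, cap = NULL) {
  coords_2d <- .embedding_coords(coords_2d)[, 1:2, drop = FALSE]
  if (grid_n < 2) stop("empty grid")
  p_diag <- diag(P_tilde)
  if (any(p_diag[unique(labels)] <= 0)) {
    message("cluster(s) with zero weight-matrix diagonal; substituting the ",
            "smallest positive diagonal")
    p_diag[p_diag <= 0] <- min(p_diag[p_diag > 0])
  }
  p_i <- p_diag[labels]
  if (is.null(sigma)) {
    sigma <- 0.15 * max(apply(coords_2d, 2, function(v) diff(range(v)))) *
      mean(p_i)
  }
  if (sigma <= 0) stop("sigma must be positive")
  rng <- apply(coords_2d, 2, range)
  pad <- expand * pmax(rng[2, ] - rng[1, ], 1)
  gx <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = grid_n)
  gy <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = grid_n)
  grid <- expand.grid(x = gx, y = gy)
  V_cell <- V_hat[labels]
  plane <- lm(V_cell ~ x + y,
              data = data.frame(x = coords_2d[, 1], y = coords_2d[, 2]))
  g <- predict(plane, newdata = grid)
  w2 <- (sigma / p_i)^2
  f <- vapply(seq_len(nrow(grid)), function(r) {
    d2 <- (grid$x[r] - coords_2d[, 1])^2 + (grid$y[r] - coords_2d[, 2])^2
    -mean(exp(-d2 / w2))
  }, numeric(1))
  V <- a * f + b * g
  if (!is.null(cap)) V[V > cap] <- NA_real_
  tibble::tibble(x = grid$x, y = grid$y, f = f, g = g, V = V)
}

#' Pearson correlation between pseudo-time and true time
#'
#' @param pseudotime,true_time equal-length numeric vectors (n >= 3) with
#'   non-zero variance.
#' @return Pearson correlation coefficient.
#' @export
evaluate_correlation <- function(pseudotime, true_time) {
  stopifnot(length(pseudotime) == length(true_time), length(pseudotime) >= 3)
  if (sd(pseudotime) == 0 || sd(true_time) == 0) {
    stop("zero variance: correlation undefined")
  }
  cor(pseudotime, true_time)
}

#' One-sided Wilcoxon rank-sum stage test
#'
#' Tests whether cells from an early developmental stage have stochastically
#' smaller pseudo-time than cells from a late stage (alternative: early <
#' late). Exact enumeration for small samples without ties, normal
#' approximation with continuity correction otherwise.
#'
#' @param pseudotime_early,pseudotime_late pseudo-times of the two stages.
#' @return one-sided p-value.
#' @export
wilcoxon_stage_test <- function(pseudotime_early, pseudotime_late) {
  if (!length(pseudotime_early) || !length(pseudotime_late)) {
    stop("both stage groups must be non-empty")
  }
  suppressWarnings(
    wilcox.test(pseudotime_early, pseudotime_late,
                alternative = "less", correct = TRUE)$p.value
  )
}
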