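test_that("gaussian kernel matches direct evaluation", {
  expect_equal(gaussian_kernel(0, 0, epsilon = 1, m = 1), (4 * pi)^(-1 / 2),
               tolerance = 1e-12)
  # m = 2, epsilon = 1/4, |x - y| = 1: (4*pi*eps)^-1 * exp(-1/(4*eps)) = e^-1/pi
  expect_equal(gaussian_kernel(c(0, 0), c(1, 0), epsilon = 0.25),
               exp(-1) / pi, tolerance = 1e-12)
  set.seed(1)
  x <- rnorm(3); y <- rnorm(3)
  expect_identical(gaussian_kernel(x, y, 0.7), gaussian_kernel(y, x, 0.7))
  expect_error(gaussian_kernel(0, 1, epsilon = 0), "positive")
})

test_that("median bandwidth halves the median pairwise distance", {
  two <- matrix(c(0, 3), 2, 1)
  expect_equal(median_bandwidth(two), 1.5)
  three <- matrix(c(0, 1, 3), 3, 1)   # distances 1, 2, 3 -> median 2
  expect_equal(median_bandwidth(three), 1)
  pts <- make_blobs(n_per = 15)
  set.seed(2); Q <- qr.Q(qr(matrix(rnorm(4), 2)))
  expect_equal(median_bandwidth(pts), median_bandwidth(pts %*% Q),
               tolerance = 1e-12)
  expect_error(median_bandwidth(matrix(1, 4, 2)), "identical")
})

test_that("kNN graph uses OR symmetrisation with self-loops", {
  pts <- matrix(c(0, 1, 10), 3, 1)
  W <- build_knn_graph(pts, k = 1, epsilon = 1)
  expect_equal(W, t(W))
  expect_equal(W[1, 3], 0)            # neither is the other's nearest neighbour
  expect_gt(W[1, 2], 0)
  expect_gt(W[2, 3], 0)               # 2 is 3's nearest neighbour (OR rule)
  expect_true(all(diag(W) > 0))
  # AND rule drops the asymmetric edge
  Wand <- build_knn_graph(pts, k = 1, epsilon = 1, symmetrization = "and")
  expect_equal(Wand[2, 3], 0)
  # complete graph when k = n - 1
  x <- make_blobs(n_per = 5, sep = 2)
  Wfull <- build_knn_graph(x, k = nrow(x) - 1, epsilon = 1)
  expect_true(all(Wfull > 0))
  expect_error(build_knn_graph(pts, k = 3, epsilon = 1), "k must")
})

test_that("anisotropic normalisation yields a reversible chain", {
  x <- make_blobs(n_per = 20, sep = 4, sd = 1)
  W <- build_knn_graph(x, k = 8, epsilon = median_bandwidth(x))
  tm <- anisotropic_transition(W, 0.5)
  expect_lt(max(abs(rowSums(tm$P) - 1)), 1e-10)
  expect_gte(min(tm$mu), 0)
  expect_equal(sum(tm$mu), 1, tolerance = 1e-12)
  expect_lt(max(abs(drop(tm$mu %*% tm$P) - tm$mu)), 1e-10)       # mu P = mu
  flux <- tm$mu * tm$P
  expect_lt(max(abs(flux - t(flux))), 1e-10)                     # detailed balance
})

test_that("two identical points give the symmetric two-state chain", {
  W <- build_knn_graph(matrix(c(0, 0), 2, 1), k = 1, epsilon = 1)
  tm <- anisotropic_transition(W, 0.5)
  expect_equal(tm$P, matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(unname(tm$mu), c(0.5, 0.5))
})

test_that("isolated cells are reported by name", {
  W <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(anisotropic_transition(W), "b")
})

test_that("backward operator annihilates constants", {
  P <- random_stochastic(6, seed = 3)
  L <- backward_operator(P, 0.5)
  expect_lt(max(abs(L %*% rep(1, 6))), 1e-12)
  expect_equal(backward_operator(diag(4), 0.3), matrix(0, 4, 4))
  offdiag <- L[row(L) != col(L)]
  expect_true(all(offdiag >= 0))
})

test_that("operator approximates the Laplacian on uniform density", {
  # on uniform samples L f ~ f'' ; for f(x) = x^2 that is the constant 2
  set.seed(7)
  x <- sort(runif(1200, -1, 1))
  co <- matrix(x, ncol = 1, dimnames = list(sprintf("c%d", seq_along(x)), "x"))
  eps <- 0.02
  W <- build_knn_graph(co, k = length(x) - 1, epsilon = eps)
  tm <- anisotropic_transition(W, 0.5)
  Lf <- drop(backward_operator(tm$P, eps) %*% x^2)
  expect_lt(abs(mean(Lf[abs(x) < 0.6]) - 2), 0.25)
})

test_that("all diffusion outputs commute with cell permutations", {
  x <- make_blobs(n_per = 12, sep = 3, sd = 1)
  dm <- diffusion_model(x, knn_k = 6)
  set.seed(8); perm <- sample(nrow(x))
  dm2 <- diffusion_model(x[perm, ], knn_k = 6)
  expect_equal(dm2$P, dm$P[perm, perm], tolerance = 1e-12)
  expect_equal(unname(dm2$mu), unname(dm$mu[perm]), tolerance = 1e-12)
})

test_that("a disconnected kNN graph is refused", {
  set.seed(12)
  far <- rbind(matrix(rnorm(20, sd = 0.1), 10, 2),
               matrix(rnorm(20, sd = 0.1), 10, 2) + 1e4)
  rownames(far) <- sprintf("c%02d", 1:20)
  colnames(far) <- c("x", "y")
  expect_error(diffusion_model(far, knn_k = 3, epsilon = 1), "disconnected")
})

test_that("equilibrium potential is -D log of a kernel density", {
  x <- make_blobs(n_per = 15, sep = 6)
  U1 <- equilibrium_potential(x, D = 1)
  U2 <- equilibrium_potential(x, D = 2)
  expect_equal(U2, 2 * U1, tolerance = 1e-12)
  # densest point has minimal U
  pts <- rbind(matrix(rnorm(60, sd = 0.2), 30, 2), c(50, 50))
  rownames(pts) <- sprintf("c%02d", 1:31)
  U <- equilibrium_potential(pts, D = 1, epsilon = 0.5)
  expect_gt(U[31], max(U[1:30]))
})

test_that("equilibrium potential recovers the Gaussian log-density", {
  set.seed(5)
  x <- rnorm(3000)
  co <- matrix(x, ncol = 1, dimnames = list(sprintf("c%d", 1:3000), "x"))
  eps <- 0.1
  U <- equilibrium_potential(co, D = 1, epsilon = eps)
  i0 <- which.min(abs(x))
  for (target in c(1, -1.5)) {
    i <- which.min(abs(x - target))
    expect_equal(unname(U[i] - U[i0]),
                 (x[i]^2 - x[i0]^2) / (2 * (1 + 2 * eps)), tolerance = 0.12)
  }
})
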