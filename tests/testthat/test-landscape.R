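test_that("potential solve: zero flow, closed form and minimum norm", {
  P <- random_stochastic(5, seed = 2)
  expect_equal(solve_potential(P, rep(0, 5), 0.7), rep(0, 5))
  # K = 2 symmetric chain has the closed-form antisymmetric solution
  P2 <- matrix(0.5, 2, 2)
  for (r in c(0.3, -1.2)) {
    expect_equal(solve_potential(P2, c(r, -r), 0.9), c(r, -r) * 0.9,
                 tolerance = 1e-10)
  }
  # minimum-norm representative is orthogonal to the constant null vector
  R <- postprocess_netflow(rnorm(5), rep(1, 5))
  V <- solve_potential(P, R, 0.5)
  expect_lt(abs(sum(V)), 1e-8)
})

test_that("pseudo-time is the negated cluster potential", {
  labels <- c(1L, 2L, 2L, 1L)
  pt <- assign_pseudotime(c(1, 0), labels)
  expect_equal(unname(pt), c(-1, 0, 0, -1))
  pt2 <- assign_pseudotime(c(1, 0) + 5, labels)
  expect_equal(unname(pt2 - pt), rep(-5, 4))
  expect_error(assign_pseudotime(c(1, 0), c(1L, 3L)), "labels")
})

test_that("paths are thresholded and oriented downhill", {
  Pt <- matrix(c(0.4, 0.05, 0.001,
                 0.05, 0.3, 0.08,
                 0.001, 0.08, 0.2), 3, 3)
  V <- c(3, 2, 1)
  all_edges <- build_paths(Pt, V, threshold = 0)
  expect_equal(nrow(all_edges$edges), 3)
  pruned <- build_paths(Pt, V, threshold = 0.01)
  expect_equal(nrow(pruned$edges), 2)
  expect_true(all(V[pruned$edges$from] >= V[pruned$edges$to]))
  expect_equal(pruned$root, 1)
  expect_warning(build_paths(Pt, c(1, 1, 0), threshold = 0.01, n_s = c(5, 9, 2)),
                 "tie")
  expect_warning(build_paths(Pt, V, threshold = 0.2), "disconnected")
})

test_that("landscape surface follows its defining mixture", {
  co <- matrix(c(0, 0), 1, 2, dimnames = list("c1", c("PC1", "PC2")))
  Pt <- matrix(1, 1, 1)
  surf <- suppressWarnings(
    landscape_surface(co, 1L, Pt, V_hat = 0, sigma = 1, a = 1, b = 0,
                      grid_n = 11, expand = 4))
  centre <- surf[which.min(surf$x^2 + surf$y^2), ]
  expect_equal(centre$f, -1, tolerance = 1e-10)     # single term, exponent 0
  corner <- surf[which.max(surf$x^2 + surf$y^2), ]
  expect_gt(corner$f, -0.05)                        # far field decays to 0
  # linear in the mixing coefficients
  co2 <- make_blobs(n_per = 8, sep = 4)
  colnames(co2) <- c("PC1", "PC2")
  lab <- rep(1:2, each = 8)
  Pt2 <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  s1 <- landscape_surface(co2, lab, Pt2, c(1, 0), sigma = 1, a = 1, b = 0,
                          grid_n = 9)
  s2 <- landscape_surface(co2, lab, Pt2, c(1, 0), sigma = 1, a = 2, b = 0,
                          grid_n = 9)
  expect_equal(s2$V, 2 * s1$V, tolerance = 1e-12)
  s3 <- landscape_surface(co2, lab, Pt2, c(1, 0), sigma = 1, a = 1, b = 0,
                          grid_n = 9, cap = -0.5)
  expect_true(any(is.na(s3$V)))
})

test_that("pearson correlation matches hand computation", {
  expect_equal(evaluate_correlation(1:5, 1:5), 1)
  expect_equal(evaluate_correlation(1:5, -(1:5)), -1)
  expect_equal(evaluate_correlation(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 14 / 3), tolerance = 1e-10)
  expect_error(evaluate_correlation(c(1, 1, 1), 1:3), "variance")
})

test_that("wilcoxon stage test matches exact enumeration", {
  expect_equal(wilcoxon_stage_test(c(1, 2), c(3, 4)), 1 / 6, tolerance = 1e-12)
  # independent oracle: enumerate all assignments of ranks to the early group
  pooled <- c(1, 2, 3, 4)
  combos <- combn(4, 2)
  obs_w <- 0                                         # early = {1,2}: no wins
  ws <- apply(combos, 2, function(idx) {
    early <- pooled[idx]; late <- pooled[-idx]
    sum(outer(early, late, ">"))
  })
  expect_equal(mean(ws <= obs_w), 1 / 6)
  # wrong direction
  expect_gt(wilcoxon_stage_test(c(3, 4), c(1, 2)), 0.9)
  expect_error(wilcoxon_stage_test(numeric(0), 1:3), "non-empty")
})

test_that("wilcoxon test is calibrated under the null", {
  set.seed(21)
  ps <- replicate(200, wilcoxon_stage_test(rnorm(30), rnorm(30)))
  expect_gt(median(ps), 0.3)
  expect_lt(median(ps), 0.7)
})
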