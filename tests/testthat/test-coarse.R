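test_that("k-means recovers separated blobs and is deterministic", {
  x <- make_blobs(n_per = 25, sep = 10)
  l1 <- cluster_cells(x, K = 2, seed = 9)
  l2 <- cluster_cells(x, K = 2, seed = 9)
  expect_identical(l1, l2)
  expect_equal(length(unique(l1[1:25])), 1)
  expect_equal(length(unique(l1[26:50])), 1)
  expect_true(l1[1] != l1[26])
  # labels ordered by descending size
  x3 <- rbind(make_blobs(40, sep = 0, sd = 0.3), make_blobs(10, sep = 0, sd = 0.3) + 20)
  rownames(x3) <- sprintf("c%03d", seq_len(nrow(x3)))
  l3 <- cluster_cells(x3, K = 2, seed = 1)
  expect_gt(sum(l3 == 1), sum(l3 == 2))
  expect_error(cluster_cells(matrix(1:4, 2, 2), K = 3), "2 <= K")
  expect_error(cluster_cells(matrix(rep(1:2, each = 4), 4, 2), K = 3), "distinct")
})

test_that("coarse transition matrix aggregates the cell-level chain", {
  fit <- fork_fit()
  P <- fit$diffusion$P; mu <- fit$diffusion$mu
  # single cluster collapses to the trivial chain
  one <- coarse_transition(P, mu, rep(1L, length(mu)))
  expect_equal(unname(one$P_hat), matrix(1))
  expect_equal(unname(one$mu_hat), 1)
  # benchmark labels: raw entries non-negative, normalised rows sum to 1
  co <- coarse_transition(P, mu, fit$labels)
  expect_true(all(co$P_hat_raw >= 0))
  expect_lt(max(abs(rowSums(co$P_hat) - 1)), 1e-10)
  expect_equal(sum(co$mu_hat), 1, tolerance = 1e-12)
  expect_equal(sum(co$n_s), length(mu))
  # raw matrix follows the mu-weighted double-sum definition
  K <- max(fit$labels)
  s <- 1; t <- 2
  manual <- sum(mu[fit$labels == t]) / (co$n_s[s] * co$n_s[t]) *
    sum(P[fit$labels == s, fit$labels == t])
  expect_equal(co$P_hat_raw[s, t], manual, tolerance = 1e-12)
  expect_error(coarse_transition(P, mu, rep(c(1L, 3L), length.out = length(mu))),
               "empty")
})

test_that("block-diagonal chains coarse-grain to the identity", {
  P1 <- random_stochastic(5, seed = 1)
  P2 <- random_stochastic(4, seed = 2)
  P <- rbind(cbind(P1, matrix(0, 5, 4)), cbind(matrix(0, 4, 5), P2))
  mu <- rep(1 / 9, 9)
  labels <- rep(1:2, c(5, 4))
  co <- coarse_transition(P, mu, labels)
  expect_equal(unname(co$P_hat), diag(2), tolerance = 1e-12)
})

test_that("coarse backward operator scales inversely with epsilon", {
  P <- random_stochastic(4, seed = 5)
  L1 <- coarse_backward(P, 0.8)
  L2 <- coarse_backward(P, 0.4)
  expect_equal(L2, 2 * L1, tolerance = 1e-12)
  expect_lt(max(abs(L1 %*% rep(1, 4))), 1e-12)
  expect_equal(coarse_backward(diag(3), 1), matrix(0, 3, 3))
})

test_that("cluster weight matrix is symmetric with unit total mass", {
  fit <- fork_fit()
  Pt <- cluster_weight_matrix(fit$diffusion$P, fit$diffusion$mu, fit$labels)
  expect_lt(max(abs(Pt - t(Pt))), 1e-10)
  expect_equal(sum(Pt), 1, tolerance = 1e-10)
  # arbitrary labels still sum to one
  set.seed(3)
  rnd <- sample(1:3, length(fit$labels), replace = TRUE)
  expect_equal(sum(cluster_weight_matrix(fit$diffusion$P, fit$diffusion$mu, rnd)),
               1, tolerance = 1e-10)
  # singleton clusters reduce to mu_i p_ij
  n <- 5
  P <- random_stochastic(n, seed = 6)
  mu <- drop(MASS::ginv(t(diag(n) - P + 1)) %*% rep(1, n))
  mu <- mu / sum(mu)
  Ps <- cluster_weight_matrix(P, mu, seq_len(n))
  expect_equal(unname(Ps), unname(mu * P), tolerance = 1e-12)
})

test_that("merging two adjacent non-bifurcation clusters preserves the order
           of the remaining clusters", {
  ds <- fork_dataset()
  f5 <- ldd_fit(ds, k_clusters = 5, m = 10)
  age <- cluster_mean_age(ds, f5$labels)
  ord <- order(age)
  m1 <- ord[1]; m2 <- ord[2]         # the two youngest: the trunk chain
  keep <- setdiff(seq_len(5), c(m1, m2))
  lab <- f5$labels
  lab[lab == m2] <- m1
  new_ids <- as.integer(factor(lab))
  map <- tapply(new_ids, f5$labels, unique)
  fm <- ldd_fit(ds, labels = new_ids, m = 10, k_clusters = NA)
  expect_equal(rank(f5$V_hat[keep]),
               rank(fm$V_hat[unlist(map[as.character(keep)])]))
})
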