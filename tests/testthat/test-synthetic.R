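test_that("drift-diffusion snapshot has the requested size and labels", {
  ds <- fork_dataset()
  expect_equal(nrow(ds$expression), 400)
  expect_equal(ncol(ds$expression), 50)
  expect_equal(ds$cells$cell_id, rownames(ds$expression))
  expect_true(all(ds$cells$true_time >= 0))
  expect_true(all(ds$cells$lineage %in%
                    c("branch_up", "branch_down", "progenitor")))
  expect_setequal(unique(ds$cells$stage), c("early", "mid", "late"))
})

test_that("zero drift, zero noise and no birth-death leaves cells in place", {
  init <- matrix(rnorm(10 * 4), 10, 4)
  spec <- drift_diffusion_spec(n_dims = 4, D = 0, speed = 0,
                               trunk_confinement = 0, split_strength = 0,
                               end_confinement = 0, birth_rate = 0,
                               removal_prob = 0, initial_cells = init,
                               n_snapshot_cells = 10, total_time = 5, seed = 2)
  spec$escape_x1 <- NULL
  ds <- simulate_drift_diffusion(spec)
  expect_equal(unname(ds$expression[order(ds$expression[, 1]), ]),
               unname(init[order(init[, 1]), ]))
})

test_that("the same spec and seed reproduce the dataset exactly", {
  s1 <- simulate_drift_diffusion(drift_diffusion_spec(
    seed = 7, target_population = 120, n_snapshot_cells = 60, total_time = 18))
  s2 <- simulate_drift_diffusion(drift_diffusion_spec(
    seed = 7, target_population = 120, n_snapshot_cells = 60, total_time = 18))
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$cells, s2$cells)

  g1 <- simulate_gene_network(gene_network_spec(2, seed = 5))
  g2 <- simulate_gene_network(gene_network_spec(2, seed = 5))
  expect_identical(g1$expression, g2$expression)
})

test_that("balanced default rates keep the population near its target", {
  ratio <- vapply(1:20, function(s) {
    ds <- simulate_drift_diffusion(drift_diffusion_spec(seed = s))
    ds$diagnostics$mean_population / ds$spec$target_population
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("population process is time-stationary at late times", {
  d1 <- simulate_drift_diffusion(drift_diffusion_spec(seed = 2, total_time = 30))
  d2 <- simulate_drift_diffusion(drift_diffusion_spec(seed = 2, total_time = 40))
  for (j in 1:2) {
    ks <- suppressWarnings(
      stats::ks.test(d1$expression[, j], d2$expression[, j])$statistic)
    expect_lt(unname(ks), 0.15)
  }
})

test_that("unbalanced rates fail with an informative error", {
  spec <- drift_diffusion_spec(birth_rate = 1, n_snapshot_cells = 400,
                               total_time = 15, seed = 3)
  expect_error(simulate_drift_diffusion(spec), "birth rate")
})

test_that("noise dimensions are statistically exchangeable", {
  ds <- fork_dataset()
  v <- apply(ds$expression[, 3:50], 2, var)
  expect_lt(sd(v) / mean(v), 0.3)
  expect_lt(max(abs(colMeans(ds$expression[, 3:50]))), 0.2)
})

test_that("lineage labels follow the deterministic sink catchment", {
  ds <- fork_dataset()
  for (sink in ds$spec$sinks) {
    d2 <- rowSums(sweep(ds$expression[, 1:2], 2, sink$center)^2)
    inside <- d2 <= sink$radius^2
    expect_true(all(ds$cells$lineage[inside] == sink$label))
  }
})

test_that("noise-free toggle kinetics have two distinct stable fixed points", {
  spec <- gene_network_spec(2, seed = 1)
  drift <- ldd:::.hill_drift(spec)
  # brute-force integration from perturbed symmetric starts
  fps <- lapply(list(c(1.5, 0.8), c(0.8, 1.5)), function(x0) {
    x <- matrix(x0, 1)
    for (i in 1:6000) x <- pmax(x + drift(x) * 0.01, 0)
    drop(x)
  })
  expect_gt(sum(abs(fps[[1]] - fps[[2]])), 1)
  for (fp in fps) {
    expect_lt(max(abs(drift(matrix(fp, 1)))), 1e-6)  # production = degradation
  }
  expect_identical(fps[[1]], rev(fps[[2]]))          # mirror symmetry
  # the spec's sink centres are these fixed points
  centres <- lapply(spec$sinks, `[[`, "center")
  expect_lt(min(vapply(centres, function(cc) sum(abs(cc - fps[[1]])), 1)), 1e-4)
})

test_that("toggle terminal cells express one gene high and one low", {
  ds <- toggle_dataset()
  for (sink in ds$spec$sinks) {
    d2 <- rowSums(sweep(ds$expression, 2, sink$center)^2)
    cells <- ds$expression[d2 <= sink$radius^2, , drop = FALSE]
    expect_gt(nrow(cells), 0)
    expect_true(all(apply(cells, 1, max) > 2))
    expect_true(all(apply(cells, 1, min) < 1))
  }
})

test_that("six-gene terminal states have exactly two high genes", {
  spec <- gene_network_spec(6, seed = 1)
  expect_length(spec$sinks, 4)
  labels <- vapply(spec$sinks, `[[`, character(1), "label")
  expect_length(unique(labels), 4)
  for (sink in spec$sinks) {
    high <- sink$center > max(sink$center) / 2
    expect_equal(sum(high), 2)
  }
})
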