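# Shared fixtures, built lazily once per test run. The default benchmark specs
# are deliberately used as-is: they are the study conditions the whole suite
# exercises.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fork_dataset <- function() {
  fixture("fork", function() simulate_drift_diffusion(drift_diffusion_spec(seed = 1)))
}

fork_fit <- function() {
  fixture("fork_fit", function() ldd_fit(fork_dataset(), k_clusters = 4, m = 10))
}

toggle_dataset <- function() {
  fixture("toggle", function() simulate_gene_network(gene_network_spec(2, seed = 1)))
}

# small, fast dataset for I/O round trips
small_dataset <- function() {
  fixture("small", function() {
    simulate_drift_diffusion(drift_diffusion_spec(
      seed = 4, target_population = 120, n_snapshot_cells = 60, total_time = 20))
  })
}

# two well-separated Gaussian blobs
make_blobs <- function(n_per = 30, sep = 10, sd = 0.5, seed = 11, dims = 2) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * dims, 0, sd), n_per),
               matrix(rnorm(n_per * dims, sep, sd), n_per))
    rownames(x) <- sprintf("cell_%03d", seq_len(2 * n_per))
    colnames(x) <- paste0("g", seq_len(dims))
    x
  })
}

random_stochastic <- function(K, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(runif(K * K), K)
    P / rowSums(P)
  })
}

cluster_mean_age <- function(dataset, labels) {
  tapply(dataset$cells$true_time, labels, mean)
}
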