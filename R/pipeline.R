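# End-to-end pipeline: expression matrix -> PCA embedding -> diffusion map
# -> k-means coarse-graining -> net-flow -> potential -> pseudo-time and
# directed paths.

#' Fit a differentiation landscape
#'
#' Runs the full pipeline on a cells x genes expression matrix: centred PCA
#' to `m` dimensions, anisotropic diffusion map (median-distance bandwidth,
#' symmetrised kNN kernel graph, `alpha = 1/2` normalisation), k-means
#' clustering into `k_clusters` metastable groups, coarse-grained cluster
#' chain, kernel-density boundary-derivative net-flow estimation with the
#' steady-state correction, minimum-norm least-squares potential solve, and
#' path construction. Pseudo-time is the additive inverse of the cluster
#' potential.
#'
#' @param data expression input: numeric matrix (cells x genes), data frame
#'   with a cell-id column, or an `ldd_dataset` from the simulators.
#' @param k_clusters number of clusters; choose at least
#'   `number of expected lineages + 2` so the stem state, the bifurcation
#'   region and each branch can occupy their own metastable cluster.
#' @param m embedding dimension (default 2).
#' @param knn_k nearest-neighbour count of the kernel graph (capped at n-1).
#' @param alpha diffusion-map normalisation exponent; `1/2` makes the
#'   discrete operator density-invariant and is the model's intended value.
#' @param epsilon kernel width; `NULL` (default) for the median-distance rule.
#' @param D noise amplitude used in the net-flow estimate. It rescales the
#'   potential uniformly and leaves the ordering unchanged, so the default 1
#'   is appropriate when only pseudo-time is needed.
#' @param edge_threshold fraction of the largest off-diagonal weight below
#'   which candidate paths are pruned.
#' @param bw_adjust bandwidth multiplier of the net-flow marginal KDEs; see
#'   [cluster_netflow()].
#' @param labels optional precomputed integer cluster labels (bypasses
#'   k-means; `k_clusters` is then ignored).
#' @param log1p log-transform the expression values before PCA.
#' @param symmetrization kNN symmetrisation rule, `"or"` or `"and"`.
#' @param seed seed for the clustering restarts.
#' @return An object of class `ldd`; see [tidy.ldd()], [glance.ldd()],
#'   [augment.ldd()] and [ggplot2::autoplot()].
#' @examples
#' ds <- simulate_drift_diffusion(drift_diffusion_spec(
#'   target_population = 150, n_snapshot_cells = 120, total_time = 25))
#' fit <- ldd_fit(ds, k_clusters = 4)
#' tidy(fit)
#' @export
ldd_fit <- function(data, k_clusters, m = 2, knn_k = 15, alpha = 0.5,
                    epsilon = NULL, D = 1, edge_threshold = 0.1,
                    labels = NULL, log1p = FALSE, bw_adjust = 3,
                    symmetrization = c("or", "and"), seed = 1) {
  symmetrization <- match.arg(symmetrization)
  cells_meta <- if (inherits(data, "ldd_dataset")) data$cells else NULL
  x <- as_expression_matrix(data)

  embedding <- reduce_dimensions(x, m = m, log1p = log1p)
  diffusion <- diffusion_model(embedding, knn_k = knn_k, alpha = alpha,
                               epsilon = epsilon,
                               symmetrization = symmetrization)
  if (is.null(labels)) {
    labels <- cluster_cells(embedding, k_clusters, seed = seed)
  } else {
    stopifnot(length(labels) == nrow(x))
    labels <- as.integer(labels)
    names(labels) <- rownames(x)
  }
  K <- max(labels)

  coarse <- coarse_transition(diffusion$P, diffusion$mu, labels)
  P_tilde <- cluster_weight_matrix(diffusion$P, diffusion$mu, labels)
  L_hat <- coarse_backward(coarse$P_hat, diffusion$epsilon)

  nf <- cluster_netflow(embedding, labels, D = D, bw_adjust = bw_adjust)
  R_tilde <- postprocess_netflow(nf$R_hat, coarse$n_s)
  V_hat <- solve_potential(coarse$P_hat, R_tilde, diffusion$epsilon)
  pseudotime <- assign_pseudotime(V_hat, labels)
  paths <- build_paths(P_tilde, V_hat,
                       threshold = edge_threshold * max(P_tilde - diag(diag(P_tilde))),
                       n_s = coarse$n_s)

  residual <- sqrt(sum(((coarse$P_hat - diag(K)) %*% V_hat +
                          R_tilde * diffusion$epsilon)^2))
  structure(
    list(embedding = embedding, diffusion = diffusion, labels = labels,
         coarse = c(coarse, list(P_tilde = P_tilde, L_hat = L_hat)),
         netflow = c(nf, list(R_tilde = R_tilde)),
         V_hat = V_hat, pseudotime = pseudotime,
         edges = paths$edges, root = paths$root,
         component = paths$component, cells_meta = cells_meta,
         report = list(n_cells = nrow(x), n_vars = ncol(x), m = m,
                       k_clusters = K, knn_k = diffusion$knn_k,
                       alpha = alpha, epsilon = diffusion$epsilon, D = D,
                       residual = residual,
                       conservation = sum(coarse$n_s * R_tilde),
                       seed = seed)),
    class = "ldd")
}

#' @export
print.ldd <- function(x, ...) {
  r <- x$report
  cat(sprintf("<ldd fit> %d cells, %d clusters, m=%d, epsilon=%.4g\n",
              r$n_cells, r$k_clusters, r$m, r$epsilon))
  cat(sprintf("  root cluster %d (max potential %.4g); %d directed paths\n",
              x$root, max(x$V_hat), nrow(x$edges)))
  cat(sprintf("  potential solve residual %.3g, steady-state balance %.3g\n",
              r$residual, r$conservation))
  invisible(x)
}

#' Per-cluster summary of a landscape fit
#'
#' @param x an `ldd` fit.
#' @param ... unused.
#' @return tibble with one row per cluster: size, stationary mass, raw and
#'   post-processed net-flow, potential and pseudo-time.
#' @method tidy ldd
#' @export
tidy.ldd <- function(x, ...) {
  K <- x$report$k_clusters
  tibble::tibble(cluster = seq_len(K),
                 n_cells = as.integer(x$coarse$n_s),
                 mu_hat = x$coarse$mu_hat,
                 net_flow_raw = x$netflow$R_hat,
                 net_flow = x$netflow$R_tilde,
                 potential = x$V_hat,
                 pseudotime = -x$V_hat,
                 is_root = seq_len(K) == x$root)
}

#' One-row summary of a landscape fit
#'
#' @inheritParams tidy.ldd
#' @return one-row tibble of fit dimensions, bandwidth, solve residual and
#'   the steady-state balance (which should be zero to round-off).
#' @method glance ldd
#' @export
glance.ldd <- function(x, ...) {
  r <- x$report
  tibble::tibble(n_cells = r$n_cells, n_vars = r$n_vars, m = r$m,
                 k_clusters = r$k_clusters, knn_k = r$knn_k,
                 epsilon = r$epsilon, alpha = r$alpha,
                 residual = r$residual, conservation = r$conservation,
                 root_cluster = x$root, n_edges = nrow(x$edges))
}

#' Per-cell results of a landscape fit
#'
#' @inheritParams tidy.ldd
#' @return tibble with one row per cell: embedding coordinates, cluster,
#'   stationary weight and pseudo-time (plus any simulator labels when the
#'   fit was built from an `ldd_dataset`).
#' @method augment ldd
#' @export
augment.ldd <- function(x, ...) {
  out <- dplyr::bind_cols(
    tibble::tibble(cell_id = x$embedding$cell_ids),
    tibble::as_tibble(x$embedding$coords),
    tibble::tibble(cluster = unname(x$labels),
                   mu = unname(x$diffusion$mu),
                   pseudotime = unname(x$pseudotime)))
  if (!is.null(x$cells_meta)) {
    out <- dplyr::left_join(out, x$cells_meta, by = "cell_id")
  }
  out
}

#' Evaluate a fit against simulator truth
#'
#' Computes the evaluation statistics for a fit built from a labelled
#' dataset: the Pearson correlation between pseudo-time and true time, and a
#' one-sided Wilcoxon rank-sum test that the earliest stage precedes the
#' latest stage in pseudo-time.
#'
#' @param fit an `ldd` fit carrying simulator labels (or supply `truth`).
#' @param truth optional tibble with `cell_id`, `true_time` and `stage`.
#' @return tibble with columns `metric` and `value`.
#' @export
evaluate_fit <- function(fit, truth = NULL) {
  cells <- augment(fit)
  if (!is.null(truth)) {
    cells <- dplyr::left_join(
      dplyr::select(cells, -dplyr::any_of(c("true_time", "lineage", "stage"))),
      truth, by = "cell_id")
  }
  if (is.null(cells$true_time)) stop("no truth labels available")
  rho <- evaluate_correlation(cells$pseudotime, cells$true_time)
  out <- tibble::tibble(metric = "pearson_true_time", value = rho)
  if (!is.null(cells$stage) && all(c("early", "late") %in% cells$stage)) {
    p <- wilcoxon_stage_test(cells$pseudotime[cells$stage == "early"],
                             cells$pseudotime[cells$stage == "late"])
    out <- dplyr::bind_rows(out,
      tibble::tibble(metric = "wilcoxon_early_vs_late_p", value = p))
  }
  out
}

#' Pre-registered benchmark conditions
#'
#' Analysis settings used for the three synthetic benchmarks throughout the
#' package. The drift-diffusion fork is analysed with four clusters (source,
#' bifurcation, two branches) in a 10-dimensional embedding - the retained
#' noise components carry the isotropic diffusion spread that grows with cell
#' age, and averaging the net-flow marginals over them stabilises the
#' estimate. The two-gene toggle uses seven clusters in its full 2-D
#' expression space. The six-gene network uses nine clusters (progenitor
#' channel, saddle, intermediates, four terminal states) in a 4-D embedding:
#' its decisions span the g1-g2 contrast plus the two downstream toggle
#' contrasts, so four components are needed to see all branches.
#'
#' @param model `"driftdiff"`, `"toggle2"` or `"net6"`.
#' @param seed simulation seed.
#' @return list with `spec`, `k_clusters` and `m`.
#' @export
benchmark_conditions <- function(model = c("driftdiff", "toggle2", "net6"),
                                 seed = 1) {
  model <- match.arg(model)
  switch(model,
    driftdiff = list(spec = drift_diffusion_spec(seed = seed),
                     k_clusters = 4, m = 10),
    toggle2 = list(spec = gene_network_spec(2, seed = seed),
                   k_clusters = 7, m = 2),
    net6 = list(spec = gene_network_spec(6, seed = seed),
                k_clusters = 9, m = 4))
}

#' Run one synthetic benchmark end to end
#'
#' Simulates the requested benchmark with its pre-registered conditions,
#' fits the landscape, and reports the Pearson correlation between
#' pseudo-time and true time.
#'
#' @inheritParams benchmark_conditions
#' @return tibble with `model`, `seed`, `n_cells`, `pearson`.
#' @export
run_benchmark <- function(model = c("driftdiff", "toggle2", "net6"),
                          seed = 1) {
  model <- match.arg(model)
  cond <- benchmark_conditions(model, seed)
  ds <- if (model == "driftdiff") simulate_drift_diffusion(cond$spec) else
    simulate_gene_network(cond$spec)
  fit <- ldd_fit(ds, k_clusters = cond$k_clusters, m = cond$m, seed = seed)
  cells <- augment(fit)
  tibble::tibble(model = model, seed = seed, n_cells = nrow(cells),
                 pearson = evaluate_correlation(cells$pseudotime,
                                                cells$true_time))
}
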