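# ldd — differentiation landscapes and pseudo-time from a continuous birth-death process

Single-cell RNA-seq captures a snapshot of a differentiating tissue: a
mixture of pluripotent, intermediate and committed cells, with no time
stamps. `ldd` reconstructs the arrow of time in such a snapshot by treating
the population as a **continuous birth-death (source–sink Fokker–Planck)
process**: cells are born in a source region, drift down a potential with
diffusion noise, and are removed at sinks. At non-equilibrium steady state
the density $p(\mathbf{x})$ satisfies

$$\nabla\cdot(p\,\nabla F) + D\,\Delta p + R\,p = 0,\qquad F = U + V,$$

where $U = -D\log p$ is the equilibrium (diffusion) potential and the
advection potential $V$ solves $[\nabla\log p\cdot\nabla + \Delta]\,V = -R$
with $R(\mathbf{x})$ the local net birth-death rate. $V$ quantifies potency:
cells run from high $V$ (stem) to low $V$ (differentiated), so $-V$ is a
pseudo-time — and, unlike distance-based methods, no root cell needs to be
supplied.

The package implements the full estimator:

1. centred PCA embedding (`reduce_dimensions()`);
2. anisotropic diffusion map with $\alpha = 1/2$ on a symmetrised kNN
   kernel graph — transition matrix $P$, stationary law $\mu$, backward
   operator $L = (P - I)/\varepsilon$ (`diffusion_model()`);
3. k-means coarse-graining into a cluster-level chain $\hat P$ and the
   symmetric flux matrix $\tilde P$ (`cluster_cells()`,
   `coarse_transition()`, `cluster_weight_matrix()`);
4. per-cluster net-flow rates from kernel-density boundary derivatives via
   the divergence theorem, with an exact steady-state correction
   (`cluster_netflow()`, `postprocess_netflow()`);
5. minimum-norm least-squares potential solve
   $\hat V = -(\hat P - I)^\dagger \tilde R\,\varepsilon$, pseudo-time
   $= -\hat V$, and directed differentiation paths oriented downhill in
   $\hat V$ (`solve_potential()`, `build_paths()`).

Three labelled synthetic benchmarks — a 50-dimensional bifurcating
drift-diffusion fork, a two-gene toggle switch and a six-gene network with
four lineages — make the whole pipeline testable end to end
(`simulate_drift_diffusion()`, `simulate_gene_network()`).

## Worked example

```r
library(ldd)

spec  <- drift_diffusion_spec(seed = 1)     # the fork benchmark, 400 cells
cells <- simulate_drift_diffusion(spec)
cells
#> <ldd_dataset> 400 cells x 50 variables (driftdiff benchmark)
#>   lineages: branch_down, branch_up, progenitor
#>   mean steady population 599 (target 600)

fit <- ldd_fit(cells, k_clusters = 4, m = 10)
fit
#> <ldd fit> 400 cells, 4 clusters, m=10, epsilon=2.023
#>   root cluster 1 (max potential 183.2); 3 directed paths
#>   potential solve residual 0.46, steady-state balance 2.27e-13

tidy(fit)
#> # A tibble: 4 x 8
#>   cluster n_cells mu_hat net_flow_raw net_flow potential pseudotime is_root
#>     <int>   <int>  <dbl>        <dbl>    <dbl>     <dbl>      <dbl> <lgl>
#> 1       1     111  0.282        15.0      6.64     183.      -183.  TRUE
#> 2       2     106  0.265         5.09    -3.32      37.2      -37.2 FALSE
#> 3       3     104  0.258         6.17    -2.25    -156.       156.  FALSE
#> 4       4      79  0.194         6.50    -1.91     -64.7       64.7 FALSE

fit$edges
#> # A tibble: 3 x 3
#>    from    to  weight
#>   <int> <int>   <dbl>
#> 1     1     2 0.0263
#> 2     2     3 0.00663
#> 3     2     4 0.00778

evaluate_fit(fit)
#> # A tibble: 2 x 2
#>   metric                      value
#>   <chr>                       <dbl>
#> 1 pearson_true_time        8.40e- 1
#> 2 wilcoxon_early_vs_late_p 1.63e-50
```

Reading the output: cluster 1 has a strongly positive net-flow (a birth
region) and the maximal potential — it is the root; the paths 1 → 2 → {3, 4}
recover the fork's source → bifurcation → two-sinks topology; per-cell
pseudo-time (via `augment(fit)`) correlates with the simulator's true cell
ages at 0.84, and early-stage cells precede late-stage cells (one-sided
Wilcoxon rank-sum p ≈ 10⁻⁵⁰). `autoplot(fit)` draws the embedding coloured
by pseudo-time with the directed paths; `plot_landscape_surface(fit)`
renders the Waddington-style surface.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/ldd.R simulate --model driftdiff --seed 1 --out data/
Rscript inst/cli/ldd.R run --input data/driftdiff_1_expression.csv \
    --clusters 4 --m 10 --out results/
Rscript inst/cli/ldd.R evaluate --pseudotime results/pseudotime.tsv \
    --truth data/driftdiff_1_cells.tsv
```

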