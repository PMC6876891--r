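# Benchmark specifications: parameter objects for the labelled synthetic
# generators. Both describe a non-equilibrium steady-state population: cells
# are born inside a source ball, drift down a potential (or along gene-network
# kinetics) with isotropic diffusion noise, and are removed stochastically
# inside sink balls at the branch termini.

#' Specification for the bifurcating drift-diffusion benchmark
#'
#' Parameters of a drift-diffusion process in `n_dims` dimensions whose first
#' two coordinates feel a "tuning fork" potential: a confined channel of
#' constant downhill slope along the first coordinate that splits, at
#' `bifurcation_at`, into two branches ending in wells at
#' \eqn{x_2 = \pm well\_sep}. The remaining coordinates carry pure diffusion
#' noise. Cells are born at rate `birth_rate` uniformly inside a source ball
#' at the channel entrance and are removed with per-step probability
#' `removal_prob` inside sink balls at the two branch termini, so the
#' population fluctuates around a steady size.
#'
#' The governing potential on the first two coordinates is
#' \deqn{F(x_1, x_2) = -v x_1 + t(x_1)\, x_2^2/2 + c(x_1)\, G(x_2),
#'   \qquad G(x_2) = \big[(x_2^2 - W^2)^2 - W^4\big] / (4 W^2),}
#' where \eqn{t(x_1)} ramps the transverse channel confinement
#' (`trunk_confinement`) down to zero across the bifurcation while
#' \eqn{c(x_1)} ramps the double-well term up to `split_strength` and then
#' back down to `end_confinement` past `relax_at`. Young cells therefore sit
#' in a tight channel; the branch choice is committed quickly at the
#' bifurcation; and the terminal populations are only loosely confined, so
#' the conditional density of a cluster broadens steadily with age - the
#' spatial signature of flow from a source towards sinks that the net-flow
#' estimator reads out. Particles follow the Euler-Maruyama update
#' \eqn{x(t+\Delta t) = x(t) - \nabla F\,\Delta t + \sqrt{D\Delta t}\,\xi}.
#'
#' @param n_dims total dimension of the state (first two carry the drift).
#' @param dt integration time step.
#' @param D noise amplitude (variance per unit time per coordinate).
#' @param speed constant drift speed along the channel coordinate.
#' @param trunk_confinement transverse restoring rate in the channel.
#' @param split_strength double-well strength right after the bifurcation
#'   (sets how fast the branch choice is committed).
#' @param end_confinement residual double-well strength at the termini.
#' @param well_sep transverse position of the two branches (wells at
#'   \eqn{\pm well\_sep}).
#' @param bifurcation_at channel position where the branches open.
#' @param relax_at position past which the confinement relaxes to
#'   `end_confinement`.
#' @param ramp_width,relax_width logistic widths of the two ramps.
#' @param branch_length distance from the bifurcation to the sink centres.
#' @param source_radius radius of the source ball at the origin.
#' @param sink_radius radius of the two sink balls.
#' @param removal_prob per-step removal probability inside a sink ball.
#' @param birth_rate expected births per unit time; default balances the
#'   removal process so the steady population sits near `target_population`.
#' @param target_population intended steady-state population size.
#' @param n_snapshot_cells number of cells sampled in the final snapshot.
#' @param total_time simulated time before the snapshot is taken.
#' @param initial_cells optional matrix of starting cells (`n x n_dims`);
#'   by default the population grows from empty.
#' @param seed integer seed controlling the whole simulation.
#'
#' @return An object of class `drift_diffusion_spec`.
#' @seealso [simulate_drift_diffusion()]
#' @export
drift_diffusion_spec <- function(n_dims = 50,
                                 dt = 0.05,
                                 D = 0.05,
                                 speed = 1,
                                 trunk_confinement = 1,
                                 split_strength = 4,
                                 end_confinement = 0.8,
                                 well_sep = 2,
                                 bifurcation_at = 4,
                                 relax_at = 6,
                                 ramp_width = 0.5,
                                 relax_width = 0.85,
                                 branch_length = 4,
                                 source_radius = 0.5,
                                 sink_radius = 1.5,
                                 removal_prob = 0.3,
                                 birth_rate = NULL,
                                 target_population = 600,
                                 n_snapshot_cells = 400,
                                 total_time = 40,
                                 initial_cells = NULL,
                                 seed = 1) {
  stopifnot(n_dims >= 2, dt > 0, D >= 0, total_time > 0, well_sep > 0,
            n_snapshot_cells >= 1, removal_prob >= 0, removal_prob <= 1,
            source_radius > 0, sink_radius > 0)
  sink_x <- bifurcation_at + branch_length
  sinks <- list(
    list(center = c(sink_x, 0.9 * well_sep), radius = sink_radius,
         removal_prob = removal_prob, dims = 1:2, label = "branch_up"),
    list(center = c(sink_x, -0.9 * well_sep), radius = sink_radius,
         removal_prob = removal_prob, dims = 1:2, label = "branch_down")
  )
  # expected lifetime: transit to first sink contact plus the pause while the
  # branch choice is committed at the bifurcation, plus the mean sink dwell
  lifetime <- if (speed > 0) {
    (sink_x - sink_radius) / speed + 1.9 + dt / max(removal_prob, dt)
  } else {
    total_time
  }
  if (is.null(birth_rate)) birth_rate <- target_population / lifetime
  structure(
    list(model = "driftdiff", n_dims = n_dims, dt = dt, D = D,
         speed = speed, trunk_confinement = trunk_confinement,
         split_strength = split_strength, end_confinement = end_confinement,
         well_sep = well_sep, bifurcation_at = bifurcation_at,
         relax_at = relax_at, ramp_width = ramp_width,
         relax_width = relax_width,
         source = list(center = c(0, 0), radius = source_radius, dims = 1:2),
         sinks = sinks, birth_rate = birth_rate,
         target_population = target_population,
         n_snapshot_cells = n_snapshot_cells, total_time = total_time,
         escape_x1 = sink_x + 1.5,
         initial_cells = initial_cells,
         lifetime_est = lifetime, seed = seed,
         var_names = sprintf("dim_%02d", seq_len(n_dims))),
    class = c("drift_diffusion_spec", "ldd_sim_spec")
  )
}

# Confinement ramps of the tuning-fork potential and their derivatives.
.fork_ramps <- function(spec, x1) {
  sb <- plogis((x1 - spec$bifurcation_at) / spec$ramp_width)
  se <- plogis((x1 - spec$relax_at) / spec$relax_width)
  list(
    t = spec$trunk_confinement * (1 - sb),
    tp = -spec$trunk_confinement * sb * (1 - sb) / spec$ramp_width,
    c = spec$split_strength * sb +
      (spec$end_confinement - spec$split_strength) * se,
    cp = spec$split_strength * sb * (1 - sb) / spec$ramp_width +
      (spec$end_confinement - spec$split_strength) * se * (1 - se) /
        spec$relax_width
  )
}

#' Tuning-fork potential of the drift-diffusion benchmark
#'
#' Evaluates \eqn{F(x_1,x_2)} of [drift_diffusion_spec()] (the remaining
#' coordinates are potential-free).
#'
#' @param spec a `drift_diffusion_spec`.
#' @param x1,x2 coordinate vectors (recycled).
#' @return numeric vector of potential values.
#' @export
fork_potential <- function(spec, x1, x2) {
  r <- .fork_ramps(spec, x1)
  W2 <- spec$well_sep^2
  G <- ((x2^2 - W2)^2 - W2^2) / (4 * W2)
  -spec$speed * x1 + r$t * x2^2 / 2 + r$c * G
}

# Negative gradient of the tuning-fork potential, vectorised over rows of X.
.fork_drift <- function(spec) {
  W2 <- spec$well_sep^2
  v <- spec$speed
  function(X) {
    x1 <- X[, 1]
    x2 <- X[, 2]
    r <- .fork_ramps(spec, x1)
    G <- ((x2^2 - W2)^2 - W2^2) / (4 * W2)
    Gp <- x2 * (x2^2 - W2) / W2
    out <- matrix(0, nrow(X), ncol(X))
    out[, 1] <- v - r$tp * x2^2 / 2 - r$cp * G
    out[, 2] <- -(r$t * x2 + r$c * Gp)
    out
  }
}

#' Specification for the mutually inhibitory gene-network benchmarks
#'
#' Parameters of a stochastic gene-regulatory network with Hill-kinetics
#' production and linear degradation,
#' \deqn{\dot x_i = a_i \prod_{j \to i} act(x_j) \prod_{j \dashv i} inh(x_j)
#'       - k_i x_i + \sqrt{D}\,\eta_i,}
#' with \eqn{act(x) = x^n/(S_{act}^n + x^n)} and
#' \eqn{inh(x) = S_{inh}^n/(S_{inh}^n + x^n)}. Two presets are provided:
#'
#' * `n_genes = 2`: the classic toggle switch - two genes inhibiting each
#'   other, producing two lineages in each of which one gene is high and the
#'   other low.
#' * `n_genes = 6`: three coupled toggles. Genes 1-2 form a first toggle;
#'   genes 3-4 (activated by gene 1) and genes 5-6 (activated by gene 2) form
#'   two downstream toggles, so four terminal branches arise, each with
#'   exactly two highly expressed genes.
#'
#' Cells are born inside a ball around a progenitor co-expression state
#' (both lineage-determining genes high), flow down a deterministic channel
#' to the undecided saddle, commit to a branch, and are removed inside balls
#' around the stable terminal states; the saddle and terminal centres are
#' located numerically from the noise-free kinetics when the spec is built.
#' Negative expression produced by the noise is clipped to zero (events are
#' counted on the simulated dataset).
#'
#' @param n_genes 2 or 6.
#' @param dt integration time step.
#' @param D noise amplitude.
#' @param hill_n Hill coefficient.
#' @param production maximal production rate per gene (scalar or vector).
#' @param basal leaky (basal) production rate added for every gene; keeps
#'   silenced genes fluctuating around `basal/degradation` rather than
#'   piling up at zero.
#' @param degradation linear degradation rate per gene.
#' @param S_inh,S_act half-saturation constants of inhibition / activation.
#' @param interaction_matrix optional signed adjacency overriding the preset
#'   wiring; entry `[j, i]` is `+1` if gene j activates gene i, `-1` if it
#'   inhibits it, `0` otherwise.
#' @param progenitor_coexpression expression level at which the two
#'   lineage-determining genes are co-expressed in newborn cells. Births are
#'   placed in a ball around this co-expression state, from which cells relax
#'   deterministically down to the undecided saddle before committing to a
#'   branch; set to `NULL` to place births at the saddle itself.
#' @param source_radius,sink_radius radii of the birth / removal balls.
#' @param removal_prob per-step removal probability inside a sink ball.
#' @param birth_rate births per unit time; defaults to balance removals near
#'   `target_population`.
#' @param target_population,n_snapshot_cells,total_time,seed as in
#'   [drift_diffusion_spec()].
#'
#' @return An object of class `gene_network_spec`.
#' @seealso [simulate_gene_network()]
#' @export
gene_network_spec <- function(n_genes = 2,
                              dt = 0.02,
                              D = 0.02,
                              hill_n = 8,
                              production = NULL,
                              basal = 0.3,
                              degradation = 1,
                              S_inh = 1,
                              S_act = 1.2,
                              interaction_matrix = NULL,
                              progenitor_coexpression = 3,
                              source_radius = 0.3,
                              sink_radius = 0.7,
                              removal_prob = 0.2,
                              birth_rate = NULL,
                              target_population = if (n_genes == 2) 800 else 600,
                              n_snapshot_cells = if (n_genes == 2) 600 else 400,
                              total_time = 40,
                              seed = 1) {
  stopifnot(n_genes %in% c(2, 6), dt > 0, D >= 0, hill_n > 0,
            removal_prob > 0, removal_prob <= 1)
  if (is.null(production)) {
    production <- if (n_genes == 2) c(4, 4) else c(4, 4, 3, 3, 3, 3)
  }
  production <- rep_len(production, n_genes)
  degradation <- rep_len(degradation, n_genes)
  if (is.null(interaction_matrix)) {
    A <- matrix(0L, n_genes, n_genes)
    A[2, 1] <- A[1, 2] <- -1L              # mutual inhibition of the top toggle
    if (n_genes == 6) {
      A[4, 3] <- A[3, 4] <- -1L
      A[6, 5] <- A[5, 6] <- -1L
      A[1, 3] <- A[1, 4] <- 1L             # gene 1 arms toggle 3-4
      A[2, 5] <- A[2, 6] <- 1L             # gene 2 arms toggle 5-6
    }
  } else {
    A <- interaction_matrix
    stopifnot(is.matrix(A), nrow(A) == n_genes, ncol(A) == n_genes)
  }
  if (A[2, 1] != -1L || A[1, 2] != -1L) {
    stop("the top two genes must form a mutually inhibitory toggle")
  }
  var_names <- paste0("g", seq_len(n_genes))
  spec <- list(model = if (n_genes == 2) "toggle2" else "net6",
               n_dims = n_genes, n_genes = n_genes, dt = dt, D = D,
               hill_n = hill_n, production = production, basal = basal,
               degradation = degradation, S_inh = S_inh, S_act = S_act,
               interaction_matrix = A,
               n_snapshot_cells = n_snapshot_cells,
               target_population = target_population,
               total_time = total_time, seed = seed, var_names = var_names)
  class(spec) <- c("gene_network_spec", "ldd_sim_spec")

  fp <- .network_fixed_points(spec)
  spec$stem <- fp$stem
  src_center <- if (is.null(progenitor_coexpression)) fp$stem else {
    .channel_entry(spec, progenitor_coexpression)
  }
  spec$source <- list(center = src_center, radius = source_radius,
                      dims = seq_len(n_genes))
  spec$sinks <- lapply(seq_along(fp$terminal), function(i) {
    list(center = fp$terminal[[i]], radius = sink_radius,
         removal_prob = removal_prob, dims = seq_len(n_genes),
         label = fp$labels[[i]])
  })
  # lifetime: co-expression channel decay + saddle launch + branch travel +
  # expected sink dwell (calibrated on the noise-free kinetics; see the
  # methods vignette)
  lifetime <- if (n_genes == 2) 3.33 else 3.55
  spec$lifetime_est <- lifetime
  spec$birth_rate <- if (is.null(birth_rate)) target_population / lifetime else birth_rate
  spec
}

# Hill-kinetics drift (production minus degradation), vectorised over rows.
.hill_drift <- function(spec) {
  A <- spec$interaction_matrix
  n <- spec$hill_n
  Sa <- spec$S_act^n
  Si <- spec$S_inh^n
  a <- spec$production
  k <- spec$degradation
  ng <- spec$n_genes
  function(X) {
    out <- matrix(0, nrow(X), ncol(X))
    Xn <- pmax(X, 0)^n
    for (i in seq_len(ng)) {
      p <- rep(a[i], nrow(X))
      for (j in seq_len(ng)) {
        if (A[j, i] == 1L) p <- p * Xn[, j] / (Sa + Xn[, j])
        if (A[j, i] == -1L) p <- p * Si / (Si + Xn[, j])
      }
      out[, i] <- spec$basal + p - k[i] * X[, i]
    }
    out
  }
}

# Locate the undecided (symmetric) fixed point and the stable terminal states
# of the noise-free kinetics by forward integration: the symmetric point is
# attracting within the symmetric subspace, which exact mirror arithmetic
# preserves; terminal states are reached from small symmetry-breaking kicks.
.network_fixed_points <- function(spec) {
  drift <- .hill_drift(spec)
  ng <- spec$n_genes
  integrate_to_fp <- function(x0, time = 80, dt = 0.01) {
    X <- matrix(x0, 1)
    for (i in seq_len(round(time / dt))) {
      X <- pmax(X + drift(X) * dt, 0)
    }
    drop(X)
  }
  stem <- integrate_to_fp(rep(0.5, ng))
  eps <- 0.1
  kick <- function(s1, s2) {
    d <- rep(0, ng)
    d[1:2] <- c(s1, -s1) * eps
    if (ng == 6) {
      if (s1 > 0) d[3:4] <- c(s2, -s2) * eps else d[5:6] <- c(s2, -s2) * eps
    }
    pmax(stem + d, 0)
  }
  kicks <- if (ng == 2) list(c(1, 0), c(-1, 0)) else {
    list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  }
  terminal <- lapply(kicks, function(k) integrate_to_fp(kick(k[1], k[2]), time = 120))
  labels <- vapply(terminal, function(x) {
    paste(spec$var_names[x > max(x) / 2], collapse = "_")
  }, character(1))
  if (anyDuplicated(labels)) {
    stop("terminal states of the network are not distinct; ",
         "check the interaction matrix and rate parameters")
  }
  list(stem = stem, terminal = terminal, labels = labels)
}

# Birth region of the gene networks: a co-expression state where the two
# lineage-determining genes sit well above their undecided level. Cells born
# there relax down a tight deterministic channel onto the saddle before the
# branch choice. Downstream genes are set to their conditional steady level
# given the clamped co-expression, found by integrating the remaining
# coordinates with the top two genes held fixed.
.channel_entry <- function(spec, level) {
  ng <- spec$n_genes
  x <- rep(0.5, ng)
  x[1:2] <- level
  if (ng > 2) {
    drift <- .hill_drift(spec)
    for (i in seq_len(4000)) {
      d <- drift(matrix(x, 1))
      d[, 1:2] <- 0
      x <- pmax(x + drop(d) * 0.01, 0)
    }
  }
  x
}

.spec_drift <- function(spec) {
  if (inherits(spec, "drift_diffusion_spec")) .fork_drift(spec) else .hill_drift(spec)
}

#' @export
print.ldd_sim_spec <- function(x, ...) {
  cat(sprintf("<%s spec> %d dims, dt=%g, D=%g, birth rate=%.3g/time, %d sinks\n",
              x$model, x$n_dims, x$dt, x$D, x$birth_rate, length(x$sinks)))
  cat(sprintf("  target population %d, snapshot %d cells, horizon %g, seed %d\n",
              x$target_population, x$n_snapshot_cells, x$total_time, x$seed))
  invisible(x)
}
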