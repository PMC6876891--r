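# Birth-death simulation engine shared by the synthetic benchmarks.
# Per step: Poisson births in the source ball, Euler-Maruyama drift+noise
# update, optional clipping at zero, Bernoulli removal inside sink balls,
# then ageing. The snapshot is taken after `total_time`, by which point the
# population-size process has settled around its steady value.

.sample_ball <- function(n, center, radius) {
  d <- length(center)
  u <- matrix(rnorm(n * d), n, d)
  r <- radius * runif(n)^(1 / d)
  u <- u / sqrt(rowSums(u^2))
  sweep(u * r, 2, center, `+`)
}

.run_birth_death <- function(spec, clip_zero = FALSE) {
  drift <- .spec_drift(spec)
  nd <- spec$n_dims
  dt <- spec$dt
  n_steps <- round(spec$total_time / dt)
  sd_noise <- sqrt(spec$D * dt)
  src <- spec$source

  X <- spec$initial_cells
  if (is.null(X)) X <- matrix(numeric(0), 0, nd)
  stopifnot(ncol(X) == nd)
  age <- rep(0, nrow(X))
  pop_trace <- integer(n_steps)
  clip_count <- 0L
  escape_count <- 0L

  for (step in seq_len(n_steps)) {
    nb <- rpois(1, spec$birth_rate * dt)
    if (nb > 0) {
      born <- matrix(0, nb, nd)
      born[, src$dims] <- .sample_ball(nb, src$center, src$radius)
      X <- rbind(X, born)
      age <- c(age, rep(0, nb))
    }
    n_alive <- nrow(X)
    if (n_alive == 0) {
      if (spec$birth_rate * dt > 0) next
      stop(sprintf(paste0("population extinct at t=%.2f: birth rate %.3g ",
                          "cannot balance sink removal probability %.3g"),
                   step * dt, spec$birth_rate,
                   max(vapply(spec$sinks, `[[`, numeric(1), "removal_prob"))))
    }
    X <- X + drift(X) * dt
    if (sd_noise > 0) X <- X + matrix(rnorm(n_alive * nd, sd = sd_noise), n_alive, nd)
    if (clip_zero) {
      neg <- X < 0
      if (any(neg)) {
        clip_count <- clip_count + sum(neg)
        X[neg] <- 0
      }
    }
    if (!all(is.finite(X))) {
      stop("non-finite coordinates during simulation; reduce dt or the noise amplitude")
    }
    keep <- rep(TRUE, n_alive)
    for (sink in spec$sinks) {
      d2 <- rowSums(sweep(X[, sink$dims, drop = FALSE], 2, sink$center)^2)
      inside <- which(keep & d2 <= sink$radius^2)
      if (length(inside)) {
        keep[inside[runif(length(inside)) < sink$removal_prob]] <- FALSE
      }
    }
    if (!is.null(spec$escape_x1)) {
      esc <- keep & X[, 1] > spec$escape_x1
      escape_count <- escape_count + sum(esc)
      keep[esc] <- FALSE
    }
    if (!all(keep)) {
      X <- X[keep, , drop = FALSE]
      age <- age[keep]
    }
    age <- age + dt
    pop_trace[step] <- nrow(X)
  }

  if (nrow(X) == 0) {
    stop(sprintf("population extinct: birth rate %.3g cannot balance sink removal",
                 spec$birth_rate))
  }
  if (nrow(X) < spec$n_snapshot_cells) {
    stop(sprintf(paste0("only %d cells alive at snapshot time but %d requested; ",
                        "birth rate %.3g is too low for the sink removal rates"),
                 nrow(X), spec$n_snapshot_cells, spec$birth_rate))
  }
  idx <- sample.int(nrow(X), spec$n_snapshot_cells)
  list(X = X[idx, , drop = FALSE], age = age[idx], pop_trace = pop_trace,
       clip_count = clip_count, escape_count = escape_count)
}

# Deterministic lineage: integrate the noise-free drift from each snapshot
# position; the first sink ball entered gives the label, cells that reach no
# sink within the horizon keep the progenitor label.
.assign_lineage <- function(spec, X, horizon = 3 * spec$lifetime_est) {
  drift <- .spec_drift(spec)
  n <- nrow(X)
  lineage <- rep(NA_character_, n)
  Y <- X
  clip <- inherits(spec, "gene_network_spec")
  n_steps <- round(horizon / spec$dt)
  for (step in seq_len(n_steps)) {
    open <- which(is.na(lineage))
    if (!length(open)) break
    for (sink in spec$sinks) {
      d2 <- rowSums(sweep(Y[open, sink$dims, drop = FALSE], 2, sink$center)^2)
      hit <- open[d2 <= sink$radius^2]
      lineage[hit] <- sink$label
      open <- setdiff(open, hit)
    }
    if (!length(open)) break
    Y[open, ] <- Y[open, , drop = FALSE] + drift(Y[open, , drop = FALSE]) * spec$dt
    if (clip) Y[open, ] <- pmax(Y[open, , drop = FALSE], 0)
  }
  lineage[is.na(lineage)] <- "progenitor"
  lineage
}

.finish_dataset <- function(spec, sim) {
  n <- nrow(sim$X)
  cell_ids <- sprintf("cell_%04d", seq_len(n))
  expr <- sim$X
  dimnames(expr) <- list(cell_ids, spec$var_names)
  lineage <- .assign_lineage(spec, sim$X)
  breaks <- unique(quantile(sim$age, c(0, 1 / 3, 2 / 3, 1)))
  stage <- if (length(breaks) >= 3) {
    as.character(cut(sim$age, breaks = breaks, include.lowest = TRUE,
                     labels = c("early", "mid", "late")[seq_len(length(breaks) - 1)]))
  } else {
    rep("early", n)
  }
  structure(
    list(expression = expr,
         cells = tibble::tibble(cell_id = cell_ids, true_time = sim$age,
                                lineage = lineage, stage = stage),
         spec = spec,
         diagnostics = list(pop_trace = sim$pop_trace,
                            mean_population = mean(tail(sim$pop_trace,
                                                        length(sim$pop_trace) %/% 2)),
                            clip_count = sim$clip_count,
                            escape_count = sim$escape_count)),
    class = "ldd_dataset"
  )
}

#' Simulate the bifurcating drift-diffusion benchmark
#'
#' Runs the birth-death particle simulation described by
#' [drift_diffusion_spec()] until the population-size process is stationary,
#' then samples a labelled snapshot. Every cell carries its `true_time` (age
#' since birth), a deterministic `lineage` label (terminal sink basin of the
#' noise-free flow started at its position) and a coarse `stage` label
#' (terciles of true time).
#'
#' @param spec a [drift_diffusion_spec()].
#' @return An `ldd_dataset`: a list with `expression` (cells x dims matrix),
#'   `cells` (tibble with `cell_id`, `true_time`, `lineage`, `stage`),
#'   the `spec`, and simulation `diagnostics`.
#' @examples
#' ds <- simulate_drift_diffusion(drift_diffusion_spec(
#'   target_population = 150, n_snapshot_cells = 100, total_time = 25))
#' dplyr::count(ds$cells, lineage)
#' @export
simulate_drift_diffusion <- function(spec) {
  stopifnot(inherits(spec, "drift_diffusion_spec"))
  sim <- withr::with_seed(spec$seed, .run_birth_death(spec, clip_zero = FALSE))
  .finish_dataset(spec, sim)
}

#' Simulate a mutually inhibitory gene-network benchmark
#'
#' Same birth-death snapshot contract as [simulate_drift_diffusion()], with
#' drift given by Hill-kinetics production minus linear degradation per
#' [gene_network_spec()]. Expression driven negative by the noise is clipped
#' to zero; the number of clip events is reported in the dataset diagnostics.
#'
#' @param spec a [gene_network_spec()].
#' @return An `ldd_dataset`; see [simulate_drift_diffusion()].
#' @export
simulate_gene_network <- function(spec) {
  stopifnot(inherits(spec, "gene_network_spec"))
  sim <- withr::with_seed(spec$seed, .run_birth_death(spec, clip_zero = TRUE))
  .finish_dataset(spec, sim)
}

#' @export
print.ldd_dataset <- function(x, ...) {
  cat(sprintf("<ldd_dataset> %d cells x %d variables (%s benchmark)\n",
              nrow(x$expression), ncol(x$expression), x$spec$model))
  cat(sprintf("  lineages: %s\n",
              paste(sort(unique(x$cells$lineage)), collapse = ", ")))
  cat(sprintf("  mean steady population %.0f (target %d)\n",
              x$diagnostics$mean_population, x$spec$target_population))
  invisible(x)
}

#' @method as_tibble ldd_dataset
#' @export
as_tibble.ldd_dataset <- function(x, ...) {
  dplyr::bind_cols(x$cells, tibble::as_tibble(x$expression))
}
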