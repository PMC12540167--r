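#' Configuration for the synthetic DREAM4-shaped benchmark
#'
#' Defines a planted directed regulatory network plus linear stochastic
#' expression dynamics that emulate the shape of DREAM4-style benchmarks
#' (multiple perturbation time series of equal length, wild-type and
#' knockout steady-state profiles, a gold-standard edge list) at desk scale.
#' This is deliberately a vector-autoregressive surrogate, not a
#' GeneNetWeaver reimplementation.
#'
#' @param n_genes Number of genes (>= 5).
#' @param n_edges Target edge count (at least one edge per two genes).
#' @param hub_bias Preferential-attachment strength on regulator out-degree;
#'   0 gives a near-uniform out-degree distribution.
#' @param strength_range Range of absolute interaction coefficients before
#'   spectral rescaling.
#' @param noise_sd Dynamics/measurement noise standard deviation (> 0).
#' @param decay Per-step expression decay rate lambda in (0, 1).
#' @param t_points Time points per series (21 matches the DREAM4 layout).
#' @param n_series Number of perturbation time series.
#' @param n_knockouts Number of single-gene knockout profiles.
#' @param n_wt Number of wild-type steady-state replicates.
#' @param seed Master seed; everything downstream is deterministic in it.
#' @return List of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 60L, n_edges = 100L, hub_bias = 2,
                             strength_range = c(0.4, 0.9), noise_sd = 0.1,
                             decay = 0.3, t_points = 21L, n_series = 5L,
                             n_knockouts = 20L, n_wt = 5L, seed = 42L) {
  stopifnot(n_genes >= 5L, noise_sd > 0, decay > 0, decay < 1,
            t_points >= 2L, n_series >= 1L,
            n_knockouts >= 0L, n_knockouts <= n_genes)
  if (n_edges < n_genes / 2) {
    stop("too sparse: need at least one edge per two genes", call. = FALSE)
  }
  if (n_edges > n_genes * (n_genes - 1L)) {
    stop("infeasible edge count", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_edges = as.integer(n_edges), hub_bias = hub_bias,
                 strength_range = strength_range, noise_sd = noise_sd,
                 decay = decay, t_points = as.integer(t_points),
                 n_series = as.integer(n_series),
                 n_knockouts = as.integer(n_knockouts),
                 n_wt = as.integer(n_wt), seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Sample a planted directed regulatory network
#'
#' Edges are drawn sequentially: the regulator is chosen with probability
#' proportional to `1 + hub_bias * current out-degree` (so a few hub
#' regulators accumulate many targets, as in curated GRNs) and the target
#' uniformly among the remaining genes; self-loops and duplicates are
#' rejected. Deterministic under the config seed.
#'
#' @param config A [synthetic_config()].
#' @return A [regulatory_network()] with exactly `n_edges` edges.
#' @export
generate_network <- function(config) {
  n <- config$n_genes
  genes <- sprintf("G%d", seq_len(n))
  with_seed(derive_seed(config$seed, "network"), {
    adj <- matrix(FALSE, n, n)
    outdeg <- integer(n)
    got <- 0L
    attempts <- 0L
    edges <- matrix(integer(0), ncol = 2L)
    while (got < config$n_edges) {
      attempts <- attempts + 1L
      if (attempts > 200L * config$n_edges) {
        stop("could not place requested edges (density infeasible?)",
             call. = FALSE)
      }
      w <- 1 + config$hub_bias * outdeg
      src <- sample.int(n, 1L, prob = w)
      dst <- sample.int(n, 1L)
      if (dst == src || adj[src, dst]) next
      adj[src, dst] <- TRUE
      outdeg[src] <- outdeg[src] + 1L
      edges <- rbind(edges, c(src, dst))
      got <- got + 1L
    }
    regulatory_network(genes, cbind(genes[edges[, 1L]], genes[edges[, 2L]]))
  })
}

# Shared linear system: x(t+1) = b + M x(t) + eps, with M = (1-decay) I + A
# rescaled to spectral radius <= 0.9 and a basal production vector b giving
# a nonzero wild-type steady state x* = (I - M)^{-1} b.
synthetic_system <- function(network, config) {
  n <- config$n_genes
  with_seed(derive_seed(config$seed, "dynamics"), {
    A <- matrix(0, n, n)
    ne <- nrow(network$edge_index)
    mag <- stats::runif(ne, config$strength_range[1L],
                        config$strength_range[2L])
    sgn <- sample(c(-1, 1), ne, replace = TRUE)
    A[cbind(network$edge_index[, 2L], network$edge_index[, 1L])] <- mag * sgn
    M <- (1 - config$decay) * diag(n) + A
    rho <- max(abs(eigen(M, only.values = TRUE)$values))
    if (rho > 0.9) M <- M * (0.9 / rho)
    rho <- max(abs(eigen(M, only.values = TRUE)$values))
    stopifnot(rho < 1)   # must hold after rescaling
    b <- stats::runif(n, 0.5, 1.5)
    xstar <- solve(diag(n) - M, b)
    list(M = M, b = b, xstar = xstar)
  })
}

#' Simulate perturbation time series
#'
#' Linear stochastic dynamics `x(t+1) = b + M x(t) + eps` with
#' `M = (1 - decay) I + A`, `A[v, u] != 0` iff `u -> v` is a planted edge
#' (random signs, magnitudes in `strength_range`, spectral radius rescaled
#' to at most 0.9), basal production `b`, and Gaussian noise. Each series
#' starts from the wild-type steady state plus a random perturbation,
#' mimicking DREAM4 perturbation experiments.
#'
#' @param network Planted [regulatory_network()].
#' @param config The [synthetic_config()] used to generate it.
#' @return List of `n_series` matrices, each `t_points x n_genes`.
#' @export
simulate_timeseries <- function(network, config) {
  sys <- synthetic_system(network, config)
  n <- config$n_genes
  genes <- network$node_ids
  lapply(seq_len(config$n_series), function(s) {
    with_seed(derive_seed(config$seed, "series", s), {
      x <- sys$xstar + stats::rnorm(n, sd = 1)
      out <- matrix(0, config$t_points, n, dimnames = list(NULL, genes))
      for (t in seq_len(config$t_points)) {
        out[t, ] <- x
        x <- sys$b + drop(sys$M %*% x) +
          stats::rnorm(n, sd = config$noise_sd)
      }
      out
    })
  })
}

#' Simulate wild-type and knockout steady-state profiles
#'
#' Wild-type replicates are the analytic steady state plus measurement
#' noise. Each knockout clamps one gene to zero and iterates the noise-free
#' dynamics to steady state (at most 200 iterations or a change below 1e-6;
#' non-convergence is flagged in the `converged` attribute); the knocked-out
#' gene is recorded as exactly zero.
#'
#' @param network Planted [regulatory_network()].
#' @param config The [synthetic_config()] used to generate it.
#' @return List with `conditions` (`(n_wt + n_knockouts) x n_genes` matrix)
#'   and `labels` (`"wt"` or `"ko:<gene>"`).
#' @export
simulate_knockouts <- function(network, config) {
  sys <- synthetic_system(network, config)
  n <- config$n_genes
  genes <- network$node_ids
  wt <- with_seed(derive_seed(config$seed, "wt"), {
    t(vapply(seq_len(config$n_wt), function(i) {
      sys$xstar + stats::rnorm(n, sd = config$noise_sd)
    }, numeric(n)))
  })
  ko_genes <- with_seed(derive_seed(config$seed, "ko_choice"), {
    sort(sample.int(n, config$n_knockouts))
  })
  converged <- logical(length(ko_genes))
  ko <- matrix(0, length(ko_genes), n)
  for (j in seq_along(ko_genes)) {
    i <- ko_genes[j]
    x <- sys$xstar
    x[i] <- 0
    for (it in seq_len(200L)) {
      xn <- sys$b + drop(sys$M %*% x)
      xn[i] <- 0
      if (max(abs(xn - x)) < 1e-6) {
        converged[j] <- TRUE
        x <- xn
        break
      }
      x <- xn
    }
    ko[j, ] <- x
    ko[j, i] <- 0
  }
  if (!all(converged)) {
    warning("knockout steady state not fully converged for ",
            sum(!converged), " gene(s)")
  }
  conditions <- rbind(wt, ko)
  colnames(conditions) <- genes
  labels <- c(rep("wt", config$n_wt),
              sprintf("ko:%s", genes[ko_genes]))
  structure(list(conditions = conditions, labels = labels),
            converged = converged)
}

#' Generate a complete in-memory benchmark
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (an [expression_dataset()]) and `network`
#'   (the planted gold standard).
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  network <- generate_network(config)
  ts <- simulate_timeseries(network, config)
  kc <- simulate_knockouts(network, config)
  dataset <- expression_dataset(network$node_ids, timeseries = ts,
                                conditions = kc$conditions,
                                condition_labels = kc$labels,
                                provenance = sprintf("synthetic(seed=%d)",
                                                     config$seed))
  list(dataset = dataset, network = network, config = config)
}

#' Write a benchmark bundle to disk in the DREAM dialects
#'
#' Produces `<prefix>_timeseries.tsv` (series stacked, fixed block length),
#' `<prefix>_conditions.tsv`, `<prefix>_condition_labels.txt` and
#' `<prefix>_goldstandard.tsv`. Two bundles from the same config are
#' byte-identical.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
make_benchmark_bundle <- function(config, outdir, prefix = "synthetic") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bench <- generate_benchmark(config)
  p <- file.path(outdir, paste0(prefix, "_", c(
    "timeseries.tsv", "conditions.tsv", "condition_labels.txt",
    "goldstandard.tsv")))
  names(p) <- c("timeseries", "conditions", "labels", "gold")
  write_expression_table(do.call(rbind, bench$dataset$timeseries),
                         p[["timeseries"]])
  write_expression_table(bench$dataset$conditions, p[["conditions"]])
  writeLines(bench$dataset$condition_labels, p[["labels"]])
  write_gold_standard(bench$network, p[["gold"]])
  invisible(p)
}

#' Load a benchmark bundle written by [make_benchmark_bundle()]
#'
#' @param outdir Directory containing the bundle.
#' @param prefix File-name prefix used when writing.
#' @param t_points Time points per series (block length for segmentation).
#' @return List with `dataset` and `network`.
#' @export
load_benchmark_bundle <- function(outdir, prefix = "synthetic",
                                  t_points = 21L) {
  ts <- read_expression_table(
    file.path(outdir, paste0(prefix, "_timeseries.tsv")),
    layout_spec = list(type = "timeseries", series_length = t_points))
  labels <- readLines(file.path(outdir,
                                paste0(prefix, "_condition_labels.txt")))
  cond <- read_expression_table(
    file.path(outdir, paste0(prefix, "_conditions.tsv")),
    layout_spec = list(type = "conditions", labels = labels))
  dataset <- expression_dataset(ts$gene_names, timeseries = ts$timeseries,
                                conditions = cond$conditions,
                                condition_labels = cond$condition_labels,
                                provenance = prefix)
  network <- read_gold_standard(
    file.path(outdir, paste0(prefix, "_goldstandard.tsv")),
    dataset$gene_names)
  list(dataset = dataset, network = network)
}
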