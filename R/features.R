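#' Z-score standardization
#'
#' Standardizes a matrix to zero mean and unit variance along the chosen
#' axis using population moments: per gene across time points (rows) for
#' time-series normalization, or per feature column for cross-feature
#' alignment. Rows/columns whose standard deviation falls below `eps` map
#' to all-zeros and are flagged constant.
#'
#' @param mat Numeric matrix.
#' @param axis `"column"` (standardize each column) or `"row"`.
#' @param eps Threshold below which a standard deviation counts as zero.
#' @return Matrix of the same shape with attributes `center`, `scale` and
#'   `constant` (logical flags).
#' @export
zscore <- function(mat, axis = c("column", "row"), eps = 1e-8) {
  axis <- match.arg(axis)
  mat <- as.matrix(mat)
  if (length(mat) == 0L) abort_dim("zscore: empty matrix")
  if (axis == "row") {
    out <- zscore(t(mat), axis = "column", eps = eps)
    res <- t(out)
    attributes(res)$center <- attr(out, "center")
    attributes(res)$scale <- attr(out, "scale")
    attributes(res)$constant <- attr(out, "constant")
    dimnames(res) <- dimnames(mat)
    return(res)
  }
  mu <- colMeans(mat)
  sigma <- sqrt(colMeans(mat^2) - mu^2)
  sigma[!is.finite(sigma)] <- 0
  constant <- sigma < eps
  denom <- ifelse(constant, 1, sigma)
  res <- sweep(sweep(mat, 2L, mu, "-"), 2L, denom, "/")
  res[, constant] <- 0
  dimnames(res) <- dimnames(mat)
  attr(res, "center") <- mu
  attr(res, "scale") <- sigma
  attr(res, "constant") <- constant
  res
}

# Population (Fisher) skewness and excess kurtosis with zero-variance guard.
moment_stats <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 < 1e-12 || n < 3L) return(c(skewness = 0, kurtosis = 0))
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# OLS slope of x against the 0-based time index.
trend_slope <- function(x) {
  t_idx <- seq_along(x) - 1
  denom <- sum((t_idx - mean(t_idx))^2)
  if (denom == 0) return(0)
  sum((t_idx - mean(t_idx)) * (x - mean(x))) / denom
}

#' Temporal gene features from time-series expression
#'
#' Per gene and series: mean, standard deviation (population), maximum,
#' minimum, skewness, excess kurtosis (both Fisher/population convention,
#' zeroed when `T < 3`), the OLS trend slope against the time index, and the
#' mean of every sliding window of size `window` advanced by `step`.
#' Multiple series are aggregated by averaging the corresponding statistics;
#' all columns are finally z-scored across genes.
#'
#' @param dataset An [expression_dataset()] with at least one time series.
#' @param window Sliding-window size (default 3).
#' @param step Sliding-window step (default 1).
#' @param standardize Z-score columns across genes (default `TRUE`).
#' @return `N x d_t` matrix with named feature columns.
#' @export
temporal_features <- function(dataset, window = 3L, step = 1L,
                              standardize = TRUE) {
  if (length(dataset$timeseries) == 0L) {
    stop("dataset has no time series", call. = FALSE)
  }
  t_len <- nrow(dataset$timeseries[[1L]])
  if (any(vapply(dataset$timeseries, nrow, 1L) != t_len)) {
    stop("all series must share T", call. = FALSE)
  }
  window <- as.integer(window); step <- as.integer(step)
  if (window > t_len) stop("window exceeds series length", call. = FALSE)
  if (window < 1L || step < 1L) stop("window and step must be >= 1",
                                     call. = FALSE)
  if (t_len < 3L) warning("T < 3: skewness and kurtosis flagged as 0")
  starts <- seq(1L, t_len - window + 1L, by = step)
  feat_names <- c("ts_mean", "ts_sd", "ts_max", "ts_min", "ts_skewness",
                  "ts_kurtosis", "ts_trend",
                  sprintf("ts_win%d_mean", seq_along(starts)))
  per_series <- lapply(dataset$timeseries, function(m) {
    t(apply(m, 2L, function(x) {
      mk <- moment_stats(x)
      wins <- vapply(starts, function(s) mean(x[s:(s + window - 1L)]), 0)
      c(mean(x), sqrt(mean((x - mean(x))^2)), max(x), min(x),
        mk[["skewness"]], mk[["kurtosis"]], trend_slope(x), wins)
    }))
  })
  raw <- Reduce(`+`, per_series) / length(per_series)
  colnames(raw) <- feat_names
  rownames(raw) <- dataset$gene_names
  if (standardize) zscore(raw, "column") else raw
}

# Condition-group key: "ko:G5" -> "ko"; used for pattern features.
condition_group <- function(labels) sub(":.*$", "", labels)

#' Expression-profile gene features from condition data
#'
#' Per gene: baseline level (mean over wild-type profiles, falling back to
#' the grand mean with a warning when no wild-type label is present),
#' stability (standard deviation across all condition profiles), coefficient
#' of variation, tau specificity index over the (min-shifted) condition
#' values, maximum and minimum condition values, the mean and maximum
#' absolute Pearson correlation to all other genes, and per-condition-group
#' mean expression for up to `max_pattern_groups` groups (labels collapsed
#' at `":"`, e.g. all `"ko:*"` profiles form one group). All columns are
#' z-scored across genes.
#'
#' @param dataset An [expression_dataset()] with a condition matrix.
#' @param wt_label Label (group key) marking wild-type profiles.
#' @param max_pattern_groups Maximum number of condition groups encoded as
#'   pattern features; 0 disables them.
#' @param standardize Z-score columns across genes (default `TRUE`).
#' @return `N x d_b` matrix with named feature columns.
#' @export
profile_features <- function(dataset, wt_label = "wt",
                             max_pattern_groups = 5L, standardize = TRUE) {
  cond <- dataset$conditions
  if (is.null(cond) || nrow(cond) == 0L) {
    stop("dataset has no condition profiles", call. = FALSE)
  }
  labels <- dataset$condition_labels
  groups <- condition_group(labels)
  wt_rows <- which(groups == wt_label)
  if (length(wt_rows) == 0L) {
    warning("no wild-type profiles; baseline falls back to grand mean")
    baseline <- colMeans(cond)
  } else {
    baseline <- colMeans(cond[wt_rows, , drop = FALSE])
  }
  mu <- colMeans(cond)
  stability <- sqrt(colMeans(cond^2) - mu^2)
  cv <- ifelse(abs(mu) < 1e-12, 0, stability / abs(mu))
  tau <- apply(cond, 2L, function(x) {
    x <- x - min(x)
    mx <- max(x)
    if (mx < 1e-12) return(0)
    sum(1 - x / mx) / (length(x) - 1L)
  })
  cmax <- apply(cond, 2L, max)
  cmin <- apply(cond, 2L, min)
  n <- ncol(cond)
  if (n > 1L && nrow(cond) > 1L) {
    cc <- suppressWarnings(stats::cor(cond))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- NA
    acc <- abs(cc)
    cor_mean <- rowMeans(acc, na.rm = TRUE)
    cor_max <- apply(acc, 1L, max, na.rm = TRUE)
    cor_mean[!is.finite(cor_mean)] <- 0
    cor_max[!is.finite(cor_max)] <- 0
  } else {
    cor_mean <- cor_max <- rep(0, n)
  }
  raw <- cbind(pf_baseline = baseline, pf_stability = stability,
               pf_cv = cv, pf_tau = tau, pf_max = cmax, pf_min = cmin,
               pf_cor_mean = cor_mean, pf_cor_max = cor_max)
  grp_keys <- unique(groups)
  if (max_pattern_groups > 0L && length(grp_keys) >= 2L) {
    grp_keys <- utils::head(grp_keys, max_pattern_groups)
    pat <- vapply(grp_keys, function(g) {
      colMeans(cond[groups == g, , drop = FALSE])
    }, numeric(n))
    colnames(pat) <- sprintf("pf_pattern_%s", grp_keys)
    raw <- cbind(raw, pat)
  }
  rownames(raw) <- dataset$gene_names
  if (standardize) zscore(raw, "column") else raw
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = as.data.frame(network$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$node_ids,
                          stringsAsFactors = FALSE))
}

# Mean inverse shortest-path length over ordered pairs of a node's
# undirected neighbors (node itself excluded from the neighborhood graph).
local_efficiency_scores <- function(g_und) {
  n <- igraph::vcount(g_und)
  vapply(seq_len(n), function(v) {
    nb <- as.integer(igraph::neighbors(g_und, v))
    nb <- setdiff(nb, v)
    k <- length(nb)
    if (k < 2L) return(0)
    sub <- igraph::induced_subgraph(g_und, nb)
    d <- igraph::distances(sub)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1L))
  }, 0)
}

#' Topological gene features from a regulatory graph
#'
#' Per node: total degree, in-degree, out-degree, local clustering
#' coefficient (undirected projection), betweenness centrality (directed
#' shortest paths, normalized), local efficiency (undirected neighborhood
#' subgraph), PageRank (directed, configurable damping) and k-core index
#' (undirected projection). Columns are z-scored across genes. An empty edge
#' set yields all-zero raw features.
#'
#' Leakage note: pass the training-fold subgraph here; test-fold edges must
#' never shape these features (see `full_graph_features` in
#' [default_config()]).
#'
#' @param network A [regulatory_network()] (usually the training subgraph).
#' @param damping PageRank damping factor.
#' @param standardize Z-score columns across genes (default `TRUE`).
#' @return `N x 8` matrix with named feature columns.
#' @export
topological_features <- function(network, damping = 0.85,
                                 standardize = TRUE) {
  n <- length(network$node_ids)
  feat_names <- c("tp_degree", "tp_in_degree", "tp_out_degree",
                  "tp_clustering", "tp_betweenness", "tp_local_efficiency",
                  "tp_pagerank", "tp_kcore")
  if (nrow(network$edges) == 0L) {
    raw <- matrix(0, n, length(feat_names),
                  dimnames = list(network$node_ids, feat_names))
    return(if (standardize) zscore(raw, "column") else raw)
  }
  g <- as_igraph(network)
  und <- igraph::as_undirected(g, mode = "collapse")
  clust <- igraph::transitivity(und, type = "local", isolates = "zero")
  betw <- if (n >= 3L) {
    igraph::betweenness(g, directed = TRUE, normalized = TRUE)
  } else rep(0, n)
  raw <- cbind(
    tp_degree = igraph::degree(g, mode = "all"),
    tp_in_degree = igraph::degree(g, mode = "in"),
    tp_out_degree = igraph::degree(g, mode = "out"),
    tp_clustering = clust,
    tp_betweenness = betw,
    tp_local_efficiency = local_efficiency_scores(und),
    tp_pagerank = igraph::page_rank(g, damping = damping)$vector,
    tp_kcore = igraph::coreness(und, mode = "all"))
  rownames(raw) <- network$node_ids
  if (standardize) zscore(raw, "column") else raw
}

#' Edge structural descriptors for candidate gene pairs
#'
#' For each candidate pair `(u, v)`: out-degree of `u`, in-degree of `v`,
#' number of common neighbors in the undirected sense, shortest-path length
#' from `u` to `v` on the (training) graph capped at `cap` when `v` is
#' unreachable, and a reachability flag (1 when a directed path `u -> v`
#' exists).
#'
#' @param network A [regulatory_network()] (the training subgraph).
#' @param pairs Two-column matrix of gene names or 1-based indices.
#' @param cap Shortest-path cap for unreachable pairs; defaults to the
#'   number of genes.
#' @return `nrow(pairs) x 5` numeric matrix with columns `out_deg_src`,
#'   `in_deg_dst`, `common_neighbors`, `sp_length`, `same_component`.
#' @export
edge_structural_descriptors <- function(network, pairs, cap = NULL) {
  n <- length(network$node_ids)
  cap <- cap %||% n
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) abort_dim("pairs must have two columns")
  if (is.character(pairs)) {
    idx <- cbind(match(pairs[, 1L], network$node_ids),
                 match(pairs[, 2L], network$node_ids))
  } else {
    idx <- matrix(as.integer(pairs), ncol = 2L)
  }
  if (anyNA(idx) || any(idx < 1L) || any(idx > n)) {
    stop("pair endpoint not in graph", call. = FALSE)
  }
  A <- matrix(0L, n, n)
  if (nrow(network$edge_index) > 0L) {
    A[network$edge_index] <- 1L
  }
  und <- (A | t(A)) * 1L
  out_deg <- rowSums(A)
  in_deg <- colSums(A)
  cn_mat <- und %*% und   # [u, v] = number of shared undirected neighbors
  if (nrow(network$edges) > 0L) {
    g <- as_igraph(network)
    usrc <- unique(idx[, 1L])
    d <- igraph::distances(g, v = usrc, mode = "out")
    sp <- d[cbind(match(idx[, 1L], usrc), idx[, 2L])]
  } else {
    sp <- ifelse(idx[, 1L] == idx[, 2L], 0, Inf)
  }
  reachable <- is.finite(sp)
  sp[!reachable] <- cap
  cbind(out_deg_src = out_deg[idx[, 1L]],
        in_deg_dst = in_deg[idx[, 2L]],
        common_neighbors = cn_mat[idx],
        sp_length = sp,
        same_component = as.numeric(reachable))
}

# Descriptor attached to the self-loop of every node when building the
# attention graph: (out-degree, in-degree, undirected degree, path 0,
# reachable).
self_loop_descriptors <- function(network) {
  n <- length(network$node_ids)
  A <- matrix(0L, n, n)
  if (nrow(network$edge_index) > 0L) A[network$edge_index] <- 1L
  und <- (A | t(A)) * 1L
  cbind(out_deg_src = rowSums(A), in_deg_dst = colSums(A),
        common_neighbors = rowSums(und), sp_length = 0,
        same_component = 1)
}

#' Bundle the three standardized feature families
#'
#' @param temporal,profile,topological Standardized `N x d` matrices sharing
#'   row count and gene order.
#' @return Object of class `FeatureBundle`.
#' @export
feature_bundle <- function(temporal, profile, topological) {
  n <- nrow(temporal)
  if (nrow(profile) != n || nrow(topological) != n) {
    abort_dim("feature matrices must share N")
  }
  nms <- c(colnames(temporal), colnames(profile), colnames(topological))
  if (anyDuplicated(nms)) stop("feature names must be unique", call. = FALSE)
  structure(list(temporal = temporal, profile = profile,
                 topological = topological),
            class = "FeatureBundle")
}

#' Extract the full feature bundle for a dataset and training graph
#'
#' @param dataset An [expression_dataset()].
#' @param network Training-fold [regulatory_network()].
#' @param config Configuration list, see [default_config()].
#' @return A [feature_bundle()].
#' @export
build_feature_bundle <- function(dataset, network, config = default_config()) {
  feature_bundle(
    temporal = temporal_features(dataset, config$window, config$window_step),
    profile = profile_features(dataset, config$wt_label,
                               config$max_pattern_groups),
    topological = topological_features(network, config$pagerank_damping))
}

#' Export a feature matrix as TSV
#'
#' @param mat Feature matrix with gene rownames and feature colnames.
#' @param path Output path.
#' @export
write_feature_table <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
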