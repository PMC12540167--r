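#' Initialize parameters for the stacked GTAT layers
#'
#' Hidden layers use `heads` parallel attention heads of width
#' `d / heads` merged by concatenation (so the width stays `d`); the last
#' layer uses heads of width `d` merged by averaging. Each head carries a
#' node projection `P`, an edge-descriptor projection `Q` and an additive
#' attention vector `a` over `[P z_src || P z_dst || Q tau_e]`.
#'
#' @param d Node-state width (input and output of every layer).
#' @param d_e Edge-descriptor width (5 for the standard descriptor set).
#' @param heads Number of attention heads `H`.
#' @param layers Number of stacked layers `L`.
#' @return Nested parameter list (class `GTATParams`).
#' @export
init_gtat_params <- function(d, d_e = 5L, heads = 4L, layers = 2L) {
  stopifnot(heads >= 1L, layers >= 1L)
  if (layers > 1L && d %% heads != 0L) {
    abort_dim("hidden width must be divisible by the number of heads")
  }
  mk_head <- function(d_in, d_h) {
    list(P = init_matrix(d_in, d_h), Q = init_matrix(d_e, d_h),
         a = init_vector(3L * d_h, fan_in = 3L * d_h))
  }
  mk_layer <- function(d_in, d_h, merge) {
    structure(list(heads = lapply(seq_len(heads), function(i) {
      mk_head(d_in, d_h)
    })), merge = merge)
  }
  out <- vector("list", layers)
  for (l in seq_len(layers)) {
    last <- l == layers
    out[[l]] <- mk_layer(d_in = d,
                         d_h = if (last) d else d %/% heads,
                         merge = if (last) "mean" else "concat")
  }
  structure(out, class = c("GTATParams", "list"))
}

#' Build the attention graph over training edges
#'
#' Appends a self-loop to every node (self-loop descriptor: out-degree,
#' in-degree, undirected degree, path length 0, reachable) and z-scores the
#' descriptor columns so the attention logits see comparable scales. Only
#' edges of the supplied (training) network enter message passing.
#'
#' @param network Training-fold [regulatory_network()].
#' @param cap Shortest-path cap, defaults to gene count.
#' @return List with `edge_index` (`E x 2` integer, self-loops last) and
#'   standardized `descriptors` (`E x 5`).
#' @export
build_attention_graph <- function(network, cap = NULL) {
  n <- length(network$node_ids)
  ei <- network$edge_index
  desc <- if (nrow(ei) > 0L) {
    edge_structural_descriptors(network, ei, cap = cap)
  } else {
    matrix(0, 0L, 5L)
  }
  self_ei <- cbind(src = seq_len(n), dst = seq_len(n))
  desc_all <- rbind(desc, self_loop_descriptors(network))
  colnames(desc_all) <- c("out_deg_src", "in_deg_dst", "common_neighbors",
                          "sp_length", "same_component")
  edge_index <- rbind(ei, self_ei)
  dimnames(edge_index) <- list(NULL, c("src", "dst"))
  list(edge_index = edge_index,
       descriptors = zscore(desc_all, "column"))
}

#' Per-edge attention logits for one head
#'
#' `logit(e) = LeakyReLU(a . [P z_src || P z_dst || Q tau_e])`. Zeroing the
#' descriptor projection `Q` (topology ablation) reduces this to a plain
#' feature-attention score.
#'
#' @param states `N x d_in` node states.
#' @param edge_index `E x 2` integer matrix (src, dst), self-loops included.
#' @param edge_descriptors `E x d_e` standardized descriptors.
#' @param params Parameters of one layer ([init_gtat_params()] element).
#' @param head Head index.
#' @param use_topo Include the descriptor term (default `TRUE`).
#' @param slope LeakyReLU negative slope.
#' @return Numeric vector of `E` logits.
#' @export
attention_logits <- function(states, edge_index, edge_descriptors, params,
                             head = 1L, use_topo = TRUE, slope = 0.2) {
  hp <- params$heads[[head]]
  d_h <- ncol(hp$P)
  if (use_topo && ncol(edge_descriptors) != nrow(hp$Q)) {
    abort_dim("descriptor width does not match Q")
  }
  U <- states %*% hp$P
  a_u <- hp$a[seq_len(d_h)]
  a_v <- hp$a[d_h + seq_len(d_h)]
  a_q <- hp$a[2L * d_h + seq_len(d_h)]
  m <- drop(U[edge_index[, 1L], , drop = FALSE] %*% a_u) +
    drop(U[edge_index[, 2L], , drop = FALSE] %*% a_v)
  if (use_topo) {
    m <- m + drop((edge_descriptors %*% hp$Q) %*% a_q)
  }
  leaky_relu(m, slope)
}

#' Normalize attention logits over the in-edges of each target
#'
#' Softmax grouped by destination node: information flows from regulatory
#' sources to targets, so each target's incoming weights (self-loop
#' included) sum to one.
#'
#' @param logits Per-edge logits.
#' @param edge_index `E x 2` integer matrix.
#' @param n_nodes Number of nodes (every node must have an in-edge after
#'   self-loop insertion).
#' @return Numeric vector of attention weights, one per edge.
#' @export
normalize_attention <- function(logits, edge_index, n_nodes) {
  dst <- edge_index[, 2L]
  stopifnot(length(unique(dst)) == n_nodes)
  gmax <- stats::ave(logits, dst, FUN = max)
  e <- exp(logits - gmax)
  denom <- stats::ave(e, dst, FUN = sum)
  e / denom
}

#' Aggregate projected source states with attention weights
#'
#' `z'_dst = sum over in-edges of alpha_(src,dst) * (P z_src)` for one head.
#'
#' @param states `N x d_in` node states.
#' @param attention Per-edge attention weights (normalized).
#' @param edge_index `E x 2` integer matrix.
#' @param params Layer parameters.
#' @param head Head index.
#' @return `N x d_h` updated states for this head.
#' @export
aggregate_attention <- function(states, attention, edge_index, params, head = 1L) {
  U <- states %*% params$heads[[head]]$P
  msg <- attention * U[edge_index[, 1L], , drop = FALSE]
  agg <- rowsum(msg, group = edge_index[, 2L])
  out <- matrix(0, nrow(states), ncol(U))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# Forward pass for one layer (all heads), with cache for backprop.
gtat_layer_forward <- function(S, edge_index, desc, layer, use_topo, slope) {
  n <- nrow(S)
  src <- edge_index[, 1L]; dst <- edge_index[, 2L]
  merge <- attr(layer, "merge")
  heads <- layer$heads
  outs <- caches <- vector("list", length(heads))
  for (h in seq_along(heads)) {
    hp <- heads[[h]]
    d_h <- ncol(hp$P)
    U <- S %*% hp$P
    Qe <- if (use_topo) desc %*% hp$Q else matrix(0, nrow(edge_index), d_h)
    a_u <- hp$a[seq_len(d_h)]
    a_v <- hp$a[d_h + seq_len(d_h)]
    a_q <- hp$a[2L * d_h + seq_len(d_h)]
    m <- drop(U[src, , drop = FALSE] %*% a_u) +
      drop(U[dst, , drop = FALSE] %*% a_v) + drop(Qe %*% a_q)
    logits <- leaky_relu(m, slope)
    alpha <- normalize_attention(logits, edge_index, n)
    msg <- alpha * U[src, , drop = FALSE]
    agg <- rowsum(msg, group = dst)
    Zh <- matrix(0, n, d_h)
    Zh[as.integer(rownames(agg)), ] <- agg
    outs[[h]] <- Zh
    caches[[h]] <- list(U = U, Qe = Qe, m = m, alpha = alpha)
  }
  out <- if (merge == "concat") do.call(cbind, outs) else {
    Reduce(`+`, outs) / length(outs)
  }
  list(out = out,
       cache = list(S = S, heads = caches, merge = merge,
                    alphas = lapply(caches, `[[`, "alpha")))
}

gtat_layer_backward <- function(d_out, cache, edge_index, desc, layer,
                                use_topo, slope) {
  S <- cache$S
  src <- edge_index[, 1L]; dst <- edge_index[, 2L]
  heads <- layer$heads
  H <- length(heads)
  dS <- matrix(0, nrow(S), ncol(S))
  grads <- vector("list", H)
  for (h in seq_len(H)) {
    hp <- heads[[h]]
    hc <- cache$heads[[h]]
    d_h <- ncol(hp$P)
    dZh <- if (cache$merge == "concat") {
      d_out[, ((h - 1L) * d_h + 1L):(h * d_h), drop = FALSE]
    } else {
      d_out / H
    }
    U <- hc$U; alpha <- hc$alpha
    dZ_dst <- dZh[dst, , drop = FALSE]
    U_src <- U[src, , drop = FALSE]
    # aggregation: z'_dst = sum alpha_e * U_src
    dalpha <- rowSums(dZ_dst * U_src)
    dU <- matrix(0, nrow(U), d_h)
    addU <- rowsum(alpha * dZ_dst, group = src)
    dU[as.integer(rownames(addU)), ] <-
      dU[as.integer(rownames(addU)), ] + addU
    # grouped softmax backward
    inner <- stats::ave(alpha * dalpha, dst, FUN = sum)
    dlogit <- alpha * (dalpha - inner)
    dm <- dlogit * ifelse(hc$m > 0, 1, slope)
    a_u <- hp$a[seq_len(d_h)]
    a_v <- hp$a[d_h + seq_len(d_h)]
    a_q <- hp$a[2L * d_h + seq_len(d_h)]
    da <- c(colSums(dm * U_src),
            colSums(dm * U[dst, , drop = FALSE]),
            colSums(dm * hc$Qe))
    addU2 <- rowsum(outer(dm, a_u), group = src)
    dU[as.integer(rownames(addU2)), ] <-
      dU[as.integer(rownames(addU2)), ] + addU2
    addU3 <- rowsum(outer(dm, a_v), group = dst)
    dU[as.integer(rownames(addU3)), ] <-
      dU[as.integer(rownames(addU3)), ] + addU3
    dQ <- if (use_topo) crossprod(desc, outer(dm, a_q)) else hp$Q * 0
    dS <- dS + dU %*% t(hp$P)
    grads[[h]] <- list(P = crossprod(S, dU), Q = dQ, a = da)
  }
  list(dS = dS, grads = list(heads = grads))
}

#' Forward pass through the stacked GTAT layers
#'
#' Applies `L` layers of logits -> grouped softmax -> aggregation with an
#' ELU nonlinearity between layers (none after the last). Returns the final
#' embeddings and, for inspection, the per-layer per-head attention maps.
#'
#' @param states `N x d` node states (fused representations).
#' @param graph Output of [build_attention_graph()].
#' @param params [init_gtat_params()] output.
#' @param use_topo Include edge descriptors in the logits.
#' @param slope LeakyReLU negative slope.
#' @return List with `out` (`N x d` embeddings) and `attention` (list of
#'   layers, each a list of per-head weight vectors aligned with
#'   `graph$edge_index`).
#' @export
gtat_forward <- function(states, graph, params, use_topo = TRUE,
                         slope = 0.2) {
  fw <- gtat_forward_cached(states, graph, params, use_topo, slope)
  list(out = fw$out, attention = lapply(fw$caches, `[[`, "alphas"))
}

gtat_forward_cached <- function(states, graph, params, use_topo, slope) {
  L <- length(params)
  S <- states
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    lf <- gtat_layer_forward(S, graph$edge_index, graph$descriptors,
                             params[[l]], use_topo, slope)
    caches[[l]] <- lf$cache
    if (l < L) {
      caches[[l]]$pre_act <- lf$out
      S <- elu(lf$out)
    } else {
      S <- lf$out
    }
  }
  list(out = S, caches = caches)
}

gtat_backward <- function(d_out, fw, graph, params, use_topo, slope) {
  L <- length(params)
  grads <- vector("list", L)
  dS <- d_out
  for (l in rev(seq_len(L))) {
    if (l < L) dS <- dS * elu_grad(fw$caches[[l]]$pre_act)
    bk <- gtat_layer_backward(dS, fw$caches[[l]], graph$edge_index,
                              graph$descriptors, params[[l]], use_topo,
                              slope)
    grads[[l]] <- bk$grads
    dS <- bk$dS
  }
  list(d_states = dS, grads = grads)
}
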