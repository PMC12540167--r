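# Fixtures and independent oracles used across the suite. Oracles are coded
# from the definitions (loops, enumeration, closed forms), never by calling
# the implementation they check.

genes <- function(n) sprintf("G%d", seq_len(n))

random_bundle <- function(n, d_t = 4L, d_b = 3L, d_g = 5L, seed = 1L) {
  set.seed(seed)
  mk <- function(d, pre) {
    matrix(stats::rnorm(n * d), n, d,
           dimnames = list(genes(n), paste0(pre, seq_len(d))))
  }
  feature_bundle(mk(d_t, "t"), mk(d_b, "b"), mk(d_g, "g"))
}

random_digraph <- function(n, p = 0.25, seed = 1L) {
  set.seed(seed)
  adj <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  diag(adj) <- 0L
  idx <- which(adj == 1L, arr.ind = TRUE)
  regulatory_network(genes(n),
                     edges = if (nrow(idx)) {
                       cbind(genes(n)[idx[, 1L]], genes(n)[idx[, 2L]])
                     } else NULL)
}

adjacency_of <- function(network) {
  n <- length(network$node_ids)
  A <- matrix(0L, n, n)
  if (nrow(network$edge_index) > 0L) A[network$edge_index] <- 1L
  A
}

tiny_config <- function(...) {
  merge_config(utils::modifyList(
    list(fused_dim = 8L, heads = 2L, gtat_layers = 2L, ffn_hidden = 6L,
         scorer_hidden = 5L, fusion_dropout = 0, scorer_dropout = 0,
         epochs = 3L, patience = 5L),
    list(...)))
}

small_benchmark <- function(seed = 7L, n = 12L) {
  suppressWarnings(generate_benchmark(synthetic_config(
    n_genes = n, n_edges = max(8L, n), t_points = 8L, n_series = 2L,
    n_knockouts = 4L, n_wt = 2L, seed = seed)))
}

# ---- graph oracles (pure R, BFS/enumeration based) ----

# All-pairs BFS distances on a directed 0/1 adjacency matrix.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0L) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] == 1L)) {
          if (D[s, w] > depth) {
            D[s, w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# Count shortest paths s -> t via DP over the BFS DAG.
count_shortest_paths <- function(A, D, s) {
  n <- nrow(A)
  cnt <- numeric(n)
  cnt[s] <- 1
  ord <- order(D[s, ])
  for (v in ord) {
    if (v == s || !is.finite(D[s, v])) next
    preds <- which(A[, v] == 1L & D[s, ] == D[s, v] - 1)
    cnt[v] <- sum(cnt[preds])
  }
  cnt
}

# Directed betweenness (endpoints excluded), normalized by (n-1)(n-2).
brute_betweenness <- function(A) {
  n <- nrow(A)
  D <- bfs_distances(A)
  sigma <- t(vapply(seq_len(n), function(s) count_shortest_paths(A, D, s),
                    numeric(n)))   # sigma[s, t]
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (!is.finite(D[s, t]) || sigma[s, t] == 0) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2)) else bc * 0
}

# PageRank by power iteration; dangling nodes teleport uniformly.
brute_pagerank <- function(A, damping = 0.85, tol = 1e-12) {
  n <- nrow(A)
  outd <- rowSums(A)
  x <- rep(1 / n, n)
  repeat {
    contrib <- numeric(n)
    for (u in seq_len(n)) {
      if (outd[u] > 0) {
        contrib[which(A[u, ] == 1L)] <- contrib[which(A[u, ] == 1L)] +
          x[u] / outd[u]
      }
    }
    dangling <- sum(x[outd == 0])
    xn <- damping * (contrib + dangling / n) + (1 - damping) / n
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
}

# Local clustering coefficient on the undirected projection.
brute_clustering <- function(A) {
  U <- ((A + t(A)) > 0) * 1L
  n <- nrow(U)
  vapply(seq_len(n), function(v) {
    nb <- which(U[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(U[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, 0)
}

# Local efficiency: mean inverse distance over ordered neighbor pairs.
brute_local_efficiency <- function(A) {
  U <- ((A + t(A)) > 0) * 1L
  n <- nrow(U)
  vapply(seq_len(n), function(v) {
    nb <- which(U[v, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    sub <- U[nb, nb, drop = FALSE]
    D <- bfs_distances(sub)
    inv <- 1 / D
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, 0)
}

# k-core index by iterative pruning of the undirected projection.
brute_kcore <- function(A) {
  U <- ((A + t(A)) > 0) * 1L
  n <- nrow(U)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    k <- k + 1L
    repeat {
      deg <- rowSums(U[, alive, drop = FALSE])
      deg[!alive] <- Inf
      drop_v <- which(alive & deg < k)
      if (length(drop_v) == 0L) break
      core[drop_v] <- k - 1L
      alive[drop_v] <- FALSE
    }
  }
  core
}

# ---- metric oracles ----

# AUC by exhaustive positive x negative pair counting (ties = 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Average precision by direct cumulative summation over the ranked list.
brute_average_precision <- function(scores, labels) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord]
  tp <- 0
  s <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      s <- s + tp / i
    }
  }
  s / sum(labels == 1)
}

# ---- dense equation-chain oracles (scalar loops, no shared code path) ----

oracle_fusion <- function(bundle, fp, use_attention = TRUE) {
  X <- list(t = bundle$temporal, b = bundle$profile, g = bundle$topological)
  n <- nrow(X$t)
  d <- length(fp$bf)
  H <- list()
  for (k in c("t", "b", "g")) {
    H[[k]] <- matrix(0, n, d)
    for (i in seq_len(n)) {
      for (j in seq_len(d)) {
        H[[k]][i, j] <- sum(X[[k]][i, ] * fp$proj[[k]]$W[, j]) +
          fp$proj[[k]]$b[j]
      }
    }
  }
  alpha <- matrix(1 / 3, n, 3)
  if (use_attention) {
    for (i in seq_len(n)) {
      s <- c(sum(H$t[i, ] * fp$attn$t$w) + fp$attn$t$b,
             sum(H$b[i, ] * fp$attn$b$w) + fp$attn$b$b,
             sum(H$g[i, ] * fp$attn$g$w) + fp$attn$g$b)
      e <- exp(s - max(s))
      alpha[i, ] <- e / sum(e)
    }
  }
  Xf <- matrix(0, n, d)
  for (i in seq_len(n)) {
    Xf[i, ] <- alpha[i, 1] * H$t[i, ] + alpha[i, 2] * H$b[i, ] +
      alpha[i, 3] * H$g[i, ]
  }
  Z <- pmax(Xf %*% fp$Wf + matrix(fp$bf, n, d, byrow = TRUE), 0)
  G <- 1 / (1 + exp(-(Xf %*% fp$Wg + matrix(fp$bg, n, d, byrow = TRUE))))
  Zg <- Z * G
  Zfinal <- Zg %*% fp$Wo + matrix(fp$bo, n, d, byrow = TRUE) + Xf
  list(alpha = alpha, X_fused = Xf, Z_final = Zfinal)
}

# One GTAT layer as an explicit dense masked-attention computation.
oracle_gtat_layer <- function(S, edge_index, desc, layer, use_topo, slope) {
  n <- nrow(S)
  merge <- attr(layer, "merge")
  outs <- list()
  for (h in seq_along(layer$heads)) {
    hp <- layer$heads[[h]]
    d_h <- ncol(hp$P)
    U <- S %*% hp$P
    logit_mat <- matrix(NA_real_, n, n)   # [src, dst]
    for (e in seq_len(nrow(edge_index))) {
      s <- edge_index[e, 1]; t <- edge_index[e, 2]
      q <- if (use_topo) drop(desc[e, ] %*% hp$Q) else rep(0, d_h)
      z <- sum(hp$a * c(U[s, ], U[t, ], q))
      logit_mat[s, t] <- ifelse(z > 0, z, slope * z)
    }
    Zh <- matrix(0, n, d_h)
    for (t in seq_len(n)) {
      ins <- which(!is.na(logit_mat[, t]))
      w <- exp(logit_mat[ins, t] - max(logit_mat[ins, t]))
      w <- w / sum(w)
      for (j in seq_along(ins)) Zh[t, ] <- Zh[t, ] + w[j] * U[ins[j], ]
    }
    outs[[h]] <- Zh
  }
  if (merge == "concat") do.call(cbind, outs) else {
    Reduce(`+`, outs) / length(outs)
  }
}

oracle_ffn <- function(h, fp) {
  n <- nrow(h)
  A1 <- h %*% fp$W1 + matrix(fp$b1, n, length(fp$b1), byrow = TRUE)
  R <- pmax(A1, 0)
  hp <- R %*% fp$W2 + matrix(fp$b2, n, length(fp$b2), byrow = TRUE)
  h + hp
}
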