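gtat_fixture <- function(n = 6L, d = 4L, heads = 2L, layers = 2L,
                         p = 0.35, seed = 3L) {
  net <- random_digraph(n, p, seed = seed)
  graph <- build_attention_graph(net)
  gp <- with_seed(seed + 10L, init_gtat_params(d, 5L, heads, layers))
  set.seed(seed + 20L)
  S <- matrix(rnorm(n * d), n, d)
  list(net = net, graph = graph, gp = gp, S = S, n = n)
}

test_that("attention logits are functional in (source state, descriptor)", {
  f <- gtat_fixture()
  ei <- f$graph$edge_index
  lg <- attention_logits(f$S, ei, f$graph$descriptors, f$gp[[1L]], head = 1L)
  expect_length(lg, nrow(ei))
  # duplicate an edge row: identical inputs give identical logits
  ei2 <- rbind(ei, ei[1L, ])
  de2 <- rbind(f$graph$descriptors, f$graph$descriptors[1L, ])
  lg2 <- attention_logits(f$S, ei2, de2, f$gp[[1L]], head = 1L)
  expect_equal(lg2[nrow(ei2)], lg2[1L])

  # zeroing Q (topology ablation) equals dropping the descriptor term
  gp0 <- f$gp
  gp0[[1L]]$heads[[1L]]$Q <- gp0[[1L]]$heads[[1L]]$Q * 0
  expect_equal(
    attention_logits(f$S, ei, f$graph$descriptors, gp0[[1L]], head = 1L),
    attention_logits(f$S, ei, f$graph$descriptors, f$gp[[1L]], head = 1L,
                     use_topo = FALSE))
})

test_that("attention normalizes to one over each target's in-edges", {
  f <- gtat_fixture(n = 8L, seed = 5L)
  ei <- f$graph$edge_index
  lg <- attention_logits(f$S, ei, f$graph$descriptors, f$gp[[1L]], 1L)
  al <- normalize_attention(lg, ei, f$n)
  sums <- tapply(al, ei[, 2L], sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(al >= 0))

  # grouping oracle: explicit per-target softmax
  for (t in unique(ei[, 2L])) {
    sel <- ei[, 2L] == t
    e <- exp(lg[sel] - max(lg[sel]))
    expect_equal(unname(al[sel]), unname(e / sum(e)), tolerance = 1e-12)
  }

  # single self-loop gets weight one; equal logits split evenly
  lone <- regulatory_network(genes(3), rbind(c("G1", "G3"), c("G2", "G3")))
  g <- build_attention_graph(lone)
  eq <- rep(0.7, nrow(g$edge_index))
  al2 <- normalize_attention(eq, g$edge_index, 3L)
  expect_equal(unname(al2[g$edge_index[, 2L] == 1L]), 1)       # only self-loop
  expect_equal(unname(al2[g$edge_index[, 2L] == 3L]), rep(1 / 3, 3))
})

test_that("aggregation reproduces identity and single-source cases", {
  # self-loops only, P = identity: output equals input
  net <- regulatory_network(genes(4), NULL)
  g <- build_attention_graph(net)
  gp <- init_gtat_params(3L, 5L, heads = 1L, layers = 1L)
  gp[[1L]]$heads[[1L]]$P <- diag(3)
  set.seed(1)
  S <- matrix(rnorm(12), 4, 3)
  al <- rep(1, 4)
  expect_equal(aggregate_attention(S, al, g$edge_index, gp[[1L]], 1L), S)

  # all attention mass on one in-edge: update equals that source's projection
  star <- regulatory_network(genes(3), rbind(c("G1", "G3"), c("G2", "G3")))
  gs <- build_attention_graph(star)
  gp2 <- with_seed(4L, init_gtat_params(3L, 5L, 1L, 1L))
  ei <- gs$edge_index
  al2 <- numeric(nrow(ei))
  al2[ei[, 1L] == 1L & ei[, 2L] == 3L] <- 1   # G1 -> G3 takes all mass
  al2[ei[, 1L] == ei[, 2L] & ei[, 2L] != 3L] <- 1
  S2 <- matrix(rnorm(9), 3, 3)
  out <- aggregate_attention(S2, al2, ei, gp2[[1L]], 1L)
  U <- S2 %*% gp2[[1L]]$heads[[1L]]$P
  expect_equal(out[3L, ], U[1L, ])
})

test_that("sparse layers match the dense masked-softmax oracle", {
  for (seed in 1:10) {
    f <- gtat_fixture(n = 4L + seed %% 9L, d = 4L, heads = 2L,
                      layers = 2L, seed = seed)
    for (use_topo in c(TRUE, FALSE)) {
      fw <- gtat_forward(f$S, f$graph, f$gp, use_topo = use_topo)
      S <- f$S
      for (l in seq_along(f$gp)) {
        S <- oracle_gtat_layer(S, f$graph$edge_index, f$graph$descriptors,
                               f$gp[[l]], use_topo, 0.2)
        if (l < length(f$gp)) S <- ifelse(S > 0, S, expm1(S))  # ELU
      }
      expect_equal(fw$out, S, tolerance = 1e-6,
                   label = paste("seed", seed, "topo", use_topo))
    }
  }
})

test_that("attention maps are normalized on every forward pass", {
  for (seed in 1:5) {
    f <- gtat_fixture(n = 5L + seed, seed = seed + 30L)
    fw <- gtat_forward(f$S, f$graph, f$gp)
    for (layer in fw$attention) {
      for (al in layer) {
        sums <- tapply(al, f$graph$edge_index[, 2L], sum)
        expect_true(all(abs(sums - 1) < 1e-6))
      }
    }
  }
})

test_that("the full layer is permutation-equivariant", {
  f <- gtat_fixture(n = 7L, seed = 8L)
  set.seed(9)
  perm <- sample.int(f$n)
  inv <- order(perm)
  net_p <- regulatory_network(
    f$net$node_ids,
    cbind(f$net$node_ids[inv[match(f$net$edges[, 1L], f$net$node_ids)]],
          f$net$node_ids[inv[match(f$net$edges[, 2L], f$net$node_ids)]]))
  # simpler: relabel node i as perm[i] and rebuild the graph
  ei <- f$net$edge_index
  ids <- f$net$node_ids
  net_p <- regulatory_network(ids, cbind(ids[perm[ei[, 1L]]],
                                         ids[perm[ei[, 2L]]]))
  graph_p <- build_attention_graph(net_p)
  S_p <- matrix(0, f$n, ncol(f$S))
  S_p[perm, ] <- f$S
  out1 <- gtat_forward(f$S, f$graph, f$gp)$out
  out2 <- gtat_forward(S_p, graph_p, f$gp)$out
  expect_equal(out2[perm, ], out1, tolerance = 1e-9)
})

test_that("identical node features with different descriptors get different attention", {
  # two parents of G3 with identical states; only the descriptors differ
  # (G1 also feeds G4 and G5, so its out-degree and the G1->G3 descriptor
  # differ from G2's)
  net <- regulatory_network(genes(5),
                            rbind(c("G1", "G3"), c("G2", "G3"),
                                  c("G1", "G4"), c("G1", "G5")))
  graph <- build_attention_graph(net)
  gp <- with_seed(11L, init_gtat_params(4L, 5L, 1L, 1L))
  S <- matrix(rnorm(20), 5, 4)
  S[2L, ] <- S[1L, ]   # G1 and G2 indistinguishable by features
  ei <- graph$edge_index
  e13 <- which(ei[, 1L] == 1L & ei[, 2L] == 3L)
  e23 <- which(ei[, 1L] == 2L & ei[, 2L] == 3L)
  lg_topo <- attention_logits(S, ei, graph$descriptors, gp[[1L]], 1L,
                              use_topo = TRUE)
  al_topo <- normalize_attention(lg_topo, ei, 5L)
  expect_gt(abs(al_topo[e13] - al_topo[e23]), 1e-6)
  # without descriptors the two edges are indistinguishable
  lg_plain <- attention_logits(S, ei, graph$descriptors, gp[[1L]], 1L,
                               use_topo = FALSE)
  al_plain <- normalize_attention(lg_plain, ei, 5L)
  expect_equal(al_plain[e13], al_plain[e23], tolerance = 1e-12)
})

test_that("self-loop-only graphs mix no neighbor information", {
  net <- regulatory_network(genes(5), NULL)
  graph <- build_attention_graph(net)
  gp <- with_seed(12L, init_gtat_params(4L, 5L, 2L, 1L))
  set.seed(13)
  S <- matrix(rnorm(20), 5, 4)
  out1 <- gtat_forward(S, graph, gp)$out
  # perturbing node 5 leaves nodes 1-4 untouched
  S2 <- S
  S2[5L, ] <- S2[5L, ] + 1
  out2 <- gtat_forward(S2, graph, gp)$out
  expect_equal(out2[1:4, ], out1[1:4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out2[5L, ], out1[5L, ])))
})
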