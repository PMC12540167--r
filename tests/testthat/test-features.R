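test_that("zscore uses population moments and flags constants", {
  m <- matrix(c(1, 2, 3), 3, 1)
  z <- zscore(m, "column")
  expect_equal(drop(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_false(attr(z, "constant"))

  zc <- zscore(matrix(c(5, 5, 5), 3, 1), "column")
  expect_equal(drop(zc), c(0, 0, 0), ignore_attr = TRUE)
  expect_true(attr(zc, "constant"))

  set.seed(1)
  already <- scale(matrix(rnorm(50), 10, 5)) * sqrt(10 / 9)  # population sd 1
  z2 <- zscore(already, "column")
  expect_equal(unclass(z2), unclass(already), tolerance = 1e-8,
               ignore_attr = TRUE)

  # row axis standardizes each gene across time points
  zr <- zscore(matrix(c(1, 2, 3, 10, 10, 10), 2, 3, byrow = TRUE), "row")
  expect_equal(zr[1L, ], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_equal(zr[2L, ], c(0, 0, 0))

  expect_error(zscore(matrix(numeric(0), 0, 0)), "empty")
})

test_that("standardized columns have zero mean and unit variance", {
  bench <- small_benchmark(seed = 5L)
  bundle <- build_feature_bundle(bench$dataset, bench$network)
  for (fam in c("temporal", "profile", "topological")) {
    m <- bundle[[fam]]
    const <- attr(m, "constant")
    expect_true(all(abs(colMeans(m)) < 1e-8), label = fam)
    sds <- sqrt(colMeans(m^2) - colMeans(m)^2)
    expect_true(all(abs(sds[!const] - 1) < 1e-6), label = fam)
    expect_true(all(sds[const] == 0), label = fam)
  }
})

test_that("temporal features match closed forms", {
  t_len <- 9L
  ramp <- matrix(rep(0:(t_len - 1), 2), t_len, 2)  # both genes = ramp
  ramp[, 2] <- 4                                   # constant gene
  ds <- expression_dataset(c("ramp", "const"), timeseries = list(ramp))
  raw <- temporal_features(ds, window = 3L, step = 1L, standardize = FALSE)
  expect_equal(raw["ramp", "ts_trend"], 1.0)
  expect_equal(raw["ramp", "ts_mean"], (t_len - 1) / 2)
  expect_equal(unname(raw["const", c("ts_sd", "ts_skewness", "ts_kurtosis",
                                     "ts_trend")]),
               rep(0, 4))
  expect_true(all(raw["const", grep("win", colnames(raw))] == 4))

  # single window: [1,3,2] with window 3 -> one window mean of 2
  ds2 <- expression_dataset("g", timeseries = list(matrix(c(1, 3, 2), 3, 1)))
  raw2 <- temporal_features(ds2, window = 3L, standardize = FALSE)
  expect_equal(sum(grepl("win", colnames(raw2))), 1L)
  expect_equal(unname(raw2[1L, "ts_win1_mean"]), 2)

  expect_error(temporal_features(ds2, window = 10L), "window")
})

test_that("temporal statistics agree with direct moment computation", {
  set.seed(8)
  x <- rnorm(21)
  ds <- expression_dataset("g", timeseries = list(matrix(x, 21, 1)))
  raw <- temporal_features(ds, standardize = FALSE)
  mu <- mean(x); s <- sqrt(mean((x - mu)^2))
  expect_equal(unname(raw[1, "ts_mean"]), mu)
  expect_equal(unname(raw[1, "ts_sd"]), s)
  expect_equal(unname(raw[1, "ts_skewness"]), mean((x - mu)^3) / s^3,
               tolerance = 1e-10)
  expect_equal(unname(raw[1, "ts_kurtosis"]), mean((x - mu)^4) / s^4 - 3,
               tolerance = 1e-10)
  expect_equal(unname(raw[1, "ts_trend"]),
               unname(coef(lm(x ~ I(0:20)))[2]), tolerance = 1e-10)
  expect_equal(unname(raw[1, "ts_win5_mean"]), mean(x[5:7]))
})

test_that("profile features match a brute-force pairwise Pearson oracle", {
  set.seed(4)
  cond <- matrix(rnorm(6 * 4), 6, 4)
  cond[, 4] <- cond[, 3]  # genes 3 and 4 perfectly correlated
  ds <- expression_dataset(genes(4), conditions = cond,
                           condition_labels = rep("wt", 6))
  raw <- profile_features(ds, standardize = FALSE)
  for (i in 1:4) {
    rs <- vapply(setdiff(1:4, i), function(j) {
      abs(cor(cond[, i], cond[, j]))
    }, 0)
    expect_equal(unname(raw[i, "pf_cor_mean"]), mean(rs), tolerance = 1e-10)
    expect_equal(unname(raw[i, "pf_cor_max"]), max(rs), tolerance = 1e-10)
  }
  expect_equal(unname(raw[3L, "pf_cor_max"]), 1.0)
  expect_equal(unname(raw[4L, "pf_cor_max"]), 1.0)
})

test_that("constant genes get zero stability, CV and tau", {
  cond <- cbind(rep(2, 5), rnorm(5))
  ds <- expression_dataset(c("flat", "var"), conditions = cond,
                           condition_labels = c("wt", "ko:var", "ko:var",
                                                "wt", "wt"))
  raw <- profile_features(ds, standardize = FALSE)
  expect_equal(unname(raw["flat", c("pf_stability", "pf_cv", "pf_tau")]),
               c(0, 0, 0))
  # baseline = mean over wt rows only
  expect_equal(unname(raw["var", "pf_baseline"]),
               mean(cond[c(1, 4, 5), 2]))
  # fallback when no wild-type label
  ds2 <- expression_dataset(c("a", "b"), conditions = cond,
                            condition_labels = rep("ko:x", 5))
  expect_warning(raw2 <- profile_features(ds2, standardize = FALSE),
                 "grand mean")
  expect_equal(unname(raw2[, "pf_baseline"]), unname(colMeans(cond)))
})

test_that("topological features handle symmetric and empty graphs", {
  cyc <- regulatory_network(genes(3),
                            cbind(genes(3), c("G2", "G3", "G1")))
  raw <- topological_features(cyc, standardize = FALSE)
  expect_equal(unname(raw[, "tp_in_degree"]), rep(1, 3))
  expect_equal(unname(raw[, "tp_out_degree"]), rep(1, 3))
  expect_equal(unname(raw[, "tp_pagerank"]), rep(1 / 3, 3),
               tolerance = 1e-10)

  empty <- regulatory_network(genes(5), NULL)
  raw0 <- topological_features(empty, standardize = FALSE)
  expect_true(all(raw0 == 0))
})

test_that("centralities match exhaustive oracles on small random digraphs", {
  for (seed in 1:12) {
    n <- 4L + (seed %% 9L)
    net <- random_digraph(n, p = 0.3, seed = seed)
    if (nrow(net$edges) == 0L) next
    A <- adjacency_of(net)
    raw <- topological_features(net, standardize = FALSE)
    expect_equal(unname(raw[, "tp_betweenness"]), brute_betweenness(A),
                 tolerance = 1e-10, label = paste("betweenness seed", seed))
    expect_equal(unname(raw[, "tp_pagerank"]), brute_pagerank(A),
                 tolerance = 1e-10, label = paste("pagerank seed", seed))
    expect_equal(unname(raw[, "tp_clustering"]), brute_clustering(A),
                 tolerance = 1e-10, label = paste("clustering seed", seed))
    expect_equal(unname(raw[, "tp_local_efficiency"]),
                 brute_local_efficiency(A), tolerance = 1e-10,
                 label = paste("local efficiency seed", seed))
    expect_equal(unname(raw[, "tp_kcore"]), as.numeric(brute_kcore(A)),
                 label = paste("kcore seed", seed))
    expect_equal(unname(raw[, "tp_degree"]), rowSums(A) + colSums(A),
                 label = paste("degree seed", seed))
  }
})

test_that("edge descriptors enumerate paths and common neighbors", {
  # u and v both point to w; u cannot reach v
  net <- regulatory_network(c("u", "v", "w"),
                            rbind(c("u", "w"), c("v", "w")))
  d <- edge_structural_descriptors(net, rbind(c("u", "v")))
  expect_equal(unname(d[1L, ]), c(1, 0, 1, 3, 0))  # cap = N = 3

  # direct edge gives path length 1
  d2 <- edge_structural_descriptors(net, rbind(c("u", "w")))
  expect_equal(unname(d2[1L, "sp_length"]), 1)
  expect_equal(unname(d2[1L, "same_component"]), 1)

  empty <- regulatory_network(genes(4), NULL)
  d3 <- edge_structural_descriptors(empty, rbind(c(1L, 2L)))
  expect_equal(unname(d3[1L, ]), c(0, 0, 0, 4, 0))

  expect_error(edge_structural_descriptors(net, rbind(c("u", "zz"))),
               "not in graph")
})

test_that("edge descriptors match brute-force enumeration on random graphs", {
  for (seed in 1:6) {
    n <- 5L + seed
    net <- random_digraph(n, 0.3, seed = seed + 50L)
    A <- adjacency_of(net)
    U <- ((A + t(A)) > 0) * 1L
    D <- bfs_distances(A)
    pairs <- which(diag(n) == 0, arr.ind = TRUE)
    d <- edge_structural_descriptors(net, pairs)
    for (r in seq_len(nrow(pairs))) {
      u <- pairs[r, 1L]; v <- pairs[r, 2L]
      expect_equal(unname(d[r, "out_deg_src"]), sum(A[u, ]))
      expect_equal(unname(d[r, "in_deg_dst"]), sum(A[, v]))
      expect_equal(unname(d[r, "common_neighbors"]),
                   sum(U[u, ] & U[v, ]))
      expect_equal(unname(d[r, "sp_length"]),
                   if (is.finite(D[u, v])) D[u, v] else n)
      expect_equal(unname(d[r, "same_component"]),
                   as.numeric(is.finite(D[u, v])))
    }
  }
})

test_that("feature extraction is permutation-equivariant", {
  bench <- small_benchmark(seed = 9L)
  ds <- bench$dataset; net <- bench$network
  n <- length(ds$gene_names)
  set.seed(2)
  perm <- sample.int(n)
  ds_p <- expression_dataset(ds$gene_names[perm],
                             lapply(ds$timeseries,
                                    function(m) m[, perm, drop = FALSE]),
                             ds$conditions[, perm, drop = FALSE],
                             ds$condition_labels)
  net_p <- regulatory_network(net$node_ids[perm], net$edges)
  b1 <- build_feature_bundle(ds, net)
  b2 <- build_feature_bundle(ds_p, net_p)
  for (fam in c("temporal", "profile", "topological")) {
    expect_equal(unclass(b2[[fam]])[ds$gene_names[perm], ],
                 unclass(b1[[fam]])[ds$gene_names[perm], ],
                 tolerance = 1e-10, ignore_attr = TRUE, label = fam)
  }
})

test_that("removing an edge never increases degree-type features", {
  net <- random_digraph(8L, 0.35, seed = 77L)
  raw <- topological_features(net, standardize = FALSE)
  for (e in seq_len(min(5L, nrow(net$edges)))) {
    reduced <- regulatory_network(net$node_ids,
                                  net$edges[-e, , drop = FALSE])
    raw2 <- topological_features(reduced, standardize = FALSE)
    cols <- c("tp_degree", "tp_in_degree", "tp_out_degree", "tp_kcore")
    expect_true(all(raw2[, cols] <= raw[, cols] + 1e-12))
  }
})
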