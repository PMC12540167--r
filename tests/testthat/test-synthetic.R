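test_that("network generation is seed-deterministic with exact edge counts", {
  cfg <- synthetic_config(n_genes = 100L, n_edges = 176L, seed = 5L)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1$edges, n2$edges)
  expect_true(nrow(n1$edges) >= 159L && nrow(n1$edges) <= 193L)
  expect_true(all(n1$edges[, 1L] != n1$edges[, 2L]))

  n3 <- generate_network(synthetic_config(n_genes = 100L, n_edges = 176L,
                                          seed = 6L))
  expect_false(identical(n1$edges, n3$edges))
})

test_that("zero hub bias gives a near-uniform out-degree distribution", {
  # aggregate out-degrees over seeds; chi-square against uniform
  counts <- numeric(30L)
  for (s in 1:10) {
    net <- generate_network(synthetic_config(n_genes = 30L, n_edges = 60L,
                                             hub_bias = 0, seed = s))
    A <- adjacency_of(net)
    counts <- counts + rowSums(A)
  }
  expect_gt(chisq.test(counts)$p.value, 1e-4)

  # strong hub bias concentrates out-degree
  counts_h <- numeric(30L)
  for (s in 1:10) {
    net <- generate_network(synthetic_config(n_genes = 30L, n_edges = 60L,
                                             hub_bias = 10, seed = s))
    counts_h <- counts_h + rowSums(adjacency_of(net))
  }
  expect_gt(max(counts_h), max(counts))
})

test_that("time series have the configured shape and stable dynamics", {
  cfg <- synthetic_config(n_genes = 20L, n_edges = 30L, t_points = 21L,
                          n_series = 5L, seed = 8L)
  net <- generate_network(cfg)
  ts <- simulate_timeseries(net, cfg)
  expect_length(ts, 5L)
  for (m in ts) {
    expect_equal(dim(m), c(21L, 20L))
    expect_true(all(is.finite(m)))
  }
  expect_identical(ts, simulate_timeseries(net, cfg))
})

test_that("without interactions the dynamics are independent AR(1) noise", {
  cfg <- synthetic_config(n_genes = 10L, n_edges = 5L,
                          strength_range = c(0, 0), t_points = 250L,
                          n_series = 5L, n_knockouts = 2L, seed = 12L)
  net <- generate_network(cfg)
  ts <- simulate_timeseries(net, cfg)
  # drop the perturbation transient (decay 0.3, gone within ~15 steps) and
  # test cross-gene independence on the stationary tail; note AR(1)
  # autocorrelation inflates var(r) by (1+phi^2)/(1-phi^2), hence the large
  # sample
  x <- do.call(rbind, lapply(ts, function(m) m[-(1:15), , drop = FALSE]))
  cc <- cor(x)
  off <- abs(cc[upper.tri(cc)])
  expect_lt(max(off), 0.2)
  expect_lt(mean(off), 0.1)
})

test_that("a strong planted edge shows up as lagged correlation", {
  lag_cor <- function(m, u, v) cor(m[-nrow(m), u], m[-1L, v])
  hits <- 0L
  for (s in 1:5) {
    cfg <- synthetic_config(n_genes = 8L, n_edges = 4L,
                            strength_range = c(0.8, 0.9), noise_sd = 0.1,
                            t_points = 60L, n_series = 2L, n_knockouts = 2L,
                            seed = 100L + s)
    net <- generate_network(cfg)
    ts <- simulate_timeseries(net, cfg)
    e <- net$edge_index[1L, ]
    signal <- mean(vapply(ts, lag_cor, 0, u = e[1L], v = e[2L]))
    # null: lagged correlation between two genes with no edge either way
    A <- adjacency_of(net)
    free <- which(A == 0L & t(A) == 0L & diag(8L) == 0L, arr.ind = TRUE)
    nulls <- vapply(seq_len(min(10L, nrow(free))), function(i) {
      mean(vapply(ts, lag_cor, 0, u = free[i, 1L], v = free[i, 2L]))
    }, 0)
    if (abs(signal) > stats::quantile(abs(nulls), 0.8)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("lagged correlation along true edges dominates non-edges", {
  cfg <- synthetic_config(seed = 21L)
  net <- generate_network(cfg)
  ts <- simulate_timeseries(net, cfg)
  lag_cor <- function(u, v) {
    mean(vapply(ts, function(m) cor(m[-nrow(m), u], m[-1L, v]), 0))
  }
  A <- adjacency_of(net)
  edges <- net$edge_index
  true_vals <- abs(vapply(seq_len(nrow(edges)), function(i) {
    lag_cor(edges[i, 1L], edges[i, 2L])
  }, 0))
  set.seed(22)
  non <- which(A == 0L & diag(nrow(A)) == 0L, arr.ind = TRUE)
  non <- non[sample.int(nrow(non), 200L), ]
  null_vals <- abs(vapply(seq_len(nrow(non)), function(i) {
    lag_cor(non[i, 1L], non[i, 2L])
  }, 0))
  wt <- wilcox.test(true_vals, null_vals, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("knockouts clamp the gene and spare unaffected genes", {
  cfg <- synthetic_config(n_genes = 15L, n_edges = 10L, n_knockouts = 15L,
                          n_wt = 3L, seed = 31L)
  net <- generate_network(cfg)
  kc <- simulate_knockouts(net, cfg)
  expect_equal(dim(kc$conditions), c(18L, 15L))
  expect_equal(kc$labels[1:3], rep("wt", 3L))
  ko_rows <- which(startsWith(kc$labels, "ko:"))
  expect_length(ko_rows, 15L)
  wt_mean <- colMeans(kc$conditions[1:3, , drop = FALSE])
  A <- adjacency_of(net)
  U <- ((A + t(A)) > 0)
  for (r in ko_rows) {
    g <- sub("^ko:", "", kc$labels[r])
    gi <- match(g, net$node_ids)
    expect_identical(unname(kc$conditions[r, gi]), 0)  # exact clamp
    # isolated knocked-out gene: everyone else stays at wild type
    if (all(!U[gi, ])) {
      expect_equal(kc$conditions[r, -gi], wt_mean[-gi],
                   tolerance = 0.2, ignore_attr = TRUE)
    }
  }
})

test_that("benchmark bundles round-trip and are byte-identical", {
  cfg <- synthetic_config(n_genes = 12L, n_edges = 14L, t_points = 7L,
                          n_series = 2L, n_knockouts = 3L, n_wt = 2L,
                          seed = 9L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- make_benchmark_bundle(cfg, d1)
  p2 <- make_benchmark_bundle(cfg, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  back <- load_benchmark_bundle(d1, t_points = 7L)
  bench <- generate_benchmark(cfg)
  expect_equal(back$network$edges, bench$network$edges)
  expect_equal(back$dataset$conditions, bench$dataset$conditions,
               tolerance = 1e-5)
  expect_equal(back$dataset$condition_labels,
               bench$dataset$condition_labels)

  # the loaded bundle feeds the pipeline directly
  cfgr <- tiny_config(epochs = 2L, seed = 2L)
  m <- train_model(back$dataset, back$network, cfgr)
  expect_true(is.finite(utils::tail(m$history$loss, 1L)))
})

test_that("default bundle matches the DREAM4-like schema", {
  cfg <- synthetic_config()
  expect_equal(cfg$n_genes, 60L)
  expect_equal(cfg$t_points, 21L)
  expect_equal(cfg$n_series, 5L)
  expect_equal(cfg$n_knockouts, 20L)
  # Net-1-like schema at full scale: 100 genes, 210 profiles, 176 edges
  cfg100 <- synthetic_config(n_genes = 100L, n_edges = 176L,
                             n_knockouts = 100L, n_wt = 5L, seed = 1L)
  net <- generate_network(cfg100)
  expect_equal(length(net$node_ids), 100L)
  expect_equal(nrow(net$edges), 176L)
  n_profiles <- cfg100$n_series * cfg100$t_points + cfg100$n_knockouts +
    cfg100$n_wt
  expect_equal(n_profiles, 210L)

  expect_error(synthetic_config(n_genes = 60L, n_edges = 10L), "sparse")
  expect_error(synthetic_config(n_genes = 4L), "n_genes")
})
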