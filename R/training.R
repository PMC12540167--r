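#' Build the candidate-pair universe
#'
#' All ordered gene pairs `(u, v)` with `u != v` and `u` restricted to
#' `regulators` when a TF list is supplied. Pairs present in the gold
#' standard are labelled 1, everything else 0.
#'
#' @param network Gold-standard [regulatory_network()].
#' @param regulators Optional character vector of allowed regulators.
#' @return data.frame with columns `regulator`, `target`, `label` and
#'   1-based index columns `src`, `dst`, in canonical (regulator-major)
#'   order.
#' @export
build_candidate_universe <- function(network, regulators = NULL) {
  nodes <- network$node_ids
  regulators <- regulators %||% nodes
  if (!all(regulators %in% nodes)) {
    stop("regulator not in node set", call. = FALSE)
  }
  src <- match(regulators, nodes)
  grid <- expand.grid(dst = seq_along(nodes), src = src,
                      KEEP.OUT.ATTRS = FALSE)[, c("src", "dst")]
  grid <- grid[grid$src != grid$dst, , drop = FALSE]
  if (nrow(grid) == 0L) stop("empty candidate universe", call. = FALSE)
  key <- paste(grid$src, grid$dst)
  gold <- paste(network$edge_index[, 1L], network$edge_index[, 2L])
  out <- data.frame(regulator = nodes[grid$src], target = nodes[grid$dst],
                    label = as.integer(key %in% gold),
                    src = grid$src, dst = grid$dst,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Stratified k-fold assignment
#'
#' Positives and negatives are shuffled separately with the seeded generator
#' and dealt round-robin into `k` folds, so per-fold class counts differ
#' from the ideal by at most one. The same seed yields bit-identical
#' assignments across processes.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (>= 2).
#' @param seed Master seed (42 by default, the conventional choice for
#'   reproducible GRN benchmark splits).
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 42L) {
  stopifnot(k >= 2L)
  if (min(sum(labels == 1), sum(labels == 0)) < k) {
    warning("a class has fewer members than folds; degenerate folds")
  }
  fold <- integer(length(labels))
  with_seed(derive_seed(seed, "kfold"), {
    for (cls in c(1, 0)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  })
  fold
}

#' Stratified fixed train/validation/test split
#'
#' @param labels Binary label vector.
#' @param fractions Named numeric vector `c(train=, val=, test=)` summing
#'   to 1.
#' @param seed Master seed.
#' @return Character vector of split tags.
#' @export
stratified_split <- function(labels, fractions = c(train = 0.7, val = 0.1,
                                                   test = 0.2),
                             seed = 42L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  tags <- character(length(labels))
  with_seed(derive_seed(seed, "split"), {
    for (cls in c(1, 0)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_train <- round(n * fractions[["train"]])
      n_val <- round(n * fractions[["val"]])
      tags[idx] <- rep(c("train", "val", "test"),
                       c(n_train, n_val, n - n_train - n_val))
    }
  })
  tags
}

#' Sample the per-epoch training batch
#'
#' All training positives plus `ratio` times as many negatives drawn without
#' replacement from the training negatives; the draw is re-keyed every epoch
#' from the seeded stream, so over many epochs the whole negative pool is
#' visited while each single epoch stays balanced. Evaluation splits are
#' never subsampled.
#'
#' @param train_idx_pos,train_idx_neg Integer row indices of training
#'   positives/negatives in the candidate universe.
#' @param ratio Negatives per positive (>= 1).
#' @param seed Master seed.
#' @param epoch Epoch number (keys the draw).
#' @return Integer vector of row indices (positives first).
#' @export
sample_training_negatives <- function(train_idx_pos, train_idx_neg,
                                      ratio = 5L, seed = 42L, epoch = 1L) {
  stopifnot(ratio >= 1)
  want <- length(train_idx_pos) * ratio
  if (want >= length(train_idx_neg)) {
    if (want > length(train_idx_neg)) {
      warning("requested more negatives than available; using all")
    }
    return(c(train_idx_pos, train_idx_neg))
  }
  picked <- with_seed(derive_seed(seed, "negatives", epoch), {
    train_idx_neg[sample.int(length(train_idx_neg), want)]
  })
  c(train_idx_pos, picked)
}

# Training-fold subgraph: only training positives enter message passing and
# topological features, unless full_graph_features mirrors the protocol of
# computing them from the full gold standard (label leakage; off by default).
training_subgraph <- function(network, universe, config) {
  if (isTRUE(config$full_graph_features)) return(network)
  tr <- universe[universe$split == "train" & universe$label == 1, ,
                 drop = FALSE]
  regulatory_network(network$node_ids,
                     edges = if (nrow(tr)) {
                       cbind(tr$regulator, tr$target)
                     } else NULL)
}

#' Train the edge classifier
#'
#' Full pipeline: extract features from the training-fold subgraph, then
#' loop forward (fusion -> GTAT -> FFN/residual -> scorer), focal loss,
#' gradient step (Adam), with per-epoch negative resampling and early
#' stopping on validation AUPR. Fully seeded: two runs with the same seed
#' produce identical loss trajectories.
#'
#' @param dataset An [expression_dataset()].
#' @param network Gold-standard [regulatory_network()].
#' @param config Configuration list ([default_config()]).
#' @param splits Optional candidate universe with a `split` column (as
#'   produced internally or by [cross_validate()]); when `NULL` a stratified
#'   fixed split per `config$split` is built.
#' @return Object of class `grn_model` with the best-validation parameters,
#'   per-epoch history, split table, feature bundle and attention graph.
#' @export
train_model <- function(dataset, network, config = default_config(),
                        splits = NULL) {
  seed <- config$seed
  universe <- splits %||% {
    u <- build_candidate_universe(network)
    u$split <- stratified_split(u$label, config$split, seed)
    u
  }
  stopifnot(all(c("regulator", "target", "label", "src", "dst", "split")
                %in% names(universe)))
  idx_train <- which(universe$split == "train")
  idx_val <- which(universe$split == "val")
  tr_pos <- idx_train[universe$label[idx_train] == 1]
  tr_neg <- idx_train[universe$label[idx_train] == 0]
  if (length(tr_pos) == 0L) stop("no training positives", call. = FALSE)

  train_net <- training_subgraph(network, universe, config)
  bundle <- build_feature_bundle(dataset, train_net, config)
  graph <- build_attention_graph(train_net, cap = config$sp_cap)
  params <- init_model_params(ncol(bundle$temporal), ncol(bundle$profile),
                              ncol(bundle$topological),
                              ncol(graph$descriptors), config, seed)
  opt <- adam_init(params)
  val_pairs <- cbind(universe$src[idx_val], universe$dst[idx_val])
  val_labels <- universe$label[idx_val]
  val_has_both <- length(idx_val) > 0L && length(unique(val_labels)) == 2L

  best <- list(score = -Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_aupr = numeric(), val_score = numeric())
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    batch_idx <- sample_training_negatives(tr_pos, tr_neg, config$neg_ratio,
                                           seed, epoch)
    pairs <- cbind(universe$src[batch_idx], universe$dst[batch_idx])
    labels <- universe$label[batch_idx]
    step <- with_seed(derive_seed(seed, "epoch", epoch), {
      fw <- model_forward(params, bundle, graph, pairs, config,
                          training = TRUE)
      loss <- focal_loss(fw$scores, labels, config$focal_alpha,
                         config$focal_gamma)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      dsc <- focal_loss_grad(fw$scores, labels, config$focal_alpha,
                             config$focal_gamma)
      grads <- model_backward(dsc, fw, params, bundle, graph, config)
      list(loss = loss, grads = grads)
    })
    upd <- adam_step(params, step$grads, opt, lr = config$lr,
                     weight_decay = config$weight_decay)
    params <- upd$params
    opt <- upd$state

    val_aupr <- NA_real_
    if (length(idx_val) > 0L) {
      vfw <- model_forward(params, bundle, graph, val_pairs, config,
                           training = FALSE)
      if (val_has_both) {
        val_aupr <- average_precision(vfw$scores, val_labels)
        val_score <- val_aupr
      } else {
        val_score <- -focal_loss(vfw$scores, val_labels,
                                 config$focal_alpha, config$focal_gamma)
      }
    } else {
      val_score <- -step$loss
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = step$loss,
                                         val_aupr = val_aupr,
                                         val_score = val_score))
    if (val_score > best$score + 1e-12) {
      best <- list(score = val_score, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, best_epoch = best$epoch,
                 config = config, history = history, universe = universe,
                 bundle = bundle, graph = graph,
                 node_ids = network$node_ids,
                 train_network = train_net),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat("grn_model:", length(x$node_ids), "genes; best epoch", x$best_epoch,
      "of", nrow(x$history), "run;",
      sprintf("final loss %.4f\n", utils::tail(x$history$loss, 1L)))
  invisible(x)
}

#' Score candidate pairs with a trained model
#'
#' @param object A `grn_model`.
#' @param pairs Optional two-column matrix of gene names or indices;
#'   defaults to every pair in the model's candidate universe.
#' @param ... Unused.
#' @return A [ranked_predictions()] table.
#' @export
predict.grn_model <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    idx <- cbind(object$universe$src, object$universe$dst)
    reg <- object$universe$regulator
    tgt <- object$universe$target
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      idx <- cbind(match(pairs[, 1L], object$node_ids),
                   match(pairs[, 2L], object$node_ids))
      if (anyNA(idx)) stop("unknown gene in pairs", call. = FALSE)
    } else {
      idx <- matrix(as.integer(pairs), ncol = 2L)
    }
    reg <- object$node_ids[idx[, 1L]]
    tgt <- object$node_ids[idx[, 2L]]
  }
  fw <- model_forward(object$params, object$bundle, object$graph, idx,
                      object$config, training = FALSE)
  ranked_predictions(reg, tgt, fw$scores)
}

#' Evaluate a trained model on one of its splits
#'
#' @param model A `grn_model`.
#' @param split `"test"`, `"val"` or `"train"`.
#' @param ks Top-k values for the report.
#' @return A [full_report()] `MetricsReport`.
#' @export
evaluate_split <- function(model, split = "test",
                           ks = model$config$topk) {
  u <- model$universe
  idx <- which(u$split == split)
  if (length(idx) == 0L) stop("empty split: ", split, call. = FALSE)
  fw <- model_forward(model$params, model$bundle, model$graph,
                      cbind(u$src[idx], u$dst[idx]), model$config,
                      training = FALSE)
  full_report(fw$scores, u$label[idx], ks = ks[ks <= length(idx)],
              pairs = cbind(u$regulator[idx], u$target[idx]))
}

#' Stratified k-fold cross-validation
#'
#' Trains one model per fold (the fold held out as test; a stratified
#' fraction of the remainder held out as validation for early stopping) and
#' reports AUC, AUPR and precision/recall/F1 at k per fold plus their mean
#' and standard deviation.
#'
#' @param dataset An [expression_dataset()].
#' @param network Gold-standard [regulatory_network()].
#' @param config Configuration list.
#' @param k Number of folds.
#' @return List with `per_fold` (data.frame), `mean`, `sd` and the list of
#'   fold `reports`.
#' @export
cross_validate <- function(dataset, network, config = default_config(),
                           k = 5L) {
  universe <- build_candidate_universe(network)
  fold <- stratified_kfold(universe$label, k, config$seed)
  reports <- vector("list", k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    u <- universe
    u$split <- "train"
    u$split[fold == i] <- "test"
    rest <- which(fold != i)
    val_tag <- with_seed(derive_seed(config$seed, "cvval", i), {
      tag <- character(length(rest))
      for (cls in c(1, 0)) {
        j <- rest[universe$label[rest] == cls]
        j <- j[sample.int(length(j))]
        n_val <- max(1L, round(length(j) * config$val_fraction_cv))
        tag[match(j[seq_len(n_val)], rest)] <- "val"
      }
      tag
    })
    u$split[rest[val_tag == "val"]] <- "val"
    u$fold <- fold
    model <- train_model(dataset, network, config, splits = u)
    reports[[i]] <- evaluate_split(model, "test")
    rows[[i]] <- as.data.frame(reports[[i]])
  }
  per_fold <- do.call(rbind, rows)
  per_fold <- cbind(fold = seq_len(k), per_fold)
  metric_cols <- c("AUC", "AUPR", "precision_at_k", "recall_at_k",
                   "f1_at_k")
  list(per_fold = per_fold,
       mean = colMeans(per_fold[metric_cols]),
       sd = apply(per_fold[metric_cols], 2L, stats::sd),
       reports = reports)
}

#' Ablation arms for the component analysis
#'
#' Trains the incremental architecture arms (`base`: fused features straight
#' into the scorer; `resffn`: adds the FFN/residual refinement; `gtat`: adds
#' the topology-aware attention layer without edge descriptors; `topo`: the
#' full model with descriptors) over one or more seeds and reports test
#' metrics per arm.
#'
#' @param dataset An [expression_dataset()].
#' @param network Gold-standard [regulatory_network()].
#' @param config Base configuration.
#' @param arms Character vector of arm names.
#' @param seeds Integer vector of seeds.
#' @return data.frame with one row per arm x seed plus per-arm medians in
#'   attribute `"medians"`.
#' @export
run_ablation <- function(dataset, network, config = default_config(),
                         arms = c("base", "resffn", "gtat", "topo"),
                         seeds = config$seed) {
  flag_sets <- list(
    base = list(use_resffn = FALSE, use_gtat = FALSE, use_topo = FALSE),
    resffn = list(use_resffn = TRUE, use_gtat = FALSE, use_topo = FALSE),
    gtat = list(use_resffn = TRUE, use_gtat = TRUE, use_topo = FALSE),
    topo = list(use_resffn = TRUE, use_gtat = TRUE, use_topo = TRUE))
  stopifnot(all(arms %in% names(flag_sets)))
  rows <- list()
  for (arm in arms) {
    for (s in seeds) {
      cfg <- config
      cfg[names(flag_sets[[arm]])] <- flag_sets[[arm]]
      cfg$seed <- s
      model <- train_model(dataset, network, cfg)
      rep <- evaluate_split(model, "test")
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(arm = arm, seed = s), as.data.frame(rep))
    }
  }
  out <- do.call(rbind, rows)
  med <- stats::aggregate(cbind(AUC, AUPR) ~ arm, data = out,
                          FUN = stats::median)
  attr(out, "medians") <- med[match(arms, med$arm), ]
  out
}
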