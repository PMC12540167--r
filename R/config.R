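#' Default run configuration
#'
#' Returns the full list of tunable knobs used across the pipeline. Every
#' knob has a default; [read_run_config()] overlays a YAML file on top of
#' these. Architecture and optimisation settings are deliberately exposed
#' because published GRN attention models rarely report them.
#'
#' @return Named list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$heads
default_config <- function() {
  list(
    # feature extraction
    window = 3L,              # sliding-window size over time points
    window_step = 1L,         # sliding-window step
    wt_label = "wt",          # condition label marking wild-type profiles
    max_pattern_groups = 5L,  # condition-group means kept as pattern features
    pagerank_damping = 0.85,
    sp_cap = NULL,            # shortest-path cap; NULL = number of genes
    full_graph_features = FALSE, # topo features from full gold standard
    # fusion block
    fused_dim = 32L,
    fusion_dropout = 0.1,
    use_fusion_attention = TRUE,  # FALSE = uniform 1/3 modality weights
    # GTAT layer
    heads = 4L,
    gtat_layers = 2L,
    leaky_slope = 0.2,
    use_gtat = TRUE,
    use_topo = TRUE,          # edge structural descriptors in the logits
    # FFN / residual refinement
    use_resffn = TRUE,
    ffn_hidden = 128L,
    # edge scorer
    scorer_hidden = 64L,
    scorer_dropout = 0.1,
    focal_alpha = 0.5,
    focal_gamma = 2.0,
    # optimisation
    lr = 3e-3,
    weight_decay = 1e-3,
    epochs = 300L,
    patience = 30L,
    neg_ratio = 5L,           # training negatives per positive, per epoch
    # splitting
    split = c(train = 0.7, val = 0.1, test = 0.2),
    val_fraction_cv = 0.125,  # validation share carved from CV training folds
    seed = 42L,
    # evaluation
    topk = c(10L, 50L, 100L)
  )
}

#' Read a run configuration file
#'
#' Loads a YAML (or flat `key: value`) configuration and merges it over
#' [default_config()]. Unknown keys raise an error so typos do not silently
#' fall back to defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return Named list with the same structure as [default_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  merge_config(user)
}

#' @rdname read_run_config
#' @param overrides Named list of configuration overrides.
#' @export
merge_config <- function(overrides = list()) {
  cfg <- default_config()
  if (length(overrides) == 0L) return(cfg)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg$window <- as.integer(cfg$window)
  cfg$heads <- as.integer(cfg$heads)
  cfg$gtat_layers <- as.integer(cfg$gtat_layers)
  stopifnot(cfg$fusion_dropout >= 0, cfg$fusion_dropout < 1,
            cfg$scorer_dropout >= 0, cfg$scorer_dropout < 1,
            cfg$heads >= 1L, cfg$gtat_layers >= 1L)
  cfg
}
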