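# Full model: fusion -> [GTAT] -> [FFN + residual] -> edge scorer.
# Ablation flags (use_gtat, use_resffn, use_topo, use_fusion_attention)
# switch components on/off without changing tensor widths, mirroring the
# incremental architecture arms base / +ResFFN / +GTAT / +Topo.

#' Initialize all model parameters
#'
#' @param d_t,d_b,d_g Widths of the three feature families.
#' @param d_e Edge-descriptor width.
#' @param config Configuration list ([default_config()]).
#' @param seed Seed for the initialisation stream.
#' @return Nested parameter list (class `grn_model_params`).
#' @export
init_model_params <- function(d_t, d_b, d_g, d_e = 5L,
                              config = default_config(),
                              seed = config$seed) {
  with_seed(derive_seed(seed, "init"), {
    d <- as.integer(config$fused_dim)
    structure(list(
      fusion = init_fusion_params(d_t, d_b, d_g, d),
      gtat = init_gtat_params(d, d_e, config$heads, config$gtat_layers),
      ffn = init_ffn_params(d, config$ffn_hidden),
      scorer = init_scorer_params(d, config$scorer_hidden)
    ), class = c("grn_model_params", "list"))
  })
}

model_forward <- function(params, bundle, graph, pairs, config,
                          training = FALSE) {
  fus <- fusion_forward(bundle, params$fusion, training,
                        config$fusion_dropout,
                        use_attention = isTRUE(config$use_fusion_attention))
  S <- fus$out
  gt <- NULL
  if (isTRUE(config$use_gtat)) {
    gt <- gtat_forward_cached(S, graph, params$gtat,
                              use_topo = isTRUE(config$use_topo),
                              slope = config$leaky_slope)
    S <- gt$out
  }
  ff <- NULL
  if (isTRUE(config$use_resffn)) {
    ff <- ffn_forward(S, params$ffn)
    S <- ff$out
  }
  sc <- scorer_forward(S, pairs, params$scorer, training,
                       config$scorer_dropout)
  list(scores = sc$scores,
       embeddings = S,
       alpha = fus$alpha,
       attention = if (is.null(gt)) NULL else {
         lapply(gt$caches, `[[`, "alphas")
       },
       cache = list(fusion = fus$cache, gtat = gt, ffn = ff,
                    scorer = sc$cache))
}

model_backward <- function(d_scores, fw, params, bundle, graph, config) {
  sb <- scorer_backward(d_scores, fw$cache$scorer, params$scorer)
  dS <- sb$d_embeddings
  g_ffn <- param_zeros_like(params$ffn)
  if (isTRUE(config$use_resffn)) {
    fb <- ffn_backward(dS, fw$cache$ffn$cache, params$ffn)
    g_ffn <- fb$grads
    dS <- fb$dh
  }
  g_gtat <- param_zeros_like(params$gtat)
  if (isTRUE(config$use_gtat)) {
    gb <- gtat_backward(dS, fw$cache$gtat, graph, params$gtat,
                        use_topo = isTRUE(config$use_topo),
                        slope = config$leaky_slope)
    g_gtat <- gb$grads
    attributes(g_gtat) <- attributes(params$gtat)
    dS <- gb$d_states
  }
  g_fus <- fusion_backward(dS, fw$cache$fusion, params$fusion)
  structure(list(fusion = g_fus, gtat = g_gtat, ffn = g_ffn,
                 scorer = sb$grads),
            class = class(params))
}

adam_init <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- map_params(function(g, p) g + weight_decay * p, grads, params)
  }
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}
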