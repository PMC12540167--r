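#' Initialize fusion-block parameters
#'
#' Each modality is first projected to a common width `d` by a learned
#' linear map (the three raw families have different widths, so the weighted
#' sum over modalities is only well-formed after projection). On top sit the
#' per-node modality attention heads, the ReLU transform, the sigmoid gate
#' and the output projection with residual.
#'
#' @param d_t,d_b,d_g Widths of the temporal, profile and topological
#'   feature families.
#' @param d Common fused dimension.
#' @return Nested parameter list (class `FusionParameters`).
#' @export
init_fusion_params <- function(d_t, d_b, d_g, d = 64L) {
  mk_proj <- function(din) list(W = init_matrix(din, d), b = rep(0, d))
  mk_attn <- function() list(w = init_vector(d), b = 0)
  structure(list(
    proj = list(t = mk_proj(d_t), b = mk_proj(d_b), g = mk_proj(d_g)),
    attn = list(t = mk_attn(), b = mk_attn(), g = mk_attn()),
    Wf = init_matrix(d, d), bf = rep(0, d),
    Wg = init_matrix(d, d), bg = rep(0, d),
    Wo = init_matrix(d, d), bo = rep(0, d)
  ), class = c("FusionParameters", "list"))
}

add_bias <- function(mat, b) sweep(mat, 2L, b, "+")

#' Concatenate the three feature families
#'
#' Column-wise concatenation in the fixed order temporal, profile,
#' topological; feature-name provenance is preserved in the column names.
#'
#' @param bundle A [feature_bundle()].
#' @return `N x (d_t + d_b + d_g)` matrix.
#' @export
concat_features <- function(bundle) {
  stopifnot(inherits(bundle, "FeatureBundle"))
  cbind(bundle$temporal, bundle$profile, bundle$topological)
}

row_softmax <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

#' Modality attention fusion
#'
#' Projects each standardized family to the common dimension, scores each
#' modality per node with a scalar attention head, softmax-normalizes the
#' three scores into weights `(alpha_t, alpha_b, alpha_g)` summing to one,
#' and forms the fused representation as the alpha-weighted sum of the
#' projected modalities (weights broadcast across the `d` columns).
#'
#' @param bundle A [feature_bundle()].
#' @param params [init_fusion_params()] output.
#' @param use_attention When `FALSE` (ablation), uniform weights 1/3 are
#'   used instead of learned attention.
#' @return List with `alpha` (`N x 3` matrix, columns t/b/g), `X_fused`
#'   (`N x d`) and the projected modalities `H` (list of three matrices).
#' @export
modality_attention_fuse <- function(bundle, params, use_attention = TRUE) {
  H <- list(
    t = add_bias(bundle$temporal %*% params$proj$t$W, params$proj$t$b),
    b = add_bias(bundle$profile %*% params$proj$b$W, params$proj$b$b),
    g = add_bias(bundle$topological %*% params$proj$g$W, params$proj$g$b))
  n <- nrow(H$t)
  if (use_attention) {
    s <- cbind(t = drop(H$t %*% params$attn$t$w) + params$attn$t$b,
               b = drop(H$b %*% params$attn$b$w) + params$attn$b$b,
               g = drop(H$g %*% params$attn$g$w) + params$attn$g$b)
    if (any(!is.finite(s))) stop("non-finite modality score", call. = FALSE)
    alpha <- row_softmax(s)
  } else {
    alpha <- matrix(1 / 3, n, 3L, dimnames = list(NULL, c("t", "b", "g")))
  }
  X_fused <- alpha[, 1L] * H$t + alpha[, 2L] * H$b + alpha[, 3L] * H$g
  list(alpha = alpha, X_fused = X_fused, H = H)
}

#' Refine the fused representation (transform, gate, residual)
#'
#' `Z = ReLU(X_fused W_f + b_f)`; `Z_gate = Z * sigmoid(X_fused W_g + b_g)`;
#' `Z_final = Dropout(Z_gate W_o + b_o) + X_fused`. Dropout (inverted, rate
#' from `dropout`) is active only when `training = TRUE`.
#'
#' @param X_fused `N x d` fused representation.
#' @param params [init_fusion_params()] output.
#' @param training Logical; enables dropout.
#' @param dropout Dropout rate in `[0, 1)`.
#' @return `N x d` matrix `Z_final`.
#' @export
refine_fused <- function(X_fused, params, training = FALSE, dropout = 0.1) {
  fusion_refine_forward(X_fused, params, training, dropout)$out
}

fusion_refine_forward <- function(X_fused, params, training, dropout) {
  d <- ncol(X_fused)
  if (nrow(params$Wf) != d || nrow(params$Wg) != d || nrow(params$Wo) != d) {
    abort_dim("fusion transform width mismatch")
  }
  Af <- add_bias(X_fused %*% params$Wf, params$bf)
  Z <- relu(Af)
  Ag <- add_bias(X_fused %*% params$Wg, params$bg)
  G <- 1 / (1 + exp(-Ag))
  Zg <- Z * G
  Ao <- add_bias(Zg %*% params$Wo, params$bo)
  mask <- if (training && dropout > 0) {
    matrix(stats::rbinom(length(Ao), 1L, 1 - dropout), nrow(Ao)) /
      (1 - dropout)
  } else NULL
  out <- (if (is.null(mask)) Ao else Ao * mask) + X_fused
  list(out = out,
       cache = list(X_fused = X_fused, Af = Af, Z = Z, G = G, Zg = Zg,
                    mask = mask))
}

# Full fusion forward: projection + modality attention + refinement.
fusion_forward <- function(bundle, params, training = FALSE, dropout = 0.1,
                           use_attention = TRUE) {
  fuse <- modality_attention_fuse(bundle, params, use_attention)
  ref <- fusion_refine_forward(fuse$X_fused, params, training, dropout)
  list(out = ref$out, alpha = fuse$alpha,
       cache = list(fuse = fuse, refine = ref$cache, bundle = bundle,
                    use_attention = use_attention))
}

fusion_backward <- function(d_out, cache, params) {
  rc <- cache$refine
  fuse <- cache$fuse
  bundle <- cache$bundle
  # refinement block
  dXf <- d_out                                   # residual path
  dAo <- if (is.null(rc$mask)) d_out else d_out * rc$mask
  dWo <- crossprod(rc$Zg, dAo)
  dbo <- colSums(dAo)
  dZg <- dAo %*% t(params$Wo)
  dZ <- dZg * rc$G
  dG <- dZg * rc$Z
  dAg <- dG * rc$G * (1 - rc$G)
  dWg <- crossprod(rc$X_fused, dAg)
  dbg <- colSums(dAg)
  dXf <- dXf + dAg %*% t(params$Wg)
  dAf <- dZ * (rc$Af > 0)
  dWf <- crossprod(rc$X_fused, dAf)
  dbf <- colSums(dAf)
  dXf <- dXf + dAf %*% t(params$Wf)
  # modality attention
  H <- fuse$H
  alpha <- fuse$alpha
  dH <- list(t = alpha[, 1L] * dXf, b = alpha[, 2L] * dXf,
             g = alpha[, 3L] * dXf)
  grads_attn <- list(t = list(w = rep(0, ncol(dXf)), b = 0),
                     b = list(w = rep(0, ncol(dXf)), b = 0),
                     g = list(w = rep(0, ncol(dXf)), b = 0))
  if (cache$use_attention) {
    dalpha <- cbind(rowSums(dXf * H$t), rowSums(dXf * H$b),
                    rowSums(dXf * H$g))
    inner <- rowSums(alpha * dalpha)
    ds <- alpha * (dalpha - inner)                # softmax backward
    keys <- c("t", "b", "g")
    for (i in seq_along(keys)) {
      k <- keys[i]
      grads_attn[[k]]$w <- drop(crossprod(H[[k]], ds[, i]))
      grads_attn[[k]]$b <- sum(ds[, i])
      dH[[k]] <- dH[[k]] + outer(ds[, i], params$attn[[k]]$w)
    }
  }
  X <- list(t = bundle$temporal, b = bundle$profile, g = bundle$topological)
  grads_proj <- lapply(c(t = "t", b = "b", g = "g"), function(k) {
    list(W = crossprod(X[[k]], dH[[k]]), b = colSums(dH[[k]]))
  })
  list(proj = grads_proj, attn = grads_attn,
       Wf = dWf, bf = dbf, Wg = dWg, bg = dbg, Wo = dWo, bo = dbo)
}
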