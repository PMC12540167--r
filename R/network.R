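#' Initialize FFN parameters
#'
#' Two linear layers around a ReLU; input and output widths are equal so the
#' residual addition is well-formed.
#'
#' @param d Node-state width.
#' @param hidden Hidden width.
#' @return Parameter list (class `FFNParams`).
#' @export
init_ffn_params <- function(d, hidden = 2L * d) {
  structure(list(W1 = init_matrix(d, hidden), b1 = rep(0, hidden),
                 W2 = init_matrix(hidden, d), b2 = rep(0, d)),
            class = c("FFNParams", "list"))
}

#' Feedforward refinement with residual connection
#'
#' `h' = ReLU(h W_1 + b_1) W_2 + b_2`; the block returns `h'' = h + h'`.
#'
#' @param h `N x d` node embeddings.
#' @param params [init_ffn_params()] output.
#' @return `N x d` refined embeddings.
#' @export
ffn_block <- function(h, params) {
  ffn_forward(h, params)$out
}

ffn_forward <- function(h, params) {
  if (ncol(h) != nrow(params$W1) || ncol(params$W2) != ncol(h)) {
    abort_dim("FFN width mismatch")
  }
  A1 <- add_bias(h %*% params$W1, params$b1)
  R1 <- relu(A1)
  hprime <- add_bias(R1 %*% params$W2, params$b2)
  list(out = h + hprime, cache = list(h = h, A1 = A1, R1 = R1))
}

ffn_backward <- function(d_out, cache, params) {
  dhp <- d_out
  dW2 <- crossprod(cache$R1, dhp)
  db2 <- colSums(dhp)
  dR1 <- dhp %*% t(params$W2)
  dA1 <- dR1 * (cache$A1 > 0)
  dW1 <- crossprod(cache$h, dA1)
  db1 <- colSums(dA1)
  dh <- d_out + dA1 %*% t(params$W1)   # residual + transform paths
  list(dh = dh,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' Initialize edge-scorer parameters
#'
#' The pair representation is the concatenation `[z_u || z_v]`, preserving
#' regulator/target direction. It is reduced by a linear layer, layer
#' normalization (with learned gain/shift), ReLU and dropout, then projected
#' to a scalar raw score.
#'
#' @param d Node-embedding width.
#' @param hidden Reduction width.
#' @return Parameter list (class `EdgeScorerParams`).
#' @export
init_scorer_params <- function(d, hidden = 64L) {
  structure(list(W = init_matrix(2L * d, hidden), b = rep(0, hidden),
                 gamma = rep(1, hidden), beta = rep(0, hidden),
                 w_out = init_vector(hidden, fan_in = hidden), b_out = 0),
            class = c("EdgeScorerParams", "list"))
}

layer_norm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = add_bias(sweep(xhat, 2L, gamma, "*"), beta),
       xhat = xhat, inv = inv)
}

layer_norm_backward <- function(d_out, cache, gamma) {
  xhat <- cache$xhat; inv <- cache$inv
  d <- ncol(xhat)
  dgamma <- colSums(d_out * xhat)
  dbeta <- colSums(d_out)
  dxhat <- sweep(d_out, 2L, gamma, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Score candidate regulator-target pairs
#'
#' `score(u, v) = w_out . Dropout(ReLU(LayerNorm(W [z_u || z_v] + b))) +
#' b_out`. The concatenated pair representation makes the score asymmetric:
#' `score(u, v)` need not equal `score(v, u)`. Raw scores above zero mark
#' predicted regulatory interactions; [predict_probability()] maps scores to
#' probabilities.
#'
#' @param embeddings `N x d` node embeddings.
#' @param pairs `B x 2` integer matrix of (regulator, target) indices.
#' @param params [init_scorer_params()] output.
#' @param training Logical; enables dropout.
#' @param dropout Dropout rate.
#' @return Numeric vector of `B` raw scores.
#' @export
edge_score <- function(embeddings, pairs, params, training = FALSE,
                       dropout = 0.1) {
  scorer_forward(embeddings, pairs, params, training, dropout)$scores
}

scorer_forward <- function(embeddings, pairs, params, training = FALSE,
                           dropout = 0.1) {
  pairs <- as.matrix(pairs)
  if (max(pairs) > nrow(embeddings) || min(pairs) < 1L) {
    stop("pair endpoint without embedding", call. = FALSE)
  }
  X <- cbind(embeddings[pairs[, 1L], , drop = FALSE],
             embeddings[pairs[, 2L], , drop = FALSE])
  A <- add_bias(X %*% params$W, params$b)
  ln <- layer_norm_forward(A, params$gamma, params$beta)
  R <- relu(ln$out)
  mask <- if (training && dropout > 0) {
    matrix(stats::rbinom(length(R), 1L, 1 - dropout), nrow(R)) /
      (1 - dropout)
  } else NULL
  Rd <- if (is.null(mask)) R else R * mask
  scores <- drop(Rd %*% params$w_out) + params$b_out
  list(scores = scores,
       cache = list(pairs = pairs, X = X, ln = ln, ln_out = ln$out, R = R,
                    mask = mask, Rd = Rd, n_nodes = nrow(embeddings),
                    d = ncol(embeddings)))
}

scorer_backward <- function(d_scores, cache, params) {
  dRd <- outer(d_scores, params$w_out)
  dw_out <- drop(crossprod(cache$Rd, d_scores))
  db_out <- sum(d_scores)
  dR <- if (is.null(cache$mask)) dRd else dRd * cache$mask
  dln_out <- dR * (cache$ln_out > 0)
  lnb <- layer_norm_backward(dln_out, cache$ln, params$gamma)
  dA <- lnb$dx
  dW <- crossprod(cache$X, dA)
  db <- colSums(dA)
  dX <- dA %*% t(params$W)
  d <- cache$d
  dZ <- matrix(0, cache$n_nodes, d)
  add1 <- rowsum(dX[, seq_len(d), drop = FALSE],
                 group = cache$pairs[, 1L])
  dZ[as.integer(rownames(add1)), ] <- dZ[as.integer(rownames(add1)), ] + add1
  add2 <- rowsum(dX[, d + seq_len(d), drop = FALSE],
                 group = cache$pairs[, 2L])
  dZ[as.integer(rownames(add2)), ] <- dZ[as.integer(rownames(add2)), ] + add2
  list(d_embeddings = dZ,
       grads = list(W = dW, b = db, gamma = lnb$dgamma, beta = lnb$dbeta,
                    w_out = dw_out, b_out = db_out))
}

#' Focal loss for imbalanced edge classification
#'
#' Mean over the batch of `-alpha_t (1 - p_t)^gamma log(p_t)` where
#' `p = sigmoid(score)`, `p_t = p` for positives and `1 - p` for negatives,
#' and `alpha` weighs positives (negatives get `1 - alpha`). Probabilities
#' are clipped to `[1e-7, 1 - 1e-7]` before the logarithm. With `gamma = 0`,
#' `alpha = 0.5` this is half the binary cross-entropy.
#'
#' @param scores Raw classifier scores.
#' @param labels Binary labels (0/1).
#' @param alpha Positive-class weight in `[0, 1]`.
#' @param gamma Focusing exponent (>= 0).
#' @return Scalar loss.
#' @export
focal_loss <- function(scores, labels, alpha = 0.25, gamma = 2.0) {
  focal_loss_forward(scores, labels, alpha, gamma)$loss
}

focal_loss_forward <- function(scores, labels, alpha, gamma) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  p <- 1 / (1 + exp(-scores))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  pt <- ifelse(labels == 1, p, 1 - p)
  at <- ifelse(labels == 1, alpha, 1 - alpha)
  terms <- -at * (1 - pt)^gamma * log(pt)
  list(loss = mean(terms), p = p, pt = pt, at = at)
}

# dLoss/dscore; derived from d/dp of the focal term times p(1-p).
focal_loss_grad <- function(scores, labels, alpha, gamma) {
  fw <- focal_loss_forward(scores, labels, alpha, gamma)
  p <- fw$p; pt <- fw$pt; at <- fw$at
  # dL/dpt for one term
  dpt <- if (gamma == 0) {
    -at / pt
  } else {
    at * (gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt)
  }
  # pt = p for positives (dpt/dp = 1), 1 - p for negatives (dpt/dp = -1)
  dp <- ifelse(labels == 1, dpt, -dpt)
  ds <- dp * p * (1 - p)
  ds / length(scores)
}

#' Map a raw score to an interaction probability
#'
#' Sigmoid with saturation guard: scores beyond +/-30 are clamped so the
#' probability stays strictly inside (0, 1). Monotone, so rankings by raw
#' score and by probability coincide.
#'
#' @param score Numeric vector of raw scores.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(score) sigmoid(score)
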