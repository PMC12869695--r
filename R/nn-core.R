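# Minimal dense neural-network machinery in base R matrix code: parameter
# initialization, forward/backward passes for dense and scaled-dot-product
# attention layers, and the Adam optimizer. All gradients are hand-derived
# and validated against finite differences in the test suite.

nn_init_dense <- function(n_in, n_out, scale = sqrt(2 / n_in), zero = FALSE) {
  W <- if (zero) matrix(0, n_in, n_out) else
    matrix(rnorm(n_in * n_out, 0, scale), n_in, n_out)
  list(W = W, b = rep(0, n_out))
}

nn_dense_forward <- function(X, layer) {
  X %*% layer$W + rep(layer$b, each = nrow(X))
}

# Returns gradients for the layer plus the gradient w.r.t. the input.
nn_dense_backward <- function(X, layer, dY) {
  list(dW = crossprod(X, dY),
       db = colSums(dY),
       dX = tcrossprod(dY, layer$W))
}

nn_relu <- function(X) pmax(X, 0)
nn_relu_backward <- function(X, dY) dY * (X > 0)

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- scaled dot-product attention over a short token sequence ----------- #

#' Attention block parameters
#'
#' Learned linear maps Q, K, V from token width `d` to head width `d_k`,
#' plus the output projection back to `d`.
#'
#' @param d Token width.
#' @param d_k Head width (default `d`).
#' @param seed Integer seed for the initialization (`NULL` uses the current
#'   RNG state).
#' @param identity If `TRUE`, initialize Q, K, V and the output projection
#'   as identity maps (requires `d == d_k`).
#' @return An `attention_block` parameter list (`Wq`, `Wk`, `Wv`, `Wo`).
#' @export
attention_block <- function(d, d_k = d, seed = NULL, identity = FALSE) {
  make <- function() {
    if (identity) {
      stopifnot(d == d_k)
      list(Wq = diag(d), Wk = diag(d), Wv = diag(d), Wo = diag(d))
    } else {
      sc <- 1 / sqrt(d)
      list(Wq = matrix(rnorm(d * d_k, 0, sc), d, d_k),
           Wk = matrix(rnorm(d * d_k, 0, sc), d, d_k),
           Wv = matrix(rnorm(d * d_k, 0, sc), d, d_k),
           Wo = matrix(rnorm(d_k * d, 0, 1 / sqrt(d_k)), d_k, d))
    }
  }
  blk <- if (is.null(seed)) make() else with_seed(seed, make())
  structure(blk, class = "attention_block", d = d, d_k = d_k)
}

# Forward pass over a list of T token matrices (each batch x d). Attention
# weights are computed row-wise over the T tokens per batch element:
# A = softmax(Q X (K X)^T / sqrt(d_k)); output token i = [sum_j A_ij V_j] Wo.
# mask_self = TRUE masks each token's attention to itself (cross-modality
# attention only). Returns outputs plus a cache for the backward pass.
nn_attention_forward <- function(tokens, blk, mask_self = FALSE) {
  Tn <- length(tokens)
  B <- nrow(tokens[[1]])
  d_k <- ncol(blk$Wq)
  Q <- lapply(tokens, function(X) X %*% blk$Wq)
  K <- lapply(tokens, function(X) X %*% blk$Wk)
  V <- lapply(tokens, function(X) X %*% blk$Wv)

  scores <- array(0, c(B, Tn, Tn))
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    scores[, i, j] <- rowSums(Q[[i]] * K[[j]]) / sqrt(d_k)
  }
  if (mask_self && Tn > 1) {
    for (i in seq_len(Tn)) scores[, i, i] <- -Inf
  }
  A <- array(0, c(B, Tn, Tn))
  for (i in seq_len(Tn)) {
    s <- scores[, i, , drop = FALSE]
    dim(s) <- c(B, Tn)
    s <- s - apply(s, 1, max)
    e <- exp(s)
    A[, i, ] <- e / rowSums(e)
  }
  AV <- vector("list", Tn)   # batch x d_k per output token
  for (i in seq_len(Tn)) {
    acc <- matrix(0, B, d_k)
    for (j in seq_len(Tn)) acc <- acc + A[, i, j] * V[[j]]
    AV[[i]] <- acc
  }
  out <- lapply(AV, function(M) M %*% blk$Wo)
  list(out = out, cache = list(tokens = tokens, Q = Q, K = K, V = V,
                               A = A, AV = AV, blk = blk, d_k = d_k))
}

# Backward pass; dOut is a list of batch x d gradients, one per token.
nn_attention_backward <- function(cache, dOut) {
  tokens <- cache$tokens; Q <- cache$Q; K <- cache$K; V <- cache$V
  A <- cache$A; blk <- cache$blk; d_k <- cache$d_k
  Tn <- length(tokens); B <- nrow(tokens[[1]])

  dWo <- matrix(0, nrow(blk$Wo), ncol(blk$Wo))
  dAV <- vector("list", Tn)
  for (i in seq_len(Tn)) {
    dWo <- dWo + crossprod(cache$AV[[i]], dOut[[i]])
    dAV[[i]] <- tcrossprod(dOut[[i]], blk$Wo)
  }

  dV <- lapply(seq_len(Tn), function(j) matrix(0, B, d_k))
  dA <- array(0, c(B, Tn, Tn))
  for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
    dA[, i, j] <- rowSums(dAV[[i]] * V[[j]])
    dV[[j]] <- dV[[j]] + A[, i, j] * dAV[[i]]
  }

  dS <- array(0, c(B, Tn, Tn))
  for (i in seq_len(Tn)) {
    Ai <- A[, i, , drop = FALSE]; dim(Ai) <- c(B, Tn)
    dAi <- dA[, i, , drop = FALSE]; dim(dAi) <- c(B, Tn)
    inner <- rowSums(Ai * dAi)
    dS[, i, ] <- Ai * (dAi - inner)
  }

  dQ <- vector("list", Tn); dK <- vector("list", Tn)
  for (i in seq_len(Tn)) {
    accQ <- matrix(0, B, d_k)
    for (j in seq_len(Tn)) accQ <- accQ + dS[, i, j] * K[[j]]
    dQ[[i]] <- accQ / sqrt(d_k)
  }
  for (j in seq_len(Tn)) {
    accK <- matrix(0, B, d_k)
    for (i in seq_len(Tn)) accK <- accK + dS[, i, j] * Q[[i]]
    dK[[j]] <- accK / sqrt(d_k)
  }

  dWq <- matrix(0, nrow(blk$Wq), ncol(blk$Wq))
  dWk <- dWq; dWv <- dWq
  dTokens <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    dWq <- dWq + crossprod(tokens[[t]], dQ[[t]])
    dWk <- dWk + crossprod(tokens[[t]], dK[[t]])
    dWv <- dWv + crossprod(tokens[[t]], dV[[t]])
    dTokens[[t]] <- tcrossprod(dQ[[t]], blk$Wq) +
      tcrossprod(dK[[t]], blk$Wk) + tcrossprod(dV[[t]], blk$Wv)
  }
  list(grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo),
       dTokens = dTokens)
}

# ---- Adam ---------------------------------------------------------------- #

# Parameters and gradients are nested named lists of matrices/vectors with
# identical structure; state is created lazily.
adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in names(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Elementwise sum of two same-shaped nested gradient lists.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) return(purrr::map2(a, b, grad_add))
  a + b
}
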