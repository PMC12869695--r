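# Expression autoencoder: symmetric encoder/decoder pre-trained to compress
# marker-gene expression into noise-resistant low-dimensional embeddings.

#' Pre-train the expression autoencoder
#'
#' Symmetric architecture `G -> hidden -> bottleneck -> hidden -> G` (rectifier
#' activations on the hidden layers, linear bottleneck and output) trained to
#' minimize mean-squared reconstruction error with input-layer dropout.
#' A 10% held-out split is evaluated after every epoch; the encoder returned
#' is the one from the epoch with the best held-out loss, together with the
#' full per-epoch loss log. Fully reproducible from the seed.
#'
#' @param expression Sample x gene matrix on the log2(TPM+1) scale (>= 10
#'   samples).
#' @param hidden Hidden layer width; default scales the classic 1024-wide
#'   layer proportionally to the gene count (bounded below at 8).
#' @param bottleneck Embedding width (default 256).
#' @param dropout Input dropout rate (default 0.2).
#' @param epochs Training epochs (default 100).
#' @param lr Adam step size.
#' @param batch_size Mini-batch size; must not exceed the sample count.
#' @param val_frac Held-out fraction (default 0.1).
#' @param seed Integer seed.
#' @return An `expression_encoder` object: weights, gene order, and the
#'   training log (tibble epoch / train_mse / val_mse).
#' @export
pretrain_autoencoder <- function(expression, hidden = NULL, bottleneck = 256,
                                 dropout = 0.2, epochs = 100, lr = 1e-3,
                                 batch_size = 8, val_frac = 0.1, seed = 1) {
  n <- nrow(expression); G <- ncol(expression)
  if (n < 10) {
    stopf("combisyn_config_error",
          "autoencoder pre-training needs >= 10 samples, got %d", n)
  }
  if (batch_size > n) {
    stopf("combisyn_config_error",
          "batch_size (%d) exceeds the sample count (%d)", batch_size, n)
  }
  hidden <- hidden %||% max(8L, round(1024 * G / 4079))
  bottleneck <- min(bottleneck, G)

  with_seed(derive_seed(seed, "autoencoder"), {
    params <- list(
      enc1 = nn_init_dense(G, hidden),
      enc2 = nn_init_dense(hidden, bottleneck),
      dec1 = nn_init_dense(bottleneck, hidden),
      dec2 = nn_init_dense(hidden, G)
    )
    n_val <- max(1L, round(val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- expression[tr_idx, , drop = FALSE]
    Xval <- expression[val_idx, , drop = FALSE]

    state <- adam_init(params)
    log <- vector("list", epochs)
    best <- list(val = Inf, params = params, epoch = 0L)

    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(Xtr))
      tr_loss <- 0; n_b <- 0
      for (start in seq(1, nrow(Xtr), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, nrow(Xtr))]
        X <- Xtr[idx, , drop = FALSE]
        Xin <- X
        if (dropout > 0) {
          mask <- matrix(runif(length(X)) >= dropout, nrow(X), ncol(X))
          Xin <- X * mask / (1 - dropout)
        }
        fw <- ae_forward(Xin, params)
        err <- fw$Xhat - X
        loss <- mean(err^2)
        dXhat <- 2 * err / length(err)
        grads <- ae_backward(Xin, fw, params, dXhat)
        st <- adam_step(params, grads, state, lr = lr)
        params <- st$params; state <- st$state
        tr_loss <- tr_loss + loss; n_b <- n_b + 1
      }
      val_mse <- mean((ae_forward(Xval, params)$Xhat - Xval)^2)
      log[[ep]] <- tibble(epoch = ep, train_mse = tr_loss / n_b,
                          val_mse = val_mse)
      if (val_mse < best$val) best <- list(val = val_mse, params = params,
                                           epoch = ep)
    }
    structure(
      list(params = best$params, genes = colnames(expression),
           hidden = hidden, bottleneck = bottleneck, dropout = dropout,
           best_epoch = best$epoch, seed = seed,
           log = bind_rows(log)),
      class = "expression_encoder")
  })
}

ae_forward <- function(X, params) {
  h1 <- nn_dense_forward(X, params$enc1); a1 <- nn_relu(h1)
  z <- nn_dense_forward(a1, params$enc2)
  h3 <- nn_dense_forward(z, params$dec1); a3 <- nn_relu(h3)
  Xhat <- nn_dense_forward(a3, params$dec2)
  list(h1 = h1, a1 = a1, z = z, h3 = h3, a3 = a3, Xhat = Xhat)
}

ae_backward <- function(X, fw, params, dXhat) {
  b4 <- nn_dense_backward(fw$a3, params$dec2, dXhat)
  da3 <- nn_relu_backward(fw$h3, b4$dX)
  b3 <- nn_dense_backward(fw$z, params$dec1, da3)
  b2 <- nn_dense_backward(fw$a1, params$enc2, b3$dX)
  da1 <- nn_relu_backward(fw$h1, b2$dX)
  b1 <- nn_dense_backward(X, params$enc1, da1)
  list(enc1 = list(W = b1$dW, b = b1$db), enc2 = list(W = b2$dW, b = b2$db),
       dec1 = list(W = b3$dW, b = b3$db), dec2 = list(W = b4$dW, b = b4$db))
}

#' Encode expression profiles with a pre-trained autoencoder
#'
#' Deterministic at inference: dropout is disabled.
#'
#' @param encoder An `expression_encoder` from [pretrain_autoencoder()].
#' @param profile A numeric vector over the encoder's genes, or a sample x
#'   gene matrix with matching column order.
#' @return A matrix (samples x bottleneck) of embeddings.
#' @export
encode_sample <- function(encoder, profile) {
  X <- if (is.null(dim(profile))) matrix(profile, nrow = 1) else as.matrix(profile)
  if (ncol(X) != length(encoder$genes)) {
    stopf("combisyn_schema_error",
          "profile has %d genes but the encoder expects %d",
          ncol(X), length(encoder$genes))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), encoder$genes)) {
    stopf("combisyn_schema_error",
          "profile gene order does not match the encoder's gene order")
  }
  a1 <- nn_relu(nn_dense_forward(X, encoder$params$enc1))
  nn_dense_forward(a1, encoder$params$enc2)
}

#' @export
print.expression_encoder <- function(x, ...) {
  cat(sprintf("<expression_encoder> %d genes -> %d -> %d (best epoch %d, val MSE %.4g)\n",
              length(x$genes), x$hidden, x$bottleneck, x$best_epoch,
              min(x$log$val_mse)))
  invisible(x)
}

#' @rdname pretrain_autoencoder
#' @param x An `expression_encoder`.
#' @param ... Unused.
#' @export
tidy.expression_encoder <- function(x, ...) x$log

#' @rdname pretrain_autoencoder
#' @export
glance.expression_encoder <- function(x, ...) {
  tibble(genes = length(x$genes), hidden = x$hidden,
         bottleneck = x$bottleneck, best_epoch = x$best_epoch,
         best_val_mse = min(x$log$val_mse))
}
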