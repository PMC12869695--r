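# The attention-fusion synergy predictor: per-branch encoders project the
# two drugs' chemistry, the two drugs' propagated target vectors and the
# sample profile into a common token width; a scaled dot-product attention
# layer lets the five tokens exchange information; the fused tokens are
# flattened into a multilayer perceptron head trained with binary
# cross-entropy; inference symmetrizes over the drug-pair order.

#' Model configuration
#'
#' @param d Common token width (default 256; desk-scale experiments in the
#'   vignette use 32).
#' @param d_k Attention head width (default `d`).
#' @param chem_hidden Hidden width of the fingerprint encoder.
#' @param dti_channels,dti_kernel,dti_stride 1-D convolution geometry of the
#'   target-vector encoder.
#' @param dti_compress Width of the target embedding layer (default 500;
#'   automatically capped at the flattened convolution width).
#' @param head_widths Hidden widths of the MLP head.
#' @param lr Adam step size.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs (the returned weights are from the
#'   best-validation epoch).
#' @param use_chem `FALSE` drops the two chemistry tokens entirely (the
#'   chemical-ablation variant; token count falls to 3).
#' @param sample_input `"expression"` or `"mutation"` (the mutation variant
#'   keeps the same architecture but feeds the binary mutation profile).
#' @param mask_self If `TRUE`, tokens attend only to the other modalities.
#' @param freeze_sample_encoder Keep the pre-trained expression encoder
#'   weights fixed during training.
#' @param seed Integer seed governing initialization, shuffling, and the
#'   validation split.
#' @return A `synergy_net_config` list.
#' @export
synergy_net_config <- function(d = 256, d_k = d, chem_hidden = 64,
                               dti_channels = 8, dti_kernel = 8,
                               dti_stride = 4, dti_compress = 500,
                               head_widths = c(512, 128),
                               lr = 1e-3, batch_size = 64, epochs = 30,
                               use_chem = TRUE,
                               sample_input = c("expression", "mutation"),
                               mask_self = FALSE,
                               freeze_sample_encoder = FALSE,
                               seed = 1) {
  structure(list(
    d = d, d_k = d_k, chem_hidden = chem_hidden,
    dti_channels = dti_channels, dti_kernel = dti_kernel,
    dti_stride = dti_stride, dti_compress = dti_compress,
    head_widths = head_widths, lr = lr, batch_size = batch_size,
    epochs = epochs, use_chem = isTRUE(use_chem),
    sample_input = match.arg(sample_input),
    mask_self = isTRUE(mask_self),
    freeze_sample_encoder = isTRUE(freeze_sample_encoder),
    seed = as.integer(seed)
  ), class = "synergy_net_config")
}

#' Binary cross-entropy loss
#'
#' `-(1/M) * sum(p*log(phat) + (1-p)*log(1-phat))` with predictions clipped
#' to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(labels, probs) {
  if (!length(labels)) {
    stopf("combisyn_value_error", "empty batch")
  }
  p <- clip(probs, 1e-7, 1 - 1e-7)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- fusion state + user-facing attention ------------------------------- #

#' Fusion state: aligned branch embeddings entering the attention layer
#'
#' @param tokens List of equal-width embedding matrices (batch x d), in the
#'   order chem_a, chem_b, dti_a, dti_b, sample (or a subset when branches
#'   are disabled).
#' @return A `fusion_state` object.
#' @export
fusion_state <- function(tokens) {
  if (is.matrix(tokens)) tokens <- list(tokens)
  widths <- vapply(tokens, ncol, integer(1))
  if (length(unique(widths)) != 1) {
    stopf("combisyn_value_error", "fusion tokens must share a common width")
  }
  if (!all(vapply(tokens, function(t) all(is.finite(t)), logical(1)))) {
    stopf("combisyn_numeric_error", "fusion tokens contain non-finite values")
  }
  structure(list(tokens = tokens, d = widths[1]), class = "fusion_state")
}

#' Cross-modal attention fusion
#'
#' Treats the tokens as a length-T sequence and applies scaled dot-product
#' self-attention: `A = softmax(Q X (K X)^T / sqrt(d_k))` row-wise over the
#' tokens, returning one updated token per input token (`A (V X)` followed by
#' a linear map back to width d).
#'
#' @param state A [fusion_state()].
#' @param block An [attention_block()] of matching width.
#' @param mask_self If `TRUE`, each token attends only to the other tokens.
#' @return A `fusion_state` of updated tokens.
#' @export
attention_fuse <- function(state, block, mask_self = FALSE) {
  stopifnot(inherits(state, "fusion_state"), inherits(block, "attention_block"))
  fw <- nn_attention_forward(state$tokens, block, mask_self = mask_self)
  fusion_state(fw$out)
}

# ---- initialization ------------------------------------------------------ #

conv_windows <- function(G, kernel, stride) {
  starts <- seq(1, G - kernel + 1, by = stride)
  t(vapply(starts, function(s) s:(s + kernel - 1), integer(kernel)))
}

init_synergy_net <- function(cfg, features) {
  n_bits <- ncol(features$fingerprints)
  G_t <- ncol(features$targets)
  sample_mat <- sample_input_matrix(cfg, features)
  G_s <- ncol(sample_mat)
  enc <- features$encoder

  kernel <- min(cfg$dti_kernel, G_t)
  win <- conv_windows(G_t, kernel, cfg$dti_stride)
  flat <- nrow(win) * cfg$dti_channels
  compress <- min(cfg$dti_compress, flat)

  with_seed(derive_seed(cfg$seed, "init"), {
    params <- list()
    if (cfg$use_chem) {
      params$chem1 <- nn_init_dense(n_bits, cfg$chem_hidden)
      params$chem2 <- nn_init_dense(cfg$chem_hidden, cfg$d)
    }
    params$dti_conv <- nn_init_dense(kernel, cfg$dti_channels)
    params$dti_fc1 <- nn_init_dense(flat, compress)
    params$dti_fc2 <- nn_init_dense(compress, cfg$d)

    if (cfg$sample_input == "expression" && !is.null(enc)) {
      params$samp1 <- enc$params$enc1
      params$samp2 <- enc$params$enc2
      samp_z <- enc$bottleneck
    } else {
      samp_h <- max(16L, min(64L, G_s))
      samp_z <- max(8L, min(32L, samp_h))
      params$samp1 <- nn_init_dense(G_s, samp_h)
      params$samp2 <- nn_init_dense(samp_h, samp_z)
    }
    params$samp_proj <- nn_init_dense(samp_z, cfg$d)

    params$attn <- unclass(attention_block(cfg$d, cfg$d_k))[c("Wq", "Wk", "Wv", "Wo")]

    n_tok <- if (cfg$use_chem) 5L else 3L
    widths <- c(n_tok * cfg$d, cfg$head_widths, 1L)
    head <- vector("list", length(widths) - 1)
    for (i in seq_along(head)) {
      head[[i]] <- nn_init_dense(widths[i], widths[i + 1],
                                 zero = (i == length(head)))
    }
    names(head) <- paste0("head", seq_along(head))
    params <- c(params, head)

    list(params = params, win = win, kernel = kernel, flat = flat,
         compress = compress, n_tok = n_tok,
         n_head = length(head))
  })
}

sample_input_matrix <- function(cfg, features) {
  if (cfg$sample_input == "mutation") {
    if (is.null(features$mutation)) {
      stopf("combisyn_config_error",
            "sample_input = 'mutation' but the feature set has no mutation matrix")
    }
    features$mutation
  } else {
    features$expression
  }
}

# ---- forward / backward -------------------------------------------------- #

# Per-entity branch encodings for all drugs and all samples (cached for the
# backward pass). Entity-level computation keeps the cost independent of the
# batch size: batches index into these matrices.
net_encode_entities <- function(params, cfg, geom, features, norm) {
  out <- list()
  if (cfg$use_chem) {
    Xc <- features$fingerprints
    h <- nn_dense_forward(Xc, params$chem1); a <- nn_relu(h)
    out$chem <- list(X = Xc, h = h, a = a,
                     E = nn_dense_forward(a, params$chem2))
  }
  Xt <- features$targets
  n <- nrow(Xt)
  win <- geom$win; kernel <- geom$kernel
  n_win <- nrow(win)
  Pm <- matrix(0, n * n_win, kernel)
  for (k in seq_len(kernel)) Pm[, k] <- as.vector(Xt[, win[, k]])
  Cv <- nn_dense_forward(Pm, params$dti_conv)
  Ca <- nn_relu(Cv)
  Fm <- Ca; dim(Fm) <- c(n, n_win * cfg$dti_channels)
  f1 <- nn_dense_forward(Fm, params$dti_fc1); f1a <- nn_relu(f1)
  out$dti <- list(Pm = Pm, Cv = Cv, Fm = Fm, f1 = f1, f1a = f1a,
                  E = nn_dense_forward(f1a, params$dti_fc2))

  Xs <- sample_input_matrix(cfg, features)
  if (!is.null(norm)) {
    Xs <- sweep(sweep(Xs, 2, norm$mu), 2, norm$sd, "/")
  }
  h1 <- nn_dense_forward(Xs, params$samp1); a1 <- nn_relu(h1)
  z <- nn_dense_forward(a1, params$samp2)
  out$samp <- list(X = Xs, h1 = h1, a1 = a1, z = z,
                   E = nn_dense_forward(z, params$samp_proj))
  out
}

net_forward_batch <- function(params, cfg, geom, ent, ia, ib, is) {
  tokens <- list()
  if (cfg$use_chem) {
    tokens$chem_a <- ent$chem$E[ia, , drop = FALSE]
    tokens$chem_b <- ent$chem$E[ib, , drop = FALSE]
  }
  tokens$dti_a <- ent$dti$E[ia, , drop = FALSE]
  tokens$dti_b <- ent$dti$E[ib, , drop = FALSE]
  tokens$sample <- ent$samp$E[is, , drop = FALSE]

  at <- nn_attention_forward(unname(tokens), params$attn,
                             mask_self = cfg$mask_self)
  H <- do.call(cbind, at$out)
  acts <- vector("list", geom$n_head)
  A <- H
  Z <- NULL
  for (i in seq_len(geom$n_head)) {
    Z <- nn_dense_forward(A, params[[paste0("head", i)]])
    if (i < geom$n_head) {
      acts[[i]] <- list(input = A, pre = Z)
      A <- nn_relu(Z)
    } else {
      acts[[i]] <- list(input = A)
    }
  }
  logit <- as.vector(Z)
  list(prob = nn_sigmoid(logit), logit = logit,
       cache = list(at = at, acts = acts, H = H))
}

net_backward_batch <- function(params, cfg, geom, ent, ia, ib, is,
                               fw, dlogit) {
  grads <- list()
  # head backward
  dZ <- matrix(dlogit, ncol = 1)
  dH <- NULL
  for (i in rev(seq_len(geom$n_head))) {
    nm <- paste0("head", i)
    bk <- nn_dense_backward(fw$cache$acts[[i]]$input, params[[nm]], dZ)
    grads[[nm]] <- list(W = bk$dW, b = bk$db)
    if (i > 1) dZ <- nn_relu_backward(fw$cache$acts[[i - 1]]$pre, bk$dX)
    else dH <- bk$dX
  }
  # split into token gradients
  d <- cfg$d
  n_tok <- geom$n_tok
  dOut <- lapply(seq_len(n_tok), function(t) {
    dH[, ((t - 1) * d + 1):(t * d), drop = FALSE]
  })
  ab <- nn_attention_backward(fw$cache$at$cache, dOut)
  grads$attn <- ab$grads
  dTok <- ab$dTokens

  accum <- function(dT, idx, n_ent) {
    dE <- matrix(0, n_ent, ncol(dT))
    rs <- rowsum(dT, group = idx)
    dE[as.integer(rownames(rs)), ] <- rs
    dE
  }

  ti <- 1
  if (cfg$use_chem) {
    n_d <- nrow(ent$chem$E)
    dEchem <- accum(dTok[[1]], ia, n_d) + accum(dTok[[2]], ib, n_d)
    b2 <- nn_dense_backward(ent$chem$a, params$chem2, dEchem)
    da <- nn_relu_backward(ent$chem$h, b2$dX)
    b1 <- nn_dense_backward(ent$chem$X, params$chem1, da)
    grads$chem2 <- list(W = b2$dW, b = b2$db)
    grads$chem1 <- list(W = b1$dW, b = b1$db)
    ti <- 3
  }
  n_d <- nrow(ent$dti$E)
  dEdti <- accum(dTok[[ti]], ia, n_d) + accum(dTok[[ti + 1]], ib, n_d)
  b3 <- nn_dense_backward(ent$dti$f1a, params$dti_fc2, dEdti)
  df1 <- nn_relu_backward(ent$dti$f1, b3$dX)
  b2 <- nn_dense_backward(ent$dti$Fm, params$dti_fc1, df1)
  dFm <- b2$dX
  n <- n_d; n_win <- nrow(geom$win); ch <- cfg$dti_channels
  dCa <- dFm; dim(dCa) <- c(n * n_win, ch)
  dCv <- nn_relu_backward(ent$dti$Cv, dCa)
  bC <- nn_dense_backward(ent$dti$Pm, params$dti_conv, dCv)
  grads$dti_fc2 <- list(W = b3$dW, b = b3$db)
  grads$dti_fc1 <- list(W = b2$dW, b = b2$db)
  grads$dti_conv <- list(W = bC$dW, b = bC$db)

  n_s <- nrow(ent$samp$E)
  dEs <- accum(dTok[[ti + 2]], is, n_s)
  bp <- nn_dense_backward(ent$samp$z, params$samp_proj, dEs)
  grads$samp_proj <- list(W = bp$dW, b = bp$db)
  if (!cfg$freeze_sample_encoder) {
    b2s <- nn_dense_backward(ent$samp$a1, params$samp2, bp$dX)
    da1 <- nn_relu_backward(ent$samp$h1, b2s$dX)
    b1s <- nn_dense_backward(ent$samp$X, params$samp1, da1)
    grads$samp2 <- list(W = b2s$dW, b = b2s$db)
    grads$samp1 <- list(W = b1s$dW, b = b1s$db)
  }
  grads
}

# ---- training ------------------------------------------------------------ #

resolve_indices <- function(triplets, features) {
  ia <- match(triplets$drug_a, features$drug_ids)
  ib <- match(triplets$drug_b, features$drug_ids)
  is <- match(triplets$sample_id, features$sample_ids)
  if (anyNA(ia) || anyNA(ib) || anyNA(is)) {
    stopf("combisyn_schema_error",
          "triplets reference drugs or samples absent from the feature set")
  }
  list(ia = ia, ib = ib, is = is)
}

#' Train the attention-fusion synergy model
#'
#' Mini-batch Adam training of all enabled branches on binary synergy labels.
#' Training sees both drug orderings of every triplet (data augmentation);
#' after each epoch the validation AUROC is evaluated (with symmetrized
#' inference) and the returned weights are those of the best-validation
#' epoch. Expression inputs are standardized per gene using statistics of the
#' training-fold samples only. Reproducible from the config seed.
#'
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`, `label`.
#' @param features A [feature_set()].
#' @param cfg A [synergy_net_config()].
#' @param val_ids Optional row indices of `triplets` held out for validation;
#'   by default a random 10% (by the config seed).
#' @return A `synergy_net` object with the training log.
#' @export
train_synergy_net <- function(triplets, features, cfg = synergy_net_config(),
                              val_ids = NULL) {
  n <- nrow(triplets)
  if (is.null(val_ids)) {
    val_ids <- with_seed(derive_seed(cfg$seed, "valsplit"),
                         sample.int(n, max(1L, round(0.1 * n))))
  }
  tr_ids <- setdiff(seq_len(n), val_ids)
  if (!length(tr_ids) || !length(val_ids)) {
    stopf("combisyn_config_error", "empty training or validation set")
  }
  ytr <- triplets$label[tr_ids]
  if (length(unique(ytr)) < 2) {
    stopf("combisyn_config_error",
          "training labels are all one class; cannot fit")
  }

  geom_init <- init_synergy_net(cfg, features)
  params <- geom_init$params
  geom <- geom_init

  # expression standardization from training-fold samples only
  norm <- NULL
  if (cfg$sample_input == "expression") {
    tr_samples <- unique(triplets$sample_id[tr_ids])
    Xs <- features$expression[tr_samples, , drop = FALSE]
    norm <- list(mu = colMeans(Xs), sd = pmax(apply(Xs, 2, sd), 1e-6))
  }

  idx <- resolve_indices(triplets, features)
  aug_ia <- c(idx$ia[tr_ids], idx$ib[tr_ids])
  aug_ib <- c(idx$ib[tr_ids], idx$ia[tr_ids])
  aug_is <- c(idx$is[tr_ids], idx$is[tr_ids])
  aug_y <- c(ytr, ytr)

  via <- idx$ia[val_ids]; vib <- idx$ib[val_ids]; vis <- idx$is[val_ids]
  yval <- triplets$label[val_ids]
  val_two_class <- length(unique(yval)) == 2

  state <- adam_init(params)
  log <- vector("list", cfg$epochs)
  best <- list(auroc = -Inf, params = params, epoch = 0L)

  with_seed(derive_seed(cfg$seed, "train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(aug_y))
      ep_loss <- 0; n_b <- 0
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        rows <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
        ent <- net_encode_entities(params, cfg, geom, features, norm)
        fw <- net_forward_batch(params, cfg, geom, ent,
                                aug_ia[rows], aug_ib[rows], aug_is[rows])
        y <- aug_y[rows]
        ep_loss <- ep_loss + bce_loss(y, fw$prob)
        n_b <- n_b + 1
        dlogit <- (fw$prob - y) / length(y)
        grads <- net_backward_batch(params, cfg, geom, ent,
                                    aug_ia[rows], aug_ib[rows], aug_is[rows],
                                    fw, dlogit)
        upd_names <- names(grads)
        st <- adam_step(params[upd_names], grads[upd_names],
                        adam_substate(state, upd_names), lr = cfg$lr)
        params[upd_names] <- st$params
        state <- adam_merge_state(state, st$state, upd_names)
      }
      ent <- net_encode_entities(params, cfg, geom, features, norm)
      pv <- symmetrized_prob(params, cfg, geom, ent, via, vib, vis)
      val_auroc <- if (val_two_class) metric_auroc(yval, pv) else NA_real_
      log[[ep]] <- tibble(epoch = ep, train_loss = ep_loss / n_b,
                          val_auroc = val_auroc)
      score <- if (val_two_class) val_auroc else -log[[ep]]$train_loss
      if (score > best$auroc) best <- list(auroc = score, params = params,
                                           epoch = ep)
    }
  })

  structure(
    list(params = best$params, cfg = cfg, geom = geom[c("win", "kernel",
         "flat", "compress", "n_tok", "n_head")],
         norm = norm, best_epoch = best$epoch,
         log = bind_rows(log),
         drug_ids = features$drug_ids, sample_ids = features$sample_ids),
    class = "synergy_net")
}

adam_substate <- function(state, nms) {
  list(m = state$m[nms], v = state$v[nms], t = state$t)
}

adam_merge_state <- function(state, sub, nms) {
  state$m[nms] <- sub$m
  state$v[nms] <- sub$v
  state$t <- sub$t
  state
}

symmetrized_prob <- function(params, cfg, geom, ent, ia, ib, is) {
  p1 <- net_forward_batch(params, cfg, geom, ent, ia, ib, is)$prob
  p2 <- net_forward_batch(params, cfg, geom, ent, ib, ia, is)$prob
  (p1 + p2) / 2
}

#' Predict synergy probabilities
#'
#' Inference is symmetrized over the drug-pair order: the reported
#' probability is the mean of both orderings, so `predict(a, b, s)` equals
#' `predict(b, a, s)` exactly. Probabilities above 0.5 are classified as
#' synergistic.
#'
#' @param object A trained `synergy_net`.
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`.
#' @param features The [feature_set()] providing entity inputs.
#' @param ... Unused.
#' @return The `triplets` tibble with columns `prob` and `effective`
#'   (`prob > 0.5`).
#' @export
predict.synergy_net <- function(object, triplets, features, ...) {
  idx <- resolve_indices(triplets, features)
  ent <- net_encode_entities(object$params, object$cfg, object$geom,
                             features, object$norm)
  p <- symmetrized_prob(object$params, object$cfg, object$geom, ent,
                        idx$ia, idx$ib, idx$is)
  out <- as_tibble(triplets)
  out$prob <- p
  out$effective <- p > 0.5
  out
}

#' @export
print.synergy_net <- function(x, ...) {
  cat(sprintf("<synergy_net> %d tokens x d=%d; best epoch %d (val AUROC %.3f)\n",
              x$geom$n_tok, x$cfg$d, x$best_epoch,
              suppressWarnings(max(x$log$val_auroc, na.rm = TRUE))))
  invisible(x)
}

#' @rdname train_synergy_net
#' @param x A `synergy_net`.
#' @param ... Unused.
#' @export
tidy.synergy_net <- function(x, ...) x$log

#' @rdname train_synergy_net
#' @export
glance.synergy_net <- function(x, ...) {
  tibble(tokens = x$geom$n_tok, d = x$cfg$d,
         sample_input = x$cfg$sample_input,
         best_epoch = x$best_epoch,
         best_val_auroc = suppressWarnings(max(x$log$val_auroc, na.rm = TRUE)))
}

#' @rdname train_synergy_net
#' @param object A `synergy_net`.
#' @export
autoplot.synergy_net <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log, -"epoch",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "synergy_net training trajectory",
                  subtitle = "dashed line: selected (best-validation) epoch")
}

#' Train an architecture variant
#'
#' `kind = "mutation"` feeds the sample branch the binary mutation profile
#' (same architecture otherwise); `kind = "ablate_chem"` removes the two
#' chemistry tokens (token count 3); `kind = "expression"` is the reference
#' model.
#'
#' @param kind Variant name.
#' @param triplets,features,cfg,val_ids As in [train_synergy_net()].
#' @return A trained `synergy_net`.
#' @export
train_variant <- function(kind = c("expression", "mutation", "ablate_chem"),
                          triplets, features, cfg = synergy_net_config(),
                          val_ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "mutation") cfg$sample_input <- "mutation"
  if (kind == "ablate_chem") cfg$use_chem <- FALSE
  train_synergy_net(triplets, features, cfg, val_ids = val_ids)
}

#' Ensemble prediction: mean of member probabilities
#'
#' @param models Non-empty list of trained `synergy_net` models sharing the
#'   entity universe.
#' @param triplets,features As in [predict.synergy_net()].
#' @return Tibble with the averaged `prob` and `effective` columns.
#' @export
ensemble_predict <- function(models, triplets, features) {
  if (!length(models)) {
    stopf("combisyn_value_error", "ensemble needs at least one member model")
  }
  probs <- purrr::map(models, function(m) {
    predict(m, triplets, features)$prob
  })
  out <- as_tibble(triplets)
  out$prob <- Reduce(`+`, probs) / length(probs)
  out$effective <- out$prob > 0.5
  out
}

#' Target-embedding inference (the compress layer of the target branch)
#'
#' @param model A trained `synergy_net`.
#' @param rows Matrix of propagated target vectors (drugs x genes), matching
#'   the width the model was trained on.
#' @return Matrix drugs x `dti_compress` of target embeddings.
#' @export
compress_targets <- function(model, rows) {
  if (!inherits(model, "synergy_net")) {
    stopf("combisyn_state_error",
          "compress_targets needs a trained synergy_net")
  }
  rows <- if (is.null(dim(rows))) matrix(rows, nrow = 1) else as.matrix(rows)
  geom <- model$geom
  n <- nrow(rows); n_win <- nrow(geom$win)
  Pm <- matrix(0, n * n_win, geom$kernel)
  for (k in seq_len(geom$kernel)) Pm[, k] <- as.vector(rows[, geom$win[, k]])
  Ca <- nn_relu(nn_dense_forward(Pm, model$params$dti_conv))
  dim(Ca) <- c(n, n_win * model$cfg$dti_channels)
  nn_relu(nn_dense_forward(Ca, model$params$dti_fc1))
}
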