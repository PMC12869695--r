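# Attention fusion, loss arithmetic, and the gradient contract.

random_tokens <- function(Tn = 5, B = 6, d = 8, seed = 1) {
  set.seed(seed)
  lapply(seq_len(Tn), function(i) matrix(rnorm(B * d), B, d))
}

test_that("attention matches the explicit-loop oracle on random states", {
  for (seed in 1:5) {
    toks <- random_tokens(seed = seed)
    blk <- attention_block(8, 8, seed = seed + 100)
    got <- attention_fuse(fusion_state(toks), blk)
    want <- oracle_attention(toks, blk)
    for (i in seq_along(toks)) {
      expect_equal(got$tokens[[i]], want[[i]], tolerance = 1e-6)
    }
  }
})

test_that("a single-token state degenerates to its V projection", {
  toks <- random_tokens(Tn = 1, B = 4, d = 6, seed = 2)
  blk <- attention_block(6, 6, seed = 3)
  got <- attention_fuse(fusion_state(toks), blk)
  expect_equal(got$tokens[[1]], toks[[1]] %*% blk$Wv %*% blk$Wo,
               tolerance = 1e-10)
})

test_that("identity-map attention on orthonormal tokens is a softmax mixture", {
  d <- 4
  toks <- lapply(1:4, function(i) {
    m <- matrix(0, 1, d); m[1, i] <- 1; m
  })
  blk <- attention_block(d, d, identity = TRUE)
  got <- attention_fuse(fusion_state(toks), blk)
  # hand computation: scores are I/sqrt(d); each row softmaxes to
  # e^{1/2}/(e^{1/2}+3) on the self token and 1/(e^{1/2}+3) elsewhere
  a_self <- exp(1 / sqrt(d)) / (exp(1 / sqrt(d)) + (4 - 1))
  a_other <- 1 / (exp(1 / sqrt(d)) + 3)
  for (i in 1:4) {
    want <- rep(a_other, d); want[i] <- a_self
    expect_equal(as.vector(got$tokens[[i]]), want, tolerance = 1e-10)
  }
})

test_that("swapping the two drugs' tokens permutes the outputs identically", {
  toks <- random_tokens(Tn = 5, B = 3, d = 8, seed = 9)
  blk <- attention_block(8, 8, seed = 10)
  out1 <- attention_fuse(fusion_state(toks), blk)$tokens
  swapped <- toks[c(2, 1, 4, 3, 5)]
  out2 <- attention_fuse(fusion_state(swapped), blk)$tokens
  expect_equal(out2, out1[c(2, 1, 4, 3, 5)], tolerance = 1e-10)
})

test_that("masked self-attention zeroes the self weight", {
  toks <- random_tokens(Tn = 3, B = 2, d = 4, seed = 5)
  blk <- attention_block(4, 4, seed = 6)
  fw <- combisyn:::nn_attention_forward(toks, blk, mask_self = TRUE)
  A <- fw$cache$A
  for (i in 1:3) expect_true(all(A[, i, i] == 0))
  expect_equal(apply(A, c(1, 2), sum), matrix(1, 2, 3), tolerance = 1e-12)
})

test_that("fusion states validate widths and finiteness", {
  expect_error(fusion_state(list(matrix(0, 2, 3), matrix(0, 2, 4))),
               "common width")
  expect_error(fusion_state(list(matrix(c(1, NaN), 1, 2))), "non-finite")
})

test_that("binary cross-entropy matches its closed forms", {
  expect_equal(bce_loss(c(0, 1, 1, 0), c(0, 1, 1, 0)), 0, tolerance = 1e-5)
  expect_equal(bce_loss(c(1, 0, 1, 0), rep(0.5, 4)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(1, 0.25), -log(0.25), tolerance = 1e-12)
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(bce_loss(c(1, 0), c(0, 1))))
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("backpropagated gradients match finite differences", {
  w <- small_world()
  fs <- small_features()
  cfg <- synergy_net_config(d = 6, chem_hidden = 8, dti_compress = 8,
                            head_widths = 10, epochs = 1, seed = 2)
  gi <- combisyn:::init_synergy_net(cfg, fs)
  params <- gi$params
  # move every bias off the ReLU kink and give the zero-initialized output
  # layer non-trivial weights so the check probes a generic point
  set.seed(3)
  for (nm in names(params)) {
    if (!is.null(params[[nm]]$b)) {
      params[[nm]]$b <- params[[nm]]$b + rnorm(length(params[[nm]]$b), 0, 0.05)
    }
  }
  last <- paste0("head", gi$n_head)
  params[[last]]$W <- matrix(rnorm(length(params[[last]]$W), 0, 0.3),
                             nrow(params[[last]]$W))
  batch <- small_triplets()[1:4, ]
  idx <- combisyn:::resolve_indices(batch, fs)
  lossfun <- function(p) {
    ent <- combisyn:::net_encode_entities(p, cfg, gi, fs, NULL)
    fw <- combisyn:::net_forward_batch(p, cfg, gi, ent, idx$ia, idx$ib, idx$is)
    bce_loss(batch$label, fw$prob)
  }
  ent <- combisyn:::net_encode_entities(params, cfg, gi, fs, NULL)
  fw <- combisyn:::net_forward_batch(params, cfg, gi, ent,
                                     idx$ia, idx$ib, idx$is)
  grads <- combisyn:::net_backward_batch(params, cfg, gi, ent,
                                         idx$ia, idx$ib, idx$is, fw,
                                         (fw$prob - batch$label) / 4)
  set.seed(11)
  checked <- 0
  while (checked < 10) {
    nm <- sample(names(grads), 1)
    sub <- sample(names(grads[[nm]]), 1)
    k <- sample(length(params[[nm]][[sub]]), 1)
    ana <- grads[[nm]][[sub]][k]
    if (abs(ana) < 1e-8) next   # skip dead units (zero fingerprint columns)
    eps <- 1e-5
    p1 <- params; p1[[nm]][[sub]][k] <- p1[[nm]][[sub]][k] + eps
    p2 <- params; p2[[nm]][[sub]][k] <- p2[[nm]][[sub]][k] - eps
    num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
    expect_lt(abs(num - ana) / max(abs(num), abs(ana)), 1e-4)
    checked <- checked + 1
  }
})

test_that("a zero-initialized head predicts exactly 0.5 and symmetrizes", {
  fs <- small_features()
  cfg <- synergy_net_config(d = 8, chem_hidden = 8, dti_compress = 8,
                            head_widths = 8, epochs = 1, seed = 4)
  gi <- combisyn:::init_synergy_net(cfg, fs)
  model <- structure(
    list(params = gi$params, cfg = cfg,
         geom = gi[c("win", "kernel", "flat", "compress", "n_tok", "n_head")],
         norm = NULL, drug_ids = fs$drug_ids, sample_ids = fs$sample_ids),
    class = "synergy_net")
  tt <- small_triplets()[1:10, ]
  pred <- predict(model, tt, fs)
  expect_equal(pred$prob, rep(0.5, 10))
  expect_false(any(pred$effective))  # 0.5 is NOT classified synergistic
  # symmetrization: swapped pair order gives identical probabilities
  swapped <- tt
  swapped$drug_a <- tt$drug_b; swapped$drug_b <- tt$drug_a
  trained <- train_synergy_net(small_triplets(), fs,
                               synergy_net_config(d = 8, chem_hidden = 8,
                                                  dti_compress = 8,
                                                  head_widths = 8,
                                                  epochs = 2, seed = 5))
  p1 <- predict(trained, tt, fs)$prob
  p2 <- predict(trained, swapped, fs)$prob
  expect_identical(p1, p2)
})
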