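# Independent reference implementations used as oracles. These deliberately
# use explicit loops / direct formulas, not the package's code paths.

# Spreadsheet-style Bliss and HSA excess of a block.
oracle_bliss_hsa <- function(block) {
  ni <- length(block$conc_a); nj <- length(block$conc_b)
  bl <- c(); hs <- c()
  for (i in 2:ni) for (j in 2:nj) {
    ya <- block$response[i, 1]; yb <- block$response[1, j]
    obs <- block$response[i, j]
    bl <- c(bl, obs - (ya + yb - ya * yb / 100))
    hs <- c(hs, obs - max(ya, yb))
  }
  list(bliss = mean(bl), hsa = mean(hs))
}

# Explicit-loop scaled dot-product attention over a list of token matrices.
oracle_attention <- function(tokens, blk) {
  Tn <- length(tokens); B <- nrow(tokens[[1]])
  d_k <- ncol(blk$Wq); d <- ncol(blk$Wo)
  out <- lapply(tokens, function(x) matrix(0, B, d))
  for (b in seq_len(B)) {
    X <- t(vapply(tokens, function(tk) tk[b, ], numeric(ncol(tokens[[1]]))))
    Q <- X %*% blk$Wq; K <- X %*% blk$Wk; V <- X %*% blk$Wv
    S <- matrix(0, Tn, Tn)
    for (i in seq_len(Tn)) for (j in seq_len(Tn)) {
      S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    }
    A <- matrix(0, Tn, Tn)
    for (i in seq_len(Tn)) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- e / sum(e)
    }
    O <- (A %*% V) %*% blk$Wo
    for (i in seq_len(Tn)) out[[i]][b, ] <- O[i, ]
  }
  out
}

# Brute-force AUROC by pair counting.
oracle_auroc <- function(labels, scores) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Direct linear solve of the restart-propagation fixed point.
oracle_rwr <- function(F0, S, alpha) {
  n <- ncol(S)
  t(solve(diag(n) - (1 - alpha) * t(S), alpha * t(F0)))
}

# Symmetrically normalized adjacency from an edge tibble over a universe.
oracle_norm_adjacency <- function(ppi, universe) {
  A <- matrix(0, length(universe), length(universe),
              dimnames = list(universe, universe))
  sc <- ppi$score
  if (length(sc) && max(sc) > 1.5) sc <- sc / 1000
  for (k in seq_len(nrow(ppi))) {
    A[ppi$protein_a[k], ppi$protein_b[k]] <- sc[k]
    A[ppi$protein_b[k], ppi$protein_a[k]] <- sc[k]
  }
  d <- rowSums(A)
  i <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- A * outer(i, i)
  iso <- which(d == 0)
  S[cbind(iso, iso)] <- 1   # isolated nodes keep their restart mass
  S
}

# A drug-vs-itself dose-additive (sham) block from an exact Hill curve.
sham_block <- function(e_max, ec50, h, doses = c(0, 10^seq(-1, 1, by = 0.5))) {
  y <- function(d) ifelse(d <= 0, 0, e_max * d^h / (ec50^h + d^h))
  resp <- outer(doses, doses, function(d1, d2) y(d1 + d2))
  dose_block("X", "Y", "S", doses, doses, resp)
}

# A Bliss-of-two-Hill-monotherapies zero-interaction block.
bliss_null_block <- function(parsA, parsB,
                             doses = c(0, 10^seq(-1, 1, by = 0.5)),
                             shift = 0) {
  y <- function(d, p) ifelse(d <= 0, 0, p[1] * d^p[3] / (p[2]^p[3] + d^p[3]))
  ya <- y(doses, parsA); yb <- y(doses, parsB)
  resp <- outer(ya, yb, function(u, v) u + v - u * v / 100)
  resp[, 1] <- ya; resp[1, ] <- yb
  if (shift != 0) {
    resp[2:length(doses), 2:length(doses)] <-
      resp[2:length(doses), 2:length(doses)] + shift
  }
  dose_block("A", "B", "S", doses, doses, resp)
}

# Construct a fingerprint object directly from bit positions (for split and
# matching tests that need exact control over similarities).
fp_from_bits <- function(bits, n_bits = 64) {
  combisyn:::new_morgan_fp(sort(unique(bits)), n_bits)
}
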