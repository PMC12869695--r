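# Affinity propagation clustering (exemplar-based message passing).
# Implemented here because no installed package provides it; the standard
# responsibility/availability updates with damping.

#' Affinity propagation clustering
#'
#' Message-passing clustering on a similarity matrix; the number of clusters
#' emerges from the `preference` (self-similarity) parameter, set to the
#' median off-diagonal similarity by default.
#'
#' @param S Square similarity matrix (larger = more similar).
#' @param preference Self-similarity; default median of the off-diagonal.
#' @param damping Damping factor in `[0.5, 1)` (default 0.9).
#' @param max_iter Iteration cap (default 1000).
#' @param conv_iter Stop when exemplars are unchanged this many iterations.
#' @param seed Unused by the deterministic updates; recorded for provenance.
#' @return List: `labels` (exemplar index per point), `exemplars`,
#'   `converged`, `iterations`.
#' @export
affinity_propagation <- function(S, preference = NULL, damping = 0.9,
                                 max_iter = 1000, conv_iter = 100,
                                 seed = NULL) {
  n <- nrow(S)
  stopifnot(n == ncol(S))
  S <- as.matrix(S)
  offdiag <- S[row(S) != col(S)]
  diag(S) <- preference %||% median(offdiag)
  # tiny deterministic jitter breaks ties without an RNG draw
  S <- S + outer(seq_len(n), seq_len(n), function(i, j) (i * n + j) * 1e-12)

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last_ex <- NULL; stable <- 0; converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(pmin(0, rep(colsum, each = n) - Rp), n, n)
    diag(Anew) <- colsum - diag(Rp)
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A + R) > 0)
    if (identical(ex, last_ex) && length(ex) > 0) {
      stable <- stable + 1
      if (stable >= conv_iter) { converged <- TRUE; break }
    } else {
      stable <- 0
    }
    last_ex <- ex
  }
  ex <- which(diag(A + R) > 0)
  if (!length(ex)) ex <- which.max(diag(A + R))
  labels <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  labels[ex] <- ex
  list(labels = labels, exemplars = ex, converged = converged,
       iterations = it)
}
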