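# Drug-target interaction matrices and network propagation (random walk with
# restart) over the protein-protein interaction network.

#' Build a binary drug x gene target matrix
#'
#' @param annotations Tibble with columns `drug_id` and `gene`.
#' @param universe Character vector of target genes (matrix columns).
#' @return Binary matrix drugs x genes with attribute `n_ignored` counting
#'   annotations to genes outside the universe (also raised as a warning).
#' @export
build_dti_matrix <- function(annotations, universe) {
  if (!length(universe)) {
    stopf("combisyn_config_error", "target universe is empty")
  }
  drugs <- sort(unique(annotations$drug_id))
  m <- matrix(0, length(drugs), length(universe),
              dimnames = list(drugs, universe))
  known <- annotations$gene %in% universe
  n_ignored <- sum(!known)
  if (n_ignored > 0) {
    warn(sprintf("%d annotation(s) to genes outside the universe ignored",
                 n_ignored))
  }
  ann <- annotations[known, , drop = FALSE]
  m[cbind(ann$drug_id, ann$gene)] <- 1
  attr(m, "n_ignored") <- n_ignored
  m
}

# Weighted adjacency matrix over `universe` from a PPI edge tibble
# (protein_a, protein_b, score); scores on a 0-1000 file scale are
# rescaled to 0-1. Edges to nodes outside the universe are dropped.
ppi_adjacency <- function(ppi, universe) {
  score <- ppi$score %||% rep(1, nrow(ppi))
  if (length(score) && max(score) > 1.5) score <- score / 1000
  inside <- ppi$protein_a %in% universe & ppi$protein_b %in% universe
  n_out <- sum(!inside)
  if (n_out > 0) {
    warn(sprintf("%d PPI edge(s) touch nodes outside the universe; dropped",
                 n_out))
  }
  e <- ppi[inside, , drop = FALSE]
  A <- matrix(0, length(universe), length(universe),
              dimnames = list(universe, universe))
  A[cbind(e$protein_a, e$protein_b)] <- score[inside]
  A[cbind(e$protein_b, e$protein_a)] <- score[inside]
  A
}

#' Propagate drug-target signal over the interactome
#'
#' Random walk with restart: per drug row `F`, iterate
#' `F_{t+1} = alpha * F0 + (1 - alpha) * F_t %*% S` with
#' `S = D^{-1/2} A D^{-1/2}` the symmetrically degree-normalized adjacency,
#' until the maximum absolute change falls below `tol`. The `hub_removed`
#' variant deletes the top 5% highest-degree nodes (ties broken by node id)
#' from the network before normalization; `degree_normalized` additionally
#' down-weights each edge by `1/sqrt(deg_i * deg_j)` before the symmetric
#' normalization.
#'
#' @param dti Binary drug x gene matrix (see [build_dti_matrix()]).
#' @param ppi PPI edge tibble (`protein_a`, `protein_b`, `score`).
#' @param alpha Restart probability in (0, 1]; `alpha = 1` returns the input.
#' @param tol Convergence tolerance on the max-abs update.
#' @param variant One of `"full"`, `"hub_removed"`, `"degree_normalized"`.
#' @param hub_frac Fraction of nodes removed by the hub variant.
#' @param max_iter Iteration cap; exceeding it raises a convergence error.
#' @return Propagated non-negative matrix of the same shape as `dti`, with
#'   attribute `removed_hubs` for the hub variant.
#' @export
rwr_propagate <- function(dti, ppi, alpha = 0.5, tol = 1e-6,
                          variant = c("full", "hub_removed", "degree_normalized"),
                          hub_frac = 0.05, max_iter = 10000) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    stopf("combisyn_value_error", "alpha must be in (0, 1]")
  }
  universe <- colnames(dti)
  A <- ppi_adjacency(ppi, universe)

  removed <- character(0)
  if (variant == "hub_removed") {
    deg <- rowSums(A > 0)
    n_rm <- ceiling(hub_frac * length(universe))
    ord <- order(-deg, universe)
    removed <- universe[ord[seq_len(n_rm)]]
    A[removed, ] <- 0
    A[, removed] <- 0
  }
  if (variant == "degree_normalized") {
    deg <- pmax(rowSums(A), .Machine$double.eps)
    A <- A / sqrt(outer(deg, deg))
  }

  d <- rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  S <- A * outer(inv_sqrt, inv_sqrt)
  # isolated nodes keep their restart mass (self-loop convention), so an
  # edgeless network returns the input for every alpha
  isolated <- which(d == 0)
  S[cbind(isolated, isolated)] <- 1

  F0 <- as.matrix(dti)
  Ft <- F0
  if (alpha < 1) {
    for (iter in seq_len(max_iter)) {
      Fn <- alpha * F0 + (1 - alpha) * (Ft %*% S)
      delta <- max(abs(Fn - Ft))
      Ft <- Fn
      if (delta < tol) break
      if (iter == max_iter) {
        stopf("combisyn_convergence_error",
              "propagation did not converge in %d iterations (residual %.3g)",
              max_iter, delta)
      }
    }
  }
  Ft[Ft < 0] <- 0
  dimnames(Ft) <- dimnames(dti)
  attr(Ft, "removed_hubs") <- removed
  Ft
}
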