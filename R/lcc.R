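# Largest-connected-component permutation test: is the subnetwork induced by
# a target gene set more connected than random same-size gene sets?

#' Largest connected component permutation test
#'
#' Computes the size of the largest connected component (LCC) of the PPI
#' subgraph induced by `target_genes`, then compares it against a null of
#' `n_perm` uniformly drawn node sets of the same size. The permutation
#' p-value uses the +1 correction, `p = (1 + #(null >= obs)) / (1 + n_perm)`,
#' so it is never exactly 0. With `exhaustive = TRUE` (feasible only for tiny
#' graphs) all node subsets are enumerated instead and the exact fraction
#' `#(null >= obs) / #subsets` is returned. `degree_matched = TRUE` samples
#' null genes within degree-decile bins of the targets (an option; the
#' default uniform null matches random target-set sampling).
#'
#' @param target_genes Character vector of genes; genes absent from the PPI
#'   are dropped and counted.
#' @param ppi Edge tibble `protein_a`, `protein_b` (scores ignored).
#' @param n_perm Number of null draws (default 10000).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all same-size subsets instead of sampling.
#' @param degree_matched Sample the null within degree-decile bins.
#' @return An `lcc_test`: `observed_lcc`, `null_sizes`, `p_value`,
#'   `n_perm`, `n_dropped`, `seed`.
#' @export
#' @examples
#' ppi <- tibble::tibble(protein_a = c("a", "b"), protein_b = c("b", "c"))
#' lcc_permutation_test(c("a", "b"), ppi, exhaustive = TRUE)$p_value  # 2/3
lcc_permutation_test <- function(target_genes, ppi, n_perm = 10000, seed = 1,
                                 exhaustive = FALSE, degree_matched = FALSE) {
  g <- igraph::graph_from_data_frame(
    ppi[, c("protein_a", "protein_b")], directed = FALSE)
  nodes <- igraph::V(g)$name
  dropped <- setdiff(unique(target_genes), nodes)
  targets <- intersect(unique(target_genes), nodes)
  if (!length(targets)) {
    stopf("combisyn_value_error",
          "no target genes remain after filtering to the PPI nodes")
  }
  if (n_perm < 1) {
    stopf("combisyn_value_error", "n_perm must be >= 1")
  }
  m <- length(targets)
  lcc_size <- function(set) {
    sub <- igraph::induced_subgraph(g, set)
    max(igraph::components(sub)$csize)
  }
  observed <- lcc_size(targets)

  if (exhaustive) {
    subsets <- combn(nodes, m, simplify = FALSE)
    null_sizes <- vapply(subsets, lcc_size, numeric(1))
    p <- mean(null_sizes >= observed)
    n_used <- length(subsets)
  } else {
    deg_bin <- NULL
    if (degree_matched) {
      deg <- igraph::degree(g)
      qs <- unique(quantile(deg, probs = seq(0, 1, 0.1)))
      deg_bin <- cut(deg, breaks = c(-Inf, qs[-1]), labels = FALSE)
      names(deg_bin) <- nodes
    }
    null_sizes <- with_seed(derive_seed(seed, "lcc"), {
      vapply(seq_len(n_perm), function(i) {
        draw <- if (is.null(deg_bin)) {
          sample(nodes, m)
        } else {
          unlist(lapply(split(targets, deg_bin[targets]), function(tg) {
            bin <- deg_bin[tg[1]]
            sample(nodes[deg_bin == bin], length(tg))
          }))
        }
        lcc_size(draw)
      }, numeric(1))
    })
    p <- (1 + sum(null_sizes >= observed)) / (1 + n_perm)
    n_used <- n_perm
  }

  structure(
    list(observed_lcc = observed, null_sizes = null_sizes, p_value = p,
         n_perm = n_used, n_targets = m, n_dropped = length(dropped),
         seed = seed, exhaustive = exhaustive,
         degree_matched = degree_matched),
    class = "lcc_test")
}

#' @export
print.lcc_test <- function(x, ...) {
  cat(sprintf("<lcc_test> observed LCC %d of %d targets; p = %.4g (%s, n = %d)\n",
              x$observed_lcc, x$n_targets, x$p_value,
              if (x$exhaustive) "exhaustive" else "permutation", x$n_perm))
  invisible(x)
}

#' @rdname lcc_permutation_test
#' @param x,object An `lcc_test`.
#' @param ... Unused.
#' @export
tidy.lcc_test <- function(x, ...) {
  tibble(null_lcc = x$null_sizes)
}

#' @rdname lcc_permutation_test
#' @export
glance.lcc_test <- function(x, ...) {
  tibble(observed_lcc = x$observed_lcc, p_value = x$p_value,
         n_perm = x$n_perm, n_targets = x$n_targets,
         n_dropped = x$n_dropped)
}

#' @rdname lcc_permutation_test
#' @export
autoplot.lcc_test <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$null_lcc)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed_lcc, color = "red") +
    ggplot2::labs(x = "largest connected component (null draws)",
                  y = "count",
                  title = sprintf("LCC permutation test (p = %.3g)",
                                  object$p_value)) +
    ggplot2::theme_minimal()
}
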