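# Leakage-free data splitting: leave-combo-out, leave-drug-out,
# leave-sample-out. Every plan carries train / validation / test triplet
# row indices per fold and is checked by assert_split_plan().

new_split_plan <- function(strategy, folds, dropped = integer(0),
                           provenance = list()) {
  structure(list(strategy = strategy, folds = folds, dropped = dropped,
                 provenance = provenance),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("<split_plan> %s: %d fold(s); test sizes %s; %d dropped\n",
              x$strategy, length(x$folds),
              paste(sizes, collapse = "/"), length(x$dropped)))
  invisible(x)
}

# carve a ~10% validation subset out of the nominal training indices
carve_validation <- function(train_idx, seed, stream) {
  if (length(train_idx) < 2) return(list(train = train_idx, val = integer(0)))
  train_idx <- unname(train_idx)
  with_seed(derive_seed(seed, stream), {
    n_val <- max(1L, round(0.1 * length(train_idx)))
    val <- sort(sample(train_idx, n_val))
    list(train = setdiff(train_idx, val), val = val)
  })
}

canonicalize_triplets <- function(triplets) {
  cp <- canonical_pair(triplets$drug_a, triplets$drug_b)
  triplets$drug_a <- cp$a
  triplets$drug_b <- cp$b
  triplets
}

#' Leave-combo-out split
#'
#' Distinct canonical drug pairs are partitioned into `k` folds of
#' near-equal size (within one pair); all triplets of a pair land in the same
#' fold regardless of sample, so no pair spans folds. Within each fold's
#' nominal training set a random 10% of triplets is carved out as validation.
#'
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `split_plan` whose folds hold `train`, `val`, `test` row
#'   indices into `triplets`.
#' @export
split_leave_combo_out <- function(triplets, k = 5, seed = 1) {
  triplets <- canonicalize_triplets(triplets)
  pair_key <- paste(triplets$drug_a, triplets$drug_b, sep = "|")
  pairs <- sort(unique(pair_key))
  if (length(pairs) < k) {
    stopf("combisyn_value_error",
          "only %d distinct drug pairs for %d folds", length(pairs), k)
  }
  fold_of_pair <- with_seed(derive_seed(seed, "combo"), {
    setNames(rep_len(seq_len(k), length(pairs))[sample.int(length(pairs))],
             pairs)
  })
  fold_of_row <- unname(fold_of_pair[pair_key])
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fold_of_row == f)
    nominal <- which(fold_of_row != f)
    c(carve_validation(nominal, seed, paste0("combo_val", f)),
      list(test = test))
  })
  plan <- new_split_plan("leave_combo_out", folds,
                         provenance = list(seed = seed, k = k))
  assert_split_plan(plan, triplets)
  plan
}

#' Leave-drug-out split
#'
#' Drugs are clustered on Tanimoto distance of their fingerprints
#' (agglomerative, average linkage, cut to `k` clusters). A triplet belongs
#' to fold `f` iff BOTH its drugs are in cluster `f`; triplets whose drugs
#' span clusters are dropped from all folds (the only choice that keeps the
#' no-shared-drug guarantee exact) and counted. Each fold's training set is
#' the union of the other folds, so test drugs never occur in training.
#'
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`.
#' @param drug_fingerprints A [fingerprint_library()] covering all drugs.
#' @param k Number of folds / structure clusters.
#' @param seed Integer seed (recorded; clustering itself is deterministic).
#' @return A `split_plan`; dropped row indices in `$dropped`.
#' @export
split_leave_drug_out <- function(triplets, drug_fingerprints, k = 5, seed = 1) {
  triplets <- canonicalize_triplets(triplets)
  drugs <- sort(unique(c(triplets$drug_a, triplets$drug_b)))
  missing <- setdiff(drugs, drug_fingerprints$drug_id)
  if (length(missing)) {
    stopf("combisyn_value_error", "no fingerprint for drug(s): %s",
          paste(missing, collapse = ", "))
  }
  if (length(drugs) < k) {
    stopf("combisyn_value_error", "fewer drugs (%d) than folds (%d)",
          length(drugs), k)
  }
  lib <- drug_fingerprints[match(drugs, drug_fingerprints$drug_id), ]
  n <- length(drugs)
  D <- matrix(0, n, n, dimnames = list(drugs, drugs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- 1 - tanimoto(lib$fp[[i]], lib$fp[[j]])
  }
  if (max(D) < 1e-12) {
    stopf("combisyn_value_error",
          paste("all drugs share an identical structure; structural",
                "clustering is degenerate - use leave-combo-out instead"))
  }
  cl <- cutree(hclust(as.dist(D), method = "average"), k = k)
  fa <- cl[triplets$drug_a]; fb <- cl[triplets$drug_b]
  dropped <- which(fa != fb)
  folds <- lapply(seq_len(k), function(f) {
    test <- which(fa == f & fb == f)
    nominal <- which(fa == fb & fa != f)
    c(carve_validation(nominal, seed, paste0("drug_val", f)),
      list(test = test))
  })
  plan <- new_split_plan("leave_drug_out", folds, dropped = dropped,
                         provenance = list(seed = seed, k = k,
                                           clusters = split(names(cl), cl)))
  assert_split_plan(plan, triplets)
  plan
}

#' Leave-sample-out split
#'
#' Samples are clustered by affinity propagation on the negative squared
#' Euclidean distance over the `top_n` most variable genes; the largest
#' cluster's triplets form the training set (with a 10% validation carve-out)
#' and all remaining samples form the single test set. Falls back to
#' k-medoids with k = 4 (logged in the provenance) if affinity propagation
#' does not converge.
#'
#' @param triplets Tibble with `drug_a`, `drug_b`, `sample_id`.
#' @param expression Samples x genes matrix covering all triplet samples.
#' @param seed Integer seed.
#' @param top_n Number of most-variable genes used (default 1000, capped).
#' @return A single-fold `split_plan`.
#' @export
split_leave_sample_out <- function(triplets, expression, seed = 1,
                                   top_n = 1000) {
  triplets <- canonicalize_triplets(triplets)
  samples <- rownames(expression)
  if (length(samples) < 4) {
    stopf("combisyn_value_error", "leave-sample-out needs >= 4 samples")
  }
  if (!all(triplets$sample_id %in% samples)) {
    stopf("combisyn_value_error", "expression lacks some triplet samples")
  }
  v <- apply(expression, 2, var)
  keep <- order(-v)[seq_len(min(top_n, ncol(expression)))]
  X <- expression[, keep, drop = FALSE]
  S <- -as.matrix(dist(X))^2

  ap <- affinity_propagation(S, seed = seed)
  method <- "affinity_propagation"
  labels <- ap$labels
  if (!ap$converged) {
    method <- "pam_fallback"
    labels <- cluster::pam(dist(X), k = 4, cluster.only = TRUE)
  }
  tab <- table(labels)
  if (length(tab) < 2) {
    stopf("combisyn_value_error",
          paste("sample clustering found a single cluster; no held-out",
                "samples - use another split strategy"))
  }
  big <- names(tab)[order(-as.numeric(tab), names(tab))][1]
  train_samples <- samples[labels == big]
  nominal <- which(triplets$sample_id %in% train_samples)
  test <- which(!triplets$sample_id %in% train_samples)
  folds <- list(c(carve_validation(nominal, seed, "sample_val"),
                  list(test = test)))
  plan <- new_split_plan("leave_sample_out", folds,
                         provenance = list(seed = seed, method = method,
                                           train_samples = train_samples))
  assert_split_plan(plan, triplets)
  plan
}

#' Assert the strategy-specific disjointness guarantees of a plan
#'
#' leave_combo_out: canonical pairs never span a fold's train/test;
#' leave_drug_out: no drug occurs in both a fold's train and test sets;
#' leave_sample_out: no sample occurs in both. Also checks that validation
#' sets are carved from the nominal training triplets and that test folds
#' are pairwise disjoint.
#'
#' @param plan A `split_plan`.
#' @param triplets The triplet tibble the plan indexes.
#' @return Invisibly `TRUE`; aborts with details on violation.
#' @export
assert_split_plan <- function(plan, triplets) {
  triplets <- canonicalize_triplets(triplets)
  pair_key <- paste(triplets$drug_a, triplets$drug_b, sep = "|")
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(all_test)) {
    stopf("combisyn_split_error", "test folds overlap")
  }
  for (f in seq_along(plan$folds)) {
    fold <- plan$folds[[f]]
    if (length(intersect(fold$val, fold$test)) ||
        length(intersect(fold$train, fold$test))) {
      stopf("combisyn_split_error", "fold %d: train/val overlaps test", f)
    }
    tr <- c(fold$train, fold$val)
    if (plan$strategy == "leave_combo_out") {
      if (length(intersect(pair_key[tr], pair_key[fold$test]))) {
        stopf("combisyn_split_error",
              "fold %d: a drug pair spans train and test", f)
      }
    } else if (plan$strategy == "leave_drug_out") {
      dtr <- c(triplets$drug_a[tr], triplets$drug_b[tr])
      dte <- c(triplets$drug_a[fold$test], triplets$drug_b[fold$test])
      if (length(intersect(dtr, dte))) {
        stopf("combisyn_split_error",
              "fold %d: a drug occurs in both train and test", f)
      }
    } else if (plan$strategy == "leave_sample_out") {
      if (length(intersect(triplets$sample_id[tr],
                           triplets$sample_id[fold$test]))) {
        stopf("combisyn_split_error",
              "fold %d: a sample occurs in both train and test", f)
      }
    }
  }
  invisible(TRUE)
}
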