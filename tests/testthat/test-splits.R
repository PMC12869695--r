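# Leakage-free split plans.

toy_triplets <- function() {
  drugs <- sprintf("D%02d", 1:10)
  prs <- t(combn(drugs, 2))
  tibble::tibble(
    drug_a = rep(prs[, 1], each = 3),
    drug_b = rep(prs[, 2], each = 3),
    sample_id = rep(sprintf("S%02d", 1:3), nrow(prs)),
    label = rep(c(0L, 1L), length.out = nrow(prs) * 3))
}

test_that("leave-combo-out balances pairs and keeps them atomic", {
  tt <- toy_triplets()
  plan <- split_leave_combo_out(tt, k = 5, seed = 1)
  key <- paste(tt$drug_a, tt$drug_b)
  sizes <- vapply(plan$folds, function(f) length(unique(key[f$test])),
                  integer(1))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_equal(sum(sizes), 45)
  # every pair's triplets stay in a single fold
  for (f in plan$folds) {
    expect_equal(length(intersect(key[c(f$train, f$val)], key[f$test])), 0)
  }
  # union of test folds is a partition of all triplets
  all_test <- sort(unlist(lapply(plan$folds, `[[`, "test")))
  expect_equal(all_test, seq_len(nrow(tt)))
  # validation is ~10% of the nominal training set
  f1 <- plan$folds[[1]]
  expect_equal(length(f1$val) / (length(f1$val) + length(f1$train)), 0.1,
               tolerance = 0.03)
  expect_error(split_leave_combo_out(tt[1:3, ], k = 5), "distinct drug pairs")
})

test_that("leave-drug-out separates structural families and drops cross-family triplets", {
  # two disjoint scaffolds with exact fingerprint control
  lib <- tibble::tibble(
    drug_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
    smiles = NA_character_,
    fp = list(fp_from_bits(1:10), fp_from_bits(1:9), fp_from_bits(2:10),
              fp_from_bits(30:40), fp_from_bits(30:39), fp_from_bits(31:40)))
  prs <- t(combn(lib$drug_id, 2))
  tt <- tibble::tibble(drug_a = prs[, 1], drug_b = prs[, 2], sample_id = "S1",
                       label = rep_len(c(0L, 1L), nrow(prs)))
  plan <- split_leave_drug_out(tt, lib, k = 2, seed = 1)
  cl <- plan$provenance$clusters
  expect_true(setequal(cl[[1]], c("A1", "A2", "A3")) ||
                setequal(cl[[1]], c("B1", "B2", "B3")))
  # cross-family triplets dropped: 3x3 pairs
  expect_equal(length(plan$dropped), 9)
  for (f in plan$folds) {
    dtr <- unique(c(tt$drug_a[c(f$train, f$val)], tt$drug_b[c(f$train, f$val)]))
    dte <- unique(c(tt$drug_a[f$test], tt$drug_b[f$test]))
    expect_equal(length(intersect(dtr, dte)), 0)
  }
})

test_that("identical structures make leave-drug-out degenerate with advice", {
  lib <- tibble::tibble(drug_id = c("X", "Y", "Z"), smiles = NA,
                        fp = list(fp_from_bits(1:5), fp_from_bits(1:5),
                                  fp_from_bits(1:5)))
  tt <- tibble::tibble(drug_a = c("X", "X"), drug_b = c("Y", "Z"),
                       sample_id = "S1", label = c(0L, 1L))
  expect_error(split_leave_drug_out(tt, lib, k = 2), "leave-combo-out")
})

test_that("leave-drug-out on the synthetic world keeps folds drug-disjoint", {
  tt <- small_triplets()
  lib <- fingerprint_library(small_world()$drugs)
  plan <- split_leave_drug_out(tt, lib, k = 3, seed = 2)
  expect_silent(assert_split_plan(plan, tt))
  expect_s3_class(plan, "split_plan")
})

test_that("leave-sample-out separates constructed expression blobs", {
  set.seed(6)
  n_per <- c(8, 5, 4)
  centers <- rbind(rep(0, 12), rep(6, 12), rep(-6, 12))
  X <- do.call(rbind, lapply(1:3, function(g) {
    sweep(matrix(rnorm(n_per[g] * 12, 0, 0.5), n_per[g], 12), 2,
          centers[g, ], "+")
  }))
  rownames(X) <- sprintf("S%02d", seq_len(nrow(X)))
  colnames(X) <- sprintf("g%02d", 1:12)
  drugs <- c("D1", "D2", "D3")
  tt <- tidyr::expand_grid(drug_a = "D1", drug_b = c("D2", "D3"),
                           sample_id = rownames(X))
  tt$label <- rep_len(c(0L, 1L), nrow(tt))
  plan <- split_leave_sample_out(tt, X, seed = 1)
  f <- plan$folds[[1]]
  str_train <- unique(tt$sample_id[c(f$train, f$val)])
  str_test <- unique(tt$sample_id[f$test])
  expect_equal(length(intersect(str_train, str_test)), 0)
  # the largest blob becomes the training set
  expect_setequal(plan$provenance$train_samples, sprintf("S%02d", 1:8))
  # determinism
  plan2 <- split_leave_sample_out(tt, X, seed = 1)
  expect_identical(plan$folds, plan2$folds)
})

test_that("identical samples leave nothing to hold out", {
  X <- matrix(1, 6, 5, dimnames = list(sprintf("S%d", 1:6),
                                       sprintf("g%d", 1:5)))
  tt <- tibble::tibble(drug_a = "D1", drug_b = "D2",
                       sample_id = rownames(X), label = rep(c(0L, 1L), 3))
  expect_error(split_leave_sample_out(tt, X, seed = 1), "single cluster")
})

test_that("plans are reproducible from their seed", {
  tt <- toy_triplets()
  expect_identical(split_leave_combo_out(tt, k = 4, seed = 9)$folds,
                   split_leave_combo_out(tt, k = 4, seed = 9)$folds)
  expect_false(identical(split_leave_combo_out(tt, k = 4, seed = 9)$folds,
                         split_leave_combo_out(tt, k = 4, seed = 10)$folds))
})
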