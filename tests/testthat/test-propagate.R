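# DTI matrices and random-walk-with-restart propagation.

test_that("build_dti_matrix places annotations and ignores unknown genes", {
  ann <- tibble::tibble(drug_id = c("d1", "d2"), gene = c("g1", "g3"))
  m <- build_dti_matrix(ann, universe = c("g1", "g2", "g3"))
  expect_equal(dim(m), c(2, 3))
  expect_equal(sum(m), 2)
  expect_equal(m["d1", "g1"], 1)
  expect_equal(m["d2", "g3"], 1)
  expect_warning(
    m2 <- build_dti_matrix(tibble::tibble(drug_id = "d1",
                                          gene = c("g1", "nope")),
                           universe = c("g1", "g2")),
    "outside the universe")
  expect_equal(attr(m2, "n_ignored"), 1)
  # duplicate annotations stay binary
  dup <- build_dti_matrix(tibble::tibble(drug_id = c("d1", "d1"),
                                         gene = c("g1", "g1")),
                          universe = c("g1"))
  expect_equal(dup["d1", "g1"], 1)
})

test_that("restart-only and edgeless limits return the input exactly", {
  ann <- tibble::tibble(drug_id = "d1", gene = "g1")
  dti <- build_dti_matrix(ann, universe = paste0("g", 1:4))
  ppi <- tibble::tibble(protein_a = "g1", protein_b = "g2", score = 0.9)
  expect_equal(rwr_propagate(dti, ppi, alpha = 1), dti,
               ignore_attr = TRUE)
  none <- tibble::tibble(protein_a = character(), protein_b = character(),
                         score = numeric())
  expect_equal(rwr_propagate(dti, none, alpha = 0.4), dti,
               ignore_attr = TRUE)
})

test_that("a path graph reproduces the closed-form linear solve", {
  dti <- build_dti_matrix(tibble::tibble(drug_id = "d", gene = "g1"),
                          universe = c("g1", "g2", "g3"))
  ppi <- tibble::tibble(protein_a = c("g1", "g2"), protein_b = c("g2", "g3"),
                        score = c(1, 1))
  S <- oracle_norm_adjacency(ppi, c("g1", "g2", "g3"))
  expected <- oracle_rwr(dti, S, alpha = 0.5)
  got <- rwr_propagate(dti, ppi, alpha = 0.5, tol = 1e-10)
  expect_equal(unclass(got), expected, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("propagation equals the direct solve on random graphs up to 50 nodes", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    genes <- sprintf("g%02d", 1:n)
    prs <- t(combn(genes, 2))
    keep <- runif(nrow(prs)) < 0.15
    ppi <- tibble::tibble(protein_a = prs[keep, 1], protein_b = prs[keep, 2],
                          score = runif(sum(keep), 0.2, 1))
    ann <- tibble::tibble(drug_id = c("d1", "d2"),
                          gene = sample(genes, 2))
    dti <- build_dti_matrix(ann, universe = genes)
    alpha <- runif(1, 0.2, 0.9)
    S <- oracle_norm_adjacency(ppi, genes)
    expect_equal(unclass(rwr_propagate(dti, ppi, alpha = alpha, tol = 1e-12)),
                 oracle_rwr(dti, S, alpha),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("output is finite, non-negative, and continuous toward alpha = 1", {
  w <- small_world()
  dti <- build_dti_matrix(w$targets, universe = w$genes$gene)
  out <- rwr_propagate(dti, w$ppi, alpha = 0.5)
  expect_true(all(is.finite(out)) && all(out >= 0))
  near <- rwr_propagate(dti, w$ppi, alpha = 0.999)
  expect_lt(max(abs(near - dti)), 1e-2)
})

test_that("hub removal deletes exactly the top-degree node set", {
  w <- small_world()
  dti <- build_dti_matrix(w$targets, universe = w$genes$gene)
  out <- rwr_propagate(dti, w$ppi, alpha = 0.5, variant = "hub_removed")
  # oracle: recompute the top ceil(5%) by unweighted degree, ties by id
  genes <- w$genes$gene
  deg <- setNames(rep(0, length(genes)), genes)
  tab <- table(c(w$ppi$protein_a, w$ppi$protein_b))
  deg[names(tab)] <- tab
  expected <- genes[order(-deg, genes)][seq_len(ceiling(0.05 * length(genes)))]
  expect_identical(sort(attr(out, "removed_hubs")), sort(expected))
  # removed hubs receive no propagated mass beyond their own restart
  non_target_hubs <- setdiff(expected, w$targets$gene)
  expect_true(all(out[, non_target_hubs] == 0))
})

test_that("degree-normalized variant runs and alpha is validated", {
  w <- small_world()
  dti <- build_dti_matrix(w$targets, universe = w$genes$gene)
  out <- rwr_propagate(dti, w$ppi, alpha = 0.5, variant = "degree_normalized")
  expect_true(all(is.finite(out)))
  expect_error(rwr_propagate(dti, w$ppi, alpha = 0), "alpha")
  expect_error(rwr_propagate(dti, w$ppi, alpha = 1.2), "alpha")
})
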