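# Marker-gene selection and mutation profiles.

test_that("identical sources yield that set with all four tags", {
  genes <- c("g1", "g2", "g3")
  expr <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, genes))
  ppi <- tibble::tibble(protein_a = c("g1", "g2"), protein_b = c("g2", "g3"),
                        score = c(0.9, 0.95))
  mk <- select_marker_genes(expr, landmark = genes, ppi = ppi,
                            dti_universe = genes, variable_frac = 1,
                            hub_n = 3)
  expect_equal(mk$gene, genes)
  expect_true(all(mk$landmark & mk$variable & mk$hub & mk$target))
})

test_that("the variable tier matches a direct variance sort on world expression", {
  w <- small_world()
  mk <- select_marker_genes(w$expression, variable_frac = 0.15, hub_n = 0,
                            ppi = NULL)
  v <- apply(w$expression, 2, var)
  oracle <- colnames(w$expression)[order(-v)][seq_len(ceiling(0.15 * ncol(w$expression)))]
  expect_setequal(mk$gene[mk$variable], oracle)
})

test_that("the hub rule selects the star center first", {
  expr <- matrix(rnorm(20), 2, 10,
                 dimnames = list(NULL, paste0("g", 1:10)))
  star <- tibble::tibble(protein_a = "g5", protein_b = paste0("g", c(1:4, 6:8)),
                         score = 0.9)
  mk <- select_marker_genes(expr, ppi = star, hub_n = 1, variable_frac = 0.1)
  expect_true(mk$hub[mk$gene == "g5"])
  expect_equal(sum(mk$hub), 1)
})

test_that("high-confidence filtering respects both score conventions", {
  expr <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("g", 1:4)))
  ppi01 <- tibble::tibble(protein_a = c("g1", "g3"), protein_b = c("g2", "g4"),
                          score = c(0.9, 0.3))
  mk <- select_marker_genes(expr, ppi = ppi01, hub_n = 10, variable_frac = 0.25)
  expect_setequal(mk$gene[mk$hub], c("g1", "g2"))
  ppi1000 <- ppi01; ppi1000$score <- c(900, 300)
  mk2 <- select_marker_genes(expr, ppi = ppi1000, hub_n = 10,
                             variable_frac = 0.25)
  expect_setequal(mk2$gene[mk2$hub], c("g1", "g2"))
})

test_that("marker selection is monotone in its sources", {
  w <- small_world()
  base <- select_marker_genes(w$expression, landmark = c("g001"),
                              ppi = w$ppi, dti_universe = c("g002"),
                              variable_frac = 0.1, hub_n = 5)
  grown <- select_marker_genes(w$expression, landmark = c("g001", "g011"),
                               ppi = w$ppi,
                               dti_universe = c("g002", "g015"),
                               variable_frac = 0.2, hub_n = 10)
  expect_true(all(base$gene %in% grown$gene))
})

test_that("degenerate inputs raise configuration errors", {
  expr1 <- matrix(rnorm(3), 1, 3, dimnames = list(NULL, paste0("g", 1:3)))
  expect_error(select_marker_genes(expr1), ">= 2 samples")
  expr0 <- matrix(numeric(0), 2, 0)
  expect_error(select_marker_genes(expr0), "empty")
})

test_that("mutation profiles binarize qualifying nonsynonymous classes", {
  calls <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2"),
    gene = c("g1", "g1", "g2", "g1", "g3"),
    variant_class = c("Missense_Mutation", "missense", "Silent",
                      "Frame_Shift_Ins", "Splice_Site"))
  m <- mutation_profile(calls, gene_set = c("g1", "g2", "g3"))
  expect_equal(m["s1", ], c(g1 = 1L, g2 = 0L, g3 = 0L))  # two hits still 1
  expect_equal(m["s2", ], c(g1 = 1L, g2 = 0L, g3 = 1L))
  # synonymous-only sample is all zero
  syn <- mutation_profile(
    tibble::tibble(sample_id = "s1", gene = "g1", variant_class = "Silent"),
    gene_set = c("g1", "g2"))
  expect_true(all(syn == 0))
  expect_warning(
    mutation_profile(tibble::tibble(sample_id = "s1", gene = "g1",
                                    variant_class = "weird_thing"),
                     gene_set = "g1"),
    "unrecognized")
})
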