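# The synthetic world: determinism, the planted synergy rule, and the
# expression generative model.

test_that("worlds are bit-identical for the same seed and differ across seeds", {
  cfg <- synth_config(n_pathways = 3, genes_per_pathway = 6, n_samples = 8,
                      n_drugs = 6, seed = 42)
  expect_identical(synth_world(cfg), synth_world(cfg))
  cfg2 <- synth_config(n_pathways = 3, genes_per_pathway = 6, n_samples = 8,
                       n_drugs = 6, seed = 43)
  expect_false(identical(synth_world(cfg)$expression,
                         synth_world(cfg2)$expression))
})

test_that("zero activity effect leaves expression uncorrelated with activity", {
  cfg <- synth_config(expr_activity_effect = 0, seed = 7)
  w <- synth_world(cfg)
  act_of_gene <- w$activity[, w$genes$pathway[match(colnames(w$expression),
                                                   w$genes$gene)]]
  expect_lt(abs(cor(as.vector(act_of_gene), as.vector(w$expression))), 0.05)
})

test_that("positive-triplet fraction matches exhaustive enumeration of the rule", {
  w <- default_world()
  # independent oracle: enumerate every (pair, sample) triple directly from
  # the pathway assignments and activity states
  pw <- setNames(w$drugs$pathway, w$drugs$drug_id)
  ids <- w$drugs$drug_id
  n_pos <- 0; n_tot <- 0
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    for (s in rownames(w$activity)) {
      n_tot <- n_tot + 1
      if (pw[ids[i]] != pw[ids[j]] &&
          w$activity[s, pw[ids[i]]] == 1 && w$activity[s, pw[ids[j]]] == 1) {
        n_pos <- n_pos + 1
      }
    }
  }
  tt <- synth_truth(w)
  expect_equal(mean(tt$label), n_pos / n_tot)
  # expected value under uniform pathway assignment and activity 0.5
  expect_lt(abs(mean(tt$label) - (11 / 12) * 0.25), 0.08)
})

test_that("planted truth is symmetric, non-negative, and targets stay in pathway", {
  w <- small_world()
  tt <- small_triplets()
  expect_true(all(tt$truth >= 0))
  expect_equal(
    synth_truth_strength(w, tt$drug_a[1:50], tt$drug_b[1:50], tt$sample_id[1:50]),
    synth_truth_strength(w, tt$drug_b[1:50], tt$drug_a[1:50], tt$sample_id[1:50]))
  joined <- merge(w$targets, w$drugs[, c("drug_id", "pathway")], by = "drug_id")
  gene_pw <- setNames(w$genes$pathway, w$genes$gene)
  expect_true(all(gene_pw[joined$gene] == joined$pathway))
})

test_that("expression separates active from inactive samples by the stated effect", {
  w <- default_world()
  cfg <- w$cfg
  for (pw in c("pw01", "pw07")) {
    genes <- w$genes$gene[w$genes$pathway == pw]
    act <- w$activity[, pw] == 1
    diff <- mean(w$expression[act, genes]) - mean(w$expression[!act, genes])
    tol <- 3 * cfg$expr_noise_sd / sqrt(cfg$genes_per_pathway)
    expect_lt(abs(diff - cfg$expr_activity_effect), tol)
  }
})

test_that("invalid configurations fail naming the violated invariant", {
  expect_error(synth_config(dose_grid = c(0.1, 1)), "dose_grid")
  expect_error(synth_config(dose_grid = c(0, 2, 1)), "dose_grid")
  expect_error(synth_config(ppi_p_within = 1.4), "ppi_p_within")
  expect_error(synth_config(synergy_bump_max = -2), "synergy_bump_max")
  expect_error(synth_config(targets_per_drug = 50), "targets_per_drug")
})

test_that("unknown ids raise lookup errors", {
  w <- small_world()
  expect_error(synth_truth_strength(w, "nope", "D02", "S01"), "unknown drug")
  expect_error(synth_block(w, "D01", "D02", "nope"), "unknown sample")
})

test_that("sentinel mutations copy pathway activity; default mutations do not", {
  cfg <- synth_config(n_pathways = 3, genes_per_pathway = 6, n_samples = 15,
                      n_drugs = 6, sentinel_mutations = TRUE, seed = 9)
  w <- synth_world(cfg)
  sentinel <- w$genes$gene[match(unique(w$genes$pathway), w$genes$pathway)]
  expect_equal(unname(w$mutation[, sentinel]), unname(w$activity))
  w0 <- synth_world(synth_config(n_pathways = 3, genes_per_pathway = 6,
                                 n_samples = 15, n_drugs = 6, seed = 9))
  expect_lt(mean(w0$mutation), 0.12)
})

test_that("world writers emit the standard flat files round-trippably", {
  w <- small_world()
  dir <- withr::local_tempdir()
  files <- write_synth_world(w, dir, n_triplets = 100)
  expect_true(all(file.exists(files)))
  smi <- read_smiles(file.path(dir, "drugs.smi"))
  expect_equal(smi$smiles, w$drugs$smiles)
  ppi <- read_ppi(file.path(dir, "ppi.tsv"))
  expect_equal(nrow(ppi), nrow(w$ppi))
  expect_true(all(ppi$score <= 1))
  expr <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(expr, w$expression, tolerance = 1e-8)
  expect_equal(nrow(read_triplets(file.path(dir, "triplets.csv"))), 100)
})
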