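# Synergy scoring under the four null models.

random_block <- function(seed, n = 4) {
  set.seed(seed)
  doses <- c(0, sort(10^runif(n - 1, -1, 1)))
  resp <- matrix(runif(n * n, 0, 95), n, n)
  resp[1, 1] <- 0
  dose_block("A", "B", "S", doses, doses, resp)
}

test_that("Bliss and HSA match a spreadsheet-style recomputation exactly", {
  for (seed in 1:20) {
    b <- random_block(seed)
    o <- oracle_bliss_hsa(b)
    expect_equal(bliss_excess(b), o$bliss, tolerance = 1e-9)
    expect_equal(hsa_excess(b), o$hsa, tolerance = 1e-9)
  }
})

test_that("closed-form single-well arithmetic is reproduced", {
  b <- dose_block("A", "B", "S", c(0, 1), c(0, 1),
                  matrix(c(0, 40, 30, 70), 2, 2))
  expect_equal(bliss_excess(b), 70 - (40 + 30 - 40 * 30 / 100))  # 12
  expect_equal(hsa_excess(b), 70 - 40)                           # 30
})

test_that("HSA excess equals its algebraic identity on the margins", {
  b <- random_block(31)
  ix <- 2:length(b$conc_a)
  obs <- b$response[ix, ix]
  marg <- outer(b$response[ix, 1], b$response[1, ix], pmax)
  expect_equal(hsa_excess(b), mean(obs) - mean(marg), tolerance = 1e-12)
})

test_that("a block observed exactly at the null expectation scores zero", {
  b <- bliss_null_block(c(80, 1, 1.5), c(90, 2, 2))
  expect_equal(bliss_excess(b), 0, tolerance = 1e-12)
  hb <- random_block(8)
  ix <- 2:length(hb$conc_a)
  hb$response[ix, ix] <- outer(hb$response[ix, 1], hb$response[1, ix], pmax)
  expect_equal(hsa_excess(hb), 0, tolerance = 1e-12)
})

test_that("Loewe sham combinations score near zero across random Hill draws", {
  set.seed(42)
  worst <- 0
  for (r in 1:50) {
    b <- sham_block(e_max = runif(1, 60, 100), ec50 = 10^runif(1, -0.5, 0.7),
                    h = runif(1, 0.8, 2.5))
    worst <- max(worst, abs(loewe_excess(b)))
  }
  expect_lt(worst, 1)
})

test_that("Loewe reduces to the active drug's curve when the partner is inert", {
  doses <- c(0, 10^seq(-1, 1, by = 0.5))
  ya <- 80 * doses^1.5 / (1 + doses^1.5)
  resp <- matrix(0, 6, 6)
  resp[, 1] <- ya
  for (j in 2:6) resp[, j] <- ya + 5   # observed above the single agent
  b <- dose_block("A", "B", "S", doses, doses, resp)
  fitA <- fit_hill(doses, ya)
  oracle <- mean(resp[2:6, 2:6] - hill_predict(fitA, doses[2:6]))
  expect_equal(loewe_excess(b), oracle, tolerance = 0.2)
})

test_that("observations below both margins give negative Loewe excess", {
  b <- bliss_null_block(c(85, 1, 1.5), c(75, 2, 1.2))
  ix <- 2:6
  low <- pmin(outer(b$response[ix, 1], rep(1, 5)),
              outer(rep(1, 5), b$response[1, ix])) * 0.5
  b$response[ix, ix] <- low
  expect_lt(loewe_excess(b), 0)
})

test_that("ZIP is near zero on zero-interaction blocks and tracks uniform shifts", {
  b0 <- bliss_null_block(c(85, 1, 1.5), c(90, 2, 1.2))
  expect_lt(abs(zip_delta(b0)), 0.5)
  b10 <- bliss_null_block(c(85, 1, 1.5), c(90, 2, 1.2), shift = 10)
  expect_equal(zip_delta(b10), 10, tolerance = 1)
  inert <- dose_block("A", "B", "S", b0$conc_a, b0$conc_b, matrix(0, 6, 6))
  expect_equal(zip_delta(inert), 0, tolerance = 1e-8)
})

test_that("adding a constant to interior wells shifts every score by that constant", {
  b <- bliss_null_block(c(80, 1.5, 1.3), c(88, 2.5, 1.8))
  ix <- 2:6
  b2 <- b
  b2$response[ix, ix] <- b2$response[ix, ix] + 7
  expect_equal(bliss_excess(b2) - bliss_excess(b), 7, tolerance = 1e-12)
  expect_equal(hsa_excess(b2) - hsa_excess(b), 7, tolerance = 1e-12)
  expect_equal(loewe_excess(b2) - loewe_excess(b), 7, tolerance = 0.5)
  expect_equal(zip_delta(b2) - zip_delta(b), 7, tolerance = 0.5)
})

test_that("all scores are invariant under transposing the block", {
  b <- random_block(13)
  tb <- combisyn:::transpose_block(b)
  expect_equal(bliss_excess(b), bliss_excess(tb), tolerance = 1e-12)
  expect_equal(hsa_excess(b), hsa_excess(tb), tolerance = 1e-12)
  expect_equal(loewe_excess(b), loewe_excess(tb), tolerance = 1e-6)
  expect_equal(zip_delta(b), zip_delta(tb), tolerance = 1e-6)
})

test_that("binarization follows the strict Loewe > 0 rule", {
  expect_equal(binarize_synergy(c(3.2, -1.0, 0.0, 1e-9)), c(1L, 0L, 0L, 1L))
})

test_that("score_block canonicalizes the drug pair", {
  w <- small_world()
  b <- synth_block(w, "D05", "D02", "S03", noise_sd = 0)
  rec <- score_block(b)
  expect_equal(rec$drug_a, "D02")
  expect_equal(rec$drug_b, "D05")
  rec2 <- score_block(synth_block(w, "D02", "D05", "S03", noise_sd = 0))
  expect_equal(rec, rec2, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(attr(rec, "zip_method"), "conditional")
})

test_that("Loewe scores rank planted synergy far above null blocks", {
  w <- default_world()
  tt <- synth_truth(w)
  set.seed(3)
  rows <- dplyr::bind_rows(
    tt[tt$truth > 0, ][sample(sum(tt$truth > 0), 15), ],
    tt[tt$truth == 0, ][sample(sum(tt$truth == 0), 15), ])
  recs <- purrr::map_dfr(seq_len(nrow(rows)), function(k) {
    score_block(synth_block(w, rows$drug_a[k], rows$drug_b[k],
                            rows$sample_id[k], noise_sd = 3, seed = k))
  })
  key_rows <- paste(pmin(rows$drug_a, rows$drug_b),
                    pmax(rows$drug_a, rows$drug_b), rows$sample_id)
  key_recs <- paste(recs$drug_a, recs$drug_b, recs$sample_id)
  truth <- rows$label[match(key_recs, key_rows)]
  expect_gte(metric_auroc(truth, recs$score_loewe), 0.95)
  expect_gte(metric_auroc(truth, recs$score_bliss), 0.95)
})

test_that("duplicate records average scores and recompute the label", {
  rec <- function(lo) tibble::tibble(drug_a = "B", drug_b = "A",
                                     sample_id = "S", score_loewe = lo,
                                     score_bliss = lo, score_hsa = lo,
                                     score_zip = lo, label = as.integer(lo > 0))
  two <- dplyr::bind_rows(rec(4), rec(-2))
  out <- average_duplicates(two)
  expect_equal(nrow(out), 1)
  expect_equal(out$drug_a, "A")  # canonicalized
  expect_equal(out$score_loewe, 1)
  expect_equal(out$label, 1L)
  tie <- average_duplicates(dplyr::bind_rows(rec(2), rec(-2)))
  expect_equal(tie$score_loewe, 0)
  expect_equal(tie$label, 0L)
  single <- average_duplicates(rec(3))
  expect_equal(single$score_loewe, 3)
})

test_that("long-format blocks round-trip and score in batch", {
  w <- small_world()
  b1 <- synth_block(w, "D01", "D04", "S02", noise_sd = 0)
  b2 <- synth_block(w, "D02", "D03", "S01", noise_sd = 0)
  wells <- dplyr::bind_rows(block_to_long(b1), block_to_long(b2))
  back <- blocks_from_long(wells)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$response,
               blocks_from_long(wells)[[1]]$response)
  recs <- score_blocks(wells)
  expect_equal(nrow(recs), 2)
  expect_true(all(c("score_loewe", "score_bliss", "score_hsa", "score_zip",
                    "label") %in% names(recs)))
})
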