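# Dose-response generation: additivity by construction, the planted bump,
# and exponential survival times.

test_that("without synergy and noise every combination well is its Bliss expectation", {
  w <- small_world()
  tt <- small_triplets()
  neg <- tt[tt$truth == 0, ][1, ]
  b <- synth_block(w, neg$drug_a, neg$drug_b, neg$sample_id, noise_sd = 0)
  ya <- b$response[, 1]; yb <- b$response[1, ]
  expect_equal(b$response, outer(ya, yb, function(u, v) u + v - u * v / 100),
               tolerance = 1e-12)
})

test_that("dose-0 margins are pure monotherapy of the other drug", {
  w <- small_world()
  b <- synth_block(w, "D01", "D02", "S01", noise_sd = 0)
  expect_equal(b$response[1, 1], 0)
  # column margin is monotone nondecreasing monotherapy
  expect_true(all(diff(b$response[, 1]) >= 0))
  expect_true(all(diff(b$response[1, ]) >= 0))
})

test_that("the central well of a planted-synergy block carries the full bump", {
  w <- default_world()
  tt <- synth_truth(w)
  pos <- tt[tt$truth > 0, ]
  for (k in c(1, 25, 111)) {
    b <- synth_block(w, pos$drug_a[k], pos$drug_b[k], pos$sample_id[k],
                     noise_sd = 0)
    ci <- central_dose_index(b$conc_a)
    ya <- b$response[ci, 1]; yb <- b$response[1, ci]
    excess <- b$response[ci, ci] - (ya + yb - ya * yb / 100)
    expect_equal(excess, w$cfg$synergy_bump_max, tolerance = 1e-8)
  }
})

test_that("mean Bliss excess matches direct evaluation of the generative kernel", {
  w <- default_world()
  tt <- synth_truth(w)
  pos <- tt[tt$truth > 0, ][7, ]
  b <- synth_block(w, pos$drug_a, pos$drug_b, pos$sample_id, noise_sd = 0)
  # oracle: rebuild the surface from the formula (Bliss of margins + bump,
  # clipped) and average the observed-minus-expected interior wells
  m <- length(b$conc_a)
  w_k <- pmax(0, 1 - abs((0:(m - 1)) - ceiling((m - 1) / 2)) / ceiling((m - 1) / 2))
  ya <- b$response[, 1]; yb <- b$response[1, ]
  bliss <- outer(ya, yb, function(u, v) u + v - u * v / 100)
  bump <- pos$truth * outer(w_k, w_k)
  expected_surface <- pmin(pmax(bliss + bump, 0), 100)
  expected_surface[1, ] <- yb; expected_surface[, 1] <- ya
  oracle <- mean((expected_surface - bliss)[2:m, 2:m])
  expect_equal(bliss_excess(b), oracle, tolerance = 1e-8)
})

test_that("noiseless central-well Bliss excess thresholded at bump/2 recovers truth", {
  w <- default_world()
  tt <- synth_truth(w)
  set.seed(5)
  rows <- tt[sample(nrow(tt), 60), ]
  ci <- central_dose_index(w$cfg$dose_grid)
  calls <- vapply(seq_len(nrow(rows)), function(k) {
    b <- synth_block(w, rows$drug_a[k], rows$drug_b[k], rows$sample_id[k],
                     noise_sd = 0)
    ya <- b$response[ci, 1]; yb <- b$response[1, ci]
    (b$response[ci, ci] - (ya + yb - ya * yb / 100)) > w$cfg$synergy_bump_max / 2
  }, logical(1))
  expect_equal(as.integer(calls), rows$label)
})

test_that("block generation is reproducible and responses stay in [0, 100]", {
  w <- small_world()
  b1 <- synth_block(w, "D03", "D07", "S05", noise_sd = 3, seed = 4)
  b2 <- synth_block(w, "D03", "D07", "S05", noise_sd = 3, seed = 4)
  expect_identical(b1, b2)
  expect_true(all(b1$response >= 0 & b1$response <= 100))
})

test_that("survival generation separates groups by hazard ratio", {
  g <- tibble::tibble(sample_id = sprintf("P%03d", 1:400),
                      group = rep(c("lo", "hi"), each = 200))
  # under the null the log-rank test is non-significant in >= 90% of seeds
  p_null <- vapply(1:100, function(s) {
    logrank_compare(g, synth_survival(g, hazard_ratio = 1, seed = s))$p_value
  }, numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)
  # hazard ratio 3 with 200 per group is detected in >= 95% of seeds
  p_alt <- vapply(1:100, function(s) {
    logrank_compare(g, synth_survival(g, hazard_ratio = 3, seed = s))$p_value
  }, numeric(1))
  expect_gte(mean(p_alt < 0.05), 0.95)
})

test_that("survival generator validates inputs and stays reproducible", {
  g <- tibble::tibble(sample_id = c("a", "b"), group = c("x", "y"))
  expect_error(synth_survival(g, hazard_ratio = 0), "positive")
  expect_error(synth_survival(g, hazard_ratio = -1), "positive")
  one <- synth_survival(g, hazard_ratio = 2, seed = 3)
  expect_identical(one, synth_survival(g, hazard_ratio = 2, seed = 3))
  expect_equal(nrow(one), 2)
  # downstream comparison reports insufficient data for single-sample groups
  no_event <- one; no_event$event <- c(1L, 0L)
  expect_error(logrank_compare(g, no_event), "insufficient")
})
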