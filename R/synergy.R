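# Synergy scoring: excess % inhibition over four null models (Bliss, HSA,
# Loewe, ZIP), computed from first principles on a dose-response checkerboard.
# Every score is the MEAN excess over the interior (both-drugs-dosed) wells,
# making scores grid-size independent.

interior_idx <- function(block) {
  list(i = seq_along(block$conc_a)[-1], j = seq_along(block$conc_b)[-1])
}

check_block <- function(block) {
  if (!inherits(block, "dose_block")) {
    stopf("combisyn_input_error", "expected a dose_block object")
  }
  invisible(block)
}

#' Synergy scores of a dose-response block
#'
#' `bliss_excess()` compares each interior well against the Bliss independence
#' expectation `yA + yB - yA*yB/100` of the *observed* monotherapy margins;
#' `hsa_excess()` against the highest single agent `max(yA, yB)`;
#' `loewe_excess()` against the dose-additivity expectation solving
#' `d1/DA(y) + d2/DB(y) = 1` on fitted Hill curves (bisection, tolerance 1e-6,
#' HSA fallback for wells where the equation has no root in range); and
#' `zip_delta()` fits conditional Hill curves along each row and column
#' (baseline pinned to the fitted monotherapy of the co-drug) and compares the
#' mean conditional fitted value against the Bliss surface of the fitted
#' monotherapies. All return the mean excess (% inhibition) over interior
#' wells and are invariant under transposing the block.
#'
#' @param block A [dose_block()].
#' @return A single numeric score (excess % inhibition).
#' @export
#' @examples
#' b <- dose_block("A", "B", "S", c(0, 1, 10), c(0, 1, 10),
#'                 matrix(c(0, 40, 60, 30, 70, 80, 50, 85, 95), 3, 3))
#' bliss_excess(b)
#' hsa_excess(b)
bliss_excess <- function(block) {
  check_block(block)
  ix <- interior_idx(block)
  ya <- block$response[ix$i, 1]
  yb <- block$response[1, ix$j]
  expected <- outer(ya, yb, function(u, v) u + v - u * v / 100)
  mean(block$response[ix$i, ix$j, drop = FALSE] - expected)
}

#' @rdname bliss_excess
#' @export
hsa_excess <- function(block) {
  check_block(block)
  ix <- interior_idx(block)
  ya <- block$response[ix$i, 1]
  yb <- block$response[1, ix$j]
  expected <- outer(ya, yb, pmax)
  mean(block$response[ix$i, ix$j, drop = FALSE] - expected)
}

# Monotherapy fits of both margins; loewe/zip prerequisites.
fit_margins <- function(block) {
  fa <- tryCatch(fit_hill(block$conc_a, block$response[, 1]),
                 error = function(e) NULL)
  fb <- tryCatch(fit_hill(block$conc_b, block$response[1, ]),
                 error = function(e) NULL)
  if (is.null(fa) && is.null(fb)) {
    stopf("combisyn_scoring_error",
          "both monotherapy fits failed for block %s + %s in %s",
          block$drug_a, block$drug_b, block$sample_id)
  }
  list(a = fa, b = fb)
}

# Loewe expected response at one interior well; HSA fallback when the
# dose-equivalence equation has no root in (0, min(e_max)).
loewe_expected_well <- function(d1, d2, fa, fb, hsa, tol = 1e-6, max_iter = 100) {
  inert_a <- is.null(fa) || fa$e_max <= 1e-6
  inert_b <- is.null(fb) || fb$e_max <= 1e-6
  if (inert_a && inert_b) return(0)
  if (inert_a) return(hill_predict(fb, d2))
  if (inert_b) return(hill_predict(fa, d1))
  hi <- min(fa$e_max, fb$e_max) * (1 - 1e-9)
  f <- function(y) d1 / hill_inverse(fa, y) + d2 / hill_inverse(fb, y) - 1
  lo <- hi * 1e-9
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo < 0 || fhi > 0) {
    # no root in range: below-additivity doses (flo < 0) or a combination
    # beyond both plateaus (fhi > 0) -> fall back to the HSA expectation
    if (is.finite(fhi) && fhi > 0) return(hsa)
    if (is.finite(flo) && flo < 0) return(0)
    return(hsa)
  }
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' @rdname bliss_excess
#' @export
loewe_excess <- function(block) {
  check_block(block)
  fits <- fit_margins(block)
  ix <- interior_idx(block)
  ya <- block$response[ix$i, 1]
  yb <- block$response[1, ix$j]
  obs <- block$response[ix$i, ix$j, drop = FALSE]
  expected <- matrix(NA_real_, length(ix$i), length(ix$j))
  for (r in seq_along(ix$i)) {
    for (c in seq_along(ix$j)) {
      hsa <- max(ya[r], yb[c])
      expected[r, c] <- loewe_expected_well(
        block$conc_a[ix$i[r]], block$conc_b[ix$j[c]], fits$a, fits$b, hsa)
    }
  }
  mean(obs - expected)
}

# Conditional Hill fit of one response series with a pinned baseline; returns
# fitted values at `doses`, or the observed values when the fit fails.
zip_conditional_fitted <- function(doses, responses, baseline) {
  fit <- tryCatch(fit_hill(doses, responses, baseline_fixed = baseline),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(responses[doses > 0])
  hill_predict(fit, doses[doses > 0])
}

#' @rdname bliss_excess
#' @export
zip_delta <- function(block) {
  check_block(block)
  fits <- fit_margins(block)
  if (is.null(fits$a) || is.null(fits$b)) {
    stopf("combisyn_scoring_error",
          "ZIP needs both monotherapy fits for block %s + %s in %s",
          block$drug_a, block$drug_b, block$sample_id)
  }
  ix <- interior_idx(block)
  ni <- length(ix$i); nj <- length(ix$j)
  ya_hat <- hill_predict(fits$a, block$conc_a[ix$i])
  yb_hat <- hill_predict(fits$b, block$conc_b[ix$j])
  bliss_fit <- outer(ya_hat, yb_hat, function(u, v) u + v - u * v / 100)

  # columns: response vs conc_a at fixed conc_b, baseline = fitted yB(conc_b)
  fit_cols <- matrix(NA_real_, ni, nj)
  for (c in seq_len(nj)) {
    fit_cols[, c] <- zip_conditional_fitted(
      block$conc_a, block$response[, ix$j[c]], yb_hat[c])
  }
  # rows: response vs conc_b at fixed conc_a, baseline = fitted yA(conc_a)
  fit_rows <- matrix(NA_real_, ni, nj)
  for (r in seq_len(ni)) {
    fit_rows[r, ] <- zip_conditional_fitted(
      block$conc_b, block$response[ix$i[r], ], ya_hat[r])
  }
  mean((fit_cols + fit_rows) / 2 - bliss_fit)
}

#' Score one block under all four null models
#'
#' Computes Bliss, HSA, Loewe and ZIP excess scores, canonicalizes the drug
#' pair (lexicographic order, transposing the response matrix as needed) and
#' attaches the binary synergy label `label = 1` iff the Loewe excess is
#' strictly greater than 0 (exactly 0 is non-synergistic).
#'
#' @param block A [dose_block()].
#' @return A one-row tibble (`drug_a`, `drug_b`, `sample_id`, `score_loewe`,
#'   `score_bliss`, `score_hsa`, `score_zip`, `label`) with attribute
#'   `zip_method = "conditional"`.
#' @export
score_block <- function(block) {
  check_block(block)
  if (block$drug_a > block$drug_b) block <- transpose_block(block)
  rec <- tibble(
    drug_a = block$drug_a,
    drug_b = block$drug_b,
    sample_id = block$sample_id,
    score_loewe = loewe_excess(block),
    score_bliss = bliss_excess(block),
    score_hsa = hsa_excess(block),
    score_zip = zip_delta(block)
  )
  rec$label <- binarize_synergy(rec$score_loewe)
  attr(rec, "zip_method") <- "conditional"
  rec
}

#' @rdname score_block
#' @param score_loewe Numeric Loewe excess score(s).
#' @export
binarize_synergy <- function(score_loewe) {
  as.integer(score_loewe > 0)
}

#' Score a batch of blocks given as a long well table
#'
#' @param wells Long-format well table (see [block_to_long()]).
#' @param viability Convert % viability to % inhibition first.
#' @return Tibble of synergy records, duplicates averaged.
#' @export
score_blocks <- function(wells, viability = FALSE) {
  blocks <- blocks_from_long(wells, viability = viability)
  recs <- purrr::map_dfr(blocks, score_block)
  average_duplicates(recs)
}

#' Average duplicate synergy records
#'
#' Records sharing the canonical `(drug_a, drug_b, sample_id)` key collapse to
#' one record with arithmetic-mean scores; the label is recomputed from the
#' averaged Loewe score.
#'
#' @param records Tibble of synergy records (as from [score_block()]).
#' @return Tibble with one row per canonical triplet.
#' @export
average_duplicates <- function(records) {
  if (nrow(records) == 0) return(records)
  cp <- canonical_pair(records$drug_a, records$drug_b)
  records$drug_a <- cp$a
  records$drug_b <- cp$b
  score_cols <- intersect(
    c("score_loewe", "score_bliss", "score_hsa", "score_zip"), names(records))
  out <- records |>
    group_by(.data$drug_a, .data$drug_b, .data$sample_id) |>
    summarise(dplyr::across(dplyr::all_of(score_cols), mean), .groups = "drop")
  if ("score_loewe" %in% names(out)) {
    out$label <- binarize_synergy(out$score_loewe)
  } else if ("label" %in% names(records)) {
    lab <- records |>
      group_by(.data$drug_a, .data$drug_b, .data$sample_id) |>
      summarise(label = as.integer(mean(.data$label) > 0.5), .groups = "drop")
    out <- left_join(out, lab, by = c("drug_a", "drug_b", "sample_id"))
  }
  arrange(out, .data$drug_a, .data$drug_b, .data$sample_id)
}
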