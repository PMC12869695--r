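# Drug identity resolution and triplet-table assembly: collapse structural
# synonyms by fingerprint identity, canonicalize pair order, average
# duplicates, and report (never abort on) unresolvable rows.

#' Assemble a harmonized triplet table
#'
#' Resolves each drug id in `records` through the fingerprint library:
#' ids whose structures are bit-identical (Tanimoto exactly 1) are merged to
#' the lexicographically smallest id of the group; near-matches (similarity
#' `>= near_threshold` but < 1) are listed in the report for manual review,
#' not merged. Rows referencing unresolvable drugs or unknown samples are
#' dropped and counted. Pair order is canonicalized and duplicate triplets
#' are averaged via [average_duplicates()]. The operation is idempotent.
#'
#' @param records Tibble with columns `drug_a`, `drug_b`, `sample_id` and any
#'   score columns (`score_loewe`, `score_bliss`, ...).
#' @param drug_library A [fingerprint_library()] tibble mapping `drug_id` to
#'   fingerprints.
#' @param sample_library Character vector of valid sample ids (`NULL` skips
#'   the sample check).
#' @param near_threshold Similarity from which near-matches are reported.
#' @return A list with `triplets` (the harmonized table) and `report` (counts
#'   plus a `near_matches` tibble).
#' @export
assemble_triplets <- function(records, drug_library, sample_library = NULL,
                              near_threshold = 0.95) {
  n_in <- nrow(records)
  syn <- synonym_map(drug_library)
  canon <- syn$map

  near <- syn$near
  near <- near[near$similarity >= near_threshold & near$similarity < 1, ,
               drop = FALSE]

  if (n_in == 0) {
    return(list(
      triplets = records,
      report = list(n_input = 0L, n_output = 0L, n_dropped_drug = 0L,
                    n_dropped_sample = 0L, n_duplicates_merged = 0L,
                    near_matches = near)))
  }

  ka <- canon[records$drug_a]
  kb <- canon[records$drug_b]
  drug_ok <- !is.na(ka) & !is.na(kb)
  sample_ok <- if (is.null(sample_library)) rep(TRUE, n_in) else
    records$sample_id %in% sample_library
  keep <- drug_ok & sample_ok

  out <- records[keep, , drop = FALSE]
  out$drug_a <- unname(ka[keep])
  out$drug_b <- unname(kb[keep])
  out <- average_duplicates(out)

  list(
    triplets = out,
    report = list(
      n_input = n_in,
      n_output = nrow(out),
      n_dropped_drug = sum(!drug_ok),
      n_dropped_sample = sum(drug_ok & !sample_ok),
      n_duplicates_merged = sum(keep) - nrow(out),
      near_matches = near
    )
  )
}

# Map every library id to the lexicographically smallest id sharing an
# identical fingerprint; also return the pairwise near-match table.
synonym_map <- function(drug_library) {
  ids <- drug_library$drug_id
  sig <- vapply(drug_library$fp, function(f) paste(f$bits, collapse = ","),
                character(1))
  canon <- stats::ave(ids, sig, FUN = function(x) min(x))
  names(canon) <- ids

  near <- tibble(drug_a = character(), drug_b = character(),
                 similarity = numeric())
  if (length(ids) > 1) {
    prs <- combn(seq_along(ids), 2)
    sims <- vapply(seq_len(ncol(prs)), function(k) {
      tanimoto(drug_library$fp[[prs[1, k]]], drug_library$fp[[prs[2, k]]])
    }, numeric(1))
    near <- tibble(drug_a = ids[prs[1, ]], drug_b = ids[prs[2, ]],
                   similarity = sims)
  }
  list(map = canon, near = near)
}
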